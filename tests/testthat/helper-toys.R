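# Toy fixtures are generated in code; callers set the RNG seed.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Random locus with a planted plus-strand site cutting at cut_a and a
# minus-strand site cutting at cut_b (PAMs point into [cut_a, cut_b)).
plant_pair <- function(len = 260, cut_a = 100, cut_b = 180, name = "toy") {
  seq <- rand_dna(len)
  substr(seq, cut_a + 4, cut_a + 6) <- "TGG"   # + site PAM at [cut_a+3, cut_a+6)
  substr(seq, cut_b - 5, cut_b - 3) <- "CCA"   # - site PAM at [cut_b-6, cut_b-3)
  loc <- locus(name, seq)
  list(locus = loc,
       site_a = spacer_site(loc, cut_a - 17, "+"),
       site_b = spacer_site(loc, cut_b - 3, "-"))
}

# Random locus with one planted site cutting at `cut`.
plant_single <- function(len = 80, cut = 30, strand = "+", name = "toy") {
  seq <- rand_dna(len)
  if (strand == "+") {
    substr(seq, cut + 4, cut + 6) <- "TGG"
    loc <- locus(name, seq)
    site <- spacer_site(loc, cut - 17, "+")
  } else {
    substr(seq, cut - 5, cut - 3) <- "CCA"
    loc <- locus(name, seq)
    site <- spacer_site(loc, cut - 3, "-")
  }
  list(locus = loc, site = site)
}

# Point mutations on plain strings, 0-based coordinates.
mut_sub <- function(seq, pos0, base = NULL) {
  old <- substr(seq, pos0 + 1, pos0 + 1)
  if (is.null(base)) base <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  substr(seq, pos0 + 1, pos0 + 1) <- base
  seq
}
mut_ins <- function(seq, pos0, insert) {
  paste0(substr(seq, 1, pos0), insert, substr(seq, pos0 + 1, nchar(seq)))
}
mut_del <- function(seq, pos0, len) {
  paste0(substr(seq, 1, pos0), substr(seq, pos0 + len + 1, nchar(seq)))
}

# Independent Gotoh global alignment score (gap of length L costs
# open + L * ext), used as an oracle against the package's aligner.
nw_affine_score <- function(a, b, match = 2, mismatch = -4,
                            gap_open = 12, gap_ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in 2:(m + 1)) {
    E[1, j] <- max(E[1, j - 1] - gap_ext, H[1, j - 1] - gap_open - gap_ext)
    H[1, j] <- E[1, j]
  }
  for (i in 2:(n + 1)) {
    F[i, 1] <- max(F[i - 1, 1] - gap_ext, H[i - 1, 1] - gap_open - gap_ext)
    H[i, 1] <- F[i, 1]
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_ext, H[i, j - 1] - gap_open - gap_ext)
      F[i, j] <- max(F[i - 1, j] - gap_ext, H[i - 1, j] - gap_open - gap_ext)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  H[n + 1, m + 1]
}

# Independent reverse complement (chartr + reversal), oracle for revcomp().
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}
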