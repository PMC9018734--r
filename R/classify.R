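#' Read merged amplicon reads from FASTQ
#'
#' @param path FASTQ file (optionally gzip-compressed). Reads are assumed
#'   pre-merged single-end amplicons; base qualities are dropped (the
#'   classifier is quality-agnostic).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write reads to FASTQ with a constant quality placeholder
#'
#' @param reads Named character vector of sequences.
#' @param path Output path.
#' @param qual_char Single Phred+33 quality character applied to every base
#'   (default `"?"`, Q30).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, qual_char = "?") {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  lines <- character(4L * length(reads))
  if (length(reads)) {
    lines[seq(1, by = 4, length.out = length(reads))] <- paste0("@", ids)
    lines[seq(2, by = 4, length.out = length(reads))] <- reads
    lines[seq(3, by = 4, length.out = length(reads))] <- "+"
    lines[seq(4, by = 4, length.out = length(reads))] <-
      vapply(nchar(reads), function(n) strrep(qual_char, n), character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Demultiplex reads by exact barcode prefix
#'
#' Assigns each read to the sample whose `barcode` (plus optional `primer`)
#' exactly prefixes the read, then trims that prefix. Reads matching no
#' barcode are discarded and counted; the policy is exact matching, so a
#' single barcode mismatch discards the read.
#'
#' @param reads Named character vector of read sequences.
#' @param barcodes `data.frame` with columns `sample`, `barcode` and
#'   optionally `primer`.
#' @return List with `samples` (named list of trimmed read vectors),
#'   `n_unassigned` and `unassigned_ids`.
#' @export
demultiplex_reads <- function(reads, barcodes) {
  stopifnot(is.data.frame(barcodes), all(c("sample", "barcode") %in% names(barcodes)))
  if (anyDuplicated(barcodes$barcode))
    stop("duplicate barcodes in the sample table")
  primer <- if ("primer" %in% names(barcodes)) barcodes$primer else ""
  prefix <- paste0(toupper(barcodes$barcode), toupper(primer))
  assigned <- rep(NA_integer_, length(reads))
  for (i in seq_along(prefix)) {
    hit <- is.na(assigned) & startsWith(reads, prefix[i])
    assigned[hit] <- i
  }
  samples <- lapply(seq_along(prefix), function(i) {
    sel <- which(assigned == i)
    substr(reads[sel], nchar(prefix[i]) + 1L, nchar(reads[sel]))
  })
  names(samples) <- barcodes$sample
  list(samples = samples,
       n_unassigned = sum(is.na(assigned)),
       unassigned_ids = names(reads)[is.na(assigned)])
}

# Indel operations from the aligner's insertion/deletion ranges. The
# aligner reports insertion runs in 1-based subject (reference) coordinates
# and deletion runs in 1-based pattern (read) coordinates; both are
# converted to the 0-based reference coordinate of the operation: the ref
# base count before an inserted run, or the first deleted ref base. Read
# coordinates are mapped through the cumulative widths of preceding
# insertions and deletions (both range sets are position-ordered).
ops_from_ranges <- function(ins, del) {
  is <- BiocGenerics::start(ins); iw <- BiocGenerics::width(ins)
  ds <- BiocGenerics::start(del); dw <- BiocGenerics::width(del)
  ni <- length(is); nd <- length(ds)
  del_pos <- integer(nd)
  i <- 1L; I <- 0L; D <- 0L
  for (d in seq_len(nd)) {
    repeat {
      cand <- (ds[d] - 1L) - I + D
      if (i <= ni && (is[i] - 1L) <= cand) { I <- I + iw[i]; i <- i + 1L }
      else break
    }
    del_pos[d] <- (ds[d] - 1L) - I + D
    D <- D + dw[d]
  }
  out <- list()
  if (ni) out$ins <- data.frame(pos = is - 1L, type = "ins", len = iw)
  if (nd) out$del <- data.frame(pos = del_pos, type = "del", len = dw)
  if (length(out) == 0L)
    data.frame(pos = integer(0), type = character(0), len = integer(0))
  else do.call(rbind, out)
}

# Same operation extraction from a pair of gapped alignment strings
# (pattern = read, subject = reference); used as an independent check of
# the range-based extraction.
ops_from_gapped <- function(p, s) {
  sg <- gregexpr("-", s, fixed = TRUE)[[1]]
  sgap_pos <- if (sg[1] == -1L) integer(0) else as.integer(sg)
  refpos0 <- function(col) (col - 1L) - vapply(col, function(a)
    sum(sgap_pos < a), integer(1))
  out <- list()
  ins <- gregexpr("-+", s)[[1]]
  if (ins[1] != -1L)
    out$ins <- data.frame(pos = refpos0(as.integer(ins)), type = "ins",
                          len = attr(ins, "match.length"))
  del <- gregexpr("-+", p)[[1]]
  if (del[1] != -1L)
    out$del <- data.frame(pos = refpos0(as.integer(del)), type = "del",
                          len = attr(del, "match.length"))
  if (length(out) == 0L)
    data.frame(pos = integer(0), type = character(0), len = integer(0))
  else do.call(rbind, out)
}

op_in_window <- function(ops, lo, hi) {
  # insertion point inside [lo, hi]; deletion run overlapping [lo, hi)
  if (nrow(ops) == 0L) return(logical(0))
  ifelse(ops$type == "ins",
         ops$pos >= lo & ops$pos <= hi,
         ops$pos < hi & (ops$pos + ops$len) > lo)
}

op_breaks_interval <- function(ops, s, e) {
  # does any op destroy sequence inside [s, e)? insertions at the interval
  # boundaries leave the interval content intact
  if (nrow(ops) == 0L) return(FALSE)
  any(ifelse(ops$type == "ins",
             ops$pos > s & ops$pos < e,
             ops$pos < e & (ops$pos + ops$len) > s))
}

#' Classify amplicon reads into prime-editing outcome classes
#'
#' Aligns each read globally (affine gap penalties) to the wild-type
#' reference(s) and the predicted accurate-edit allele, then assigns one of
#' the outcome classes `UNEDITED`, `ACCURATE_EDIT`, `EDIT_WITH_INDEL`,
#' `PURE_INDEL` or `DISCARDED`:
#'
#' * the better-scoring reference is taken; an exact score tie is broken by
#'   presence of the exact edit string spanning the junction, and discarded
#'   if that cannot disambiguate;
#' * the edit is "detected" when the exact edit plus `junction_flank` nt of
#'   flanking context occurs in the read, or the read aligns to the edited
#'   allele with no indel disrupting the edit interval;
#' * only indel operations inside the quantification window (`window` nt
#'   around the cut positions / edit junction) count; substitutions alone
#'   never change the class (sequencing-error tolerance).
#'
#' @param reads Named character vector of merged reads (or a path handled
#'   by [read_fastq()] upstream).
#' @param alleles A [predict_alleles()] result for the design being
#'   quantified.
#' @param window Quantification half-window in nt around each cut/junction
#'   (default 20).
#' @param junction_flank Flanking context length for the exact-edit string
#'   check (default 6 nt).
#' @param read_len_bounds Length bounds; reads outside are `DISCARDED`.
#' @param scoring Alignment scoring: match, mismatch, gap open, gap extend.
#' @return `data.frame` with one row per read: `read_id`, `class`,
#'   `aligned_to` (`"wt"`/`"edited"`), `ref`, `score`, `edit_distance`,
#'   `n_indel_ops`, `indel_ops` (CIGAR-like `pos:type:len` string). The
#'   quantification window is attached as attribute `"window"`.
#' @export
classify_reads <- function(reads, alleles, window = 20L, junction_flank = 6L,
                           read_len_bounds = c(20, Inf),
                           scoring = list(match = 2, mismatch = -4,
                                          gap_open = 12, gap_ext = 2)) {
  stopifnot(inherits(alleles, "wtpe_alleles"))
  reads <- toupper(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  n <- length(reads)

  refs <- c(alleles$wt_refs, setNames(alleles$accurate_ref, ".edited"))
  kind <- c(rep("wt", length(alleles$wt_refs)), "edited")
  js <- alleles$junction_interval[1]; je <- alleles$junction_interval[2]
  e_len <- je - js
  windows <- c(
    lapply(alleles$wt_cuts, function(cc)
      cbind(lo = cc - window, hi = cc + window)),
    list(.edited = cbind(lo = js - window, hi = je + window))
  )
  acc_len <- nchar(alleles$accurate_ref)
  probe <- if (e_len > 0)
    substr0(alleles$accurate_ref, max(0L, js - junction_flank),
            min(acc_len, je + junction_flank))
  else ""

  ok <- !is.na(reads) & nchar(reads) >= read_len_bounds[1] &
    nchar(reads) <= read_len_bounds[2] & grepl("^[ACGTN]+$", reads)
  res <- data.frame(read_id = ids, class = "DISCARDED",
                    aligned_to = NA_character_, ref = NA_character_,
                    score = NA_real_, edit_distance = NA_integer_,
                    n_indel_ops = NA_integer_, indel_ops = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
    pat <- Biostrings::DNAStringSet(reads[ok])
    alns <- lapply(refs, function(r)
      Biostrings::pairwiseAlignment(pat, r, type = "global",
                                    substitutionMatrix = sub_mat,
                                    gapOpening = scoring$gap_open,
                                    gapExtension = scoring$gap_ext))
    sc <- vapply(alns, Biostrings::score, numeric(sum(ok)))
    if (sum(ok) == 1L) sc <- matrix(sc, nrow = 1)
    mm <- vapply(alns, Biostrings::nmismatch, numeric(sum(ok)))
    if (sum(ok) == 1L) mm <- matrix(mm, nrow = 1)
    ins_l <- lapply(alns, Biostrings::insertion)
    del_l <- lapply(alns, Biostrings::deletion)

    idx_ok <- which(ok)
    wt_cols <- which(kind == "wt"); ed_col <- which(kind == "edited")
    for (k in seq_along(idx_ok)) {
      i <- idx_ok[k]
      rd <- reads[i]
      s_wt <- max(sc[k, wt_cols])
      best_wt <- wt_cols[which.max(sc[k, wt_cols])]
      s_ed <- sc[k, ed_col]
      probe_hit <- e_len > 0 && grepl(probe, rd, fixed = TRUE)
      if (abs(s_ed - s_wt) < 1e-9) {
        if (e_len == 0L) next  # ambiguous; stays DISCARDED
        col <- if (probe_hit) ed_col else best_wt
      } else col <- if (s_ed > s_wt) ed_col else best_wt
      ops <- ops_from_ranges(ins_l[[col]][[k]], del_l[[col]][[k]])
      win <- windows[[col]]
      in_win <- rep(FALSE, nrow(ops))
      for (r in seq_len(nrow(win)))
        in_win <- in_win | op_in_window(ops, win[r, "lo"], win[r, "hi"])
      edit_detected <- e_len > 0 &&
        (probe_hit ||
           (kind[col] == "edited" && !op_breaks_interval(ops, js, je)))
      cls <- if (edit_detected && any(in_win)) "EDIT_WITH_INDEL"
      else if (edit_detected) "ACCURATE_EDIT"
      else if (any(in_win)) "PURE_INDEL"
      else "UNEDITED"
      res$class[i] <- cls
      res$aligned_to[i] <- kind[col]
      res$ref[i] <- if (kind[col] == "edited") alleles$accurate_name else names(refs)[col]
      res$score[i] <- sc[k, col]
      res$edit_distance[i] <- as.integer(mm[k, col] + sum(ops$len))
      res$n_indel_ops[i] <- nrow(ops)
      res$indel_ops[i] <- if (nrow(ops)) paste(
        sprintf("%d:%s:%d", ops$pos, ops$type, ops$len), collapse = ";") else ""
    }
  }
  attr(res, "window") <- window
  res
}

#' Tabulate classified reads into an outcome table
#'
#' Frequencies are percentages of retained (non-discarded) reads. "Prime
#' edits" are accurate edits plus edits containing indels; total editing
#' activity additionally includes pure indels and is compared against the
#' reporting threshold: above 0.2% for on-target editing, lowered to 0.01%
#' for off-target analysis.
#'
#' @param classified Output of [classify_reads()].
#' @param mode `"on_target"` or `"off_target"` (sets the activity
#'   threshold).
#' @return Object of class `wtpe_outcome`: read counts, per-class
#'   percentage frequencies, `prime_edit_freq`, `total_indel_freq`,
#'   `activity`, `threshold` and `above_threshold`.
#' @export
tabulate_outcomes <- function(classified, mode = c("on_target", "off_target")) {
  mode <- match.arg(mode)
  classes <- c("UNEDITED", "ACCURATE_EDIT", "EDIT_WITH_INDEL", "PURE_INDEL")
  n_total <- nrow(classified)
  n_disc <- sum(classified$class == "DISCARDED")
  n_ret <- n_total - n_disc
  if (n_ret == 0L) stop("no retained reads to tabulate")
  counts <- vapply(classes, function(cl) sum(classified$class == cl), integer(1))
  freq <- 100 * counts / n_ret
  prime <- freq[["ACCURATE_EDIT"]] + freq[["EDIT_WITH_INDEL"]]
  indel_tot <- freq[["EDIT_WITH_INDEL"]] + freq[["PURE_INDEL"]]
  activity <- prime + freq[["PURE_INDEL"]]
  thr <- if (mode == "on_target") 0.2 else 0.01
  structure(
    list(n_total = n_total, n_discarded = n_disc, n_retained = n_ret,
         counts = counts, freq = freq,
         prime_edit_freq = prime, total_indel_freq = indel_tot,
         activity = activity, mode = mode, threshold = thr,
         above_threshold = activity > thr,
         window = attr(classified, "window")),
    class = "wtpe_outcome"
  )
}

#' @export
print.wtpe_outcome <- function(x, ...) {
  cat(sprintf("<wtpe_outcome> %d reads (%d discarded), mode %s\n",
              x$n_total, x$n_discarded, x$mode))
  for (cl in names(x$freq))
    cat(sprintf("  %-16s %6d  %6.2f%%\n", cl, x$counts[[cl]], x$freq[[cl]]))
  cat(sprintf("  prime edits %.2f%%, total indels %.2f%%, activity %.2f%% (%s threshold %.2g%%)\n",
              x$prime_edit_freq, x$total_indel_freq, x$activity,
              if (x$above_threshold) "above" else "below", x$threshold))
  invisible(x)
}

#' Compare two editors' outcome tables
#'
#' @param table_a,table_b `wtpe_outcome` objects computed over the same
#'   locus and quantification window.
#' @return `data.frame` with per-metric frequencies, differences (a - b),
#'   ratios (a / b) and a flag marking metrics where editor A is below
#'   editor B.
#' @export
compare_editors <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "wtpe_outcome"), inherits(table_b, "wtpe_outcome"))
  if (!is.null(table_a$window) && !is.null(table_b$window) &&
      table_a$window != table_b$window)
    stop("outcome tables use different quantification windows")
  metrics <- c(names(table_a$freq), "prime_edit_freq", "activity")
  fa <- c(table_a$freq, prime_edit_freq = table_a$prime_edit_freq,
          activity = table_a$activity)
  fb <- c(table_b$freq, prime_edit_freq = table_b$prime_edit_freq,
          activity = table_b$activity)
  data.frame(metric = metrics,
             freq_a = unname(fa[metrics]), freq_b = unname(fb[metrics]),
             diff = unname(fa[metrics] - fb[metrics]),
             ratio = unname(ifelse(fb[metrics] == 0, NA_real_,
                                   fa[metrics] / fb[metrics])),
             a_below_b = unname(fa[metrics] < fb[metrics]))
}
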