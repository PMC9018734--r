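#' Outcome mixture for read simulation
#'
#' Proportions of the four sequencing outcome classes plus a simple
#' sequencing error model (per-base substitution and indel rates applied
#' after the true allele sequence is drawn).
#'
#' @param unedited,accurate_edit,edit_with_indel,pure_indel Class
#'   proportions; must sum to 1.
#' @param n_reads Number of reads to simulate.
#' @param error_sub Per-base substitution error rate (default 0.001,
#'   Illumina-like; max 0.05).
#' @param error_indel Per-base indel error rate (default 1e-4; max 0.05).
#' @return Object of class `wtpe_mixture`.
#' @export
outcome_mixture <- function(unedited = 0.2, accurate_edit = 0.4,
                            edit_with_indel = 0.3, pure_indel = 0.1,
                            n_reads = 10000L, error_sub = 0.001,
                            error_indel = 1e-4) {
  p <- stats::setNames(
    as.numeric(c(unedited, accurate_edit, edit_with_indel, pure_indel)),
    c("UNEDITED", "ACCURATE_EDIT", "EDIT_WITH_INDEL", "PURE_INDEL"))
  if (abs(sum(p) - 1) > 1e-9) stop("class proportions must sum to 1")
  if (any(p < 0)) stop("class proportions must be non-negative")
  if (error_sub < 0 || error_sub > 0.05 || error_indel < 0 || error_indel > 0.05)
    stop("error rates must lie in [0, 0.05]")
  structure(list(proportions = p, n_reads = as.integer(n_reads),
                 error_sub = error_sub, error_indel = error_indel),
            class = "wtpe_mixture")
}

#' Indel archetype model
#'
#' Weights over the structural archetypes of indel-bearing outcomes:
#' `ha_duplication_join` (flap joined by end joining without collapsing the
#' homology arm, leaving the HA duplicated at the junction),
#' `blunt_join_indel` (direct fusion of the break ends with no edit
#' written) and `random_small_indel` (small insertion/deletion near the
#' junction, geometric length distribution).
#'
#' @param w_ha_dup,w_blunt,w_random Archetype weights; must sum to 1.
#' @param geom_p Geometric parameter of the random indel length
#'   (length = 1 + Geom(`geom_p`), capped at `max_len`).
#' @param max_len Maximum random indel length.
#' @return Object of class `wtpe_indel_model`.
#' @export
indel_model <- function(w_ha_dup = 0.5, w_blunt = 0.25, w_random = 0.25,
                        geom_p = 0.35, max_len = 8L) {
  w <- stats::setNames(as.numeric(c(w_ha_dup, w_blunt, w_random)),
                       c("ha_duplication_join", "blunt_join_indel",
                         "random_small_indel"))
  if (abs(sum(w) - 1) > 1e-9) stop("archetype weights must sum to 1")
  if (any(w < 0)) stop("archetype weights must be non-negative")
  structure(list(weights = w, geom_p = geom_p, max_len = as.integer(max_len)),
            class = "wtpe_indel_model")
}

# Insert or delete a short stretch near (but never inside) keep_iv,
# at an offset of min_off..max_off from the interval boundary.
random_indel_near <- function(seq, keep_iv, model, min_off = 3L, max_off = 12L) {
  len <- min(1L + stats::rgeom(1L, model$geom_p), model$max_len)
  type <- sample(c("ins", "del"), 1L)
  side <- sample(c("left", "right"), 1L)
  off <- sample(seq.int(min_off, max_off), 1L)
  L <- nchar(seq)
  if (side == "right") {
    pos <- min(keep_iv[2] + off, L)      # insertion point / deletion start
    if (type == "del") len <- min(len, L - pos)
  } else {
    if (type == "ins") pos <- max(keep_iv[1] - off, 0L)
    else { pos <- max(keep_iv[1] - off - len, 0L); len <- min(len, keep_iv[1] - pos) }
  }
  if (len < 1L) { type <- "ins"; len <- 1L }  # degenerate clamp: fall back to 1-nt insertion
  if (type == "ins") {
    insert <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    list(seq = paste0(substr0(seq, 0L, pos), insert, substr0(seq, pos, L)),
         pos = pos, type = "ins", len = len)
  } else {
    list(seq = paste0(substr0(seq, 0L, pos), substr0(seq, pos + len, L)),
         pos = pos, type = "del", len = len)
  }
}

# Resection-style deletion spanning the break point: removes `len` bases
# split at random between the two sides of `point`. The NHEJ signature of a
# failed flap join; always produces a deletion overlapping the junction.
resection_del <- function(seq, point, model) {
  len <- min(1L + stats::rgeom(1L, model$geom_p), model$max_len)
  dl <- sample.int(len + 1L, 1L) - 1L
  start <- max(point - dl, 0L)
  len <- min(len, nchar(seq) - start)
  list(seq = paste0(substr0(seq, 0L, start),
                    substr0(seq, start + len, nchar(seq))),
       pos = start, type = "del", len = len)
}

apply_seq_error <- function(seq, sub_rate, indel_rate) {
  v <- strsplit(seq, "")[[1]]
  if (sub_rate > 0) {
    hit <- which(stats::runif(length(v)) < sub_rate)
    for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
  }
  if (indel_rate > 0) {
    hit <- which(stats::runif(length(v)) < indel_rate)
    for (i in rev(hit)) {
      if (stats::runif(1) < 0.5) v <- append(v, sample(DNA_BASES, 1L), after = i)
      else v <- v[-i]
    }
  }
  paste(v, collapse = "")
}

#' Simulate amplicon reads with known ground truth
#'
#' Draws each read's outcome class from the mixture (multinomial by
#' default; `fixed_counts = TRUE` uses exact rounded counts), takes the
#' matching allele sequence — wild type, accurate edit, or an indel
#' archetype built around the predicted junction — applies sequencing
#' error, and returns reads plus a truth table holding the class, archetype
#' and exact pre-error sequence of every read. Output is deterministic for
#' a fixed seed.
#'
#' @param alleles A [predict_alleles()] result.
#' @param mix An [outcome_mixture()].
#' @param model An [indel_model()].
#' @param seed Integer RNG seed (the function calls `set.seed`).
#' @param fixed_counts Use exact per-class counts instead of a multinomial
#'   draw.
#' @param fastq_out,truth_out Optional output paths (FASTQ; truth TSV).
#' @return List with `reads` (named character vector) and `truth`
#'   (`data.frame`: `read_id`, `true_class`, `archetype`,
#'   `pre_error_seq`).
#' @export
simulate_reads <- function(alleles, mix, model = indel_model(), seed = 1L,
                           fixed_counts = FALSE, fastq_out = NULL,
                           truth_out = NULL) {
  stopifnot(inherits(alleles, "wtpe_alleles"), inherits(mix, "wtpe_mixture"),
            inherits(model, "wtpe_indel_model"))
  set.seed(as.integer(seed))
  n <- mix$n_reads
  classes <- names(mix$proportions)
  if (n == 0L) {
    truth <- data.frame(read_id = character(0), true_class = character(0),
                        archetype = character(0), pre_error_seq = character(0))
    if (!is.null(fastq_out)) write_fastq(character(0), fastq_out)
    if (!is.null(truth_out))
      write.table(truth, truth_out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(list(reads = character(0), truth = truth))
  }
  cls <- if (fixed_counts) {
    cnt <- floor(n * mix$proportions)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(n * mix$proportions - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    rep(classes, times = cnt)
  } else {
    sample(classes, n, replace = TRUE, prob = mix$proportions)
  }

  js <- alleles$junction_interval[1]; je <- alleles$junction_interval[2]
  has_ha_dup <- "ha_duplication" %in% names(alleles$archetypes)
  has_blunt <- "no_flap_join" %in% names(alleles$archetypes)
  w <- model$weights

  pre <- character(n); arch <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (cls[i] == "UNEDITED") {
      k <- if (length(alleles$wt_refs) > 1L)
        sample(seq_along(alleles$wt_refs), 1L) else 1L
      pre[i] <- alleles$wt_refs[[k]]
      arch[i] <- names(alleles$wt_refs)[k]
    } else if (cls[i] == "ACCURATE_EDIT") {
      pre[i] <- alleles$accurate_ref
      arch[i] <- "accurate"
    } else if (cls[i] == "EDIT_WITH_INDEL") {
      use_hadup <- has_ha_dup && w[["ha_duplication_join"]] > 0 &&
        stats::runif(1) < w[["ha_duplication_join"]] /
          (w[["ha_duplication_join"]] + w[["random_small_indel"]])
      if (use_hadup) {
        pre[i] <- alleles$archetypes[["ha_duplication"]]
        arch[i] <- "ha_duplication"
      } else {
        r <- random_indel_near(alleles$accurate_ref, c(js, je), model)
        pre[i] <- r$seq
        arch[i] <- sprintf("random_%s%d", r$type, r$len)
      }
    } else if (cls[i] == "PURE_INDEL") {
      if (has_blunt) {
        base <- alleles$archetypes[["no_flap_join"]]
        keep <- c(js, js)  # junction point in blunt-join coordinates
        use_blunt <- w[["blunt_join_indel"]] > 0 &&
          stats::runif(1) < w[["blunt_join_indel"]] /
            (w[["blunt_join_indel"]] + w[["random_small_indel"]])
        if (use_blunt) {
          pre[i] <- base
          arch[i] <- "blunt_join"
        } else {
          r <- resection_del(base, keep[1], model)
          pre[i] <- r$seq
          arch[i] <- sprintf("blunt_join_%s%d", r$type, r$len)
        }
      } else {
        cut <- alleles$wt_cuts[[1]][1]
        r <- resection_del(alleles$wt_refs[[1]], cut, model)
        pre[i] <- r$seq
        arch[i] <- sprintf("cut_%s%d", r$type, r$len)
      }
    } else stop("unknown outcome class: ", cls[i])
  }
  reads <- vapply(pre, apply_seq_error, character(1),
                  sub_rate = mix$error_sub, indel_rate = mix$error_indel,
                  USE.NAMES = FALSE)
  ids <- sprintf("read%06d", seq_len(n))
  names(reads) <- ids
  truth <- data.frame(read_id = ids, true_class = cls, archetype = arch,
                      pre_error_seq = pre, stringsAsFactors = FALSE)
  if (!is.null(fastq_out)) write_fastq(reads, fastq_out)
  if (!is.null(truth_out))
    write.table(truth, truth_out, sep = "\t", quote = FALSE, row.names = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a gel densitometry lane
#'
#' Generates band greyscales whose noise-free evaluation under the
#' length-normalised ratio returns `100 * true_fraction`: each band's
#' intensity is molecules times length, with molecules split
#' `true_fraction` / `1 - true_fraction` between deleted and undeleted
#' alleles. Optional multiplicative Gaussian noise.
#'
#' @param true_fraction True deleted-allele fraction in `[0, 1]`.
#' @param lengths Band lengths `c(deleted, undeleted)` in bp.
#' @param intensity_scale Total molecule scale factor.
#' @param noise_sd Relative (multiplicative) Gaussian noise s.d.
#' @param seed Optional RNG seed.
#' @return A [gel_lane()].
#' @export
simulate_gel <- function(true_fraction, lengths = c(346L, 1000L),
                         intensity_scale = 1000, noise_sd = 0, seed = NULL) {
  if (true_fraction < 0 || true_fraction > 1)
    stop("true_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  gd <- true_fraction * intensity_scale * lengths[1]
  gu <- (1 - true_fraction) * intensity_scale * lengths[2]
  if (noise_sd > 0) {
    gd <- max(gd * (1 + stats::rnorm(1, 0, noise_sd)), 0)
    gu <- max(gu * (1 + stats::rnorm(1, 0, noise_sd)), 0)
  }
  gel_lane(gd, gu, lengths[1], lengths[2])
}

#' Simulate absolute qPCR of a deletion
#'
#' Generates CT tables for the tenfold dilution series of each reference
#' assay and replicate CTs for a genomic DNA sample in which
#' `true_fraction` of `total_copies` molecules carry the deletion (the
#' flanking assay sees all `total_copies`). With `replicate_sd = 0` the
#' full pipeline (curve fit, copy conversion, copy ratio) recovers
#' `100 * true_fraction` exactly.
#'
#' @param true_fraction True deleted fraction in `(0, 1]`.
#' @param curve_params List with numeric `slope`/`intercept` pairs for the
#'   `deleted` and `flanking` assays.
#' @param total_copies Total genome copies per microlitre in the sample.
#' @param replicate_sd Gaussian CT noise s.d. applied to sample and
#'   dilution CTs.
#' @param n_replicates Replicate CT count per assay.
#' @param dilution_copies Dilution series (copies per microlitre); default
#'   is the serial tenfold series 2e1, 1e2, ..., 1e9.
#' @param seed Optional RNG seed.
#' @return List: `sample` (replicate CT vectors `ct_deleted`,
#'   `ct_flanking`), `dilution_tables` (per-assay `data.frame`s of
#'   `copies`, `ct`), and `true_fraction`.
#' @export
simulate_qpcr <- function(true_fraction,
                          curve_params = list(
                            deleted = c(slope = -3.3219, intercept = 38),
                            flanking = c(slope = -3.3219, intercept = 37)),
                          total_copies = 1e5, replicate_sd = 0,
                          n_replicates = 3L,
                          dilution_copies = c(2e1, 1e2, 1e3, 1e4, 1e5,
                                              1e6, 1e7, 1e8, 1e9),
                          seed = NULL) {
  if (true_fraction <= 0 || true_fraction > 1)
    stop("true_fraction must lie in (0, 1]")
  for (p in curve_params)
    if (p[["slope"]] >= 0) stop("standard-curve slopes must be negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ct_of <- function(copies, p)
    p[["slope"]] * log10(copies) + p[["intercept"]]
  noisy <- function(ct, m = 1L)
    ct + if (replicate_sd > 0) stats::rnorm(length(ct) * m, 0, replicate_sd) else 0
  dil <- lapply(curve_params, function(p)
    data.frame(copies = dilution_copies,
               ct = noisy(ct_of(dilution_copies, p))))
  sample_ct <- list(
    ct_deleted = noisy(rep(ct_of(true_fraction * total_copies,
                                 curve_params$deleted), n_replicates)),
    ct_flanking = noisy(rep(ct_of(total_copies, curve_params$flanking),
                            n_replicates))
  )
  list(sample = sample_ct, dilution_tables = dil, true_fraction = true_fraction)
}

#' Run the full qPCR quantification pipeline on a simulated experiment
#'
#' Fits a standard curve per assay from the dilution tables and computes
#' the deletion efficiency from the sample CTs.
#'
#' @param sim A [simulate_qpcr()] result (or any list with the same shape).
#' @return The [qpcr_deletion_efficiency()] result, with the fitted curves
#'   attached as `curves`.
#' @export
qpcr_pipeline <- function(sim) {
  curves <- lapply(sim$dilution_tables, function(d)
    fit_standard_curve(d$copies, d$ct))
  out <- qpcr_deletion_efficiency(sim$sample, curves$deleted, curves$flanking)
  out$curves <- curves
  out
}
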