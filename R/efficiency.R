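#' Gel lane densitometry record
#'
#' Background-corrected band greyscale values and band lengths for one lane
#' of a deletion PCR gel (deleted-allele band and undeleted band).
#'
#' @param greyscale_deleted,greyscale_undeleted Non-negative band
#'   intensities (at least one positive).
#' @param len_deleted_bp,len_undeleted_bp Band lengths in bp (positive).
#' @return Object of class `wtpe_gel_lane`.
#' @export
gel_lane <- function(greyscale_deleted, greyscale_undeleted,
                     len_deleted_bp, len_undeleted_bp) {
  if (greyscale_deleted < 0 || greyscale_undeleted < 0)
    stop("greyscale values must be non-negative")
  if (len_deleted_bp <= 0 || len_undeleted_bp <= 0)
    stop("band lengths must be positive")
  if (greyscale_deleted == 0 && greyscale_undeleted == 0)
    stop("both greyscales are zero: deletion efficiency undefined")
  structure(
    list(greyscale_deleted = greyscale_deleted,
         greyscale_undeleted = greyscale_undeleted,
         len_deleted_bp = len_deleted_bp,
         len_undeleted_bp = len_undeleted_bp),
    class = "wtpe_gel_lane"
  )
}

#' Deletion efficiency from gel densitometry
#'
#' Length-normalised greyscale ratio: band intensity is proportional to
#' molar amount times fragment length, so dividing each band's greyscale by
#' its length in bp converts intensities to relative molecule counts:
#'
#' \deqn{100 \cdot \frac{G_d / L_d}{G_d / L_d + G_u / L_u}}
#'
#' @param lane A [gel_lane()] (or a list with the same fields).
#' @return Deletion efficiency as a percentage.
#' @examples
#' gel_deletion_efficiency(gel_lane(30, 70, 300, 1000)) # 58.82
#' @export
gel_deletion_efficiency <- function(lane) {
  if (!inherits(lane, "wtpe_gel_lane"))
    lane <- gel_lane(lane$greyscale_deleted, lane$greyscale_undeleted,
                     lane$len_deleted_bp, lane$len_undeleted_bp)
  d <- lane$greyscale_deleted / lane$len_deleted_bp
  u <- lane$greyscale_undeleted / lane$len_undeleted_bp
  100 * d / (d + u)
}

#' Read a gel densitometry table
#'
#' @param path TSV with columns `sample`, `greyscale_deleted`,
#'   `greyscale_undeleted`, `len_deleted_bp`, `len_undeleted_bp`.
#' @return `data.frame` with an added `efficiency_pct` column.
#' @export
read_gel_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$efficiency_pct <- vapply(seq_len(nrow(tab)), function(i)
    gel_deletion_efficiency(as.list(tab[i, ])), numeric(1))
  tab
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of CT on log10(copies) from a serial dilution of a
#' reference plasmid. Amplification efficiency is `10^(-1/slope) - 1`
#' (1.0 = perfect doubling per cycle, slope -3.3219).
#'
#' @param dilution_copies Copies per microlitre at each dilution point
#'   (positive; at least 3 points).
#' @param cts Measured CT values, same length.
#' @return Object of class `wtpe_stdcurve`: `slope`, `intercept`,
#'   `r_squared`, `amplification_efficiency` (fraction), `n_points`,
#'   `ct_range`, `copies_range`, and `findings` (e.g. a warning when the
#'   slope is not negative).
#' @export
fit_standard_curve <- function(dilution_copies, cts) {
  if (length(dilution_copies) != length(cts))
    stop("dilution_copies and cts must have equal length")
  if (length(cts) < 3L)
    stop("at least 3 dilution points are required to fit a standard curve")
  if (any(dilution_copies <= 0)) stop("copies must be positive")
  lc <- log10(dilution_copies)
  fit <- stats::lm(cts ~ lc)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  findings <- character(0)
  if (!is.finite(slope) || slope >= 0)
    findings <- c(findings, "non-negative slope: CT should fall with template amount")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cts - mean(cts))^2)
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         amplification_efficiency = 10^(-1 / slope) - 1,
         n_points = length(cts),
         ct_range = range(cts), copies_range = range(dilution_copies),
         findings = findings),
    class = "wtpe_stdcurve"
  )
}

#' @export
print.wtpe_stdcurve <- function(x, ...) {
  cat(sprintf("<wtpe_stdcurve> CT = %.4f * log10(copies) + %.4f (r2=%.4f, eff=%.1f%%, %d points)\n",
              x$slope, x$intercept, x$r_squared,
              100 * x$amplification_efficiency, x$n_points))
  for (f in x$findings) cat("  finding:", f, "\n")
  invisible(x)
}

#' Absolute copy number from a CT value
#'
#' Inverts the standard curve: `copies = 10^((ct - intercept) / slope)`.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param ct CT value(s).
#' @return Copies per microlitre; attribute `"extrapolated"` marks CTs
#'   outside the fitted dilution range.
#' @export
absolute_copies <- function(curve, ct) {
  stopifnot(inherits(curve, "wtpe_stdcurve"))
  copies <- 10^((ct - curve$intercept) / curve$slope)
  attr(copies, "extrapolated") <-
    ct < min(curve$ct_range) | ct > max(curve$ct_range)
  copies
}

#' Deletion efficiency by absolute qPCR
#'
#' Replicate CTs of each assay are arithmetically averaged, converted to
#' absolute copies on that assay's standard curve, and the efficiency is
#' the copy ratio: `100 * copies(deleted junction) / copies(flanking)`.
#' The result is not clamped: assay noise can push the ratio above 100%,
#' which is flagged rather than truncated, as is any CT outside the fitted
#' dilution range.
#'
#' @param sample List with numeric replicate CT vectors `ct_deleted` and
#'   `ct_flanking` (as produced by [simulate_qpcr()]).
#' @param curve_deleted,curve_flanking Standard curves of the
#'   deletion-junction and flanking assays.
#' @return List: `efficiency` (percent), `copies_deleted`,
#'   `copies_flanking`, and `flags` (character vector; possibly empty).
#' @export
qpcr_deletion_efficiency <- function(sample, curve_deleted, curve_flanking) {
  stopifnot(is.numeric(sample$ct_deleted), is.numeric(sample$ct_flanking))
  if (any(!is.finite(c(sample$ct_deleted, sample$ct_flanking))) ||
      any(c(sample$ct_deleted, sample$ct_flanking) <= 0))
    stop("CT values must be finite and positive")
  cd <- absolute_copies(curve_deleted, mean(sample$ct_deleted))
  cf <- absolute_copies(curve_flanking, mean(sample$ct_flanking))
  if (cf == 0) stop("flanking copies are zero: efficiency undefined")
  eff <- 100 * as.numeric(cd) / as.numeric(cf)
  flags <- character(0)
  if (attr(cd, "extrapolated") || attr(cf, "extrapolated"))
    flags <- c(flags, "extrapolated")
  if (eff > 100) flags <- c(flags, "over_100_percent")
  list(efficiency = eff, copies_deleted = as.numeric(cd),
       copies_flanking = as.numeric(cf), flags = flags)
}

#' Summarise replicate efficiencies
#'
#' @param x Numeric vector of per-replicate efficiencies (percent).
#' @return Named vector with `mean`, `sd` and `n`.
#' @export
replicate_summary <- function(x) {
  c(mean = mean(x), sd = stats::sd(x), n = length(x))
}
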