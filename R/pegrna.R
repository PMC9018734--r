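# Standard SpCas9 sgRNA scaffold, stored as DNA (T for U); configurable via
# the `scaffold` argument of the designers.
#' @export
SGRNA_SCAFFOLD <- paste0(
  "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTG",
  "GCACCGAGTCGGTGC"
)

#' Edit specification for pegRNA design
#'
#' Describes what the reverse-transcribed flap should write at the junction:
#' the intended edit sequence, an optional homology arm (HA) copied from the
#' sequence adjacent to the (partner) cut, and the primer binding site
#' length.
#'
#' @param edit_seq DNA to be written at the junction (may be `""` for pure
#'   joins). Stored upper case.
#' @param ha_len Homology-arm length in nt; `0` selects the
#'   homology-independent mode. Arms shorter than 8 nt are allowed but
#'   flagged by [validate_plan()], since 8 nt is the shortest microhomology
#'   known to support Rad51-assisted homology search.
#' @param pbs_len Primer-binding-site length in nt; practical range 8-17.
#' @param include_ecorv If `TRUE`, append a `GATATC` (EcoRV) site at the 3'
#'   end of the flap (the 5' proximal portion of the RT template) to make
#'   integration detectable by digestion. Only valid with `ha_len = 0`.
#' @param flap_override Optional explicit flap DNA, replacing the
#'   `edit_seq + HA` construction (used for base-substitution edits where
#'   the flap is a modified copy of the reference).
#' @return Object of class `wtpe_editspec`.
#' @export
edit_spec <- function(edit_seq = "", ha_len = 13L, pbs_len = 13L,
                      include_ecorv = FALSE, flap_override = NULL) {
  edit_seq <- toupper(edit_seq)
  if (nchar(edit_seq) > 0) check_dna(edit_seq, allow_n = FALSE, what = "edit_seq")
  ha_len <- as.integer(ha_len); pbs_len <- as.integer(pbs_len)
  if (ha_len < 0L) stop("ha_len must be non-negative")
  if (pbs_len < 1L) stop("pbs_len must be positive")
  if (!is.null(flap_override)) {
    flap_override <- toupper(flap_override)
    check_dna(flap_override, allow_n = FALSE, what = "flap_override")
  }
  structure(
    list(edit_seq = edit_seq, ha_len = ha_len, pbs_len = pbs_len,
         include_ecorv = isTRUE(include_ecorv), flap_override = flap_override),
    class = "wtpe_editspec"
  )
}

# Plus-strand frame of a site: the locus sequence oriented so the
# protospacer strand (= non-target strand, NTS) reads left to right and the
# cut coordinate is measured in that frame.
site_frame <- function(site, locus) {
  stopifnot(inherits(site, "wtpe_site"), inherits(locus, "wtpe_locus"))
  if (site$locus_name != locus$name)
    stop("site does not belong to locus '", locus$name, "'")
  L <- nchar(locus$sequence)
  if (site$strand == "+") list(seq = locus$sequence, cut = site$cut, len = L)
  else list(seq = revcomp(locus$sequence), cut = L - site$cut, len = L)
}

# Flap written by RT for a single-site design: edit, then ha_len nt
# identical to the PAM-proximal non-target strand starting at the cut.
single_site_flap <- function(site, locus, spec) {
  if (!is.null(spec$flap_override)) {
    flap <- spec$flap_override
  } else {
    fr <- site_frame(site, locus)
    if (fr$cut + spec$ha_len > fr$len)
      stop("homology arm window exceeds locus bounds")
    ha <- if (spec$ha_len > 0L) substr0(fr$seq, fr$cut, fr$cut + spec$ha_len) else ""
    flap <- paste0(spec$edit_seq, ha)
  }
  if (spec$include_ecorv) {
    if (spec$ha_len > 0L)
      stop("EcoRV site insertion conflicts with a homology arm; use ha_len = 0")
    if (!grepl("GATATC", flap, fixed = TRUE)) flap <- paste0(flap, "GATATC")
  }
  flap
}

# Core pegRNA assembly given an explicit flap.
build_pegrna <- function(site, locus, flap, pbs_len, scaffold, spec) {
  fr <- site_frame(site, locus)
  if (fr$cut - pbs_len < 0L)
    stop("PBS window exceeds locus bounds")
  pbs <- revcomp(substr0(fr$seq, fr$cut - pbs_len, fr$cut))
  rt_template <- revcomp(flap)
  structure(
    list(site = site, spacer_rna = site$protospacer, scaffold = scaffold,
         rt_template = rt_template, pbs = pbs,
         full_sequence = paste0(site$protospacer, scaffold, rt_template, pbs),
         flap = flap, spec = spec),
    class = "wtpe_pegrna"
  )
}

#' DNA flap encoded by a pegRNA
#'
#' The 3' DNA flap that reverse transcription appends to the broken
#' non-target strand; equal to the reverse complement of the RT template.
#'
#' @param pegrna A `wtpe_pegrna`.
#' @return Character flap DNA, 5'->3' on the non-target strand.
#' @export
flap_dna <- function(pegrna) {
  stopifnot(inherits(pegrna, "wtpe_pegrna"))
  pegrna$flap
}

#' @export
print.wtpe_pegrna <- function(x, ...) {
  cat(sprintf("<wtpe_pegrna> %s(%s) spacer=%s\n  RT template=%s PBS=%s (flap=%s)\n",
              x$site$locus_name, x$site$strand, x$spacer_rna,
              x$rt_template, x$pbs, x$flap))
  invisible(x)
}

#' Design a single-site pegRNA
#'
#' Builds a pegRNA whose RT template encodes a flap consisting of the
#' intended edit followed by `ha_len` nt identical to the PAM-proximal
#' non-target strand starting at the cut (so the flap's homology arm can
#' anneal back to the PAM-proximal target strand). The PBS is the reverse
#' complement of the `pbs_len` nt immediately 5' of the cut on the
#' non-target strand.
#'
#' @param site A [spacer_site()] on `locus`.
#' @param locus The [locus()] carrying the site.
#' @param spec An [edit_spec()].
#' @param scaffold Invariant sgRNA scaffold (DNA alphabet).
#' @return A `wtpe_pegrna`.
#' @export
design_single <- function(site, locus, spec, scaffold = SGRNA_SCAFFOLD) {
  stopifnot(inherits(spec, "wtpe_editspec"))
  flap <- single_site_flap(site, locus, spec)
  build_pegrna(site, locus, flap, spec$pbs_len, scaffold, spec)
}

#' Design a C1 or C2 pegRNA pair for deletion or translocation
#'
#' Both pegRNAs extend flaps toward each other so the edited allele joins
#' the two retained fragments across the intended edit. In class C2 the two
#' flaps are exactly the edit and its reverse complement, annealing over
#' their full length; in class C1 each flap additionally carries a homology
#' arm identical to the retained sequence adjacent to the partner cut, so
#' the accurate join is `retained_a + edit + retained_b`.
#'
#' Orientation rule (enforced): PAMs point into the fragment being removed
#' or exchanged, i.e. `site_a` is a plus-strand site and `site_b` a
#' minus-strand site, with the flap-bearing retained fragments being the
#' left arm of locus A and the right arm of locus B.
#'
#' @param site_a,site_b [spacer_site()]s. For a deletion both lie on the
#'   same locus with `cut_a < cut_b`; for a translocation on different loci.
#' @param loci A single [locus()] (deletion) or list of two loci
#'   (translocation; order a, b).
#' @param spec An [edit_spec()]; `ha_len` must be 0 for C2 and positive for
#'   C1.
#' @param design_class `"C1"` or `"C2"`.
#' @param scaffold Invariant sgRNA scaffold.
#' @return Object of class `wtpe_plan` with fields `intent`, `design_class`,
#'   `pegrna_a`, `pegrna_b`, `locus_a`, `locus_b`, `site_a`, `site_b`,
#'   `edit_seq`, `ha_len`, and `retained_segments`.
#' @export
design_pair <- function(site_a, site_b, loci, spec,
                        design_class = c("C1", "C2"),
                        scaffold = SGRNA_SCAFFOLD) {
  design_class <- match.arg(design_class)
  stopifnot(inherits(spec, "wtpe_editspec"))
  if (inherits(loci, "wtpe_locus")) {
    locus_a <- locus_b <- loci
    intent <- "deletion"
  } else {
    stopifnot(length(loci) == 2L, inherits(loci[[1]], "wtpe_locus"),
              inherits(loci[[2]], "wtpe_locus"))
    locus_a <- loci[[1]]; locus_b <- loci[[2]]
    intent <- if (identical(locus_a$name, locus_b$name)) "deletion" else "translocation"
  }
  if (site_a$locus_name != locus_a$name || site_b$locus_name != locus_b$name)
    stop("sites must lie on the supplied loci (order a, b)")
  if (site_a$strand != "+" || site_b$strand != "-")
    stop("incompatible orientation: PAMs must point into the removed/",
         "exchanged fragment (site_a on '+', site_b on '-')")
  if (intent == "deletion") {
    if (site_a$cut >= site_b$cut) stop("deletion requires cut_a < cut_b")
    if (site_a$cut + 6L > site_b$cut - 6L)
      stop("protospacer/PAM footprints overlap between the cuts")
  }
  if (design_class == "C1" && spec$ha_len == 0L)
    stop("C1 designs require ha_len > 0")
  if (design_class == "C2" && spec$ha_len > 0L)
    stop("C2 designs are homology-independent; use ha_len = 0")
  if (spec$include_ecorv)
    stop("EcoRV tagging applies to single-site designs only")

  edit <- spec$edit_seq
  ha <- spec$ha_len
  La <- nchar(locus_a$sequence); Lb <- nchar(locus_b$sequence)
  if (site_b$cut + ha > Lb || site_a$cut - ha < 0L)
    stop("homology arm window exceeds locus bounds")
  # HA of each flap copies the retained sequence adjacent to the PARTNER cut
  ha_a <- if (ha > 0L) substr0(locus_b$sequence, site_b$cut, site_b$cut + ha) else ""
  ha_b <- if (ha > 0L) revcomp(substr0(locus_a$sequence, site_a$cut - ha, site_a$cut)) else ""
  flap_a <- paste0(edit, ha_a)
  flap_b <- paste0(revcomp(edit), ha_b)

  peg_a <- build_pegrna(site_a, locus_a, flap_a, spec$pbs_len, scaffold, spec)
  peg_b <- build_pegrna(site_b, locus_b, flap_b, spec$pbs_len, scaffold, spec)

  retained <- list(
    a = list(locus = locus_a$name, start = 0L, end = site_a$cut),
    b = list(locus = locus_b$name, start = site_b$cut, end = Lb)
  )
  structure(
    list(intent = intent, design_class = design_class,
         pegrna_a = peg_a, pegrna_b = peg_b,
         locus_a = locus_a, locus_b = locus_b,
         site_a = site_a, site_b = site_b,
         edit_seq = edit, ha_len = ha,
         retained_segments = retained),
    class = "wtpe_plan"
  )
}

#' Wrap a single pegRNA as a design plan
#'
#' @param pegrna A [design_single()] result.
#' @param locus The targeted [locus()].
#' @return A `wtpe_plan` with `intent = "single_edit"`.
#' @export
single_edit_plan <- function(pegrna, locus) {
  stopifnot(inherits(pegrna, "wtpe_pegrna"))
  structure(
    list(intent = "single_edit", design_class = if (pegrna$spec$ha_len > 0L) "C1" else "C2",
         pegrna_a = pegrna, pegrna_b = NULL,
         locus_a = locus, locus_b = NULL,
         site_a = pegrna$site, site_b = NULL,
         edit_seq = pegrna$spec$edit_seq, ha_len = pegrna$spec$ha_len,
         retained_segments = NULL),
    class = "wtpe_plan"
  )
}

#' @export
print.wtpe_plan <- function(x, ...) {
  cat(sprintf("<wtpe_plan> %s (%s)\n", x$intent, x$design_class))
  cat("  a: "); print(x$pegrna_a)
  if (!is.null(x$pegrna_b)) { cat("  b: "); print(x$pegrna_b) }
  invisible(x)
}

#' Validate a design plan
#'
#' Machine-checkable findings rather than errors: flap complementarity for
#' C2, HA identity against the partner-adjacent retained sequence for C1,
#' homology arms below the 8-nt microhomology floor, edit-free C2 designs,
#' and PBS lengths outside the practical 8-17 nt melting window.
#'
#' @param plan A `wtpe_plan`.
#' @return `data.frame` with columns `level` (`"error"`/`"warning"`),
#'   `check`, `message`; zero rows when the plan is clean.
#' @export
validate_plan <- function(plan) {
  stopifnot(inherits(plan, "wtpe_plan"))
  out <- list()
  add <- function(level, check, message)
    out[[length(out) + 1L]] <<- data.frame(level = level, check = check,
                                           message = message)
  pbs_lens <- vapply(Filter(Negate(is.null), list(plan$pegrna_a, plan$pegrna_b)),
                     function(p) nchar(p$pbs), integer(1))
  if (any(pbs_lens < 8L | pbs_lens > 17L))
    add("warning", "pbs_window", "PBS length outside the 8-17 nt melting window")
  if (plan$ha_len > 0L && plan$ha_len < 8L)
    add("warning", "ha_short", "HA below 8 nt (shortest microhomology supporting strand invasion)")
  if (!is.null(plan$pegrna_b)) {
    fa <- flap_dna(plan$pegrna_a); fb <- flap_dna(plan$pegrna_b)
    if (plan$design_class == "C2") {
      if (nchar(plan$edit_seq) == 0L)
        add("error", "c2_empty_edit", "C2 design with empty edit: flaps cannot anneal")
      if (!identical(revcomp(fa), fb))
        add("error", "c2_complementarity", "C2 flaps are not mutually reverse-complementary")
    } else {
      ha <- plan$ha_len
      exp_ha_a <- substr0(plan$locus_b$sequence, plan$site_b$cut, plan$site_b$cut + ha)
      exp_ha_b <- revcomp(substr0(plan$locus_a$sequence, plan$site_a$cut - ha, plan$site_a$cut))
      if (!identical(substr(fa, nchar(fa) - ha + 1L, nchar(fa)), exp_ha_a) ||
          !identical(substr(fb, nchar(fb) - ha + 1L, nchar(fb)), exp_ha_b))
        add("error", "c1_ha_identity", "C1 homology arm does not match partner-adjacent retained sequence")
      ea <- substr(fa, 1L, nchar(fa) - ha)
      eb <- substr(fb, 1L, nchar(fb) - ha)
      if (!identical(revcomp(ea), eb))
        add("error", "c1_edit_complementarity", "C1 edit portions of the flaps are not complementary")
    }
  }
  if (length(out) == 0L)
    data.frame(level = character(0), check = character(0), message = character(0))
  else do.call(rbind, out)
}

#' Tabulate pegRNA parts and cloning oligos
#'
#' @param plan A `wtpe_plan`.
#' @return `data.frame` with one row per pegRNA: spacer, scaffold, RT
#'   template, PBS, full sequence, and the 3'-extension oligo (RT template +
#'   PBS followed by a polyT terminator signal), all in DNA alphabet.
#' @export
pegrna_parts_table <- function(plan) {
  stopifnot(inherits(plan, "wtpe_plan"))
  pegs <- Filter(Negate(is.null), list(a = plan$pegrna_a, b = plan$pegrna_b))
  do.call(rbind, lapply(names(pegs), function(nm) {
    p <- pegs[[nm]]
    data.frame(
      pegrna = nm, locus = p$site$locus_name, strand = p$site$strand,
      spacer = p$spacer_rna, scaffold = p$scaffold,
      rt_template = p$rt_template, pbs = p$pbs,
      full_sequence = p$full_sequence,
      extension_oligo = paste0(p$rt_template, p$pbs, "TTTTTTT")
    )
  }))
}
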