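# interval [a,b) in a sequence of length M, mirrored to the opposite strand
mirror_iv <- function(iv, M) c(M - iv[2], M - iv[1])

new_alleles <- function(intent, wt_refs, wt_cuts, accurate_name, accurate_ref,
                        junction_interval, residue_spacer_intervals,
                        archetypes, edit_seq, ha_len, notes = character(0)) {
  structure(
    list(intent = intent, wt_refs = wt_refs, wt_cuts = wt_cuts,
         accurate_name = accurate_name, accurate_ref = accurate_ref,
         junction_interval = as.integer(junction_interval),
         residue_spacer_intervals = residue_spacer_intervals,
         archetypes = archetypes, edit_seq = edit_seq,
         ha_len = as.integer(ha_len), notes = notes),
    class = "wtpe_alleles"
  )
}

#' @export
print.wtpe_alleles <- function(x, ...) {
  cat(sprintf("<wtpe_alleles> %s: %d WT ref(s), accurate '%s' (%d bp), edit at [%d,%d)\n",
              x$intent, length(x$wt_refs), x$accurate_name,
              nchar(x$accurate_ref), x$junction_interval[1], x$junction_interval[2]))
  if (length(x$archetypes)) cat("  archetypes:", paste(names(x$archetypes), collapse = ", "), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Predict expected alleles for a design plan
#'
#' Constructs the exact wild-type, accurate-edit and indel-archetype
#' sequences implied by a design plan. The accurate allele of a
#' homology-armed (C1) design collapses each homology arm to a single copy
#' (the successful homology-mediated join); the `ha_duplication` archetype
#' keeps both the flap copy and the genomic copy, the canonical error
#' signature of end joining between the extended flap and the PAM-proximal
#' break end. The `no_flap_join` archetype is the direct fusion of the
#' retained fragments with no edit written.
#'
#' @param plan A `wtpe_plan` from [design_pair()] or [single_edit_plan()].
#' @return A `wtpe_alleles` object: named `wt_refs` with their cut
#'   positions, `accurate_ref` with the edit `junction_interval` and 17-nt
#'   `residue_spacer_intervals` (all 0-based half-open in accurate-allele
#'   coordinates), and named `archetypes`.
#' @export
predict_alleles <- function(plan) {
  stopifnot(inherits(plan, "wtpe_plan"))
  switch(plan$intent,
         single_edit = predict_single_edit(plan),
         deletion = predict_deletion(plan),
         translocation = predict_translocation(plan),
         stop("unknown intent: ", plan$intent))
}

#' @rdname predict_alleles
#' @export
predict_single_edit <- function(plan) {
  stopifnot(plan$intent == "single_edit")
  loc <- plan$locus_a; site <- plan$site_a; spec <- plan$pegrna_a$spec
  fr <- site_frame(site, loc)
  flap <- flap_dna(plan$pegrna_a)
  ha <- spec$ha_len
  if (ha > 0L) {
    ha_part <- substr(flap, nchar(flap) - ha + 1L, nchar(flap))
    if (!identical(ha_part, substr0(fr$seq, fr$cut, fr$cut + ha)))
      stop("flap homology arm does not match the reference downstream of the cut")
  }
  ins <- substr(flap, 1L, nchar(flap) - ha)
  accP <- paste0(substr0(fr$seq, 0L, fr$cut), flap,
                 substr0(fr$seq, fr$cut + ha, fr$len))
  M <- nchar(accP)
  jP <- c(fr$cut, fr$cut + nchar(ins))
  rsP <- list(c(fr$cut - 17L, fr$cut))
  arch <- character(0)
  if (ha > 0L)
    arch["ha_duplication"] <- paste0(substr0(fr$seq, 0L, fr$cut), flap,
                                     substr0(fr$seq, fr$cut, fr$len))
  if (site$strand == "-") {
    accP <- revcomp(accP)
    jP <- mirror_iv(jP, M)
    rsP <- lapply(rsP, mirror_iv, M = M)
    arch <- vapply(arch, revcomp, character(1))
  }
  new_alleles(
    intent = "single_edit",
    wt_refs = setNames(loc$sequence, loc$name),
    wt_cuts = setNames(list(site$cut), loc$name),
    accurate_name = paste0(loc$name, "_edited"), accurate_ref = accP,
    junction_interval = jP, residue_spacer_intervals = rsP,
    archetypes = arch, edit_seq = plan$edit_seq, ha_len = ha
  )
}

#' @rdname predict_alleles
#' @export
predict_deletion <- function(plan) {
  stopifnot(plan$intent == "deletion")
  loc <- plan$locus_a
  ca <- plan$site_a$cut; cb <- plan$site_b$cut
  if (ca > cb) stop("deletion cuts out of order")
  edit <- plan$edit_seq; e <- nchar(edit); ha <- plan$ha_len
  L <- nchar(loc$sequence)
  left <- substr0(loc$sequence, 0L, ca)
  right <- substr0(loc$sequence, cb, L)
  if (ha > 0L) {
    fa <- flap_dna(plan$pegrna_a)
    ha_a <- substr(fa, nchar(fa) - ha + 1L, nchar(fa))
    if (!identical(ha_a, substr0(loc$sequence, cb, cb + ha)))
      stop("flap homology arm does not match the retained sequence beyond cut_b")
  }
  acc <- paste0(left, edit, right)
  arch <- c(no_flap_join = paste0(left, right))
  if (ha > 0L)
    arch["ha_duplication"] <- paste0(left, edit,
                                     substr0(loc$sequence, cb, cb + ha), right)
  new_alleles(
    intent = "deletion",
    wt_refs = setNames(loc$sequence, loc$name),
    wt_cuts = setNames(list(c(ca, cb)), loc$name),
    accurate_name = paste0(loc$name, "_deleted"), accurate_ref = acc,
    junction_interval = c(ca, ca + e),
    residue_spacer_intervals = list(c(ca - 17L, ca), c(ca + e, ca + e + 17L)),
    archetypes = arch, edit_seq = edit, ha_len = ha
  )
}

#' @rdname predict_alleles
#' @export
predict_translocation <- function(plan) {
  stopifnot(plan$intent == "translocation")
  la <- plan$locus_a; lb <- plan$locus_b
  ca <- plan$site_a$cut; cb <- plan$site_b$cut
  edit <- plan$edit_seq; e <- nchar(edit); ha <- plan$ha_len
  La <- nchar(la$sequence); Lb <- nchar(lb$sequence)
  left <- substr0(la$sequence, 0L, ca)
  right <- substr0(lb$sequence, cb, Lb)
  acc <- paste0(left, edit, right)
  arch <- c(no_flap_join = paste0(left, right))
  if (ha > 0L)
    arch["ha_duplication"] <- paste0(left, edit,
                                     substr0(lb$sequence, cb, cb + ha), right)
  # reciprocal (balanced) derivative; the observed product in the source
  # system was the unbalanced derivative only, so this is emitted as a
  # prediction with a note, never merged into accurate_ref
  arch["reciprocal_derivative"] <- paste0(substr0(lb$sequence, 0L, cb),
                                          revcomp(edit),
                                          substr0(la$sequence, ca, La))
  new_alleles(
    intent = "translocation",
    wt_refs = setNames(c(la$sequence, lb$sequence), c(la$name, lb$name)),
    wt_cuts = setNames(list(ca, cb), c(la$name, lb$name)),
    accurate_name = paste0("der_", lb$name), accurate_ref = acc,
    junction_interval = c(ca, ca + e),
    residue_spacer_intervals = list(c(ca - 17L, ca), c(ca + e, ca + e + 17L)),
    archetypes = arch, edit_seq = edit, ha_len = ha,
    notes = "reciprocal_derivative is predicted, not expected to be recovered (unbalanced outcome)"
  )
}

#' Write predicted alleles to FASTA with an interval sidecar
#'
#' @param alleles A `wtpe_alleles`.
#' @param fasta_path Output FASTA of WT reference(s), accurate allele and
#'   archetypes.
#' @param tsv_path Optional BED-like TSV (`seq`, `start`, `end`, `label`;
#'   0-based half-open) annotating the edit junction, residue spacers and WT
#'   cut positions.
#' @return Invisibly, the annotation `data.frame`.
#' @export
write_alleles <- function(alleles, fasta_path, tsv_path = NULL) {
  stopifnot(inherits(alleles, "wtpe_alleles"))
  seqs <- c(alleles$wt_refs,
            setNames(alleles$accurate_ref, alleles$accurate_name),
            alleles$archetypes)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  ann <- rbind(
    data.frame(seq = alleles$accurate_name,
               start = alleles$junction_interval[1],
               end = alleles$junction_interval[2], label = "edit_junction"),
    do.call(rbind, lapply(alleles$residue_spacer_intervals, function(iv)
      data.frame(seq = alleles$accurate_name, start = iv[1], end = iv[2],
                 label = "residue_spacer"))),
    do.call(rbind, lapply(names(alleles$wt_cuts), function(nm)
      data.frame(seq = nm, start = alleles$wt_cuts[[nm]],
                 end = alleles$wt_cuts[[nm]], label = "cut_site")))
  )
  if (!is.null(tsv_path))
    write.table(ann, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}
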