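# Shared toy deletion design for classifier tests
make_del_alleles <- function(seed = 301, edit = "CTGCAG", ha = 13,
                             class_ = "C1") {
  set.seed(seed)
  toy <- plant_pair()
  plan <- design_pair(toy$site_a, toy$site_b, toy$locus,
                      edit_spec(edit, ha_len = if (class_ == "C2") 0 else ha),
                      class_)
  list(toy = toy, plan = plan, alleles = predict_alleles(plan))
}

test_that("exact reference reads are classified as their own class", {
  d <- make_del_alleles()
  al <- d$alleles
  reads <- c(wt = al$wt_refs[[1]], acc = al$accurate_ref,
             hadup = al$archetypes[["ha_duplication"]],
             blunt = al$archetypes[["no_flap_join"]])
  res <- classify_reads(reads, al)
  expect_identical(res$class,
                   c("UNEDITED", "ACCURATE_EDIT", "EDIT_WITH_INDEL", "PURE_INDEL"))
  expect_identical(res$aligned_to[2], "edited")
})

test_that("indels inside the window flip the class; substitutions never do", {
  d <- make_del_alleles()
  al <- d$alleles
  js <- al$junction_interval[1]; je <- al$junction_interval[2]
  cut <- al$wt_cuts[[1]][1]
  reads <- c(
    acc_del2 = mut_del(al$accurate_ref, je + 4, 2),       # 2-nt del in window
    wt_ins4 = mut_ins(al$wt_refs[[1]], cut, "TTAA"),      # 4-nt ins at cut
    wt_sub = mut_sub(mut_sub(al$wt_refs[[1]], 10), cut + 2),
    acc_sub = mut_sub(al$accurate_ref, js + 2),           # sub inside the edit
    wt_far_del = mut_del(al$wt_refs[[1]], 30, 2),         # indel far from cuts
    acc_far_ins = mut_ins(al$accurate_ref, js - 60, "GT")
  )
  res <- classify_reads(reads, al)
  expect_identical(unname(setNames(res$class, res$read_id)),
                   c("EDIT_WITH_INDEL", "PURE_INDEL", "UNEDITED",
                     "ACCURATE_EDIT", "UNEDITED", "ACCURATE_EDIT"))
})

test_that("degenerate reads are discarded with the rest untouched", {
  d <- make_del_alleles()
  al <- d$alleles
  res <- classify_reads(c(a = "", b = "ACGT", c = al$accurate_ref), al)
  expect_identical(res$class, c("DISCARDED", "DISCARDED", "ACCURATE_EDIT"))
})

test_that("indel operations are reported at reference coordinates", {
  ops <- wtpe:::ops_from_gapped("ACG--TTACG", "ACGGGTT-CG")
  expect_identical(ops$type, c("ins", "del"))
  expect_identical(ops$pos, c(7L, 3L))
  expect_identical(ops$len, c(1L, 2L))

  d <- make_del_alleles()
  al <- d$alleles
  je <- al$junction_interval[2]
  res <- classify_reads(c(r = mut_del(al$accurate_ref, je + 4, 3)), al)
  expect_identical(res$indel_ops, sprintf("%d:del:3", je + 4))
  expect_identical(res$edit_distance, 3L)
})

test_that("range-based op extraction matches the gapped-string extraction", {
  d <- make_del_alleles(seed = 310)
  al <- d$alleles
  set.seed(311)
  reads <- vapply(1:30, function(i) {
    s <- if (i %% 2) al$accurate_ref else al$wt_refs[[1]]
    s <- mut_sub(s, sample(nchar(s), 1) - 1)
    if (i %% 3 == 0) s <- mut_ins(s, sample(nchar(s) - 1, 1), rand_dna(sample(1:4, 1)))
    if (i %% 4 == 0) s <- mut_del(s, sample(nchar(s) - 6, 1), sample(1:4, 1))
    s
  }, "")
  mat <- Biostrings::nucleotideSubstitutionMatrix(2, -4, baseOnly = FALSE)
  for (ref in c(al$wt_refs[[1]], al$accurate_ref)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reads), ref, type = "global",
      substitutionMatrix = mat, gapOpening = 12, gapExtension = 2)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    for (k in seq_along(reads)) {
      expect_identical(
        wtpe:::ops_from_ranges(Biostrings::insertion(aln)[[k]],
                               Biostrings::deletion(aln)[[k]]),
        wtpe:::ops_from_gapped(ap[k], as_[k]))
    }
  }
})

test_that("alignment scores agree with an independent Gotoh oracle", {
  d <- make_del_alleles(seed = 303)
  al <- d$alleles
  set.seed(304)
  reads <- c(
    al$accurate_ref,
    mut_del(al$accurate_ref, al$junction_interval[2] + 5, 2),
    mut_sub(al$wt_refs[[1]], 50),
    mut_ins(al$wt_refs[[1]], al$wt_cuts[[1]][1], "ACGT")
  )
  names(reads) <- paste0("r", seq_along(reads))
  res <- classify_reads(reads, al)
  for (i in seq_along(reads)) {
    ref <- if (res$aligned_to[i] == "edited") al$accurate_ref
           else al$wt_refs[[res$ref[i]]]
    expect_equal(res$score[i], nw_affine_score(reads[[i]], ref))
  }
})

test_that("classification is deterministic and order-invariant", {
  d <- make_del_alleles(seed = 305)
  al <- d$alleles
  sim <- simulate_reads(al, outcome_mixture(n_reads = 200, error_sub = 0.01),
                        seed = 9)
  res1 <- classify_reads(sim$reads, al)
  set.seed(306)
  perm <- sample(length(sim$reads))
  res2 <- classify_reads(sim$reads[perm], al)
  m <- match(res1$read_id, res2$read_id)
  expect_identical(res1$class, res2$class[m])
  expect_identical(res1$score, res2$score[m])
})

test_that("single-edit and translocation designs classify end to end", {
  # single edit, minus-strand site, homology-independent EcoRV tag
  set.seed(312)
  toy <- plant_single(160, 70, "-")
  peg <- design_single(toy$site, toy$locus,
                       edit_spec("", ha_len = 0, include_ecorv = TRUE))
  al1 <- predict_alleles(single_edit_plan(peg, toy$locus))
  mix <- outcome_mixture(0.25, 0.25, 0.25, 0.25, n_reads = 200,
                         error_sub = 0, error_indel = 0)
  sim1 <- simulate_reads(al1, mix, seed = 21)
  cls1 <- classify_reads(sim1$reads, al1)
  expect_identical(cls1$class, sim1$truth$true_class)
  # translocation between two loci; unedited reads come from both
  a <- plant_single(180, 110, "+", name = "chrA")
  b <- plant_single(180, 70, "-", name = "chrB")
  plan <- design_pair(a$site, b$site, list(a$locus, b$locus),
                      edit_spec("CTGCAG", ha_len = 10), "C1")
  al2 <- predict_alleles(plan)
  sim2 <- simulate_reads(al2, mix, seed = 22)
  cls2 <- classify_reads(sim2$reads, al2)
  expect_identical(cls2$class, sim2$truth$true_class)
  expect_setequal(unique(cls2$ref[cls2$class == "UNEDITED"]),
                  c("chrA", "chrB"))
})

test_that("demultiplexing is exact-prefix with trimming", {
  set.seed(307)
  bc <- data.frame(sample = c("s1", "s2"), barcode = c("ACGTAC", "TGCATG"),
                   primer = c("GGATTA", "GGATTA"))
  body <- replicate(10, rand_dna(40))
  reads <- setNames(c(paste0("ACGTACGGATTA", body), paste0("TGCATGGGATTA", body),
                      paste0("AAAAAAGGATTA", body[1]),  # no matching barcode
                      paste0("ACGTAGGGATTA", body[2])), # 1-mismatch barcode
                    paste0("r", 1:22))
  dm <- demultiplex_reads(reads, bc)
  expect_identical(lengths(dm$samples), c(s1 = 10L, s2 = 10L))
  expect_identical(unname(dm$samples$s1), body)
  expect_identical(dm$n_unassigned, 2L)
  expect_error(demultiplex_reads(reads, data.frame(sample = c("a", "b"),
                                                   barcode = c("AC", "AC"))),
               "duplicate")
})

test_that("outcome tables compute the published summary quantities", {
  cls <- rep(c("ACCURATE_EDIT", "EDIT_WITH_INDEL", "PURE_INDEL", "UNEDITED"),
             c(400, 300, 100, 200))
  tab <- tabulate_outcomes(data.frame(class = cls), "on_target")
  expect_equal(tab$prime_edit_freq, 70)
  expect_equal(tab$total_indel_freq, 40)
  expect_equal(tab$activity, 80)
  expect_true(tab$above_threshold)
  expect_error(tabulate_outcomes(data.frame(class = rep("DISCARDED", 5))),
               "retained")
})

test_that("activity thresholds follow the on- and off-target reporting rules", {
  mk <- function(n_edit, n_total)
    data.frame(class = rep(c("ACCURATE_EDIT", "UNEDITED"),
                           c(n_edit, n_total - n_edit)))
  # 0.15% activity: below the 0.2% on-target threshold
  expect_false(tabulate_outcomes(mk(15, 10000), "on_target")$above_threshold)
  # 0.25%: above
  expect_true(tabulate_outcomes(mk(25, 10000), "on_target")$above_threshold)
  # 0.015% clears the lowered 0.01% off-target threshold
  expect_true(tabulate_outcomes(mk(3, 20000), "off_target")$above_threshold)
  expect_false(tabulate_outcomes(mk(1, 20000), "off_target")$above_threshold)
  # boundary: "above 0.2%" is strict
  expect_false(tabulate_outcomes(mk(20, 10000), "on_target")$above_threshold)
})

test_that("editor comparisons report differences and ratios", {
  mk <- function(n_edit, n_total) {
    tabulate_outcomes(data.frame(class = rep(c("ACCURATE_EDIT", "UNEDITED"),
                                             c(n_edit, n_total - n_edit))))
  }
  a <- mk(100, 1000); b <- mk(50, 1000)
  cmp <- compare_editors(a, b)
  act <- cmp[cmp$metric == "activity", ]
  expect_equal(act$ratio, 2)
  expect_equal(act$diff, 5)
  same <- compare_editors(a, a)
  expect_true(all(same$diff == 0))
  expect_true(all(same$ratio[!is.na(same$ratio)] == 1))
  # independent division oracle on random tables
  set.seed(308)
  for (i in 1:10) {
    x <- mk(sample(10:500, 1), 1000); y <- mk(sample(10:500, 1), 1000)
    cxy <- compare_editors(x, y)
    expect_equal(cxy$ratio[cxy$metric == "activity"], x$activity / y$activity)
    expect_identical(cxy$a_below_b[cxy$metric == "activity"],
                     x$activity < y$activity)
  }
})

test_that("FASTQ round-trips through the reader and writer", {
  set.seed(309)
  reads <- setNames(replicate(5, rand_dna(30)), paste0("r", 1:5))
  tmp <- tempfile(fileext = ".fastq")
  write_fastq(reads, tmp)
  back <- read_fastq(tmp)
  expect_identical(back, reads)
})
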