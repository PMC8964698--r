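test_that("classification follows the perfect/unedited/imperfect/indel rules", {
  tg4 <- amplicon_target("fbn1_like", example_target()$amplicon_seq, 30L, "+",
                         "CBE", intended_positions = 4L)
  calls <- function(...) {
    m <- list(...)
    data.frame(position = vapply(m, `[[`, numeric(1), 1),
               ref = vapply(m, `[[`, character(1), 2),
               obs = vapply(m, `[[`, character(1), 3))
  }
  expect_identical(classify_allele(calls(list(4, "C", "T")), FALSE, tg4),
                   "perfect")
  expect_identical(classify_allele(calls(list(4, "C", "T"), list(1, "C", "T")),
                                   FALSE, tg4), "imperfect_edit")
  expect_identical(classify_allele(NULL, FALSE, tg4), "unedited")
  expect_identical(classify_allele(NULL, TRUE, tg4), "indel_allele")
  # non-intended product at the intended position is imperfect
  expect_identical(classify_allele(calls(list(4, "C", "G")), FALSE, tg4),
                   "imperfect_edit")
  # intended conversion missing, bystander present
  expect_identical(classify_allele(calls(list(1, "C", "T")), FALSE, tg4),
                   "imperfect_edit")
})

test_that("classifier agrees with the brute-force oracle over random substitution sets", {
  tg <- example_target()       # intended position 6
  ref <- FIXTURE_SPACER_CHARS
  set.seed(2024)
  n_cases <- 400
  for (k in seq_len(n_cases)) {
    nsub <- sample(0:3, 1)
    allele <- ref
    if (nsub > 0) {
      at <- sample(1:20, nsub)
      for (p in at) allele[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                ref[p]), 1)
    }
    calls_at <- which(allele != ref)
    calls <- if (length(calls_at))
      data.frame(position = calls_at, ref = ref[calls_at],
                 obs = allele[calls_at]) else NULL
    got <- classify_allele(calls, FALSE, tg)
    want <- oracle_classify(paste(allele, collapse = ""), FIXTURE_SPACER,
                            tg$intended_positions, "CBE")
    expect_identical(got, want)
  }
})

test_that("allele tables aggregate, classify and partition called reads", {
  tg <- example_target()
  amp <- tg$amplicon_seq
  perfect <- edited_amplicon(tg, list("6" = "T"))
  bystand <- edited_amplicon(tg, list("6" = "T", "1" = "T"))
  indel <- paste0(substr(amp, 1, 39), substr(amp, 42, 120))
  reads <- c(rep(amp, 50), rep(perfect, 30), rep(bystand, 15), rep(indel, 5))
  aln <- align_to_amplicon(as_consensus(reads), tg)
  at <- call_alleles(aln, tg)
  expect_identical(at$total_reads, 100L)
  expect_equal(unname(at$class_fractions),
               c(0.50, 0.30, 0.15, 0.05))
  expect_equal(at$perfect_of_total, 0.30)
  expect_equal(at$edited_of_total, 0.50)
  expect_equal(at$perfect_of_edited, 0.60)
  # classes partition called reads
  expect_identical(sum(at$class_counts), at$total_reads)
  expect_identical(sum(at$alleles$count), at$total_reads)
  expect_equal(sum(at$alleles$frequency), 1)
  expect_true(at$perfect_of_total <= at$edited_of_total)
  # edit annotations round-trip
  prow <- at$alleles[at$alleles$class == "perfect", ]
  expect_identical(prow$edits, "6:C>T")

  # 100% reference reads
  at2 <- call_alleles(align_to_amplicon(as_consensus(rep(amp, 10)), tg), tg)
  expect_identical(nrow(at2$alleles), 1L)
  expect_identical(at2$alleles$class, "unedited")
  expect_equal(at2$alleles$frequency, 1)
  expect_true(is.na(at2$perfect_of_edited))
})

test_that("reads with masked bases or partial coverage are dropped from allele calling", {
  tg <- example_target()
  amp <- tg$amplicon_seq
  q <- rep(35L, 120); q[to_amplicon_coord(tg, 10) + 1L] <- 10L
  cons <- structure(list(read_id = c("clean", "lowq", "partial"),
                         seq = c(amp, amp, substr(amp, 45, 120)),
                         qual = list(rep(35L, 120), q, rep(35L, 76)),
                         overlap_len = rep(0L, 3), n_disagreements = rep(0L, 3),
                         merged = rep(TRUE, 3)), class = "consensus_reads")
  aln <- align_to_amplicon(cons, tg)
  at <- call_alleles(aln, tg)
  expect_identical(at$total_reads, 1L)
  expect_identical(at$n_dropped, 2L)
  # but the partial read still contributes to the per-position matrix
  cm <- build_conversion_matrix(aln, tg)
  expect_identical(attr(cm, "total_reads"), 3L)
  expect_identical(cm$C[cm$position == 16], 3L)   # offset 45 covered by all
})

test_that("rare alleles pool into an 'other' bin preserving class totals", {
  tg <- example_target()
  amp <- tg$amplicon_seq
  rare1 <- edited_amplicon(tg, list("1" = "T"))
  rare2 <- edited_amplicon(tg, list("11" = "T"))
  reads <- c(rep(amp, 20), rare1, rare2)
  at <- call_alleles(align_to_amplicon(as_consensus(reads), tg), tg,
                     min_allele_count = 2L)
  expect_identical(sum(at$alleles$count), 22L)
  expect_true(any(grepl("^other_", at$alleles$allele_seq)))
  expect_equal(unname(at$class_counts[["imperfect_edit"]]), 2)
})

test_that("perfect-edit summary reports fractions and fold change", {
  tg <- example_target()
  amp <- tg$amplicon_seq
  perfect <- edited_amplicon(tg, list("6" = "T"))
  bystand <- edited_amplicon(tg, list("6" = "T", "4" = "T"))
  ctl_reads <- c(rep(amp, 56), rep(perfect, 4), rep(bystand, 40))
  trt_reads <- c(rep(amp, 52), rep(perfect, 38), rep(bystand, 10))
  ctl <- call_alleles(align_to_amplicon(as_consensus(ctl_reads), tg), tg)
  trt <- call_alleles(align_to_amplicon(as_consensus(trt_reads), tg), tg)
  s <- perfect_edit_summary(ctl, trt)
  expect_equal(s$control$perfect_of_total, 0.04)
  expect_equal(s$treated$perfect_of_total, 0.38)
  expect_equal(s$perfect_fold, 9.5)
  expect_equal(s$treated$perfect_of_edited, 38 / 48)
  expect_identical(s$control$n_imperfect_genotypes, 1L)
  same <- perfect_edit_summary(ctl, ctl)
  expect_equal(same$perfect_fold, 1.0)
})

test_that("inhibitor-style bystander suppression raises perfect-of-edited", {
  tg <- example_target()
  base_p <- c("6" = 0.4, "1" = 0.3, "11" = 0.25)
  ctl_cfg <- sim_config(tg, edit_prob = base_p, coverage = 2000L,
                        seq_error_rate = 0, seed = 61L)
  inhib <- numeric(20); inhib[c(1, 11)] <- 0.9; inhib[6] <- 0.05
  trt_cfg <- sim_config(tg, edit_prob = base_p, inhibition = inhib,
                        coverage = 2000L, seq_error_rate = 0, seed = 61L)
  ctl_pool <- simulate_allele_pool(ctl_cfg, "control")
  trt_pool <- simulate_allele_pool(trt_cfg, "treated")
  td <- withr::local_tempdir()
  tab <- list()
  for (nm in c("ctl", "trt")) {
    pool <- if (nm == "ctl") ctl_pool else trt_pool
    r1 <- file.path(td, paste0(nm, "1.fq")); r2 <- file.path(td, paste0(nm, "2.fq"))
    quiet_fastq(pool, r1, r2)
    q <- quantify_sample(read_fastq_pairs(r1, r2), tg)
    tab[[nm]] <- call_alleles(q$alignments, tg)
  }
  s <- perfect_edit_summary(tab$ctl, tab$trt)
  expect_gt(s$treated$perfect_of_edited, s$control$perfect_of_edited)
  # direction agrees with the simulator truth
  truth_dir <- (expected_class_fractions(trt_cfg, "treated")[["perfect"]] /
                  (1 - expected_class_fractions(trt_cfg, "treated")[["unedited"]])) >
    (expected_class_fractions(ctl_cfg, "control")[["perfect"]] /
       (1 - expected_class_fractions(ctl_cfg, "control")[["unedited"]]))
  expect_true(truth_dir)
})

test_that("region bounds are validated", {
  tg <- example_target()
  aln <- align_to_amplicon(as_consensus(tg$amplicon_seq), tg)
  expect_error(call_alleles(aln, tg, region = 0:5), "1\\.\\.23")
  expect_error(call_alleles(aln, tg, region = 15:22), "1\\.\\.20")
})
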