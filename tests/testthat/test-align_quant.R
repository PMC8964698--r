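test_that("identity, indel and reverse-complement alignments behave as expected", {
  tg <- example_target()
  amp <- tg$amplicon_seq

  aln <- align_to_amplicon(as_consensus(amp), tg)
  expect_true(aln$accepted[1])
  expect_identical(aln$ref_start[1], 1L)
  expect_identical(aln$ref_end[1], 120L)
  expect_identical(aln$score[1], 2 * 120)
  expect_length(aln$ins_start[[1]], 0L)
  expect_length(aln$del_start[[1]], 0L)

  # 2-nt deletion inside the protospacer (positions 10-11 -> offsets 39-40)
  del2 <- paste0(substr(amp, 1, 39), substr(amp, 42, 120))
  aln2 <- align_to_amplicon(as_consensus(del2), tg)
  expect_identical(aln2$score[1], 2 * 118 - (6 + 2))
  expect_identical(sum(aln2$del_width[[1]]), 2L)
  expect_identical(aln2$score[1], dp_align_score(del2, amp))

  # reverse-complemented read gives the same alignment after orientation flip
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(del2)))
  aln3 <- align_to_amplicon(as_consensus(rc), tg)
  expect_true(aln3$revcomp[1])
  expect_identical(aln3$score[1], aln2$score[1])
  expect_identical(aln3$del_start[[1]], aln2$del_start[[1]])

  # low-identity junk is rejected and counted
  junk <- paste(rep("A", 120), collapse = "")
  aln4 <- align_to_amplicon(as_consensus(junk), tg)
  expect_false(aln4$accepted[1])
  expect_identical(aln4$n_rejected, 1L)
})

test_that("alignment scores equal the exhaustive affine-gap DP oracle", {
  tg <- example_target()
  set.seed(314)
  n_pairs <- 60
  for (k in seq_len(n_pairs)) {
    # mutate the amplicon into a related read: substitutions plus indels
    amp <- tg$amplicon_seq
    s <- strsplit(substr(amp, sample(1:20, 1), sample(90:120, 1)), "",
                  fixed = TRUE)[[1]]
    nsub <- sample(0:6, 1)
    if (nsub > 0) {
      at <- sample(seq_along(s), nsub)
      s[at] <- sample(c("A", "C", "G", "T"), nsub, TRUE)
    }
    if (runif(1) < 0.5) {
      at <- sample(seq_along(s) - 1, 1)
      s <- append(s, sample(c("A", "C", "G", "T"), sample(1:3, 1), TRUE), at)
    }
    if (runif(1) < 0.5 && length(s) > 30) {
      at <- sample(seq_len(length(s) - 4), 1)
      s <- s[-(at:(at + sample(1:3, 1) - 1))]
    }
    read <- paste(s, collapse = "")
    aln <- align_to_amplicon(as_consensus(read), tg, min_identity = 0)
    expect_equal(aln$score[1], dp_align_best(read, amp))
  }
  # and on fully random pairs (local-in-subject shape exercised hard)
  for (k in 1:20) {
    read <- random_dna(sample(20:100, 1))
    sub <- random_dna(sample(50:150, 1))
    tgr <- suppressWarnings(
      amplicon_target("rand", paste0(random_dna(35), sub, random_dna(35)),
                      30L, "+", "CBE"))
    aln <- align_to_amplicon(as_consensus(read), tgr, min_identity = 0)
    expect_equal(aln$score[1], dp_align_best(read, tgr$amplicon_seq))
  }
})

test_that("conversion matrix counts constructed edits and conserves totals", {
  tg <- example_target()
  amp <- tg$amplicon_seq
  edited <- edited_amplicon(tg, list("6" = "T"))
  reads <- c(rep(amp, 6), rep(edited, 4))
  aln <- align_to_amplicon(as_consensus(reads), tg)
  cm <- build_conversion_matrix(aln, tg)
  expect_identical(attr(cm, "total_reads"), 10L)
  expect_identical(cm$C[cm$position == 6], 6L)
  expect_identical(cm$T[cm$position == 6], 4L)
  expect_true(all(cm$masked == 0L))
  # conservation at every position
  expect_true(all(cm$A + cm$C + cm$G + cm$T + cm$del + cm$masked == 10L))

  prof <- editing_profile(cm, tg)
  expect_equal(prof$freq[prof$position == 6], 0.4)
  # non-editable position (ref G at position 3) is not applicable
  expect_false(prof$editable[prof$position == 3])
  expect_true(is.na(prof$freq[prof$position == 3]))
})

test_that("low-quality and N bases are masked with per-position denominators", {
  tg <- example_target()
  amp <- tg$amplicon_seq
  # read with base at protospacer position 6 below the Phred-30 floor
  q <- rep(35L, 120); q[to_amplicon_coord(tg, 6) + 1L] <- 20L
  cons <- structure(list(read_id = c("a", "b"),
                         seq = c(amp, edited_amplicon(tg, list("6" = "T"))),
                         qual = list(q, rep(35L, 120)),
                         overlap_len = c(0L, 0L), n_disagreements = c(0L, 0L),
                         merged = c(TRUE, TRUE)), class = "consensus_reads")
  aln <- align_to_amplicon(cons, tg)
  cm <- build_conversion_matrix(aln, tg, min_base_qual = 30L)
  expect_identical(cm$masked[cm$position == 6], 1L)
  expect_identical(cm$T[cm$position == 6], 1L)
  prof <- editing_profile(cm, tg)
  expect_equal(prof$denominator[prof$position == 6], 1)
  expect_equal(prof$freq[prof$position == 6], 1)
  expect_equal(prof$denominator[prof$position == 4], 2)

  # an N in the read is masked regardless of quality
  ampN <- paste0(substr(amp, 1, 35), "N", substr(amp, 37, 120))
  alnN <- align_to_amplicon(as_consensus(ampN), tg)
  cmN <- build_conversion_matrix(alnN, tg)
  expect_identical(cmN$masked[cmN$position == 6], 1L)
})

test_that("zero denominators give undefined frequencies, not zero", {
  tg <- example_target()
  q <- rep(35L, 120); q[to_amplicon_coord(tg, 6) + 1L] <- 2L
  cons <- structure(list(read_id = "a", seq = tg$amplicon_seq,
                         qual = list(q), overlap_len = 0L,
                         n_disagreements = 0L, merged = TRUE),
                    class = "consensus_reads")
  cm <- build_conversion_matrix(align_to_amplicon(cons, tg), tg)
  prof <- editing_profile(cm, tg)
  expect_true(prof$editable[prof$position == 6])
  expect_true(is.na(prof$freq[prof$position == 6]))
  expect_equal(prof$denominator[prof$position == 6], 0)
})

test_that("indel frequency counts protospacer-intersecting indels only", {
  tg <- example_target()
  amp <- tg$amplicon_seq
  in_del <- paste0(substr(amp, 1, 39), substr(amp, 42, 120))   # offsets 39-40
  out_del <- paste0(substr(amp, 1, 10), substr(amp, 13, 120))  # flank only
  reads <- c(rep(amp, 97), rep(in_del, 3))
  aln <- align_to_amplicon(as_consensus(reads), tg)
  expect_equal(indel_frequency(aln, tg), 0.03)

  aln2 <- align_to_amplicon(as_consensus(c(rep(amp, 9), out_del)), tg)
  expect_equal(indel_frequency(aln2, tg), 0)

  # undefined with no accepted alignments
  aln3 <- align_to_amplicon(as_consensus(paste(rep("A", 120), collapse = "")), tg)
  expect_true(is.na(indel_frequency(aln3, tg)))
})

test_that("estimates track simulator truth within binomial error", {
  cfg <- sim_config(example_target(), edit_prob = c("6" = 0.30),
                    indel_rate = 0.02, seq_error_rate = 0.002,
                    coverage = 3000L, seed = 33L)
  pool <- simulate_allele_pool(cfg, "control")
  td <- withr::local_tempdir()
  r1 <- file.path(td, "r1.fastq"); r2 <- file.path(td, "r2.fastq")
  quiet_fastq(pool, r1, r2)
  q <- quantify_sample(read_fastq_pairs(r1, r2), example_target())
  f6 <- q$profile$freq[q$profile$position == 6]
  expect_lt(abs(f6 - 0.30), 3 * binom_sd(0.30, 3000))
  expect_lt(abs(q$indel_frequency - 0.02), 3 * binom_sd(0.02, 3000))
})

test_that("editing profiles are strand-invariant for the same allele pool", {
  tgp <- example_target()
  tgm <- fixture_target_minus()
  # same biological alleles presented on the opposite amplicon strand
  edits <- list(list(), list("6" = "T"), list("6" = "T", "1" = "T"),
                list("4" = "T"))
  counts <- c(5L, 3L, 1L, 1L)
  frag_p <- rep(mapply(function(e) edited_amplicon(tgp, e), edits), counts)
  frag_m <- rep(mapply(function(e) edited_amplicon(tgm, e), edits), counts)
  prof_p <- editing_profile(build_conversion_matrix(
    align_to_amplicon(as_consensus(frag_p), tgp), tgp), tgp)
  prof_m <- editing_profile(build_conversion_matrix(
    align_to_amplicon(as_consensus(frag_m), tgm), tgm), tgm)
  expect_equal(prof_p$freq, prof_m$freq)
  expect_identical(prof_p$ref, prof_m$ref)
})

test_that("QC filter retains samples by accepted-read floor", {
  batch <- list(s1 = 500, s2 = 1500, s3 = 2000)
  res <- amplicon_qc_filter(batch, min_reads = 1000)
  expect_identical(res$retained, c("s2", "s3"))
  expect_identical(res$excluded, "s1")
  expect_match(res$report$reason[1], "min_reads")
  all_in <- amplicon_qc_filter(batch, min_reads = 0)
  expect_length(all_in$excluded, 0L)
  expect_identical(amplicon_qc_filter(list(a = 900), 1000)$excluded, "a")
})

test_that("SAM serialization produces well-formed records", {
  tg <- example_target()
  amp <- tg$amplicon_seq
  del2 <- paste0(substr(amp, 1, 39), substr(amp, 42, 120))
  aln <- align_to_amplicon(as_consensus(c(amp, del2)), tg)
  td <- withr::local_tempdir()
  sam <- file.path(td, "out.sam")
  write_sam(aln, sam)
  lines <- readLines(sam)
  expect_identical(sum(startsWith(lines, "@")), 3L)
  body <- strsplit(lines[!startsWith(lines, "@")], "\t")
  expect_length(body, 2L)
  expect_identical(body[[1]][6], "120M")
  expect_identical(body[[2]][6], "39M2D79M")
  expect_identical(body[[1]][3], tg$name)
})
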