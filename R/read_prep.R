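#' Read paired FASTQ files into a read-pair set
#'
#' Parses R1/R2 FASTQ (plain or gzip, decompressed transparently) with
#' per-base Phred qualities. Records are paired by file order; a record-count
#' mismatch is an error naming the counts.
#'
#' @param path_r1,path_r2 FASTQ file paths.
#' @return A `read_pairs` object: list with character vectors `r1_seq`,
#'   `r2_seq`, lists of integer Phred vectors `r1_qual`, `r2_qual`, and
#'   `read_id`.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  # the constructor inside the reader warns about absent metadata columns
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path_r1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path_r2))
  if (length(r1) != length(r2))
    stop(sprintf("record count mismatch: %d reads in R1 vs %d in R2",
                 length(r1), length(r2)), call. = FALSE)
  structure(
    list(read_id = if (!is.null(names(r1))) sub("\\s.*$", "", names(r1))
                   else as.character(seq_along(r1)),
         r1_seq = unname(as.character(r1)),
         r1_qual = as_phred_list(Biostrings::quality(r1)),
         r2_seq = unname(as.character(r2)),
         r2_qual = as_phred_list(Biostrings::quality(r2))),
    class = "read_pairs")
}

as_phred_list <- function(q) {
  unname(lapply(as(q, "IntegerList"), as.integer))
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("<read_pairs> %d pairs (R1 %d-%d nt, R2 %d-%d nt)\n",
              length(x$r1_seq),
              min(nchar(x$r1_seq)), max(nchar(x$r1_seq)),
              min(nchar(x$r2_seq)), max(nchar(x$r2_seq))))
  invisible(x)
}

#' @export
length.read_pairs <- function(x) length(x$r1_seq)

#' Write sequences with qualities as FASTQ
#'
#' @param seqs character vector of sequences.
#' @param quals list of integer Phred vectors, lengths matching `seqs`.
#' @param ids record identifiers.
#' @param path output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, quals, ids, path) {
  # the constructor warns about (absent) metadata columns on its input
  qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(vapply(quals, phred_to_string, character(1)))))
  names(qs) <- ids
  Biostrings::writeQualityScaledXStringSet(qs, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

phred_to_string <- function(q) {
  rawToChar(as.raw(pmin(pmax(q, 0L), 41L) + 33L))
}

#' Merge read pairs into quality-aware consensus reads
#'
#' R2 is reverse-complemented into R1 orientation and the highest-scoring
#' ungapped overlap (score = matches - mismatches) of length at least
#' `min_overlap` with mismatch fraction at most `max_mismatch_frac` is
#' merged. At agreeing overlap columns the consensus quality is the maximum
#' of the two Phreds, capped at 41; at disagreeing columns the higher-quality
#' base wins and the consensus quality is the difference of the two Phreds.
#' Pairs with no qualifying overlap, or with a read shorter than
#' `min_overlap`, are flagged unmerged and excluded downstream.
#'
#' The default `min_overlap = 11` is the conventional minimum for calling a
#' pair overlap real; `max_mismatch_frac = 0.1` is a permissive mismatch
#' tolerance in the overlap, consistent with common read mergers.
#'
#' @param pairs a `read_pairs` object (or anything with the same fields).
#' @param min_overlap minimum overlap length (bp) to merge.
#' @param max_mismatch_frac maximum fraction of mismatching columns in the
#'   overlap.
#' @return A `consensus_reads` object: list with `seq` (character), `qual`
#'   (list of integer Phreds), `read_id`, `overlap_len`, `n_disagreements`,
#'   and logical `merged`; unmerged entries carry `NA` sequence.
#' @export
merge_pairs <- function(pairs, min_overlap = 11L, max_mismatch_frac = 0.1) {
  n <- length(pairs$r1_seq)
  bad <- nchar(pairs$r1_seq) != lengths(pairs$r1_qual) |
         nchar(pairs$r2_seq) != lengths(pairs$r2_qual)
  if (any(bad))
    stop(sprintf("malformed record: sequence/quality length mismatch at pair %d",
                 which(bad)[1]), call. = FALSE)

  r2rc <- revcomp_vec(pairs$r2_seq)
  r2rc_qual <- lapply(pairs$r2_qual, rev)

  seq_out <- rep(NA_character_, n)
  qual_out <- vector("list", n)
  overlap_len <- integer(n)
  n_dis <- integer(n)
  merged <- logical(n)

  # group pairs by (len1, len2); within a group all candidate shifts can be
  # scored for every read at once on integer code matrices
  l1 <- nchar(pairs$r1_seq); l2 <- nchar(r2rc)
  grp <- split(seq_len(n), paste(l1, l2))
  for (idx in grp) {
    L1 <- l1[idx[1]]; L2 <- l2[idx[1]]
    if (L1 < min_overlap || L2 < min_overlap) next
    m1 <- t(vapply(pairs$r1_seq[idx], utf8ToInt, integer(L1)))
    m2 <- t(vapply(r2rc[idx], utf8ToInt, integer(L2)))
    # shift s: r2rc starts at consensus column s+1; r1 occupies columns 1..L1
    shifts <- 0:(L1 - min_overlap)
    ov_len <- pmin(L1 - shifts, L2)
    mism <- matrix(0L, length(idx), length(shifts))
    for (k in seq_along(shifts)) {
      s <- shifts[k]; ov <- ov_len[k]
      mism[, k] <- rowSums(m1[, (s + 1):(s + ov), drop = FALSE] !=
                           m2[, 1:ov, drop = FALSE])
    }
    score <- matrix(ov_len, length(idx), length(shifts), byrow = TRUE) - 2L * mism
    frac <- sweep(mism, 2, ov_len, "/")
    score[frac > max_mismatch_frac] <- NA_integer_
    any_ok <- rowSums(!is.na(score)) > 0L
    best_k <- rep(NA_integer_, length(idx))
    best_k[any_ok] <- max.col(replace(score, is.na(score), -.Machine$integer.max),
                              ties.method = "first")[any_ok]

    for (j in which(any_ok)) {
      i <- idx[j]; k <- best_k[j]; s <- shifts[k]; ov <- ov_len[k]
      q1 <- pairs$r1_qual[[i]]; q2 <- r2rc_qual[[i]]
      b1 <- m1[j, ]; b2 <- m2[j, ]
      cons_len <- max(L1, s + L2)
      cb <- integer(cons_len); cq <- integer(cons_len)
      if (s > 0) { cb[1:s] <- b1[1:s]; cq[1:s] <- q1[1:s] }
      o1 <- (s + 1):(s + ov)                       # consensus cols from r1
      a1 <- b1[o1]; a2 <- b2[1:ov]
      qa1 <- q1[o1]; qa2 <- q2[1:ov]
      agree <- a1 == a2
      cb[o1] <- ifelse(agree | qa1 >= qa2, a1, a2)
      cq[o1] <- ifelse(agree, pmin(pmax(qa1, qa2), 41L), abs(qa1 - qa2))
      if (s + L2 > L1) {                           # r2 tail beyond r1
        tail_cols <- (L1 + 1):(s + L2)
        cb[tail_cols] <- b2[(ov + 1):L2]
        cq[tail_cols] <- q2[(ov + 1):L2]
      } else if (L1 > s + ov) {                    # r1 tail beyond r2 (containment)
        tail_cols <- (s + ov + 1):L1
        cb[tail_cols] <- b1[tail_cols]
        cq[tail_cols] <- q1[tail_cols]
      }
      seq_out[i] <- intToUtf8(cb)
      qual_out[[i]] <- cq
      overlap_len[i] <- ov
      n_dis[i] <- sum(!agree)
      merged[i] <- TRUE
    }
  }
  structure(list(read_id = pairs$read_id, seq = seq_out, qual = qual_out,
                 overlap_len = overlap_len, n_disagreements = n_dis,
                 merged = merged),
            class = "consensus_reads")
}

#' Merge a single read pair
#'
#' Convenience wrapper around [merge_pairs()] for one pair.
#'
#' @param r1_seq,r2_seq read sequences (R2 in its own sequencing orientation).
#' @param r1_qual,r2_qual integer Phred vectors; default constant 35.
#' @param min_overlap,max_mismatch_frac see [merge_pairs()].
#' @return list with `seq`, `qual`, `overlap_len`, `n_disagreements`,
#'   `merged`.
#' @export
merge_pair <- function(r1_seq, r2_seq,
                       r1_qual = rep(35L, nchar(r1_seq)),
                       r2_qual = rep(35L, nchar(r2_seq)),
                       min_overlap = 11L, max_mismatch_frac = 0.1) {
  pairs <- list(read_id = "pair", r1_seq = r1_seq, r1_qual = list(r1_qual),
                r2_seq = r2_seq, r2_qual = list(r2_qual))
  m <- merge_pairs(pairs, min_overlap, max_mismatch_frac)
  list(seq = m$seq[1], qual = m$qual[[1]], overlap_len = m$overlap_len[1],
       n_disagreements = m$n_disagreements[1], merged = m$merged[1])
}

#' @export
print.consensus_reads <- function(x, ...) {
  cat(sprintf("<consensus_reads> %d pairs, %d merged (%.1f%%)\n",
              length(x$seq), sum(x$merged), 100 * mean(x$merged)))
  invisible(x)
}

revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
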