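#' Affine-gap alignment scoring parameters
#'
#' BWA-MEM-like defaults: match +2, mismatch -4, gap open -6, gap extend -1,
#' so a gap of length k costs 6 + k. Reads are aligned globally in the read
#' and locally in the amplicon (free leading/trailing amplicon positions).
#'
#' @param match,mismatch,gap_open,gap_extend scoring parameters (penalties
#'   given as positive numbers for `gap_open`/`gap_extend`).
#' @return list of scoring parameters.
#' @export
alignment_scoring <- function(match = 2, mismatch = -4, gap_open = 6,
                              gap_extend = 1) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

# substitution matrix over A/C/G/T/N; N scores as a mismatch against
# everything (N bases are additionally masked during counting)
subst_matrix <- function(scoring) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m)[1:4] <- scoring$match
  m["N", "N"] <- scoring$mismatch
  m
}

#' Align consensus reads to an amplicon reference
#'
#' Global-in-read, local-in-amplicon affine-gap alignment via
#' [Biostrings::pairwiseAlignment()]. Both read orientations are tried and
#' the better-scoring one kept. Reads whose identity over aligned columns
#' (matches / alignment columns, gaps counted as columns) falls below
#' `min_identity` are rejected and counted -- the single-amplicon analog of a
#' minimum mapping-quality filter.
#'
#' @param reads a `consensus_reads` object, or a character vector of
#'   sequences (optionally with `quals` supplied).
#' @param target an `amplicon_target`.
#' @param scoring from [alignment_scoring()].
#' @param min_identity minimum fraction of matching columns (default 0.7).
#' @param quals optional list of integer Phred vectors when `reads` is a
#'   character vector; defaults to constant 35.
#' @return An `aligned_reads` object: list with per-read `read_id`, `score`,
#'   `identity`, `accepted` (logical), `revcomp` (logical, read aligned as
#'   reverse complement), `ref_start`/`ref_end` (1-based amplicon span),
#'   `read` (sequence in aligned orientation), `qual` (list of Phreds, same
#'   orientation), insertion/deletion ranges in alignment-column coordinates
#'   (`ins_start`, `ins_width`, `del_start`, `del_width`), plus the `target`
#'   and counters `n_input`, `n_rejected`.
#' @export
align_to_amplicon <- function(reads, target, scoring = alignment_scoring(),
                              min_identity = 0.7, quals = NULL) {
  if (inherits(reads, "consensus_reads")) {
    keep <- reads$merged
    ids <- reads$read_id[keep]
    seqs <- reads$seq[keep]
    quals <- reads$qual[keep]
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(seqs))) names(seqs) else as.character(seq_along(seqs))
    if (is.null(quals)) quals <- lapply(nchar(seqs), function(l) rep(35L, l))
  }
  n <- length(seqs)
  if (n == 0L)
    return(structure(list(read_id = character(), score = numeric(),
                          identity = numeric(), accepted = logical(),
                          revcomp = logical(), ref_start = integer(),
                          ref_end = integer(), read = character(),
                          qual = list(), ins_start = list(),
                          ins_width = list(), del_start = list(),
                          del_width = list(), target = target,
                          n_input = 0L, n_rejected = 0L),
                     class = "aligned_reads"))
  if (any(!nzchar(seqs))) stop("empty read sequence", call. = FALSE)

  sm <- subst_matrix(scoring)
  subject <- Biostrings::DNAString(target$amplicon_seq)
  seqs_rc <- revcomp_vec(seqs)
  fwd <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), subject, type = "global-local",
    substitutionMatrix = sm, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend)
  rc <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs_rc), subject,
    type = "global-local", substitutionMatrix = sm,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  use_rev <- Biostrings::score(rc) > Biostrings::score(fwd)

  extract <- function(aln) {
    list(score = Biostrings::score(aln),
         start = IRanges::start(Biostrings::subject(aln)),
         end = IRanges::end(Biostrings::subject(aln)),
         nmatch = Biostrings::nmatch(aln),
         ins_start = as.list(IRanges::start(Biostrings::insertion(aln))),
         ins_width = as.list(IRanges::width(Biostrings::insertion(aln))),
         del_start = as.list(IRanges::start(Biostrings::deletion(aln))),
         del_width = as.list(IRanges::width(Biostrings::deletion(aln))))
  }
  ef <- extract(fwd); er <- extract(rc)
  pick_num <- function(field) ifelse(use_rev, er[[field]], ef[[field]])
  pick_list <- function(field) {
    out <- ef[[field]]
    out[use_rev] <- er[[field]][use_rev]
    out
  }
  score <- pick_num("score")
  ref_start <- as.integer(pick_num("start"))
  ref_end <- as.integer(pick_num("end"))
  ins_start <- pick_list("ins_start"); ins_width <- pick_list("ins_width")
  del_start <- pick_list("del_start"); del_width <- pick_list("del_width")

  ins_tot <- vapply(ins_width, sum, numeric(1))
  ncol_aln <- (ref_end - ref_start + 1L) + ins_tot
  identity <- pick_num("nmatch") / ncol_aln
  accepted <- identity >= min_identity

  read <- ifelse(use_rev, seqs_rc, seqs)
  qual <- vector("list", n)
  for (i in seq_len(n))
    qual[[i]] <- if (use_rev[i]) rev(quals[[i]]) else quals[[i]]

  structure(list(read_id = ids, score = score, identity = identity,
                 accepted = accepted, revcomp = use_rev,
                 ref_start = ref_start, ref_end = ref_end, read = read,
                 qual = qual, ins_start = ins_start, ins_width = ins_width,
                 del_start = del_start, del_width = del_width,
                 target = target, n_input = n, n_rejected = sum(!accepted)),
            class = "aligned_reads")
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf("<aligned_reads> target %s: %d reads, %d accepted, %d rejected (identity < threshold)\n",
              x$target$name, x$n_input, sum(x$accepted), x$n_rejected))
  invisible(x)
}

# Per accepted read, observations over protospacer positions 1..20 in the
# protospacer-strand frame: matrix of base codes plus quality, deletion and
# insertion-adjacency flags. Internal workhorse shared by the conversion
# matrix and the allele caller.
#
# Returns a list with, per accepted read (rows): obs (character matrix n x 20,
# "-" = deletion, NA = position not covered), qual (integer matrix), ins
# (logical matrix: insertion immediately 3' of p on the protospacer strand),
# has_indel (any inserted/deleted nt with footprint intersecting positions
# 1..20), covered (logical matrix).
protospacer_observations <- function(alignments, target) {
  acc <- which(alignments$accepted)
  n <- length(acc)
  offs <- to_amplicon_coord(target, 1:20)         # 0-based amplicon offsets
  span <- range(offs)
  obs <- matrix(NA_character_, n, 20)
  qual <- matrix(NA_integer_, n, 20)
  ins <- matrix(FALSE, n, 20)
  has_indel <- logical(n)
  minus <- target$protospacer_strand == "-"
  read_chars <- strsplit(alignments$read[acc], "", fixed = TRUE)

  for (j in seq_len(n)) {
    i <- acc[j]
    cs <- alignments$ref_start[i]; ce <- alignments$ref_end[i]
    iw <- alignments$ins_width[[i]]; is_ <- alignments$ins_start[[i]]
    dw <- alignments$del_width[[i]]; ds <- alignments$del_start[[i]]
    ncol_aln <- (ce - cs + 1L) + sum(iw)
    is_ins <- logical(ncol_aln); is_del <- logical(ncol_aln)
    for (k in seq_along(is_)) is_ins[is_[k]:(is_[k] + iw[k] - 1L)] <- TRUE
    for (k in seq_along(ds)) is_del[ds[k]:(ds[k] + dw[k] - 1L)] <- TRUE

    # non-insertion columns consume the subject; non-deletion columns
    # consume the read
    subj0 <- rep(NA_integer_, ncol_aln)           # 0-based amplicon offset
    subj0[!is_ins] <- cs - 1L + seq_len(sum(!is_ins)) - 1L
    patidx <- cumsum(!is_del)
    q <- alignments$qual[[i]]
    rc <- read_chars[[j]]

    col_of <- match(offs, subj0)
    covered <- !is.na(col_of)
    if (any(covered)) {
      cc <- col_of[covered]
      base <- character(length(cc)); qv <- rep(NA_integer_, length(cc))
      deleted <- is_del[cc]
      base[deleted] <- "-"
      base[!deleted] <- rc[patidx[cc[!deleted]]]
      qv[!deleted] <- q[patidx[cc[!deleted]]]
      if (minus) base <- ifelse(base == "-", "-", complement_chars(base))
      obs[j, covered] <- base
      qual[j, covered] <- qv
    }

    if (length(is_)) {
      # 0-based forward-strand offset of the base immediately left of each
      # insertion (cs - 2 when the insertion precedes the covered span)
      left0 <- vapply(is_, function(s) {
        if (s <= 1L) cs - 2L else subj0[s - 1L]
      }, integer(1))
      # insertion adjacent 3' of protospacer position p on the protospacer
      # strand: + strand, right of offset(p); - strand, left of offset(p)
      hit <- if (!minus) match(left0, offs) else match(left0 + 1L, offs)
      hit <- hit[!is.na(hit)]
      if (length(hit)) ins[j, hit] <- TRUE
      has_indel[j] <- has_indel[j] ||
        any(left0 >= span[1] - 1L & left0 <= span[2])
    }
    if (any(is_del))
      has_indel[j] <- has_indel[j] ||
        any(subj0[is_del] >= span[1] & subj0[is_del] <= span[2])
  }
  list(acc = acc, obs = obs, qual = qual, ins = ins, has_indel = has_indel)
}

#' Build a per-position base-conversion count matrix
#'
#' For each protospacer position 1..20 (protospacer-strand frame), counts the
#' observed A/C/G/T bases, deletion-spanning reads, insertion-adjacent reads
#' and low-quality-masked bases among accepted alignments. Bases with Phred
#' below `min_base_qual` (default 30, the usual base-quality floor for
#' amplicon variant counting) and all N calls are masked. Reads not covering
#' a position (alignment ends within the protospacer) count as masked at that
#' position so that per-position counts always sum to the number of accepted
#' reads.
#'
#' @param alignments an `aligned_reads` object.
#' @param target the same `amplicon_target` used for alignment.
#' @param min_base_qual Phred threshold below which a base call is masked.
#' @return A `conversion_matrix`: data frame with one row per position
#'   (`position`, `ref`, `A`, `C`, `G`, `T`, `del`, `masked`, `ins_adj`),
#'   plus attributes `total_reads` (accepted alignments) and
#'   `indel_reads` (reads with >= 1 inserted/deleted nt in the protospacer).
#' @export
build_conversion_matrix <- function(alignments, target, min_base_qual = 30L) {
  if (!identical(alignments$target$name, target$name))
    stop("alignments were built for a different target", call. = FALSE)
  po <- protospacer_observations(alignments, target)
  n <- length(po$acc)
  counts <- matrix(0L, 20, 7,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del",
                                           "masked", "ins_adj")))
  for (p in 1:20) {
    b <- po$obs[, p]
    q <- po$qual[, p]
    is_del <- !is.na(b) & b == "-"
    masked <- is.na(b) | (!is_del & (b == "N" | is.na(q) | q < min_base_qual))
    clean <- !is_del & !masked
    counts[p, "A"] <- sum(clean & b == "A")
    counts[p, "C"] <- sum(clean & b == "C")
    counts[p, "G"] <- sum(clean & b == "G")
    counts[p, "T"] <- sum(clean & b == "T")
    counts[p, "del"] <- sum(is_del)
    counts[p, "masked"] <- sum(masked)
    counts[p, "ins_adj"] <- sum(po$ins[, p])
  }
  out <- data.frame(position = 1:20,
                    ref = vapply(1:20, function(p) reference_base(target, p),
                                 character(1)),
                    counts[, 1:6, drop = FALSE],
                    ins_adj = counts[, "ins_adj"])
  attr(out, "total_reads") <- n
  attr(out, "indel_reads") <- sum(po$has_indel)
  attr(out, "target_name") <- target$name
  attr(out, "editor") <- target$editor
  class(out) <- c("conversion_matrix", "data.frame")
  out
}

#' @export
print.conversion_matrix <- function(x, ...) {
  cat(sprintf("<conversion_matrix> target %s (%s), %d accepted reads, %d with protospacer indel\n",
              attr(x, "target_name"), attr(x, "editor"),
              attr(x, "total_reads"), attr(x, "indel_reads")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Per-position intended-conversion frequency profile
#'
#' The editing frequency at position p is the count of the intended product
#' base (T for CBE, G for ABE) divided by the quality-passing base calls at p
#' (total accepted reads minus masked minus deletion-spanning), computed only
#' at positions whose reference base is editable (C for CBE, A for ABE).
#' Other positions are not applicable (`NA` frequency, `editable = FALSE`);
#' editable positions with a zero denominator are undefined (`NA` frequency,
#' `editable = TRUE`).
#'
#' @param matrix a `conversion_matrix`.
#' @param target the corresponding `amplicon_target`.
#' @param label,replicate optional sample/condition label and replicate id
#'   carried on the result.
#' @return An `editing_profile`: data frame with `position`, `ref`,
#'   `editable`, `freq`, `denominator`, and attributes `editor`, `label`,
#'   `replicate`.
#' @export
editing_profile <- function(matrix, target, label = NA_character_,
                            replicate = NA_integer_) {
  if (!identical(attr(matrix, "target_name"), target$name))
    stop("conversion matrix was built for a different target", call. = FALSE)
  sub <- editable_base(target$editor)
  prod <- product_base(target$editor)
  editable <- matrix$ref == sub
  denom <- attr(matrix, "total_reads") - matrix$masked - matrix$del
  freq <- ifelse(editable & denom > 0, matrix[[prod]] / denom, NA_real_)
  out <- data.frame(position = matrix$position, ref = matrix$ref,
                    editable = editable, freq = freq, denominator = denom)
  attr(out, "editor") <- target$editor
  attr(out, "target_name") <- target$name
  attr(out, "label") <- label
  attr(out, "replicate") <- replicate
  class(out) <- c("editing_profile", "data.frame")
  out
}

#' @export
print.editing_profile <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<editing_profile> target %s (%s)%s\n", attr(x, "target_name"),
              attr(x, "editor"),
              if (!is.na(lab)) paste0(", sample ", lab) else ""))
  ed <- x[x$editable, ]
  cat(sprintf("  %d editable positions; frequencies: %s\n", nrow(ed),
              paste(sprintf("p%d=%.3f", ed$position, ed$freq), collapse = " ")))
  invisible(x)
}

#' Protospacer indel frequency
#'
#' Number of accepted reads containing at least one inserted or deleted
#' nucleotide whose amplicon footprint intersects protospacer positions
#' 1..20, divided by the total accepted alignments. Undefined (NA, with a
#' message attribute) when no alignments were accepted.
#'
#' @param alignments an `aligned_reads` object.
#' @param target the corresponding `amplicon_target`.
#' @return numeric fraction, or `NA` when undefined.
#' @export
indel_frequency <- function(alignments, target) {
  po <- protospacer_observations(alignments, target)
  n <- length(po$acc)
  if (n == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "no accepted alignments"
    return(out)
  }
  sum(po$has_indel) / n
}

#' Filter amplicon samples by accepted-read count
#'
#' Drops samples whose accepted-read total falls below `min_reads`, with a
#' per-sample exclusion report. The threshold is fully configurable and
#' defaults to 0 (filter disabled); typical deep-sequencing runs warrant a
#' floor of a few hundred to a few thousand reads per amplicon.
#'
#' @param samples named list (or vector) of per-sample accepted-read totals,
#'   or a named list of objects carrying `n_accepted`.
#' @param min_reads minimum accepted reads to retain a sample.
#' @return list with `retained` (names), `excluded` (names) and `report`
#'   (data frame: sample, reads, retained, reason).
#' @export
amplicon_qc_filter <- function(samples, min_reads = 0L) {
  reads <- if (is.list(samples) && length(samples) && is.list(samples[[1]]))
    vapply(samples, `[[`, numeric(1), "n_accepted") else unlist(samples)
  if (is.null(names(reads))) names(reads) <- as.character(seq_along(reads))
  keep <- reads >= min_reads
  report <- data.frame(sample = names(reads), reads = as.numeric(reads),
                       retained = keep,
                       reason = ifelse(keep, "",
                                       sprintf("accepted reads %d < min_reads %d",
                                               as.integer(reads), as.integer(min_reads))),
                       row.names = NULL)
  list(retained = names(reads)[keep], excluded = names(reads)[!keep],
       report = report)
}

#' Write accepted alignments as SAM
#'
#' Minimal single-reference SAM serialization of accepted alignments
#' (standard header, amplicon as the reference), for inspection in standard
#' tools.
#'
#' @param alignments an `aligned_reads` object.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path) {
  target <- alignments$target
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", target$name,
                       nchar(target$amplicon_seq)),
               "@PG\tID:bequant\tPN:bequant"), con)
  for (i in which(alignments$accepted)) {
    cs <- alignments$ref_start[i]; ce <- alignments$ref_end[i]
    iw <- alignments$ins_width[[i]]; is_ <- alignments$ins_start[[i]]
    dw <- alignments$del_width[[i]]; ds <- alignments$del_start[[i]]
    ncol_aln <- (ce - cs + 1L) + sum(iw)
    op <- rep("M", ncol_aln)
    for (k in seq_along(is_)) op[is_[k]:(is_[k] + iw[k] - 1L)] <- "I"
    for (k in seq_along(ds)) op[ds[k]:(ds[k] + dw[k] - 1L)] <- "D"
    r <- rle(op)
    cigar <- paste0(r$lengths, r$values, collapse = "")
    q <- alignments$qual[[i]]
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       alignments$read_id[i],
                       if (alignments$revcomp[i]) 16L else 0L,
                       target$name, cs, cigar, alignments$read[i],
                       phred_to_string(q)), con)
  }
  invisible(path)
}
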