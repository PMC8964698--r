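# Shared fixtures, built in code.

# the fixture protospacer of example_target(), written out by hand:
# positions 1..20 with C at 1,4,6,8,11,16 and A at 2,7,10,14,18,20
FIXTURE_SPACER <- "CAGCTCACGACTGATCGATA"
FIXTURE_SPACER_CHARS <- strsplit(FIXTURE_SPACER, "", fixed = TRUE)[[1]]

# same locus presented on the opposite amplicon strand: the amplicon is
# reverse-complemented, so the 20-nt window starts at offset
# 120 - (30 + 20) = 70 and the protospacer reads on the minus strand
fixture_target_minus <- function(editor = "CBE") {
  plus <- example_target(editor)
  amp_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus$amplicon_seq)))
  amplicon_target(paste0(plus$name, "_minus"), amp_rc,
                  protospacer_start = 120L - (30L + 20L),
                  protospacer_strand = "-", editor = editor,
                  intended_positions = plus$intended_positions)
}

# build a consensus_reads object directly from sequences (qualities constant)
as_consensus <- function(seqs, qual = 35L, ids = NULL) {
  structure(list(
    read_id = ids %||% sprintf("read_%d", seq_along(seqs)),
    seq = seqs,
    qual = lapply(nchar(seqs), function(l) rep(as.integer(qual), l)),
    overlap_len = rep(0L, length(seqs)),
    n_disagreements = rep(0L, length(seqs)),
    merged = rep(TRUE, length(seqs))),
    class = "consensus_reads")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# amplicon sequence with substitutions applied at protospacer positions
# (protospacer-strand bases), via the target's own coordinate map
edited_amplicon <- function(target, edits = list()) {
  s <- strsplit(target$amplicon_seq, "", fixed = TRUE)[[1]]
  for (e in names(edits)) {
    p <- as.integer(e)
    b <- edits[[e]]
    off <- to_amplicon_coord(target, p)
    if (target$protospacer_strand == "-") b <- chartr("ACGT", "TGCA", b)
    s[off + 1L] <- b
  }
  paste(s, collapse = "")
}

# split a fragment into an R1/R2 pair (R2 reverse-complemented), constant quality
fragment_to_pair <- function(frag, read_length = 100L, qual = 35L) {
  L <- nchar(frag)
  rl <- min(read_length, L)
  r1 <- substr(frag, 1L, rl)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(frag, L - rl + 1L, L))))
  list(r1_seq = r1, r2_seq = r2,
       r1_qual = rep(as.integer(qual), rl), r2_qual = rep(as.integer(qual), rl))
}

pairs_from_fragments <- function(frags, read_length = 100L, qual = 35L) {
  ps <- lapply(frags, fragment_to_pair, read_length = read_length, qual = qual)
  structure(list(read_id = sprintf("frag_%d", seq_along(frags)),
                 r1_seq = vapply(ps, `[[`, character(1), "r1_seq"),
                 r1_qual = lapply(ps, `[[`, "r1_qual"),
                 r2_seq = vapply(ps, `[[`, character(1), "r2_seq"),
                 r2_qual = lapply(ps, `[[`, "r2_qual")),
            class = "read_pairs")
}

quiet_fastq <- function(pool, r1, r2) suppressWarnings(pool_to_fastq(pool, r1, r2))

# hand-built editing profile: freqs is a named vector over positions, NA
# allowed; unnamed positions are non-editable
make_profile <- function(freqs, editor = "CBE", target_name = "fix",
                         label = NA_character_, denominator = 1000) {
  pos <- 1:20
  editable <- pos %in% as.integer(names(freqs))
  f <- rep(NA_real_, 20)
  f[as.integer(names(freqs))] <- as.numeric(freqs)
  out <- data.frame(position = pos, ref = ifelse(editable, "C", "G"),
                    editable = editable, freq = f,
                    denominator = ifelse(editable, denominator, 0))
  attr(out, "editor") <- editor
  attr(out, "target_name") <- target_name
  attr(out, "label") <- label
  attr(out, "replicate") <- NA_integer_
  class(out) <- c("editing_profile", "data.frame")
  out
}
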