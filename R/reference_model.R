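#' Define an amplicon target for base-editing quantification
#'
#' An `amplicon_target` is the coordinate authority for all position-indexed
#' statistics in the package: it ties a sequenced amplicon reference to the
#' 20-nt protospacer embedded in it, the protospacer strand, the editor type
#' and the positions carrying the intended edit. Protospacer positions are
#' 1-based, 1..20, with the PAM trinucleotide at positions 21..23 (the field's
#' standard numbering); amplicon offsets are 0-based internally.
#'
#' `protospacer_start` is always the leftmost 0-based offset of the 20-nt
#' protospacer window on the forward strand of `amplicon_seq`, for both
#' strands. On strand `"+"` protospacer position 1 sits at that offset and
#' positions run rightward, with the PAM immediately 3' (offsets
#' `protospacer_start + 20 .. + 22`). On strand `"-"` position 1 sits at the
#' rightmost offset of the window and positions run leftward, the PAM
#' extending further left; all reported bases are complemented into the
#' protospacer-strand frame.
#'
#' Validation enforces that the protospacer (plus PAM) lies wholly within the
#' amplicon with at least `min_flank` nucleotides of flank on each side, that
#' intended positions carry the editable base (C for CBE, A for ABE) on the
#' protospacer strand, and warns -- without failing -- when the PAM does not
#' match NGG, so non-NGG designs remain analyzable.
#'
#' @param name identifier for the target.
#' @param amplicon_seq reference amplicon sequence as sequenced (A/C/G/T).
#' @param protospacer_start 0-based leftmost offset of the 20-nt protospacer
#'   window on the forward strand of `amplicon_seq`.
#' @param protospacer_strand `"+"` or `"-"`, strand of the protospacer
#'   relative to `amplicon_seq`.
#' @param editor `"CBE"` (C->T) or `"ABE"` (A->G).
#' @param intended_positions integer vector of protospacer positions (1..20)
#'   carrying the intended edit.
#' @param min_flank minimum flank (nt) required on each side of the
#'   protospacer window within the amplicon.
#' @return An object of class `amplicon_target`.
#' @examples
#' tg <- example_target()
#' tg
#' reference_base(tg, 4)
#' @export
amplicon_target <- function(name, amplicon_seq, protospacer_start,
                            protospacer_strand = c("+", "-"),
                            editor = c("CBE", "ABE"),
                            intended_positions = integer(),
                            min_flank = 10L) {
  protospacer_strand <- match.arg(protospacer_strand)
  editor <- match.arg(editor)
  amplicon_seq <- toupper(as.character(amplicon_seq))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (grepl("[^ACGT]", amplicon_seq))
    stop("amplicon_seq must contain only A/C/G/T", call. = FALSE)
  protospacer_start <- as.integer(protospacer_start)
  intended_positions <- sort(unique(as.integer(intended_positions)))
  if (length(intended_positions) && (any(intended_positions < 1L) ||
                                     any(intended_positions > 20L)))
    stop("intended_positions must lie in 1..20", call. = FALSE)

  len <- nchar(amplicon_seq)
  # PAM occupies 3 nt beyond the window on the protospacer 3' side
  left_need  <- if (protospacer_strand == "+") min_flank else min_flank + 3L
  right_need <- if (protospacer_strand == "+") min_flank + 3L else min_flank
  if (protospacer_start < left_need ||
      protospacer_start + 20L + right_need > len)
    stop(sprintf(
      "protospacer window must lie within the amplicon with >= %d nt flank on each side (plus the PAM)",
      min_flank), call. = FALSE)

  target <- structure(
    list(name = name,
         amplicon_seq = amplicon_seq,
         protospacer_start = protospacer_start,
         protospacer_strand = protospacer_strand,
         editor = editor,
         intended_positions = intended_positions,
         pam_seq = NA_character_),
    class = "amplicon_target")
  target$pam_seq <- paste(vapply(21:23, function(p) reference_base(target, p),
                                 character(1)), collapse = "")

  if (!grepl("^[ACGT]GG$", target$pam_seq))
    warning(sprintf("target '%s': PAM '%s' does not match NGG", name,
                    target$pam_seq), call. = FALSE)
  editable <- editable_base(editor)
  if (length(intended_positions)) {
    ref <- vapply(intended_positions, function(p) reference_base(target, p),
                  character(1))
    bad <- intended_positions[ref != editable]
    if (length(bad))
      stop(sprintf(
        "target '%s': intended position(s) %s do not carry %s on the protospacer strand",
        name, paste(bad, collapse = ", "), editable), call. = FALSE)
  }
  target
}

#' @export
print.amplicon_target <- function(x, ...) {
  cat(sprintf("<amplicon_target> %s (%s, strand %s)\n", x$name, x$editor,
              x$protospacer_strand))
  cat(sprintf("  amplicon: %d nt; protospacer window at offset %d; PAM %s\n",
              nchar(x$amplicon_seq), x$protospacer_start, x$pam_seq))
  cat(sprintf("  protospacer: %s\n", protospacer_seq(x)))
  cat(sprintf("  intended positions: %s\n",
              if (length(x$intended_positions))
                paste(x$intended_positions, collapse = ", ") else "(none)"))
  invisible(x)
}

# intended substrate base on the protospacer strand
editable_base <- function(editor) if (editor == "CBE") "C" else "A"
# intended product base
product_base <- function(editor) if (editor == "CBE") "T" else "G"

#' Protospacer sequence of a target
#'
#' Returns the 20-nt protospacer on the protospacer strand (what the sgRNA
#' spacer matches).
#' @param target an `amplicon_target`.
#' @return 20-character string.
#' @export
protospacer_seq <- function(target) {
  paste(vapply(1:20, function(p) reference_base(target, p), character(1)),
        collapse = "")
}

#' Map a protospacer position to an amplicon offset
#'
#' Protospacer positions 1..20 plus PAM positions 21..23 map to 0-based
#' offsets on the forward strand of the amplicon. For strand `"+"` the offset
#' is `protospacer_start + (p - 1)`; for strand `"-"` it is
#' `protospacer_start + (20 - p)`, so that positions count toward the PAM on
#' the protospacer strand. Inverse of [from_amplicon_coord()].
#'
#' @param target an `amplicon_target`.
#' @param p protospacer position(s), 1..23 (21..23 are the PAM).
#' @return integer 0-based amplicon offset(s).
#' @export
to_amplicon_coord <- function(target, p) {
  p <- as.integer(p)
  if (any(p < 1L) || any(p > 23L))
    stop("protospacer position must lie in 1..23", call. = FALSE)
  if (target$protospacer_strand == "+")
    target$protospacer_start + (p - 1L)
  else
    target$protospacer_start + (20L - p)
}

#' Map an amplicon offset back to a protospacer position
#'
#' @param target an `amplicon_target`.
#' @param offset 0-based amplicon offset(s).
#' @return integer protospacer position(s) in 1..23, or `NA` for offsets
#'   outside the protospacer+PAM span.
#' @export
from_amplicon_coord <- function(target, offset) {
  offset <- as.integer(offset)
  p <- if (target$protospacer_strand == "+")
    offset - target$protospacer_start + 1L
  else
    20L - (offset - target$protospacer_start)
  p[p < 1L | p > 23L] <- NA_integer_
  p
}

#' Reference base at a protospacer position
#'
#' Returns the amplicon reference base at position `p`, reported on the
#' protospacer strand (complemented when the protospacer lies on the
#' amplicon's reverse strand) -- the frame in which C->T (CBE) or A->G (ABE)
#' conversions are observed regardless of sequencing strand.
#'
#' @param target an `amplicon_target`.
#' @param p protospacer position(s), 1..23.
#' @return character base(s).
#' @export
reference_base <- function(target, p) {
  off <- to_amplicon_coord(target, p)
  b <- substring(target$amplicon_seq, off + 1L, off + 1L)
  if (target$protospacer_strand == "-") b <- complement_chars(b)
  b
}

complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' On-target / out-of-window partition of the protospacer
#'
#' Canonical editing windows: positions 4..8 for CBEs, 4..7 for ABE7.10-class
#' editors; all remaining positions in 1..20 are out-of-window. An explicit
#' `override` set replaces the editor default (e.g. to probe a single
#' position).
#'
#' @param editor `"CBE"` or `"ABE"`.
#' @param override optional integer set of on-target positions (subset of
#'   1..20) replacing the editor default.
#' @return A `window_partition`: list with integer vectors `on_target` and
#'   `out_of_window` forming a partition of 1..20.
#' @examples
#' window_partition("CBE")$on_target   # 4 5 6 7 8
#' window_partition("ABE")$on_target   # 4 5 6 7
#' @export
window_partition <- function(editor = c("CBE", "ABE"), override = NULL) {
  editor <- match.arg(editor)
  on <- if (!is.null(override)) sort(unique(as.integer(override)))
        else if (editor == "CBE") 4:8 else 4:7
  if (length(on) == 0L || any(on < 1L) || any(on > 20L))
    stop("window override must be a non-empty subset of 1..20", call. = FALSE)
  out <- setdiff(1:20, on)
  structure(list(on_target = as.integer(on), out_of_window = as.integer(out)),
            class = "window_partition")
}

#' @export
print.window_partition <- function(x, ...) {
  cat("<window_partition>\n")
  cat("  on-target:    ", paste(x$on_target, collapse = " "), "\n")
  cat("  out-of-window:", paste(x$out_of_window, collapse = " "), "\n")
  invisible(x)
}

#' Read amplicon target definitions from a YAML config
#'
#' The config holds one record per amplicon under `targets:`, each with
#' `name`, either `amplicon_seq` (inline) or `amplicon_fasta` (path, first
#' record used; relative paths resolved against the config file), either
#' `protospacer_seq` (located in the amplicon, strand required) or
#' `protospacer_start` (0-based), `protospacer_strand`, `editor`, and
#' `intended_positions`.
#'
#' @param path YAML file path.
#' @return named list of `amplicon_target` objects.
#' @export
read_target_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$targets)) stop("config has no 'targets' section", call. = FALSE)
  out <- lapply(cfg$targets, function(rec) {
    seq <- rec$amplicon_seq
    if (is.null(seq)) {
      fa <- rec$amplicon_fasta
      if (is.null(fa)) stop("target record needs amplicon_seq or amplicon_fasta",
                            call. = FALSE)
      if (!file.exists(fa)) fa <- file.path(dirname(path), fa)
      seq <- as.character(Biostrings::readDNAStringSet(fa)[[1]])
    }
    seq <- toupper(seq)
    strand <- rec$protospacer_strand %||% "+"
    start <- rec$protospacer_start
    if (is.null(start)) {
      if (is.null(rec$protospacer_seq))
        stop("target record needs protospacer_start or protospacer_seq",
             call. = FALSE)
      ps <- toupper(rec$protospacer_seq)
      query <- if (strand == "+") ps else revcomp(ps)
      hit <- gregexpr(query, seq, fixed = TRUE)[[1]]
      if (hit[1] == -1L) stop(sprintf("protospacer not found in amplicon '%s'",
                                      rec$name), call. = FALSE)
      if (length(hit) > 1L) stop(sprintf("protospacer matches amplicon '%s' more than once",
                                         rec$name), call. = FALSE)
      start <- hit[1] - 1L
    }
    amplicon_target(name = rec$name, amplicon_seq = seq,
                    protospacer_start = start, protospacer_strand = strand,
                    editor = rec$editor %||% "CBE",
                    intended_positions = unlist(rec$intended_positions))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in example target
#'
#' A 120-nt amplicon with a CBE protospacer on the forward strand at offset
#' 30 (NGG PAM at offsets 50..52) and intended edit at protospacer position
#' 6. Shipped with the package for examples and tests; the same sequence is
#' available as FASTA plus YAML config under `inst/extdata/`.
#'
#' @param editor `"CBE"` (default) or `"ABE"` (an A-bearing window position
#'   becomes the intended position).
#' @return an `amplicon_target`.
#' @export
example_target <- function(editor = c("CBE", "ABE")) {
  editor <- match.arg(editor)
  amp <- paste0(
    "ATGCTAGCTAGGATCGATCGTACGATCGAT",          # 30-nt left flank
    "CAGCTCACGACTGATCGATA", "CGG",             # protospacer (20) + PAM CGG
    "ATCGATCGATTAGCTAGCATGCATGCATCGATCGATCGATCATCGATCGATCGATCGAGCTAGCTAC")
  if (editor == "CBE")
    amplicon_target("example_CBE", amp, 30L, "+", "CBE",
                    intended_positions = 6L)
  else
    amplicon_target("example_ABE", amp, 30L, "+", "ABE",
                    intended_positions = 7L)
}
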