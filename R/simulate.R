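#' Configure a synthetic base-editing amplicon simulation
#'
#' Defines the generative truth for a simulated sample: window-shaped
#' per-position editing probabilities over the protospacer, a per-position
#' inhibition vector applied in the treated condition, low-rate indels inside
#' the protospacer, and Illumina-like per-base miscalls with Phred quality
#' strings on overlapping read pairs. Everything downstream of a config is a
#' deterministic function of its `seed`.
#'
#' @param target an `amplicon_target`.
#' @param edit_prob per-position editing probability: either a full length-20
#'   vector or a named vector like `c("4" = 0.4, "6" = 0.3)` (positions not
#'   named get 0). Non-zero entries are only allowed at editable positions
#'   (C for CBE, A for ABE on the protospacer strand).
#' @param inhibition per-position truth inhibition rate in `[0, 1]` applied
#'   in the treated condition (treated probability = `edit_prob * (1 -
#'   inhibition)`); same vector conventions as `edit_prob`; default 0.
#' @param coedit_correlation in `[0, 1)`: Gaussian-copula correlation of
#'   per-position edit events within a read (shared editing propensity);
#'   0 = independent edits.
#' @param indel_rate per-read probability of one indel placed uniformly over
#'   protospacer positions 1..20.
#' @param indel_length_probs named distribution over small indel lengths.
#' @param seq_error_rate per-base miscall probability.
#' @param qual_mean,qual_sd mean/dispersion of simulated Phred scores
#'   (truncated to 2..41); the default mean 35 leaves a realistic tail below
#'   a Phred-30 masking threshold.
#' @param read_length read length (nt); `2 * read_length` must exceed the
#'   amplicon length by at least `min_overlap_check` so pairs overlap.
#' @param coverage reads per sample.
#' @param seed integer seed fixing the full output.
#' @param min_overlap_check minimum guaranteed pair overlap (default 11).
#' @return a `sim_config` object.
#' @export
sim_config <- function(target, edit_prob, inhibition = 0,
                       coedit_correlation = 0, indel_rate = 0,
                       indel_length_probs = c("1" = 0.6, "2" = 0.3, "3" = 0.1),
                       seq_error_rate = 0.002, qual_mean = 35, qual_sd = 3,
                       read_length = 100L, coverage = 2000L, seed = 1L,
                       min_overlap_check = 11L) {
  expand <- function(v, what) {
    out <- numeric(20)
    if (!is.null(names(v)) && any(nzchar(names(v)))) {
      p <- as.integer(names(v))
      if (any(is.na(p)) || any(p < 1L) || any(p > 20L))
        stop(sprintf("%s names must be positions 1..20", what), call. = FALSE)
      out[p] <- as.numeric(v)
    } else if (length(v) == 1L) out[] <- v
    else if (length(v) == 20L) out <- as.numeric(v)
    else stop(sprintf("%s must be length 1, length 20, or position-named", what),
              call. = FALSE)
    if (any(out < 0) || any(out > 1))
      stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
    out
  }
  edit_prob <- expand(edit_prob, "edit_prob")
  inhibition <- expand(inhibition, "inhibition")
  editable <- protospacer_chars(target) == editable_base(target$editor)
  if (any(edit_prob[!editable] > 0))
    stop("edit_prob must be zero at non-editable positions", call. = FALSE)
  stopifnot(coedit_correlation >= 0, coedit_correlation < 1,
            indel_rate >= 0, indel_rate <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1)
  if (abs(sum(indel_length_probs) - 1) > 1e-9)
    stop("indel_length_probs must sum to 1", call. = FALSE)
  if (2L * read_length < nchar(target$amplicon_seq) + min_overlap_check)
    stop(sprintf(
      "2 * read_length must exceed the amplicon length by >= %d nt so pairs overlap",
      min_overlap_check), call. = FALSE)
  structure(list(target = target, edit_prob = edit_prob,
                 inhibition = inhibition,
                 coedit_correlation = coedit_correlation,
                 indel_rate = indel_rate,
                 indel_length_probs = indel_length_probs,
                 seq_error_rate = seq_error_rate, qual_mean = qual_mean,
                 qual_sd = qual_sd, read_length = as.integer(read_length),
                 coverage = as.integer(coverage), seed = as.integer(seed)),
            class = "sim_config")
}

protospacer_chars <- function(target) {
  strsplit(protospacer_seq(target), "", fixed = TRUE)[[1]]
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> target %s, coverage %d, read length %d, seed %d\n",
              x$target$name, x$coverage, x$read_length, x$seed))
  nz <- which(x$edit_prob > 0)
  cat(sprintf("  edit_prob: %s\n",
              paste(sprintf("p%d=%.2f", nz, x$edit_prob[nz]), collapse = " ")))
  if (any(x$inhibition > 0))
    cat(sprintf("  inhibition (treated): mean on-window %.2f\n",
                mean(x$inhibition[x$inhibition > 0])))
  cat(sprintf("  indel_rate %.3f, seq_error_rate %.4f, qual ~ N(%.0f, %.0f)\n",
              x$indel_rate, x$seq_error_rate, x$qual_mean, x$qual_sd))
  invisible(x)
}

sub_seed <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483647)

#' Simulate an allele pool with known truth
#'
#' Draws `coverage` alleles. Each editable position converts with probability
#' `edit_prob[p]` (times `1 - inhibition[p]` in the treated condition);
#' co-editing within a read follows a Gaussian copula with correlation
#' `coedit_correlation` (marginals preserved exactly; 0 = independent).
#' Indels occur per read at `indel_rate`, placed uniformly over protospacer
#' positions, insertion or deletion with equal probability, lengths from
#' `indel_length_probs`. Truth tables are emitted alongside: the expected
#' per-position frequency vector, the realized (empirical) frequencies of
#' the generated pool, and the realized allele-class fractions.
#'
#' @param config a `sim_config`.
#' @param condition `"control"` or `"treated"` (applies the inhibition
#'   vector). The two conditions use distinct sub-seeds of `config$seed`.
#' @return an `allele_pool`: list with per-read `seqs` (full edited amplicon
#'   sequences), `edits` (logical coverage x 20 matrix), `indel`
#'   (logical), `class` (truth classification per read), `truth_expected`
#'   (length-20 expected frequency), `truth_profile` (realized frequency
#'   among reads whose position is not deleted), `truth_class_fractions`,
#'   `condition`, and the `config`.
#' @export
simulate_allele_pool <- function(config, condition = c("control", "treated")) {
  condition <- match.arg(condition)
  target <- config$target
  set.seed(sub_seed(config$seed, if (condition == "control") 0 else 1))
  n <- config$coverage
  p_eff <- config$edit_prob *
    (if (condition == "treated") 1 - config$inhibition else 1)

  rho <- config$coedit_correlation
  if (rho > 0) {
    z0 <- stats::rnorm(n)
    z <- sqrt(rho) * matrix(z0, n, 20) +
      sqrt(1 - rho) * matrix(stats::rnorm(n * 20), n, 20)
    edits <- stats::pnorm(z) < matrix(p_eff, n, 20, byrow = TRUE)
  } else {
    edits <- matrix(stats::runif(n * 20), n, 20) <
      matrix(p_eff, n, 20, byrow = TRUE)
  }

  has_indel <- stats::runif(n) < config$indel_rate
  indel_pos <- ifelse(has_indel, sample.int(20L, n, replace = TRUE), NA_integer_)
  indel_is_del <- has_indel & (stats::runif(n) < 0.5)
  lens <- as.integer(names(config$indel_length_probs))
  indel_len <- ifelse(has_indel,
                      sample(lens, n, replace = TRUE,
                             prob = config$indel_length_probs), NA_integer_)

  amp <- target$amplicon_seq
  prod_fwd <- if (target$protospacer_strand == "+")
    product_base(target$editor) else complement_chars(product_base(target$editor))
  offs <- to_amplicon_coord(target, 1:20)
  bases <- c("A", "C", "G", "T")

  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- strsplit(amp, "", fixed = TRUE)[[1]]
    ed <- which(edits[i, ])
    if (length(ed)) s[offs[ed] + 1L] <- prod_fwd
    if (has_indel[i]) {
      at <- offs[indel_pos[i]] + 1L            # 1-based amplicon position
      L <- indel_len[i]
      if (indel_is_del[i]) {
        s <- s[-(at:min(at + L - 1L, length(s)))]
      } else {
        s <- append(s, sample(bases, L, replace = TRUE), after = at)
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }

  intended <- target$intended_positions
  cls <- character(n)
  for (i in seq_len(n)) {
    ed <- which(edits[i, ])
    cls[i] <- if (has_indel[i]) "indel_allele"
    else if (length(ed) == 0L) "unedited"
    else if (setequal(ed, intended)) "perfect"
    else "imperfect_edit"
  }
  classes <- c("unedited", "perfect", "imperfect_edit", "indel_allele")
  class_fractions <- vapply(classes, function(cl) mean(cls == cl), numeric(1))

  # realized frequencies among reads where the position is observable
  # (not removed by a deletion)
  del_span <- matrix(FALSE, n, 20)
  di <- which(indel_is_del)
  for (i in di) {
    span <- indel_pos[i]:min(indel_pos[i] + indel_len[i] - 1L, 20L)
    if (target$protospacer_strand == "-")  # deletion runs 5'->3' on + strand
      span <- pmax(indel_pos[i] - indel_len[i] + 1L, 1L):indel_pos[i]
    del_span[i, span] <- TRUE
  }
  truth_profile <- vapply(1:20, function(p) {
    ok <- !del_span[, p]
    if (!any(ok)) NA_real_ else mean(edits[ok, p])
  }, numeric(1))
  editable <- protospacer_chars(target) == editable_base(target$editor)
  truth_profile[!editable] <- NA_real_
  te <- p_eff; te[!editable] <- NA_real_

  structure(list(seqs = seqs, edits = edits, indel = has_indel,
                 class = cls, truth_expected = te,
                 truth_profile = truth_profile,
                 truth_class_fractions = class_fractions,
                 condition = condition, config = config),
            class = "allele_pool")
}

#' @export
print.allele_pool <- function(x, ...) {
  cat(sprintf("<allele_pool> %s, %d reads, %d distinct alleles\n",
              x$condition, length(x$seqs), length(unique(x$seqs))))
  cat("  truth class fractions:",
      paste(sprintf("%s=%.3f", names(x$truth_class_fractions),
                    x$truth_class_fractions), collapse = " "), "\n")
  invisible(x)
}

#' Closed-form expected allele-class fractions
#'
#' Under independent per-position edits (`coedit_correlation = 0`), the
#' probability of a perfect allele is `(1 - indel_rate) * prod(p at intended
#' positions) * prod(1 - p elsewhere)`; unedited is `(1 - indel_rate) *
#' prod(1 - p)`; indel alleles occur at `indel_rate`; imperfect edits take
#' the remainder.
#'
#' @param config a `sim_config` with `coedit_correlation = 0`.
#' @param condition `"control"` or `"treated"`.
#' @return named numeric: unedited, perfect, imperfect_edit, indel_allele.
#' @export
expected_class_fractions <- function(config,
                                     condition = c("control", "treated")) {
  condition <- match.arg(condition)
  if (config$coedit_correlation != 0)
    stop("closed form requires independent edits (coedit_correlation = 0)",
         call. = FALSE)
  p <- config$edit_prob *
    (if (condition == "treated") 1 - config$inhibition else 1)
  intended <- config$target$intended_positions
  no_indel <- 1 - config$indel_rate
  perfect <- no_indel * prod(p[intended]) * prod(1 - p[setdiff(1:20, intended)])
  unedited <- no_indel * prod(1 - p)
  indel <- config$indel_rate
  c(unedited = unedited, perfect = perfect,
    imperfect_edit = 1 - perfect - unedited - indel, indel_allele = indel)
}

#' Emit an allele pool as paired FASTQ
#'
#' Each read pair covers its allele's full amplicon span: R1 is the first
#' `read_length` nt of the fragment, R2 the reverse complement of the last
#' `read_length` nt, guaranteeing the configured pair overlap. Per-base
#' miscalls occur at `seq_error_rate` (uniform over the three other bases);
#' Phred scores are drawn from a truncated normal `N(qual_mean, qual_sd)` on
#' 2..41. Byte-identical output under a fixed config seed.
#'
#' @param pool an `allele_pool`.
#' @param path_r1,path_r2 output FASTQ paths (`.gz` to compress).
#' @return list with `path_r1`, `path_r2`, `read_ids`, invisibly.
#' @export
pool_to_fastq <- function(pool, path_r1, path_r2) {
  config <- pool$config
  set.seed(sub_seed(config$seed,
                    if (pool$condition == "control") 2 else 3))
  n <- length(pool$seqs)
  RL <- config$read_length
  ids <- sprintf("sim_%s_%06d", pool$condition, seq_len(n))

  add_errors <- function(s) {
    if (config$seq_error_rate == 0) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < config$seq_error_rate)
    if (length(hit)) {
      for (k in hit) ch[k] <- sample(setdiff(c("A", "C", "G", "T"), ch[k]), 1)
      s <- paste(ch, collapse = "")
    }
    s
  }
  draw_qual <- function(len) {
    pmin(pmax(as.integer(round(stats::rnorm(len, config$qual_mean,
                                            config$qual_sd))), 2L), 41L)
  }

  r1 <- character(n); r2 <- character(n)
  q1 <- vector("list", n); q2 <- vector("list", n)
  for (i in seq_len(n)) {
    frag <- pool$seqs[i]
    L <- nchar(frag)
    rl <- min(RL, L)
    r1[i] <- add_errors(substr(frag, 1L, rl))
    r2[i] <- add_errors(revcomp(substr(frag, L - rl + 1L, L)))
    q1[[i]] <- draw_qual(rl)
    q2[[i]] <- draw_qual(rl)
  }
  write_fastq(r1, q1, ids, path_r1)
  write_fastq(r2, q2, ids, path_r2)
  invisible(list(path_r1 = path_r1, path_r2 = path_r2, read_ids = ids))
}

#' Named simulation presets
#'
#' Seeded configurations emulating the study designs the package targets:
#' \describe{
#'   \item{broad_window_CBE}{A3A-like CBE with a broad window-shaped profile
#'     peaking at positions 4..8 and low-rate out-of-window editing, 1\%
#'     indels, 0.2\% base-call error, coverage 2000.}
#'   \item{focused_inhibitor}{the same editor under an inhibitor that
#'     attenuates out-of-window editing far more strongly than on-target:
#'     truth inhibition 0.1 at positions 4..8 and 0.9 elsewhere, so the
#'     construction selectivity fold is exactly 0.9 / 0.1 = 9. Coverage is
#'     25000 reads per condition, sized so the sampling error of the
#'     recovered fold (dominated by the small on-target inhibition rates in
#'     the denominator) stays a few percent relative.}
#'   \item{abe_window}{ABE with its 4..7 window; the single editable
#'     in-window adenine carries the peak frequency.}
#' }
#'
#' @param seed base seed for the configs.
#' @return named list; each element has `config`, and for
#'   `focused_inhibitor` the documented `truth_fold`.
#' @export
scenario_presets <- function(seed = 1L) {
  cbe <- example_target("CBE")
  abe <- example_target("ABE")
  on <- window_partition("CBE")$on_target
  inhib <- numeric(20); inhib[on] <- 0.1; inhib[setdiff(1:20, on)] <- 0.9
  list(
    broad_window_CBE = list(
      config = sim_config(
        cbe,
        edit_prob = c("4" = 0.35, "6" = 0.45, "8" = 0.30,
                      "1" = 0.08, "11" = 0.06, "16" = 0.04),
        indel_rate = 0.01, seq_error_rate = 0.002, coverage = 2000L,
        seed = seed)),
    focused_inhibitor = list(
      config = sim_config(
        cbe,
        edit_prob = c("4" = 0.35, "6" = 0.45, "8" = 0.30,
                      "1" = 0.15, "11" = 0.12, "16" = 0.10),
        inhibition = inhib,
        indel_rate = 0.005, seq_error_rate = 0.002, coverage = 25000L,
        seed = sub_seed(seed, 100)),
      truth_fold = 0.9 / 0.1),
    abe_window = list(
      config = sim_config(
        abe,
        edit_prob = c("7" = 0.50, "2" = 0.06, "10" = 0.05, "14" = 0.04,
                      "18" = 0.03, "20" = 0.03),
        indel_rate = 0.005, seq_error_rate = 0.002, coverage = 2000L,
        seed = sub_seed(seed, 200))))
}
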