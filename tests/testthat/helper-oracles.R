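# Independent oracles used to cross-check the implementation.

# Exhaustive affine-gap DP, global in the pattern and local in the subject
# (free leading/trailing subject). Gap of length k costs open + k * ext.
# Row-vectorised; independent of the package's aligner.
dp_align_score <- function(pat, sub, match = 2, mismatch = -4,
                           open = 6, ext = 1) {
  p <- strsplit(pat, "", fixed = TRUE)[[1]]
  s <- strsplit(sub, "", fixed = TRUE)[[1]]
  n <- length(p); m <- length(s)
  NEG <- -1e9
  prevM <- rep(0, m + 1)                  # free leading subject skip
  prevIx <- rep(NEG, m + 1)
  prevIy <- rep(NEG, m + 1)
  for (i in seq_len(n)) {
    subs <- ifelse(s == p[i], match, mismatch)
    best_prev <- pmax(prevM, prevIx, prevIy)
    M <- c(NEG, best_prev[1:m] + subs)
    Ix <- pmax(pmax(prevM, prevIy) - open - ext, prevIx - ext)
    B <- pmax(M, Ix) - open + ext * (0:m)
    Iy <- c(NEG, cummax(B)[1:m] - ext * (1:m))
    prevM <- M; prevIx <- Ix; prevIy <- Iy
  }
  max(prevM, prevIx, prevIy)
}

# both read orientations, better score kept (as the aligner specifies)
dp_align_best <- function(pat, sub, ...) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat)))
  max(dp_align_score(pat, sub, ...), dp_align_score(rc, sub, ...))
}

# Permutation p-value for the two-sample t statistic (two-sided).
perm_t_p <- function(x, y, B = 4000, seed = 99) {
  set.seed(seed)
  obs <- abs(stats::t.test(x, y, var.equal = TRUE)$statistic)
  z <- c(x, y); nx <- length(x)
  hits <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(length(z), nx)
    tb <- tryCatch(abs(stats::t.test(z[idx], z[-idx],
                                     var.equal = TRUE)$statistic),
                   error = function(e) Inf)
    if (tb >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (B + 1)
}

# Allele-class oracle by direct sequence comparison: perfect iff the allele
# equals the reference with the intended product substituted at every
# intended position; unedited iff it equals the reference; indel wins over
# everything.
oracle_classify <- function(allele, ref, intended, editor,
                            indel_flag = FALSE) {
  if (indel_flag || grepl("-", allele, fixed = TRUE)) return("indel_allele")
  if (allele == ref) return("unedited")
  prod <- if (editor == "CBE") "T" else "G"
  perfect_seq <- strsplit(ref, "", fixed = TRUE)[[1]]
  perfect_seq[intended] <- prod
  if (allele == paste(perfect_seq, collapse = "")) return("perfect")
  "imperfect_edit"
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

binom_sd <- function(p, n) sqrt(p * (1 - p) / n)
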