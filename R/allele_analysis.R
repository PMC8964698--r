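#' Classify a protospacer allele
#'
#' Operational definition of a "perfectly edited" allele: the intended
#' conversion (C->T for CBE, A->G for ABE) is present at every intended
#' position, with zero other substitutions and zero indels inside the
#' quantification region. The classes partition all called alleles:
#' \describe{
#'   \item{indel_allele}{any inserted or deleted nucleotide in the region;}
#'   \item{unedited}{no substitution calls and no indel;}
#'   \item{perfect}{calls exactly equal to the intended conversions at the
#'     intended positions and nothing else;}
#'   \item{imperfect_edit}{any other call set, including a non-intended
#'     product at an intended position (e.g. C->G) and bystander edits at
#'     out-of-window positions.}
#' }
#'
#' @param edit_calls data frame (or NULL) with columns `position`, `ref`,
#'   `obs` restricted to the quantification region: the substitution calls
#'   observed on the allele.
#' @param indel_flag logical: the allele carries an indel in the region.
#' @param target an `amplicon_target` (supplies editor and intended
#'   positions).
#' @return one of `"perfect"`, `"unedited"`, `"imperfect_edit"`,
#'   `"indel_allele"`.
#' @export
classify_allele <- function(edit_calls, indel_flag, target) {
  if (isTRUE(indel_flag)) return("indel_allele")
  n_calls <- if (is.null(edit_calls)) 0L else nrow(edit_calls)
  if (n_calls == 0L) return("unedited")
  intended <- target$intended_positions
  prod <- product_base(target$editor)
  sub <- editable_base(target$editor)
  if (length(intended) &&
      n_calls == length(intended) &&
      setequal(edit_calls$position, intended) &&
      all(edit_calls$ref == sub) &&
      all(edit_calls$obs == prod))
    return("perfect")
  "imperfect_edit"
}

#' Enumerate and classify distinct protospacer alleles
#'
#' Aggregates accepted alignments into distinct allele sequences over the
#' quantification region (protospacer positions `region`, default 1..20, on
#' the protospacer strand; deletions shown as `-`). Reads that do not cover
#' the full region, or that carry any quality-masked base (Phred <
#' `min_base_qual` or N) inside it, are dropped from allele calling and
#' counted separately -- allele identity requires full, confident
#' observation. Alleles below `min_allele_count` are aggregated into an
#' `"other"` bin that keeps the class tally consistent.
#'
#' @param alignments an `aligned_reads` object.
#' @param target the corresponding `amplicon_target`.
#' @param region integer range of protospacer positions to genotype
#'   (within 1..23).
#' @param min_base_qual Phred floor below which a base invalidates the read
#'   for allele calling.
#' @param min_allele_count alleles seen fewer times are pooled into "other".
#' @return An `allele_table`: list with `alleles` (data frame: `allele_seq`,
#'   `count`, `frequency`, `class`, `edits` -- comma-separated
#'   position:ref>obs calls), `total_reads` (called), `n_dropped`
#'   (uncallable reads), class count/fraction vectors, and summary fractions
#'   `perfect_of_total`, `edited_of_total`, `perfect_of_edited`.
#' @export
call_alleles <- function(alignments, target, region = 1:20,
                         min_base_qual = 30L, min_allele_count = 1L) {
  region <- sort(unique(as.integer(region)))
  if (any(region < 1L) || any(region > 23L))
    stop("region must lie within protospacer positions 1..23", call. = FALSE)
  if (any(region > 20L))
    stop("allele calling is defined over protospacer positions 1..20",
         call. = FALSE)
  po <- protospacer_observations(alignments, target)
  ridx <- region                      # columns of the observation matrices
  obs <- po$obs[, ridx, drop = FALSE]
  qual <- po$qual[, ridx, drop = FALSE]
  ins <- po$ins[, ridx, drop = FALSE]

  is_del <- !is.na(obs) & obs == "-"
  masked <- is.na(obs) | (!is_del & (obs == "N" | is.na(qual) | qual < min_base_qual))
  callable <- rowSums(masked) == 0L
  n_dropped <- sum(!callable)

  ref <- vapply(region, function(p) reference_base(target, p), character(1))
  allele_seq <- apply(obs[callable, , drop = FALSE], 1, paste, collapse = "")
  has_ins <- rowSums(ins[callable, , drop = FALSE]) > 0L
  has_del <- rowSums(is_del[callable, , drop = FALSE]) > 0L
  indel_flag <- has_ins | has_del
  # insertions distinguish alleles even when the substitution pattern matches
  key <- paste0(allele_seq, ifelse(has_ins, "+ins", ""))

  agg <- tapply(seq_along(key), key, identity)
  recs <- lapply(agg, function(ii) {
    seqchars <- strsplit(allele_seq[ii[1]], "", fixed = TRUE)[[1]]
    subst <- seqchars != ref & seqchars != "-"
    calls <- if (any(subst))
      data.frame(position = region[subst], ref = ref[subst],
                 obs = seqchars[subst]) else NULL
    cls <- classify_allele(calls, indel_flag[ii[1]], target)
    data.frame(allele_seq = key[ii[1]],
               count = length(ii),
               class = cls,
               edits = if (is.null(calls)) "" else
                 paste(sprintf("%d:%s>%s", calls$position, calls$ref,
                               calls$obs), collapse = ","))
  })
  alleles <- do.call(rbind, recs)
  if (is.null(alleles)) {
    alleles <- data.frame(allele_seq = character(), count = integer(),
                          class = character(), edits = character())
  }
  total <- sum(alleles$count)
  alleles <- alleles[order(-alleles$count, alleles$allele_seq), , drop = FALSE]
  rownames(alleles) <- NULL

  # pool rare alleles into an "other" bin per class, keeping class totals
  if (min_allele_count > 1L && nrow(alleles)) {
    rare <- alleles$count < min_allele_count
    if (any(rare)) {
      pooled <- stats::aggregate(count ~ class, alleles[rare, ], sum)
      pooled <- data.frame(allele_seq = sprintf("other_%s", pooled$class),
                           count = pooled$count, class = pooled$class,
                           edits = "")
      alleles <- rbind(alleles[!rare, , drop = FALSE], pooled)
      alleles <- alleles[order(-alleles$count, alleles$allele_seq), ,
                         drop = FALSE]
      rownames(alleles) <- NULL
    }
  }
  alleles$frequency <- if (total > 0) alleles$count / total else numeric(nrow(alleles))
  alleles <- alleles[, c("allele_seq", "count", "frequency", "class", "edits")]

  classes <- c("unedited", "perfect", "imperfect_edit", "indel_allele")
  class_counts <- vapply(classes, function(cl)
    as.integer(sum(alleles$count[alleles$class == cl])), integer(1))
  class_fractions <- if (total > 0) class_counts / total else class_counts * NA
  edited <- total - class_counts[["unedited"]]
  structure(list(target_name = target$name, region = region,
                 alleles = alleles, total_reads = total,
                 n_dropped = n_dropped,
                 class_counts = class_counts,
                 class_fractions = class_fractions,
                 perfect_of_total = unname(class_fractions[["perfect"]]),
                 edited_of_total = if (total > 0) edited / total else NA_real_,
                 perfect_of_edited = if (edited > 0)
                   class_counts[["perfect"]] / edited else NA_real_),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, n = 10L, ...) {
  cat(sprintf("<allele_table> target %s, %d called reads (%d dropped), %d distinct alleles\n",
              x$target_name, x$total_reads, x$n_dropped, nrow(x$alleles)))
  cat(sprintf("  perfect-of-total %.3f | edited-of-total %.3f | perfect-of-edited %s\n",
              x$perfect_of_total, x$edited_of_total,
              if (is.na(x$perfect_of_edited)) "undefined"
              else sprintf("%.3f", x$perfect_of_edited)))
  print(utils::head(x$alleles, n), row.names = FALSE)
  if (nrow(x$alleles) > n) cat(sprintf("  ... %d more\n", nrow(x$alleles) - n))
  invisible(x)
}

#' Summarize the perfect-editing gain between two conditions
#'
#' Reports perfect-of-total, perfect-of-edited and edited-of-total for a
#' control and a treated allele table over the same target, the fold change
#' of perfect-of-total (treated / control), and the number of distinct
#' imperfectly edited genotypes above a frequency floor in each condition.
#'
#' @param control,treated `allele_table` objects for the same target.
#' @param genotype_freq_floor minimum allele frequency for a genotype to
#'   count in the imperfect-genotype tally.
#' @return list with per-condition fractions, `perfect_fold`, and
#'   `n_imperfect_genotypes` per condition; undefined fractions propagate as
#'   `NA`.
#' @export
perfect_edit_summary <- function(control, treated, genotype_freq_floor = 0) {
  if (!identical(control$target_name, treated$target_name))
    stop("allele tables must refer to the same target", call. = FALSE)
  n_imp <- function(tab) {
    a <- tab$alleles
    sum(a$class == "imperfect_edit" & a$frequency >= genotype_freq_floor)
  }
  fold <- if (!is.na(control$perfect_of_total) && control$perfect_of_total > 0)
    treated$perfect_of_total / control$perfect_of_total else NA_real_
  list(target = control$target_name,
       control = list(perfect_of_total = control$perfect_of_total,
                      perfect_of_edited = control$perfect_of_edited,
                      edited_of_total = control$edited_of_total,
                      n_imperfect_genotypes = n_imp(control)),
       treated = list(perfect_of_total = treated$perfect_of_total,
                      perfect_of_edited = treated$perfect_of_edited,
                      edited_of_total = treated$edited_of_total,
                      n_imperfect_genotypes = n_imp(treated)),
       perfect_fold = fold)
}

#' Write an allele table as TSV
#'
#' @param table an `allele_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_table <- function(table, path) {
  utils::write.table(table$alleles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
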