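#' Quantify one sample end to end
#'
#' Parses (or accepts) paired reads, merges them into consensus reads,
#' aligns to the amplicon, and builds the conversion matrix, editing profile
#' and indel frequency, with per-stage read counts (parsed >= merged >=
#' aligned >= accepted).
#'
#' @param pairs a `read_pairs` object, or `path_r1`/`path_r2` FASTQ paths.
#' @param target an `amplicon_target`.
#' @param path_r1,path_r2 FASTQ paths (used when `pairs` is NULL).
#' @param label,replicate sample label and replicate id carried on the
#'   profile.
#' @param min_overlap,max_mismatch_frac merging thresholds, see
#'   [merge_pairs()].
#' @param min_identity alignment identity gate, see [align_to_amplicon()].
#' @param min_base_qual base-quality mask, see [build_conversion_matrix()].
#' @param scoring see [alignment_scoring()].
#' @return a `sample_quant`: list with `matrix`, `profile`,
#'   `indel_frequency`, `alignments`, `consensus`, stage counts `n_parsed`,
#'   `n_merged`, `n_aligned`, `n_accepted`, and `label`.
#' @export
quantify_sample <- function(pairs = NULL, target, path_r1 = NULL,
                            path_r2 = NULL, label = NA_character_,
                            replicate = NA_integer_, min_overlap = 11L,
                            max_mismatch_frac = 0.1, min_identity = 0.7,
                            min_base_qual = 30L,
                            scoring = alignment_scoring()) {
  if (is.null(pairs)) pairs <- read_fastq_pairs(path_r1, path_r2)
  cons <- merge_pairs(pairs, min_overlap = min_overlap,
                      max_mismatch_frac = max_mismatch_frac)
  aln <- align_to_amplicon(cons, target, scoring = scoring,
                           min_identity = min_identity)
  cm <- build_conversion_matrix(aln, target, min_base_qual = min_base_qual)
  prof <- editing_profile(cm, target, label = label, replicate = replicate)
  structure(list(matrix = cm, profile = prof,
                 indel_frequency = indel_frequency(aln, target),
                 alignments = aln, consensus = cons,
                 n_parsed = length(pairs$r1_seq),
                 n_merged = sum(cons$merged),
                 n_aligned = aln$n_input,
                 n_accepted = sum(aln$accepted),
                 label = label),
            class = "sample_quant")
}

#' @export
print.sample_quant <- function(x, ...) {
  cat(sprintf("<sample_quant>%s parsed %d -> merged %d -> aligned %d -> accepted %d\n",
              if (!is.na(x$label)) paste0(" ", x$label, ":") else "",
              x$n_parsed, x$n_merged, x$n_aligned, x$n_accepted))
  cat(sprintf("  protospacer indel frequency: %s\n",
              if (is.na(x$indel_frequency)) "undefined"
              else sprintf("%.4f", x$indel_frequency)))
  invisible(x)
}

#' Write a conversion matrix (with frequencies) as TSV
#'
#' One row per protospacer position: reference base, A/C/G/T/del/masked
#' counts, insertion adjacency, and the intended-conversion frequency where
#' applicable.
#'
#' @param sample a `sample_quant` (or pass `matrix` and `profile`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conversion_tsv <- function(sample, path) {
  out <- cbind(as.data.frame(sample$matrix), freq = sample$profile$freq)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML with a `targets:` section (see [read_target_config()]), a `samples:`
#' list (each: `id`, `target`, `condition` in control/treated, `replicate`,
#' `r1`, `r2`; relative paths resolved against the config file), and an
#' optional `thresholds:` map (`min_overlap`, `max_mismatch_frac`,
#' `min_identity`, `min_base_qual`, `min_control_freq`, `min_reads`,
#' `allele_region` as `[from, to]`).
#'
#' @param path YAML file.
#' @return list with `targets`, `samples` (data frame), `thresholds`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  targets <- read_target_config(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dirname(path), p)
  samples <- do.call(rbind, lapply(cfg$samples, function(s)
    data.frame(id = s$id, target = s$target,
               condition = s$condition %||% "control",
               replicate = as.integer(s$replicate %||% 1L),
               r1 = resolve(s$r1), r2 = resolve(s$r2))))
  if (!is.null(samples)) {
    bad <- setdiff(samples$target, names(targets))
    if (length(bad))
      stop(sprintf("sample(s) reference undefined target(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  th <- cfg$thresholds %||% list()
  defaults <- list(min_overlap = 11L, max_mismatch_frac = 0.1,
                   min_identity = 0.7, min_base_qual = 30L,
                   min_control_freq = 0.005, min_reads = 0L,
                   allele_region = c(1L, 20L))
  thresholds <- utils::modifyList(defaults, th)
  list(targets = targets, samples = samples, thresholds = thresholds)
}

run_log <- function(...) message(sprintf(...))

#' Run per-sample quantification over a run config
#'
#' For each sample: parse, merge, align, count; writes
#' `<out_dir>/<id>.conversion.tsv` and records per-stage counts. Samples with
#' missing/empty FASTQ are skipped with a logged reason; samples below the
#' `min_reads` accepted-read floor are excluded by [amplicon_qc_filter()].
#'
#' @param config path to a run-config YAML or the list from
#'   [read_run_config()].
#' @param out_dir output directory (created).
#' @return list with `samples` (named list of `sample_quant`), `qc`
#'   (filter report), `log` (data frame of per-stage counts).
#' @export
run_quantify <- function(config, out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  results <- list()
  logs <- list()
  for (i in seq_len(nrow(config$samples))) {
    s <- config$samples[i, ]
    if (!file.exists(s$r1) || !file.exists(s$r2)) {
      run_log("sample %s skipped: FASTQ missing", s$id)
      next
    }
    pairs <- tryCatch(read_fastq_pairs(s$r1, s$r2), error = function(e) e)
    if (inherits(pairs, "error") || length(pairs$r1_seq) == 0L) {
      run_log("sample %s skipped: %s", s$id,
              if (inherits(pairs, "error")) conditionMessage(pairs)
              else "no reads")
      next
    }
    q <- quantify_sample(pairs, config$targets[[s$target]], label = s$id,
                         replicate = s$replicate,
                         min_overlap = th$min_overlap,
                         max_mismatch_frac = th$max_mismatch_frac,
                         min_identity = th$min_identity,
                         min_base_qual = th$min_base_qual)
    write_conversion_tsv(q, file.path(out_dir, paste0(s$id, ".conversion.tsv")))
    results[[s$id]] <- q
    logs[[s$id]] <- data.frame(sample = s$id, parsed = q$n_parsed,
                               merged = q$n_merged, aligned = q$n_aligned,
                               accepted = q$n_accepted)
    run_log("sample %s: parsed %d, merged %d, aligned %d, accepted %d",
            s$id, q$n_parsed, q$n_merged, q$n_aligned, q$n_accepted)
  }
  qc <- amplicon_qc_filter(lapply(results, function(r)
    list(n_accepted = r$n_accepted)), min_reads = th$min_reads)
  for (ex in qc$excluded) run_log("sample %s excluded by QC filter", ex)
  list(samples = results[qc$retained], qc = qc,
       log = do.call(rbind, logs))
}

#' Run the control-vs-treated window comparison over a run config
#'
#' Pairs control and treated samples per target (matched replicate indices
#' where available), computes per-pair inhibition profiles, writes the
#' long-format heat-map table and a JSON window comparison per target.
#'
#' @param config run config (path or list).
#' @param out_dir output directory.
#' @param quant optional result of [run_quantify()] to reuse.
#' @return list per target: `profiles`, `comparison`, `heatmap`.
#' @export
run_compare <- function(config, out_dir = ".", quant = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(quant)) quant <- run_quantify(config, out_dir = out_dir)
  th <- config$thresholds
  smp <- config$samples[config$samples$id %in% names(quant$samples), ]
  out <- list()
  for (tn in unique(smp$target)) {
    target <- config$targets[[tn]]
    sub <- smp[smp$target == tn, ]
    ctl <- sub[sub$condition == "control", ]
    trt <- sub[sub$condition == "treated", ]
    if (nrow(ctl) == 0L || nrow(trt) == 0L)
      stop(sprintf("target %s lacks a %s sample", tn,
                   if (nrow(ctl) == 0L) "control" else "treated"),
           call. = FALSE)
    reps <- intersect(ctl$replicate, trt$replicate)
    pairs <- if (length(reps))
      lapply(reps, function(r) c(ctl$id[ctl$replicate == r][1],
                                 trt$id[trt$replicate == r][1]))
    else list(c(ctl$id[1], trt$id[1]))
    profiles <- lapply(pairs, function(pr)
      inhibition_rate(quant$samples[[pr[1]]]$profile,
                      quant$samples[[pr[2]]]$profile,
                      min_control_freq = th$min_control_freq))
    names(profiles) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    comp <- window_comparison(profiles, window_partition(target$editor))
    hm <- heatmap_table(profiles)
    utils::write.table(hm, file.path(out_dir, paste0(tn, ".inhibition.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(target = tn, mean_on = comp$mean_on, mean_out = comp$mean_out,
           selectivity_fold = comp$fold, t = comp$t, p = comp$p),
      file.path(out_dir, paste0(tn, ".window_comparison.json")),
      auto_unbox = TRUE, digits = NA)
    out[[tn]] <- list(profiles = profiles, comparison = comp, heatmap = hm)
  }
  out
}

#' Run allele calling and the perfect-edit summary over a run config
#'
#' Writes an allele TSV per sample and a JSON of class fractions; when both
#' conditions are present for a target, adds the control-vs-treated
#' perfect-edit summary.
#'
#' @param config run config (path or list).
#' @param out_dir output directory.
#' @param quant optional result of [run_quantify()] to reuse.
#' @return list with `tables` (per sample) and `summaries` (per target,
#'   where both conditions exist).
#' @export
run_alleles <- function(config, out_dir = ".", quant = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(quant)) quant <- run_quantify(config, out_dir = out_dir)
  th <- config$thresholds
  region <- seq(th$allele_region[1], th$allele_region[2])
  smp <- config$samples[config$samples$id %in% names(quant$samples), ]
  tables <- list()
  for (i in seq_len(nrow(smp))) {
    s <- smp[i, ]
    at <- call_alleles(quant$samples[[s$id]]$alignments,
                       config$targets[[s$target]], region = region,
                       min_base_qual = th$min_base_qual)
    write_allele_table(at, file.path(out_dir, paste0(s$id, ".alleles.tsv")))
    jsonlite::write_json(
      list(sample = s$id, class_fractions = as.list(at$class_fractions),
           perfect_of_total = at$perfect_of_total,
           edited_of_total = at$edited_of_total,
           perfect_of_edited = at$perfect_of_edited),
      file.path(out_dir, paste0(s$id, ".allele_summary.json")),
      auto_unbox = TRUE, digits = NA)
    tables[[s$id]] <- at
  }
  summaries <- list()
  for (tn in unique(smp$target)) {
    sub <- smp[smp$target == tn, ]
    ctl <- sub$id[sub$condition == "control"]
    trt <- sub$id[sub$condition == "treated"]
    if (length(ctl) && length(trt)) {
      summaries[[tn]] <- perfect_edit_summary(tables[[ctl[1]]],
                                              tables[[trt[1]]])
      jsonlite::write_json(summaries[[tn]],
                           file.path(out_dir,
                                     paste0(tn, ".perfect_edit_summary.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(tables = tables, summaries = summaries)
}

#' Simulate a control/treated pair of FASTQ samples with truth
#'
#' Generates the allele pools and paired FASTQ for both conditions of a
#' simulation config and writes a truth JSON (expected and realized
#' per-position frequencies, class fractions) alongside.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory.
#' @param conditions which conditions to emit.
#' @return named list per condition: `pool`, `r1`, `r2`, `truth_json`.
#' @export
run_simulate <- function(config, out_dir = ".",
                         conditions = c("control", "treated")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (cond in conditions) {
    pool <- simulate_allele_pool(config, cond)
    r1 <- file.path(out_dir, sprintf("%s_R1.fastq", cond))
    r2 <- file.path(out_dir, sprintf("%s_R2.fastq", cond))
    pool_to_fastq(pool, r1, r2)
    tj <- file.path(out_dir, sprintf("%s_truth.json", cond))
    jsonlite::write_json(
      list(condition = cond,
           truth_expected = pool$truth_expected,
           truth_profile = pool$truth_profile,
           truth_class_fractions = as.list(pool$truth_class_fractions),
           coverage = config$coverage, seed = config$seed),
      tj, auto_unbox = TRUE, digits = NA, na = "null")
    out[[cond]] <- list(pool = pool, r1 = r1, r2 = r2, truth_json = tj)
  }
  out
}
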