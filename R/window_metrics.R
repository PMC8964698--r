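#' Position-indexed inhibition rates between control and treated profiles
#'
#' The inhibition rate at protospacer position p is
#' \deqn{IR(p) = 1 - f_{treated}(p) / f_{control}(p),}
#' the fractional reduction of editing frequency under the inhibitor
#' relative to control. IR is computed only at editable positions where both
#' profiles are defined and the control frequency is at least
#' `min_control_freq` (default 0.005): below that floor the ratio is
#' dominated by sampling noise and the position is masked instead. The raw
#' (unclamped) value is retained for diagnostics; the reported value is
#' clamped to [0, 1], matching heat-map semantics where 1 is complete
#' suppression.
#'
#' @param control,treated `editing_profile` objects for the same target and
#'   editor.
#' @param min_control_freq minimum control editing frequency for IR to be
#'   defined at a position.
#' @return An `inhibition_profile`: data frame with `position`, `ref`,
#'   `defined`, `ir` (clamped), `ir_raw`, `f_control`, `f_treated`; carries
#'   the target/editor and the two sample labels as attributes.
#' @export
inhibition_rate <- function(control, treated, min_control_freq = 0.005) {
  if (!identical(attr(control, "editor"), attr(treated, "editor")) ||
      !identical(attr(control, "target_name"), attr(treated, "target_name")))
    stop("control and treated profiles must share target and editor",
         call. = FALSE)
  stopifnot(identical(control$position, treated$position))
  fc <- control$freq
  ft <- treated$freq
  defined <- control$editable & !is.na(fc) & !is.na(ft) & fc >= min_control_freq
  ir_raw <- ifelse(defined, 1 - ft / fc, NA_real_)
  out <- data.frame(position = control$position, ref = control$ref,
                    defined = defined,
                    ir = pmin(pmax(ir_raw, 0), 1),
                    ir_raw = ir_raw,
                    f_control = fc, f_treated = ft)
  attr(out, "editor") <- attr(control, "editor")
  attr(out, "target_name") <- attr(control, "target_name")
  attr(out, "control_label") <- attr(control, "label")
  attr(out, "treated_label") <- attr(treated, "label")
  class(out) <- c("inhibition_profile", "data.frame")
  out
}

#' @export
print.inhibition_profile <- function(x, ...) {
  cat(sprintf("<inhibition_profile> target %s (%s), %d defined positions\n",
              attr(x, "target_name"), attr(x, "editor"), sum(x$defined)))
  d <- x[x$defined, ]
  cat(sprintf("  %s\n",
              paste(sprintf("p%d=%.2f", d$position, d$ir), collapse = " ")))
  invisible(x)
}

#' Two-tailed two-sample Student's t test
#'
#' Pooled-variance (equal-variance) two-sample t test with a two-sided
#' p-value, the convention used when comparing on-target and out-of-window
#' inhibition-rate groups. Welch's unequal-variance form is available behind
#' `var_equal = FALSE`. Undefined (NA with a reason) when either group has
#' fewer than 2 values, or when both groups are constant and identical
#' (t = 0, p = 1 is returned for identical constant groups).
#'
#' @param x,y numeric vectors (NAs dropped).
#' @param var_equal pool variances (Student) rather than Welch.
#' @return list with `t`, `p`, `df`, `n_x`, `n_y`; `t`/`p` are `NA` with a
#'   `reason` field when undefined.
#' @export
student_t_two_tailed <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                n_x = length(x), n_y = length(y),
                reason = "each group needs n >= 2"))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate: constant groups; t.test errors here
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                p = if (eq) 1 else 0,
                df = length(x) + length(y) - 2, n_x = length(x),
                n_y = length(y)))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n_x = length(x), n_y = length(y))
}

#' Compare inhibition rates on-target vs out-of-window
#'
#' Splits defined inhibition rates by a window partition, reports the group
#' means, the selectivity fold (ratio of the mean out-of-window IR to the
#' mean on-target IR -- the fold by which the inhibitor prefers out-of-window
#' positions), and the two-tailed Student's t test between the two groups.
#' Multiple profiles (replicates and/or sites) may be supplied; their defined
#' IR values are pooled per group.
#'
#' @param profiles an `inhibition_profile` or list of them.
#' @param partition a `window_partition` (default: from the profiles' editor).
#' @return A `window_comparison`: list with `on_values`, `out_values`,
#'   `mean_on`, `mean_out`, `fold`, `t`, `p`, `n_on`, `n_out`; `fold` is
#'   `NA` when the on-target mean is 0 and the comparison is `undefined`
#'   (with a reason) when either group is empty.
#' @export
window_comparison <- function(profiles, partition = NULL) {
  if (inherits(profiles, "inhibition_profile")) profiles <- list(profiles)
  editor <- attr(profiles[[1]], "editor")
  if (is.null(partition)) partition <- window_partition(editor)
  on_values <- numeric(); out_values <- numeric()
  for (pr in profiles) {
    d <- pr[pr$defined, ]
    on_values <- c(on_values, d$ir[d$position %in% partition$on_target])
    out_values <- c(out_values, d$ir[d$position %in% partition$out_of_window])
  }
  if (length(on_values) == 0L || length(out_values) == 0L) {
    return(structure(list(undefined = TRUE,
                          reason = sprintf("no defined IR values %s",
                                           if (length(on_values) == 0L)
                                             "on-target" else "out-of-window"),
                          on_values = on_values, out_values = out_values),
                     class = "window_comparison"))
  }
  mean_on <- mean(on_values); mean_out <- mean(out_values)
  # no measurable inhibition in either group means no selectivity (fold 1);
  # inhibition only out-of-window has no finite fold
  fold <- if (mean_on > 0) mean_out / mean_on
          else if (mean_out == 0) 1 else NA_real_
  tt <- student_t_two_tailed(out_values, on_values)
  structure(list(undefined = FALSE, partition = partition,
                 on_values = on_values, out_values = out_values,
                 mean_on = mean_on, mean_out = mean_out, fold = fold,
                 t = tt$t, p = tt$p, n_on = length(on_values),
                 n_out = length(out_values)),
            class = "window_comparison")
}

#' @export
print.window_comparison <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("<window_comparison> undefined:", x$reason, "\n")
    return(invisible(x))
  }
  cat("<window_comparison>\n")
  cat(sprintf("  mean IR on-target    : %.4f (n = %d)\n", x$mean_on, x$n_on))
  cat(sprintf("  mean IR out-of-window: %.4f (n = %d)\n", x$mean_out, x$n_out))
  cat(sprintf("  selectivity fold (out/on): %s\n",
              if (is.na(x$fold)) "undefined (on-target mean 0)"
              else sprintf("%.2f", x$fold)))
  cat(sprintf("  Student's t = %.3f, two-sided p = %.3g\n", x$t, x$p))
  invisible(x)
}

#' Long-format table of inhibition profiles for plotting
#'
#' Tabulates one or more inhibition profiles as (site, position, ir) rows --
#' the layout behind position-by-site heat maps. Masked (undefined) positions
#' are emitted with `NA` ir so the table is lossless and can be rebuilt into
#' profiles.
#'
#' @param profiles an `inhibition_profile` or (optionally named) list of them.
#' @param keep_masked emit rows for masked positions (default TRUE).
#' @return data frame with `site`, `position`, `ir`, `ir_raw`.
#' @export
heatmap_table <- function(profiles, keep_masked = TRUE) {
  if (inherits(profiles, "inhibition_profile")) profiles <- list(profiles)
  nm <- names(profiles)
  if (is.null(nm))
    nm <- vapply(profiles, function(p) attr(p, "target_name"), character(1))
  rows <- lapply(seq_along(profiles), function(i) {
    pr <- profiles[[i]]
    if (!keep_masked) pr <- pr[pr$defined, ]
    data.frame(site = nm[i], position = pr$position, ir = pr$ir,
               ir_raw = pr$ir_raw)
  })
  do.call(rbind, rows)
}
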