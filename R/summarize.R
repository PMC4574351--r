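#' Per-microtubule dynamics statistics
#'
#' Reduces one segmentation to the standard dynamic-instability statistics.
#' Catastrophe frequency is the number of catastrophes divided by the total
#' time the microtubule spent in assembly and pause phases (per minute);
#' rescue frequency is the number of rescues divided by the total time in
#' disassembly and pause phases.  Undetermined time is excluded from all
#' denominators.  Rates are duration-weighted means over phases of each
#' kind; mean length is the time-average of the sampled lengths.
#' A frequency with a zero denominator is marked `NA` and later dropped from
#' condition-level aggregation.
#'
#' @param seg a [classify_trace()] result
#' @param trace the `length_trace` the segmentation was derived from
#' @return one-row data.frame with columns `cell_id`, `mt_id`,
#'   `mean_length`, `assembly_rate`, `assembly_duration`,
#'   `disassembly_rate`, `disassembly_duration`, `catastrophe_freq`,
#'   `rescue_freq`, `pause_duration`, `n_catastrophes`, `n_rescues`,
#'   `n_pauses`, `t_assembly`, `t_disassembly`, `t_pause` (times s,
#'   rates um/min, frequencies min^-1)
#' @export
summarize_mt <- function(seg, trace) {
  stopifnot(inherits(seg, "phase_segmentation"))
  ph <- seg$phases
  by_kind <- function(kind) ph[ph$kind == kind, , drop = FALSE]
  asm <- by_kind("assembly"); dis <- by_kind("disassembly"); pau <- by_kind("pause")

  t_asm <- sum(asm$duration_s); t_dis <- sum(dis$duration_s)
  t_pau <- sum(pau$duration_s)
  n_cat <- sum(seg$transitions$kind == "catastrophe")
  n_res <- sum(seg$transitions$kind == "rescue")

  wmean <- function(x, w) if (length(x)) sum(x * w) / sum(w) else NA_real_
  freq <- function(nev, denom_s) {
    if (denom_s > 0) nev / (denom_s / 60) else NA_real_
  }

  data.frame(
    cell_id = seg$trace_ref$cell_id, mt_id = seg$trace_ref$mt_id,
    mean_length = mean(trace$length_um),
    assembly_rate = wmean(asm$rate_um_min, asm$duration_s),
    assembly_duration = if (nrow(asm)) mean(asm$duration_s) else NA_real_,
    disassembly_rate = wmean(abs(dis$rate_um_min), dis$duration_s),
    disassembly_duration = if (nrow(dis)) mean(dis$duration_s) else NA_real_,
    catastrophe_freq = freq(n_cat, t_asm + t_pau),
    rescue_freq = freq(n_res, t_dis + t_pau),
    pause_duration = if (nrow(pau)) mean(pau$duration_s) else NA_real_,
    n_catastrophes = n_cat, n_rescues = n_res, n_pauses = nrow(pau),
    t_assembly = t_asm, t_disassembly = t_dis, t_pause = t_pau,
    stringsAsFactors = FALSE
  )
}

# the eight reported statistics, in report order
mt_statistics <- c("mean_length", "assembly_rate", "assembly_duration",
                   "disassembly_rate", "disassembly_duration",
                   "catastrophe_freq", "rescue_freq", "pause_duration")

#' Condition-level summary of microtubule dynamics
#'
#' Aggregates per-microtubule statistics to mean and SEM over microtubules.
#' `NA` entries (e.g. a catastrophe frequency whose denominator was zero)
#' are dropped per statistic, with the effective n reported.  Cohorts drawn
#' from fewer than five cells trigger a warning (not an error).
#'
#' @param dyn data.frame of [summarize_mt()] rows (one per microtubule)
#' @param label condition label
#' @return object of class `condition_summary`: list with `label`, `stats`
#'   (data.frame: statistic, mean, sem, n), `n_mts`, `n_cells`, and the
#'   per-microtubule table in `per_mt`
#' @export
summarize_condition <- function(dyn, label = "condition") {
  if (is.null(dyn) || nrow(dyn) == 0) stop("empty per-microtubule table")
  if (nrow(dyn) < 2) stop("need at least two microtubules to summarize")
  n_cells <- length(unique(dyn$cell_id))
  if (n_cells < 5) {
    warning(sprintf("condition '%s' has only %d cell(s); reference protocol uses >= 5",
                    label, n_cells))
  }
  stats_df <- do.call(rbind, lapply(mt_statistics, function(s) {
    x <- dyn[[s]]
    x <- x[!is.na(x)]
    n <- length(x)
    data.frame(statistic = s,
               mean = if (n) mean(x) else NA_real_,
               sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
  structure(list(label = label, stats = stats_df,
                 n_mts = nrow(dyn), n_cells = n_cells, per_mt = dyn),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Condition '%s': %d microtubules from %d cells\n",
              x$label, x$n_mts, x$n_cells))
  df <- x$stats
  df$value <- sprintf("%.3g ± %.2g", df$mean, df$sem)
  print(df[, c("statistic", "value", "n")], row.names = FALSE)
  invisible(x)
}

#' Compare two conditions statistic by statistic
#'
#' Welch (unequal-variance) two-sided two-sample t-test on the
#' per-microtubule values of each statistic, flagged at the supplied alpha.
#' When both cohorts are degenerate (zero variance), the p-value is reported
#' as an exact comparison of means (1 if equal, 0 otherwise) with a warning.
#'
#' @param a,b [summarize_condition()] results, or per-microtubule
#'   data.frames as produced by [summarize_mt()]
#' @param alpha significance level for the flags (0.05 for table-style
#'   reports, 0.01 for figure-style reports)
#' @return data.frame: statistic, mean_a, mean_b, n_a, n_b, p_value,
#'   significant
#' @export
compare_conditions <- function(a, b, alpha = 0.05) {
  per_mt <- function(x) if (inherits(x, "condition_summary")) x$per_mt else x
  da <- per_mt(a); db <- per_mt(b)
  if (nrow(da) < 2 || nrow(db) < 2) stop("both cohorts need >= 2 microtubules")
  out <- do.call(rbind, lapply(mt_statistics, function(s) {
    xa <- da[[s]]; xa <- xa[!is.na(xa)]
    xb <- db[[s]]; xb <- xb[!is.na(xb)]
    p <- NA_real_
    if (length(xa) >= 2 && length(xb) >= 2) {
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        warning(sprintf("zero variance in both cohorts for %s; exact mean comparison", s))
        p <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
      } else {
        p <- stats::t.test(xa, xb, var.equal = FALSE)$p.value
      }
    }
    data.frame(statistic = s, mean_a = if (length(xa)) mean(xa) else NA_real_,
               mean_b = if (length(xb)) mean(xb) else NA_real_,
               n_a = length(xa), n_b = length(xb), p_value = p,
               significant = !is.na(p) & p < alpha,
               stringsAsFactors = FALSE)
  }))
  attr(out, "alpha") <- alpha
  out
}

#' Summarize a whole cohort of traces in one call
#'
#' Convenience wrapper: classify every trace and stack the per-microtubule
#' statistics.
#'
#' @param traces list of `length_trace` objects
#' @param config a [classifier_config()]
#' @return data.frame of [summarize_mt()] rows
#' @export
summarize_cohort <- function(traces, config = classifier_config()) {
  do.call(rbind, lapply(traces, function(tr) {
    summarize_mt(classify_trace(tr, config), tr)
  }))
}

#' Condition summaries in a report-shaped table
#'
#' Formats one or more condition summaries as a wide table, one row per
#' condition, columns `mean +/- SEM` per statistic.
#'
#' @param summaries list of [summarize_condition()] results
#' @return data.frame, one row per condition
#' @export
condition_report <- function(summaries) {
  do.call(rbind, lapply(summaries, function(cs) {
    row <- data.frame(condition = cs$label, n_mts = cs$n_mts,
                      n_cells = cs$n_cells, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(cs$stats))) {
      row[[cs$stats$statistic[k]]] <-
        sprintf("%.3g ± %.2g", cs$stats$mean[k], cs$stats$sem[k])
    }
    row
  }))
}
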