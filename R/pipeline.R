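# tiny FNV-1a hash of a string, hex encoded; used only for run manifests
fnv1a <- function(s) {
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Configuration of an end-to-end dynamics run
#'
#' @param conditions named list; each element a list with `targets` (a
#'   [summary_targets()]), `v_g`, `v_s` (um/min) and optionally `n_traces`.
#'   [mt_reference_targets()] builds such elements from the reference table.
#' @param reference label of the condition the others are compared against
#' @param n_traces default number of traces per condition
#' @param alpha significance level of the comparison report
#' @param classifier a [classifier_config()]
#' @param dt,duration,noise_sd trace parameters, as in [sim_params()]
#' @param calibrate calibrate the generator against the classifier
#'   ([calibrate_generator()]) rather than using the raw chain-level
#'   inversion
#' @return list of class `dynamics_config`
#' @export
dynamics_config <- function(conditions, reference = names(conditions)[1],
                            n_traces = 100, alpha = 0.05,
                            classifier = classifier_config(),
                            dt = 4, duration = 600, noise_sd = 0.05,
                            calibrate = TRUE) {
  if (is.null(names(conditions)) || anyDuplicated(names(conditions))) {
    stop("conditions must be uniquely named")
  }
  if (!reference %in% names(conditions)) stop("reference condition not found")
  structure(list(conditions = conditions, reference = reference,
                 n_traces = n_traces, alpha = alpha, classifier = classifier,
                 dt = dt, duration = duration, noise_sd = noise_sd,
                 calibrate = calibrate),
            class = "dynamics_config")
}

#' Run the full dynamics pipeline
#'
#' For every condition: solve (and optionally calibrate) generative hazards
#' from its targets, simulate a cohort of traces, classify them, and
#' summarize.  Conditions are then compared against the reference with
#' Welch t-tests.  All tables are written tab-delimited under `out_dir`
#' together with a manifest recording the seed fan-out and a config hash;
#' a rerun with the same config and seed is bit-identical.
#'
#' @param config a [dynamics_config()]
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing
#' @param seed master seed; fanned out per condition by stable label
#'   hashing, so adding a condition does not perturb the others
#' @return (invisibly) list: `summaries` (per-condition
#'   [summarize_condition()]), `comparisons`, `report`, `per_mt`
#' @export
run_dynamics_pipeline <- function(config, out_dir = NULL, seed = 1) {
  stopifnot(inherits(config, "dynamics_config"))
  results <- list(); per_mt_all <- list(); traces_all <- list()
  truth_all <- list()

  for (label in names(config$conditions)) {
    cond <- config$conditions[[label]]
    seed_c <- fanout_seed(seed, label)
    res <- tryCatch({
      if (isTRUE(config$calibrate)) {
        cal <- calibrate_generator(cond$targets, v_g = cond$v_g, v_s = cond$v_s,
                                   seed = seed_c, config = config$classifier,
                                   dt = config$dt, duration = config$duration,
                                   noise_sd = config$noise_sd)
        params <- cal$params
      } else {
        params <- sim_params(v_g = cond$v_g, v_s = cond$v_s,
                             hazards = hazards_from_summary(cond$targets),
                             dt = config$dt, duration = config$duration,
                             noise_sd = config$noise_sd)
      }
      n <- cond$n_traces %||% config$n_traces
      traces <- simulate_cohort(n, params, seed = fanout_seed(seed_c, "cohort"))
      dyn <- summarize_cohort(traces, config$classifier)
      cs <- summarize_condition(dyn, label)
      list(summary = cs, traces = traces, params = params)
    }, error = function(e) {
      stop(sprintf("dynamics pipeline failed at condition '%s': %s",
                   label, conditionMessage(e)))
    })
    results[[label]] <- res$summary
    per_mt_all[[label]] <- cbind(condition = label, res$summary$per_mt)
    traces_all[[label]] <- res$traces
    truth_all[[label]] <- list(v_g = res$params$v_g, v_s = res$params$v_s,
                               hazards = as.list(unclass(res$params$hazards)),
                               seed = seed_c)
  }

  comparisons <- list()
  for (label in setdiff(names(results), config$reference)) {
    comparisons[[label]] <- compare_conditions(results[[config$reference]],
                                               results[[label]],
                                               alpha = config$alpha)
  }
  report <- condition_report(results)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (label in names(traces_all)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", label)
      write_traces(traces_all[[label]],
                   file.path(out_dir, paste0("traces_", safe, ".tsv")))
      segs <- lapply(traces_all[[label]], classify_trace, config = config$classifier)
      write_tsv(do.call(rbind, lapply(segs, phase_table)),
                file.path(out_dir, paste0("phases_", safe, ".tsv")))
      write_tsv(do.call(rbind, lapply(segs, transition_table)),
                file.path(out_dir, paste0("transitions_", safe, ".tsv")))
    }
    write_tsv(do.call(rbind, per_mt_all), file.path(out_dir, "per_mt.tsv"))
    write_tsv(report, file.path(out_dir, "condition_summary.tsv"))
    if (length(comparisons)) {
      cmp <- do.call(rbind, Map(cbind, condition = names(comparisons), comparisons))
      write_tsv(cmp, file.path(out_dir, "comparison.tsv"))
    }
    manifest <- list(kind = "dynamics", seed = seed,
                     config_hash = fnv1a(yaml::as.yaml(rapply(
                       unclass(config), unclass, how = "replace"))),
                     conditions = truth_all)
    writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  }

  invisible(list(summaries = results, comparisons = comparisons,
                 report = report, per_mt = do.call(rbind, per_mt_all)))
}

#' Run the kinetics pipeline
#'
#' For every condition: generate a synthetic titration at its ground-truth
#' parameters, fit the Michaelis-Menten model, and report Km and kcat with
#' standard errors plus the percent change in kcat relative to a reference
#' condition.
#'
#' @param conditions named list of lists with `Km`, `kcat` and optionally
#'   `enzyme_conc`, `noise_cv`; or a data.frame like
#'   [gtpase_reference_conditions()]
#' @param reference label of the reference condition
#' @param out_dir output directory; `NULL` writes nothing
#' @param seed master seed (fanned out per condition)
#' @param noise_cv default multiplicative rate noise
#' @param mode titration mode, see [simulate_titration()]
#' @return (invisibly) list: `fits` (named [fit_mm()] list), `report`
#' @export
run_kinetics_pipeline <- function(conditions, reference = NULL,
                                  out_dir = NULL, seed = 1,
                                  noise_cv = 0.03,
                                  mode = "initial_rate") {
  if (is.data.frame(conditions)) {
    conditions <- stats::setNames(
      lapply(seq_len(nrow(conditions)), function(i) {
        list(Km = conditions$Km_uM[i], kcat = conditions$kcat_per_min[i])
      }), conditions$condition)
  }
  reference <- reference %||% names(conditions)[1]
  fits <- list(); series_all <- list()
  for (label in names(conditions)) {
    cond <- conditions[[label]]
    res <- tryCatch({
      truth <- kinetic_truth(Km = cond$Km, kcat = cond$kcat,
                             enzyme_conc = cond$enzyme_conc %||% 1,
                             noise_cv = cond$noise_cv %||% noise_cv,
                             seed = fanout_seed(seed, label))
      series <- simulate_titration(truth, mode = mode, condition = label)
      list(fit = fit_mm(series), series = series)
    }, error = function(e) {
      stop(sprintf("kinetics pipeline failed at condition '%s': %s",
                   label, conditionMessage(e)))
    })
    fits[[label]] <- res$fit
    series_all[[label]] <- res$series
  }
  report <- data.frame(
    condition = names(fits),
    Km_uM = vapply(fits, `[[`, numeric(1), "Km"),
    Km_se = vapply(fits, `[[`, numeric(1), "Km_se"),
    kcat_per_min = vapply(fits, `[[`, numeric(1), "kcat"),
    kcat_se = vapply(fits, `[[`, numeric(1), "kcat_se"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  if (!is.null(reference) && reference %in% names(fits)) {
    cmp <- compare_kcat(fits, reference)
    report$percent_decrease <- cmp$percent_decrease[match(report$condition,
                                                          cmp$condition)]
  }
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (label in names(series_all)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", label)
      write_titration(series_all[[label]],
                      file.path(out_dir, paste0("titration_", safe, ".tsv")))
    }
    write_tsv(report, file.path(out_dir, "kinetics_report.tsv"))
    manifest <- list(kind = "kinetics", seed = seed, reference = reference,
                     conditions = lapply(conditions, function(x) x[c("Km", "kcat")]))
    writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  }
  invisible(list(fits = fits, report = report))
}
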