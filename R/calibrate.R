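#' Calibrate the trace generator against the classifier
#'
#' [hazards_from_summary()] matches the targeted statistics in the
#' stationary regime of the underlying chain.  The measured statistics,
#' however, are produced by classifying noisy sampled traces, and
#' classification censors short phases: a growth excursion below the net
#' change threshold or a pause shorter than the minimum point count is not
#' counted, which biases the recovered frequencies and mean pause duration
#' relative to the chain values.  Because the targeted reference statistics
#' are themselves classifier outputs, the generator is calibrated against
#' the same measurement operator: a multiplicative fixed point adjusts the
#' chain-level targets (and the phase velocities) until the
#' simulate-classify-summarize round trip returns the requested values.
#'
#' @param targets a [summary_targets()]
#' @param v_g,v_s target assembly / disassembly speeds, um/min
#' @param n traces per calibration iteration
#' @param seed integer seed (calibration is deterministic given the seed)
#' @param config classifier configuration used for the round trip
#' @param dt,duration,noise_sd,l0 trace parameters, as in [sim_params()]
#' @param maxit calibration iterations
#' @param rtol stop when every measured statistic is within `rtol` of its
#'   target
#' @return list: `params` (a [sim_params()] ready for [simulate_cohort()]),
#'   `hazards`, `measured` (statistics of the last calibration round),
#'   `adjusted` (the adjusted chain-level targets), `iterations`
#' @export
calibrate_generator <- function(targets, v_g, v_s, n = 250, seed = 1,
                                config = classifier_config(),
                                dt = 4, duration = 600, noise_sd = 0.05,
                                l0 = 0.9, maxit = 10, rtol = 0.05) {
  stopifnot(inherits(targets, "summary_targets"))
  want <- c(assembly_rate = v_g, disassembly_rate = v_s,
            catastrophe_freq = targets$catastrophe_freq,
            rescue_freq = targets$rescue_freq,
            pause_duration = targets$pause_duration,
            assembly_duration = targets$assembly_duration,
            disassembly_duration = targets$disassembly_duration)

  adj <- list(v_g = v_g, v_s = v_s,
              fc = targets$catastrophe_freq, fr = targets$rescue_freq,
              tau_p = targets$pause_duration,
              tau_g = targets$assembly_duration,
              tau_s = targets$disassembly_duration)
  measured <- NULL; h <- NULL; it_done <- 0; used <- adj

  for (it in seq_len(maxit)) {
    used <- adj
    tg <- summary_targets(catastrophe_freq = adj$fc, rescue_freq = adj$fr,
                          pause_duration = adj$tau_p,
                          assembly_duration = adj$tau_g,
                          disassembly_duration = adj$tau_s)
    h <- hazards_from_summary(tg)
    p <- sim_params(v_g = adj$v_g, v_s = adj$v_s, hazards = h, dt = dt,
                    duration = duration, noise_sd = noise_sd, l0 = l0)
    traces <- simulate_cohort(n, p, seed = fanout_seed(seed, paste0("cal", it)))
    dyn <- summarize_cohort(traces, config)
    cs <- suppressWarnings(summarize_condition(dyn, "calibration"))
    m <- cs$stats$mean
    names(m) <- cs$stats$statistic
    measured <- m[names(want)]
    it_done <- it

    rel <- abs(measured - want) / want
    if (all(is.finite(rel)) && max(rel) < rtol) break
    step <- function(cur, target, meas) {
      if (!is.finite(meas) || meas <= 0) return(cur)
      cur * min(max(target / meas, 0.6), 1.6)
    }
    adj$v_g <- step(adj$v_g, want[["assembly_rate"]], measured[["assembly_rate"]])
    adj$v_s <- step(adj$v_s, want[["disassembly_rate"]], measured[["disassembly_rate"]])
    adj$fc <- step(adj$fc, want[["catastrophe_freq"]], measured[["catastrophe_freq"]])
    adj$fr <- step(adj$fr, want[["rescue_freq"]], measured[["rescue_freq"]])
    adj$tau_p <- step(adj$tau_p, want[["pause_duration"]], measured[["pause_duration"]])
    adj$tau_g <- step(adj$tau_g, want[["assembly_duration"]], measured[["assembly_duration"]])
    adj$tau_s <- step(adj$tau_s, want[["disassembly_duration"]], measured[["disassembly_duration"]])
  }

  # params matching the hazards/velocities of the last measured round
  params <- sim_params(v_g = used$v_g, v_s = used$v_s, hazards = h, dt = dt,
                       duration = duration, noise_sd = noise_sd, l0 = l0)
  list(params = params, hazards = h, measured = measured,
       adjusted = used, iterations = it_done)
}
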