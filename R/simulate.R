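#' Simulation parameters for a single microtubule length trace
#'
#' @param v_g assembly (growth) speed, um/min; > 0
#' @param v_s disassembly (shrinkage) speed, um/min; > 0 (speed, not signed)
#' @param hazards a [hazard_set()] of transition rates (min^-1)
#' @param dt sampling interval, seconds (4 or 5)
#' @param duration trace duration, seconds
#' @param noise_sd additive Gaussian measurement noise on each sampled
#'   length, um (sub-pixel localisation scale)
#' @param l0 initial length, um
#' @param init_state `"stationary"` draws the initial state from the
#'   stationary occupancy of the chain; or one of `"growth"`, `"shrink"`,
#'   `"pause"`
#' @param boundary behaviour when length hits 0 during shrinkage:
#'   `"renucleate"` forces an immediate transition to growth;
#'   `"terminate"` ends the trajectory (remaining samples stay at 0)
#' @param seed integer seed; `NULL` uses the current RNG stream
#' @return object of class `sim_params` (a validated list)
#' @export
sim_params <- function(v_g, v_s, hazards, dt = 4, duration = 600,
                       noise_sd = 0.05, l0 = 0.5,
                       init_state = "stationary",
                       boundary = c("renucleate", "terminate"),
                       seed = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(hazards, "hazard_set"))
  if (!(v_g > 0) || !(v_s > 0)) stop("v_g and v_s must be > 0")
  if (!(dt %in% c(4, 5))) stop("dt must be 4 or 5 seconds")
  if (duration < 4 * dt) stop("duration must cover at least 4 sampling intervals")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (l0 < 0) stop("l0 must be >= 0")
  init_state <- match.arg(init_state, c("stationary", "growth", "shrink", "pause"))
  structure(list(v_g = v_g, v_s = v_s, hazards = hazards, dt = dt,
                 duration = duration, noise_sd = noise_sd, l0 = l0,
                 init_state = init_state, boundary = boundary, seed = seed),
            class = "sim_params")
}

# exit rates (min^-1) per state and per-state destination hazards
state_exits <- function(h) {
  list(growth = c(shrink = h[["gs"]], pause = h[["gp"]]),
       shrink = c(growth = h[["sg"]], pause = h[["sp"]]),
       pause  = c(shrink = h[["ps"]], growth = h[["pg"]]))
}

#' Simulate one microtubule length trace
#'
#' Draws a trajectory of the three-state continuous-time Markov chain
#' (growth at `v_g`, shrinkage at `-v_s`, pause at 0), integrating length
#' exactly between exponentially distributed transition events.  When length
#' reaches 0 during shrinkage the trajectory either renucleates (forced
#' transition to growth) or terminates, per `params$boundary`.  The
#' continuous trajectory is then sampled every `dt` seconds and independent
#' Gaussian measurement noise is added to each sample (truncated at 0).
#'
#' @param params a [sim_params()]
#' @param cell_id,mt_id identifiers carried into the output table
#' @return a `length_trace`: data.frame with columns `cell_id`, `mt_id`,
#'   `time_s`, `length_um`.  Attributes: `dt`, `dwell` (exact per-state dwell
#'   ledger of the underlying trajectory, seconds) and `states` (the
#'   piecewise-linear ground-truth segments).
#' @examples
#' p <- sim_params(v_g = 1.4, v_s = 3.06,
#'                 hazards = hazard_set(gs = 0.9, sg = 1.5),
#'                 init_state = "growth", l0 = 1, seed = 1)
#' tr <- simulate_trace(p)
#' head(tr)
#' @export
simulate_trace <- function(params, cell_id = "cell1", mt_id = "mt1") {
  stopifnot(inherits(params, "sim_params"))
  h <- unclass(params$hazards)
  exits <- state_exits(h)
  exit_rate <- vapply(exits, sum, numeric(1))

  if (params$init_state == "stationary") {
    occ <- stationary_occupancy(params$hazards) # errors if chain is absorbing
  }
  if (params$l0 == 0 && exit_rate[["shrink"]] == 0 &&
      (params$init_state == "shrink")) {
    stop("degenerate: absorbing shrink state starting at zero length")
  }

  with_seed(params$seed, {
    state <- if (params$init_state == "stationary") {
      sample(c("growth", "shrink", "pause"), 1, prob = occ)
    } else params$init_state

    T_min <- params$duration / 60
    vel <- c(growth = params$v_g, shrink = -params$v_s, pause = 0)

    # event-driven integration; breakpoints in minutes
    t_cur <- 0; l_cur <- params$l0
    bp_t <- 0; bp_l <- l_cur
    seg_state <- character(0); seg_t0 <- numeric(0); seg_t1 <- numeric(0)
    terminated <- FALSE

    while (t_cur < T_min && !terminated) {
      k <- exit_rate[[state]]
      dwell <- if (k > 0) stats::rexp(1, k) else Inf
      t_next <- t_cur + dwell
      next_state <- NULL
      # shrinkage can hit the zero-length boundary before the next event
      if (state == "shrink" && l_cur > 0) {
        t_hit <- t_cur + l_cur / params$v_s
        if (t_hit < min(t_next, T_min)) {
          t_next <- t_hit
          next_state <- if (params$boundary == "renucleate") "growth" else "end"
        }
      } else if (state == "shrink" && l_cur == 0) {
        # already at the boundary
        t_next <- t_cur
        next_state <- if (params$boundary == "renucleate") "growth" else "end"
      }
      if (t_next >= T_min) {         # trace ends mid-dwell
        l_end <- l_cur + vel[[state]] * (T_min - t_cur)
        seg_state <- c(seg_state, state)
        seg_t0 <- c(seg_t0, t_cur); seg_t1 <- c(seg_t1, T_min)
        bp_t <- c(bp_t, T_min); bp_l <- c(bp_l, l_end)
        break
      }
      if (is.null(next_state)) {
        ex <- exits[[state]]
        next_state <- sample(names(ex), 1, prob = ex)
      }
      l_next <- l_cur + vel[[state]] * (t_next - t_cur)
      l_next <- max(l_next, 0)       # guard against roundoff at the boundary
      if (t_next > t_cur) {
        seg_state <- c(seg_state, state)
        seg_t0 <- c(seg_t0, t_cur); seg_t1 <- c(seg_t1, t_next)
        bp_t <- c(bp_t, t_next); bp_l <- c(bp_l, l_next)
      }
      t_cur <- t_next; l_cur <- l_next
      if (identical(next_state, "end")) terminated <- TRUE else state <- next_state
    }
    if (terminated && t_cur < T_min) { # flat tail at zero length
      seg_state <- c(seg_state, "terminated")
      seg_t0 <- c(seg_t0, t_cur); seg_t1 <- c(seg_t1, T_min)
      bp_t <- c(bp_t, T_min); bp_l <- c(bp_l, 0)
    }

    times_s <- seq(0, params$duration, by = params$dt)
    lengths <- stats::approx(bp_t * 60, bp_l, xout = times_s, rule = 2)$y
    if (params$noise_sd > 0) {
      lengths <- lengths + stats::rnorm(length(lengths), 0, params$noise_sd)
    }
    lengths <- pmax(lengths, 0)

    dwell <- tapply((seg_t1 - seg_t0) * 60, seg_state, sum)
    out <- data.frame(cell_id = cell_id, mt_id = mt_id,
                      time_s = times_s, length_um = lengths,
                      stringsAsFactors = FALSE)
    structure(out, dt = params$dt, dwell = dwell,
              states = data.frame(state = seg_state, t0_s = seg_t0 * 60,
                                  t1_s = seg_t1 * 60),
              class = c("length_trace", "data.frame"))
  })
}

#' Simulate a cohort of microtubule traces
#'
#' Generates `n` independent traces from one parameter set, assigning two
#' astral microtubules per cell (the typical count in preanaphase cells).
#' Reproducible from `seed`; trace `i` does not depend on `n`.
#'
#' @param n number of traces
#' @param params a [sim_params()]; its `seed` field is ignored in favour of
#'   `seed`
#' @param seed integer master seed for the cohort
#' @return list of `length_trace` objects
#' @export
simulate_cohort <- function(n, params, seed = NULL) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- if (is.null(seed)) NULL else fanout_seed(seed, paste0("trace", i))
    simulate_trace(p, cell_id = sprintf("cell%03d", ceiling(i / 2)),
                   mt_id = sprintf("mt%03d", i))
  })
}
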