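#' Transition hazards for the three-state dynamic instability model
#'
#' A microtubule end is modelled as a continuous-time Markov chain over three
#' states: growth (assembly at speed `v_g`), shrinkage (disassembly at speed
#' `v_s`) and pause (zero speed).  The six hazards are the exponential rates
#' (per minute) of the allowed transitions.  Direct growth<->shrink switches
#' correspond to catastrophes (`gs`) and rescues (`sg`); transitions through
#' pause contribute to the catastrophe and rescue counts when the chain leaves
#' pause towards shrinkage (`ps`) or growth (`pg`).
#'
#' @param gs,gp growth -> shrink / growth -> pause rate, min^-1
#' @param sg,sp shrink -> growth / shrink -> pause rate, min^-1
#' @param ps,pg pause -> shrink / pause -> growth rate, min^-1
#' @return an object of class `hazard_set` (named numeric vector, min^-1)
#' @examples
#' hazard_set(gs = 0.9, sg = 1.5)
#' @export
hazard_set <- function(gs = 0, gp = 0, sg = 0, sp = 0, ps = 0, pg = 0) {
  h <- c(gs = gs, gp = gp, sg = sg, sp = sp, ps = ps, pg = pg)
  if (any(!is.finite(h)) || any(h < 0)) {
    stop("all hazards must be finite and >= 0")
  }
  structure(h, class = "hazard_set")
}

#' @export
print.hazard_set <- function(x, ...) {
  cat("Dynamic instability hazards (min^-1):\n")
  cat(sprintf("  growth -> shrink %.4g   growth -> pause %.4g\n", x["gs"], x["gp"]))
  cat(sprintf("  shrink -> growth %.4g   shrink -> pause %.4g\n", x["sg"], x["sp"]))
  cat(sprintf("  pause  -> shrink %.4g   pause  -> growth %.4g\n", x["ps"], x["pg"]))
  if (isTRUE(attr(x, "approx"))) {
    cat(sprintf("  (least-squares approximation; constraint residual %.3g)\n",
                attr(x, "residual")))
  }
  invisible(x)
}

# generator matrix, states ordered (growth, shrink, pause)
hazard_Q <- function(h) {
  matrix(c(-(h["gs"] + h["gp"]), h["gs"], h["gp"],
           h["sg"], -(h["sg"] + h["sp"]), h["sp"],
           h["pg"], h["ps"], -(h["ps"] + h["pg"])),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("growth", "shrink", "pause"),
                         c("growth", "shrink", "pause")))
}

#' Stationary state occupancy of the three-state chain
#'
#' Fraction of time spent in growth, shrinkage and pause in the stationary
#' regime (the normalised left null vector of the generator matrix).
#'
#' @param hazards a [hazard_set()]
#' @return named numeric vector (growth, shrink, pause) summing to 1
#' @export
stationary_occupancy <- function(hazards) {
  h <- unclass(hazards)
  exit <- c(growth = h[["gs"]] + h[["gp"]],
            shrink = h[["sg"]] + h[["sp"]],
            pause  = h[["ps"]] + h[["pg"]])
  if (any(exit == 0)) {
    stop("chain has an absorbing state (zero exit rate); ",
         "stationary occupancy is not defined for the full state space")
  }
  Q <- hazard_Q(h)
  A <- rbind(t(Q), rep(1, 3))
  b <- c(0, 0, 0, 1)
  pi_hat <- qr.solve(A, b)
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- c("growth", "shrink", "pause")
  pi_hat
}

# Analytic catastrophe / rescue frequencies and mean dwell times implied by a
# hazard set, using the field definitions: catastrophes are transitions into
# shrinkage from growth or pause, counted per minute spent in growth + pause;
# rescues are transitions into growth from shrinkage or pause, per minute in
# shrinkage + pause.
chain_statistics <- function(hazards) {
  h <- unclass(hazards)
  p <- stationary_occupancy(hazards)
  cat_f <- (p[["growth"]] * h[["gs"]] + p[["pause"]] * h[["ps"]]) /
    (p[["growth"]] + p[["pause"]])
  res_f <- (p[["shrink"]] * h[["sg"]] + p[["pause"]] * h[["pg"]]) /
    (p[["shrink"]] + p[["pause"]])
  dwell <- 60 / c(h[["gs"]] + h[["gp"]], h[["sg"]] + h[["sp"]],
                  h[["ps"]] + h[["pg"]])
  list(catastrophe_freq = cat_f, rescue_freq = res_f,
       assembly_duration = dwell[1], disassembly_duration = dwell[2],
       pause_duration = dwell[3], occupancy = p)
}

#' Reference statistics for microtubule dynamics of a condition
#'
#' Bundles the targeted summary statistics of a condition: the quantities a
#' dynamics experiment reports, used by [hazards_from_summary()] to invert
#' them into generative hazards.
#'
#' @param catastrophe_freq catastrophes per minute of assembly + pause time
#' @param rescue_freq rescues per minute of disassembly + pause time
#' @param pause_duration mean pause duration, seconds; `Inf` or `NULL`
#'   disables the pause state entirely (two-state chain)
#' @param assembly_duration,disassembly_duration mean phase durations, seconds
#' @return object of class `summary_targets`
#' @export
summary_targets <- function(catastrophe_freq, rescue_freq,
                            pause_duration = NULL,
                            assembly_duration = NULL,
                            disassembly_duration = NULL) {
  pause_free <- is.null(pause_duration) || !is.finite(pause_duration)
  vals <- list(catastrophe_freq = catastrophe_freq,
               rescue_freq = rescue_freq,
               pause_duration = if (pause_free) Inf else pause_duration,
               assembly_duration = assembly_duration,
               disassembly_duration = disassembly_duration)
  num <- unlist(vals[!vapply(vals, is.null, TRUE)])
  if (any(!is.finite(num) & !(names(num) == "pause_duration")) || any(num <= 0)) {
    stop("all targets must be positive")
  }
  structure(vals, pause_free = pause_free, class = "summary_targets")
}

#' Solve generative hazards from targeted dynamics statistics
#'
#' Inverts the condition-level statistics (catastrophe and rescue frequency,
#' mean phase durations) into the six transition hazards of the three-state
#' chain, in its stationary regime.  Mean dwell times fix the total exit rate
#' of each state; the two frequency constraints fix how growth and shrinkage
#' exits split between the direct switch and the pause route.  The split of
#' pause exits between shrinkage and growth is not identified by these
#' statistics; it defaults to `pause_split = 0.5` (balanced) and is moved only
#' if the balanced system is infeasible.
#'
#' Solved by fixed-point iteration over the stationary occupancies
#' (tolerance 1e-8 on the constraint residuals).  If no exact solution exists
#' within valid branching probabilities, the least-squares-closest feasible
#' hazards are returned with attribute `approx = TRUE`.
#'
#' With `pause_duration = Inf` (pause disabled) the two-state closed form is
#' used: `gs = catastrophe_freq`, `sg = rescue_freq`.
#'
#' @param targets a [summary_targets()]
#' @param pause_split preferred probability that a pause ends in shrinkage
#' @param tol convergence tolerance on the constraint residuals
#' @param maxit maximum fixed-point iterations
#' @return a [hazard_set()], with attributes `approx` and `residual`
#' @export
hazards_from_summary <- function(targets, pause_split = 0.5,
                                 tol = 1e-8, maxit = 500) {
  stopifnot(inherits(targets, "summary_targets"))
  fc <- targets$catastrophe_freq
  fr <- targets$rescue_freq

  if (isTRUE(attr(targets, "pause_free"))) {
    h <- hazard_set(gs = fc, sg = fr)
    # in the two-state chain dwell times are implied: flag if user-supplied
    # durations disagree with them
    approx <- FALSE
    if (!is.null(targets$assembly_duration) &&
        abs(targets$assembly_duration - 60 / fc) > 1e-6 * (60 / fc)) approx <- TRUE
    if (!is.null(targets$disassembly_duration) &&
        abs(targets$disassembly_duration - 60 / fr) > 1e-6 * (60 / fr)) approx <- TRUE
    attr(h, "approx") <- approx
    attr(h, "residual") <- 0
    return(h)
  }

  if (is.null(targets$assembly_duration) || is.null(targets$disassembly_duration)) {
    stop("assembly_duration and disassembly_duration are required when pause is enabled")
  }
  kG <- 60 / targets$assembly_duration     # total growth exit rate, min^-1
  kS <- 60 / targets$disassembly_duration
  kP <- 60 / targets$pause_duration

  build <- function(pGS, pSG, pPS) {
    hazard_set(gs = kG * pGS, gp = kG * (1 - pGS),
               sg = kS * pSG, sp = kS * (1 - pSG),
               ps = kP * pPS, pg = kP * (1 - pPS))
  }
  resid <- function(pGS, pSG, pPS) {
    h <- build(pGS, pSG, pPS)
    p <- stationary_occupancy(h)
    c((p[["growth"]] * kG * pGS + p[["pause"]] * kP * pPS) -
        fc * (p[["growth"]] + p[["pause"]]),
      (p[["shrink"]] * kS * pSG + p[["pause"]] * kP * (1 - pPS)) -
        fr * (p[["shrink"]] + p[["pause"]]))
  }

  # fixed point at the preferred pause split
  pGS <- 0.5; pSG <- 0.5; pPS <- pause_split
  clamped <- FALSE
  for (it in seq_len(maxit)) {
    h <- build(pGS, pSG, pPS)
    p <- stationary_occupancy(h)
    pGS_new <- (fc * (p[["growth"]] + p[["pause"]]) - p[["pause"]] * kP * pPS) /
      (p[["growth"]] * kG)
    pSG_new <- (fr * (p[["shrink"]] + p[["pause"]]) - p[["pause"]] * kP * (1 - pPS)) /
      (p[["shrink"]] * kS)
    clamped <- pGS_new < 0 || pGS_new > 1 || pSG_new < 0 || pSG_new > 1
    pGS_new <- min(max(pGS_new, 0), 1)
    pSG_new <- min(max(pSG_new, 0), 1)
    # damped update for stability
    pGS <- 0.5 * pGS + 0.5 * pGS_new
    pSG <- 0.5 * pSG + 0.5 * pSG_new
    if (max(abs(resid(pGS, pSG, pPS))) < tol && !clamped) break
  }
  r <- resid(pGS, pSG, pPS)

  if (max(abs(r)) >= tol) {
    # infeasible at the preferred split: least-squares over all three
    # branching probabilities with a weak pull towards the preferred split
    obj <- function(x) {
      rr <- resid(x[1], x[2], x[3])
      sum(rr^2) + 1e-8 * (x[3] - pause_split)^2
    }
    opt <- stats::optim(c(pGS, pSG, pPS), obj, method = "L-BFGS-B",
                        lower = rep(1e-9, 3), upper = rep(1 - 1e-9, 3),
                        control = list(maxit = 500, factr = 1e3))
    pGS <- opt$par[1]; pSG <- opt$par[2]; pPS <- opt$par[3]
    r <- resid(pGS, pSG, pPS)
  }

  h <- build(pGS, pSG, pPS)
  attr(h, "approx") <- max(abs(r)) >= 1e-6
  attr(h, "residual") <- max(abs(r))
  h
}
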