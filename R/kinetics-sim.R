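#' Ground truth for a synthetic GTPase titration
#'
#' Parameters of a Michaelis-Menten GTP hydrolysis reaction used to generate
#' synthetic titration data with known truth.  The default substrate grid
#' spans the 0-800 uM GTP range of the plate assay at 10 levels; the default
#' noise model is 3% multiplicative Gaussian on the rate.
#'
#' @param Km Michaelis constant, uM
#' @param kcat turnover number, min^-1 (per uM enzyme)
#' @param enzyme_conc enzyme concentration, uM
#' @param substrate_grid GTP concentrations, uM
#' @param noise_cv multiplicative rate noise (coefficient of variation)
#' @param noise_sd_rate additive rate noise, uM/min
#' @param seed integer seed
#' @return object of class `kinetic_truth`
#' @export
kinetic_truth <- function(Km, kcat, enzyme_conc = 1,
                          substrate_grid = c(0, 10, 25, 50, 100, 150,
                                             250, 400, 600, 800),
                          noise_cv = 0.03, noise_sd_rate = 0, seed = NULL) {
  if (!(Km > 0)) stop("Km must be > 0")
  if (kcat < 0) stop("kcat must be >= 0")
  if (!(enzyme_conc > 0)) stop("enzyme_conc must be > 0")
  if (any(substrate_grid < 0)) stop("substrate concentrations must be >= 0")
  if (noise_cv < 0 || noise_sd_rate < 0) stop("noise parameters must be >= 0")
  structure(list(Km = Km, kcat = kcat, enzyme_conc = enzyme_conc,
                 substrate_grid = substrate_grid, noise_cv = noise_cv,
                 noise_sd_rate = noise_sd_rate, seed = seed),
            class = "kinetic_truth")
}

mm_rate <- function(S, Km, Vmax) Vmax * S / (Km + S)

#' Simulate a GTP titration series
#'
#' `initial_rate` mode evaluates the Michaelis-Menten rate
#' `v = kcat * E * S / (Km + S)` at each substrate level and adds the noise
#' of the ground truth.  `depleting` mode instead integrates substrate
#' consumption over the full incubation (default 90 min) and reports the
#' mean rate, accumulated phosphate divided by incubation time - the
#' quantity an endpoint assay actually measures, which underestimates the
#' initial rate when a low-substrate reaction runs towards completion.
#' Rates are truncated at 0 (phosphate is never negative).
#'
#' @param truth a [kinetic_truth()]
#' @param mode `"initial_rate"` or `"depleting"`
#' @param incubation_min incubation time for `depleting` mode, minutes
#' @param condition condition label carried into the output
#' @return `titration_series`: data.frame with columns `substrate_uM`,
#'   `rate_uM_per_min`; attributes `condition`, `enzyme_conc`, `truth`
#' @examples
#' tt <- kinetic_truth(Km = 100, kcat = 2, noise_cv = 0, seed = 1)
#' simulate_titration(tt)
#' @export
simulate_titration <- function(truth, mode = c("initial_rate", "depleting"),
                               incubation_min = 90, condition = "condition") {
  stopifnot(inherits(truth, "kinetic_truth"))
  mode <- match.arg(mode)
  S <- truth$substrate_grid
  Vmax <- truth$kcat * truth$enzyme_conc
  v <- if (mode == "initial_rate") {
    mm_rate(S, truth$Km, Vmax)
  } else {
    vapply(S, function(s0) {
      if (s0 == 0 || Vmax == 0) return(0)
      sol <- deSolve::ode(y = c(S = s0), times = c(0, incubation_min),
                          func = function(t, y, parms) {
                            list(-Vmax * y[1] / (truth$Km + y[1]))
                          }, parms = NULL, method = "lsoda")
      (s0 - max(sol[nrow(sol), "S"], 0)) / incubation_min
    }, numeric(1))
  }
  v_obs <- with_seed(truth$seed, {
    e <- stats::rnorm(length(S), 0, 1)
    v * (1 + truth$noise_cv * e) +
      if (truth$noise_sd_rate > 0) stats::rnorm(length(S), 0, truth$noise_sd_rate) else 0
  })
  v_obs <- pmax(v_obs, 0)
  structure(data.frame(substrate_uM = S, rate_uM_per_min = v_obs),
            condition = condition, enzyme_conc = truth$enzyme_conc,
            mode = mode, truth = truth,
            class = c("titration_series", "data.frame"))
}

#' Simulate a phosphate standard series
#'
#' Absorbance at 621 nm of a linear 0-5 uM free-phosphate standard curve:
#' `A = slope * Pi + intercept + noise`.
#'
#' @param slope absorbance per uM phosphate
#' @param intercept blank absorbance
#' @param phosphate_points phosphate concentrations, uM, within 0-5;
#'   at least 3 points
#' @param noise_sd absorbance noise sd
#' @param seed integer seed
#' @return data.frame `pi_uM`, `a621` of class `standard_series`
#' @export
simulate_standard_series <- function(slope, intercept = 0,
                                     phosphate_points = seq(0, 5, by = 1),
                                     noise_sd = 0, seed = NULL) {
  if (length(phosphate_points) < 3) stop("need at least 3 standard points")
  if (any(phosphate_points < 0 | phosphate_points > 5)) {
    stop("standard points must lie within 0-5 uM")
  }
  a <- with_seed(seed, {
    slope * phosphate_points + intercept +
      if (noise_sd > 0) stats::rnorm(length(phosphate_points), 0, noise_sd) else 0
  })
  structure(data.frame(pi_uM = phosphate_points, a621 = a),
            class = c("standard_series", "data.frame"))
}
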