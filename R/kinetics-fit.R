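#' Fit the phosphate standard curve
#'
#' Ordinary least-squares line through the 0-5 uM phosphate standard series.
#'
#' @param series a `standard_series` or data.frame with columns `pi_uM`,
#'   `a621`
#' @return object of class `standard_curve`: list with `slope` (absorbance
#'   per uM), `intercept`, `r_squared`, `n`
#' @export
fit_standard_curve <- function(series) {
  pi_u <- series$pi_uM; a <- series$a621
  if (length(pi_u) < 3) stop("need at least 3 standard points")
  if (length(unique(pi_u)) < 2) stop("all phosphate levels identical; cannot fit a line")
  fit <- stats::lm(a ~ pi_u)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((a - mean(a))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(pi_u)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Phosphate standard curve: A621 = %.4g * Pi + %.4g (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Convert endpoint absorbances to hydrolysis rates
#'
#' Inverts the standard curve, `Pi = (A - intercept) / slope` (clamped at
#' 0), and divides by the incubation time, assuming linear phosphate
#' accumulation over the incubation.
#'
#' @param a621 absorbance values
#' @param curve a [fit_standard_curve()] result
#' @param incubation_min incubation time, minutes
#' @return numeric vector of rates, uM/min, with attribute `pi_uM`
#' @export
absorbance_to_rate <- function(a621, curve, incubation_min = 90) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!(curve$slope > 0)) stop("standard curve slope must be > 0")
  pi_u <- (a621 - curve$intercept) / curve$slope
  n_clamped <- sum(pi_u < 0)
  if (n_clamped > 0) {
    message(sprintf("absorbance_to_rate: %d value(s) below the blank clamped to 0",
                    n_clamped))
  }
  pi_u <- pmax(pi_u, 0)
  structure(pi_u / incubation_min, pi_uM = pi_u)
}

# profiled sum of squared residuals: for fixed Km the model is linear in
# Vmax, so Vmax(Km) has a closed form and the fit reduces to a 1-D search
mm_profile <- function(S, v, w) {
  function(log_km) {
    x <- S / (exp(log_km) + S)
    vmax <- sum(w * v * x) / sum(w * x^2)
    sum(w * (v - vmax * x)^2)
  }
}

#' Michaelis-Menten fit of a titration series
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)`.  For fixed `Km`
#' the model is linear in `Vmax`, so the fit is profiled: `Vmax(Km)` is
#' solved in closed form and `Km` is found by Brent search on the log
#' scale.  This makes the fit deterministic, immune to poor starting
#' values, and exactly scale-equivariant (scaling all rates by a constant
#' scales `Vmax` and leaves `Km` unchanged).  Standard errors come from the
#' local linearisation at the optimum.  `kcat = Vmax / enzyme_conc` by
#' construction.
#'
#' @param series a `titration_series` or data.frame with columns
#'   `substrate_uM`, `rate_uM_per_min`
#' @param enzyme_conc enzyme concentration, uM (taken from the series
#'   attribute when present)
#' @param weights optional least-squares weights (default unweighted)
#' @param tol convergence tolerance of the Km search (log scale)
#' @return object of class `mm_fit`: list with `Km`, `Vmax`, `kcat`,
#'   `Km_se`, `Vmax_se`, `kcat_se`, `converged`, `residual_norm`,
#'   `enzyme_conc`, `n`
#' @examples
#' tt <- kinetic_truth(Km = 100, kcat = 2, noise_cv = 0)
#' fit_mm(simulate_titration(tt))
#' @export
fit_mm <- function(series, enzyme_conc = NULL, weights = NULL, tol = 1e-12) {
  S <- series$substrate_uM; v <- series$rate_uM_per_min
  enzyme_conc <- enzyme_conc %||% attr(series, "enzyme_conc") %||% 1
  keep <- is.finite(S) & is.finite(v)
  S <- S[keep]; v <- v[keep]
  w <- weights %||% rep(1, length(S))
  if (length(unique(S)) < 5) {
    warning("fewer than 5 distinct substrate levels; Km is poorly constrained")
  }
  if (all(v == 0)) {
    return(structure(list(Km = NA_real_, Vmax = 0, kcat = 0,
                          Km_se = NA_real_, Vmax_se = NA_real_,
                          kcat_se = NA_real_, converged = TRUE,
                          residual_norm = 0, enzyme_conc = enzyme_conc,
                          n = length(S)), class = "mm_fit"))
  }
  Sp <- S[S > 0]
  if (length(Sp) == 0) stop("need at least one positive substrate level")
  lo <- log(min(Sp) / 100)
  hi <- log(max(Sp) * 100)
  ssr <- mm_profile(S, v, w)
  opt <- stats::optimize(ssr, lower = lo, upper = hi, tol = tol)
  log_km <- opt$minimum
  Km <- exp(log_km)
  x <- S / (Km + S)
  Vmax <- sum(w * v * x) / sum(w * x^2)
  res <- v - Vmax * x
  n <- length(S)
  converged <- log_km > lo + 1e-6 && log_km < hi - 1e-6 && is.finite(Vmax)
  if (!converged) {
    warning("Michaelis-Menten fit hit the Km search boundary; estimates are unreliable")
  }
  if (max(S) < 1.5 * Km || min(Sp) > Km) {
    warning(sprintf(
      "substrate design poorly spans the fitted Km (%.3g uM); estimates may be unstable", Km))
  }
  # local linearisation: J columns d v / d Vmax, d v / d Km
  J <- cbind(x, -Vmax * S / (Km + S)^2)
  se <- rep(NA_real_, 2)
  if (n > 2) {
    sigma2 <- sum(w * res^2) / (n - 2)
    JtJ <- crossprod(J * sqrt(w))
    cv <- try(solve(JtJ) * sigma2, silent = TRUE)
    if (!inherits(cv, "try-error")) se <- sqrt(pmax(diag(cv), 0))
  }
  structure(list(Km = Km, Vmax = Vmax, kcat = Vmax / enzyme_conc,
                 Km_se = se[2], Vmax_se = se[1],
                 kcat_se = se[1] / enzyme_conc,
                 converged = converged,
                 residual_norm = sqrt(sum(w * res^2)),
                 enzyme_conc = enzyme_conc, n = n),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d, E = %g uM):\n", x$n, x$enzyme_conc))
  cat(sprintf("  Km   = %.4g +/- %.2g uM\n", x$Km, x$Km_se))
  cat(sprintf("  Vmax = %.4g +/- %.2g uM/min\n", x$Vmax, x$Vmax_se))
  cat(sprintf("  kcat = %.4g +/- %.2g min^-1\n", x$kcat, x$kcat_se))
  if (!isTRUE(x$converged)) cat("  (not converged)\n")
  invisible(x)
}

#' Compare turnover numbers across conditions
#'
#' Percent change of each condition's `kcat` relative to a reference
#' condition: `100 * (kcat_ref - kcat) / kcat_ref`, plus the plain ratio.
#'
#' @param fits named list of [fit_mm()] results (or of numeric kcat values)
#' @param reference name of the reference condition
#' @return data.frame: condition, kcat_per_min, kcat_ratio,
#'   percent_decrease
#' @export
compare_kcat <- function(fits, reference) {
  if (!reference %in% names(fits)) stop("reference condition not found")
  kc <- vapply(fits, function(f) if (inherits(f, "mm_fit")) f$kcat else as.numeric(f),
               numeric(1))
  kref <- kc[[reference]]
  if (!(kref > 0)) stop("reference kcat must be > 0")
  data.frame(condition = names(kc), kcat_per_min = unname(kc),
             kcat_ratio = unname(kc / kref),
             percent_decrease = unname(100 * (kref - kc) / kref),
             stringsAsFactors = FALSE)
}
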