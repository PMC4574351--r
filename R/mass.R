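#' Subunit masses of the yeast tubulin-cofactor system
#'
#' Exact molecular masses (Da) of the chaperone subunits TBCD (Cin1), TBCE
#' (Pac2), Arl2 (Cin4) and TBCC (Cin2), plus the alpha/beta-tubulin
#' heterodimer.  Two tubulin-dimer constants are in common use: the nominal
#' 110 kDa sequence-based value used for predicted complex masses, and the
#' 100 kDa value measured for the free dimer by light scattering; choose
#' with `tubulin`.
#'
#' @param tubulin which tubulin-dimer mass preset to include
#' @return data.frame `name`, `mass_da`
#' @export
tbc_subunits <- function(tubulin = c("nominal", "sec_mals")) {
  tubulin <- match.arg(tubulin)
  data.frame(
    name = c("TBCD", "TBCE", "Arl2", "TBCC", "tubulin_dimer"),
    mass_da = c(116647.8, 59257.6, 22066.6, 34045.4,
                if (tubulin == "nominal") 110000 else 100000),
    stringsAsFactors = FALSE
  )
}

as_mass_table <- function(subunits) {
  if (is.data.frame(subunits)) {
    m <- subunits$mass_da
    names(m) <- subunits$name
  } else {
    m <- unlist(subunits)
  }
  if (any(!is.finite(m)) || any(m <= 0)) stop("subunit masses must be > 0")
  m
}

#' Predicted mass of a stoichiometric complex
#'
#' Exact integer-weighted sum of subunit masses, in Da.  Rounding to kDa
#' happens only at display.
#'
#' @param counts named non-negative integer vector, subunit name -> copy
#'   number
#' @param subunits subunit mass table ([tbc_subunits()] format) or named
#'   numeric vector of masses in Da
#' @return predicted mass, Da
#' @examples
#' predicted_mass(c(TBCD = 1, TBCE = 1, Arl2 = 1), tbc_subunits())
#' @export
predicted_mass <- function(counts, subunits) {
  m <- as_mass_table(subunits)
  if (length(counts) == 0) return(0)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  unknown <- setdiff(names(counts), names(m))
  if (length(unknown)) {
    stop("unknown subunit(s): ", paste(unknown, collapse = ", "))
  }
  sum(counts * m[names(counts)])
}

#' Infer integer stoichiometry from a measured complex mass
#'
#' Exhaustively enumerates compositions with up to `max_copies` of each
#' subunit and keeps those whose predicted mass lies within
#' `tolerance_sd` standard deviations of the measured mean, ranked by
#' absolute residual (ties broken lexicographically by composition).
#'
#' @param mean_kda measured mass, kDa (e.g. from SEC-MALS)
#' @param sd_kda measurement standard deviation, kDa
#' @param subunits subunit mass table, as in [predicted_mass()]
#' @param max_copies maximum copies per subunit
#' @param tolerance_sd acceptance window half-width in units of `sd_kda`
#' @return data.frame, one row per admissible composition: one count column
#'   per subunit, `predicted_da`, `predicted_kda`, `residual_kda`; zero rows
#'   when nothing fits
#' @examples
#' infer_stoichiometry(310, 10, tbc_subunits())
#' @export
infer_stoichiometry <- function(mean_kda, sd_kda, subunits,
                                max_copies = 2, tolerance_sd = 2) {
  if (max_copies < 1) stop("max_copies must be >= 1")
  if (sd_kda < 0) stop("sd_kda must be >= 0")
  m <- as_mass_table(subunits)
  if (length(m) < 1) stop("need at least one subunit")
  grid <- expand.grid(rep(list(0:max_copies), length(m)))
  names(grid) <- names(m)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  pred <- as.matrix(grid) %*% m
  resid_da <- pred - mean_kda * 1000
  tol_da <- max(tolerance_sd * sd_kda * 1000, 1e-6)
  keep <- abs(resid_da) <= tol_da
  out <- grid[keep, , drop = FALSE]
  out$predicted_da <- pred[keep]
  out$predicted_kda <- round(pred[keep] / 1000)
  out$residual_kda <- resid_da[keep] / 1000
  # rank by |residual|, lexicographic composition as the deterministic
  # tie-break
  ord <- do.call(order, c(list(abs(out$residual_kda)),
                          unname(as.list(out[names(m)]))))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Measured-vs-predicted mass report for a set of complexes
#'
#' @param complexes named list of count vectors (as in [predicted_mass()])
#' @param measured named numeric vector of measured masses, kDa (NA where
#'   not measured)
#' @param subunits subunit mass table
#' @return data.frame: complex, predicted_kda, measured_kda, difference_kda
#' @export
mass_report <- function(complexes, measured = NULL, subunits = tbc_subunits()) {
  pred <- vapply(complexes, predicted_mass, numeric(1), subunits = subunits)
  out <- data.frame(complex = names(complexes),
                    predicted_kda = round(pred / 1000),
                    stringsAsFactors = FALSE)
  if (!is.null(measured)) {
    out$measured_kda <- unname(measured[out$complex])
    out$difference_kda <- out$measured_kda - pred / 1000
  }
  out
}
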