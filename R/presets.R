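#' Reference astral microtubule dynamics statistics
#'
#' Published in-vivo dynamic-instability statistics for budding yeast
#' astral microtubules: wild type, cells acutely expressing the GTP-locked
#' Arl2/Cin4 Q73L mutant (90 min induction), and cells constitutively
#' expressing cin4-Q73L.  Columns follow the standard report: mean length
#' (um), assembly and disassembly rates (um/min) and mean phase durations
#' (s), catastrophe and rescue frequencies (min^-1), mean pause duration
#' (s).  These rows parameterise the synthetic trace generator for
#' round-trip recovery studies.
#'
#' @return data.frame, one row per condition
#' @export
mt_reference_conditions <- function() {
  data.frame(
    condition = c("wild_type", "wild_type_Q73L_90min", "cin4_Q73L"),
    mean_length = c(0.90, 2.69, 0.71),
    assembly_rate = c(1.4, 1.4, 1.5),
    assembly_duration = c(46, 58, 41),
    disassembly_rate = c(3.06, 1.56, 3.00),
    disassembly_duration = c(27, 53, 24),
    catastrophe_freq = c(0.90, 0.66, 0.78),
    rescue_freq = c(1.5, 0.48, 0.66),
    pause_duration = c(18, 36, 37),
    stringsAsFactors = FALSE
  )
}

#' Summary targets for a reference condition
#'
#' Convenience accessor: the [summary_targets()] of one row of
#' [mt_reference_conditions()], plus its phase speeds.
#'
#' @param condition condition name
#' @return list: `targets` (a [summary_targets()]), `v_g`, `v_s` (um/min)
#' @export
mt_reference_targets <- function(condition = "wild_type") {
  ref <- mt_reference_conditions()
  row <- ref[ref$condition == condition, ]
  if (nrow(row) != 1) {
    stop("unknown condition; see mt_reference_conditions()$condition")
  }
  list(targets = summary_targets(
    catastrophe_freq = row$catastrophe_freq,
    rescue_freq = row$rescue_freq,
    pause_duration = row$pause_duration,
    assembly_duration = row$assembly_duration,
    disassembly_duration = row$disassembly_duration),
    v_g = row$assembly_rate, v_s = row$disassembly_rate)
}

#' Reference steady-state GTP hydrolysis parameters
#'
#' Published Michaelis-Menten parameters of the chaperone GTPase assayed by
#' malachite-green phosphate detection, at 1 uM enzyme: the TBC-DEG
#' chaperone alone and in combination with its TBCC GAP, alpha/beta-tubulin,
#' the GTP-locked Arl2 Q73L mutant, and TBCC active-site mutants (arginine
#' finger R186A; catalytic loop deletion).  `kcat` is per uM enzyme, so
#' numeric values are min^-1 at the 1 uM reference enzyme concentration.
#'
#' @return data.frame: condition, Km_uM, kcat_per_min
#' @export
gtpase_reference_conditions <- function() {
  data.frame(
    condition = c("TBC-DEG",
                  "TBCC:tubulin",
                  "TBC-DEG:tubulin",
                  "TBC-DEG:TBCC",
                  "TBC-DEG:TBCC:tubulin",
                  "TBC-DEG-Q73L:TBCC:tubulin",
                  "TBC-DEG:TBCC-R186A:tubulin",
                  "TBC-DEG:TBCC-dloop:tubulin"),
    Km_uM = c(400, 20, 69, 94, 99, 371, 40, 35),
    kcat_per_min = c(0.06, 0.00, 0.40, 0.77, 1.85, 0.50, 0.53, 0.34),
    stringsAsFactors = FALSE
  )
}

#' Ground truth generator for a reference GTPase condition
#'
#' @param condition condition name from [gtpase_reference_conditions()]
#' @param ... passed to [kinetic_truth()] (noise, grid, seed, ...)
#' @return a [kinetic_truth()]
#' @export
gtpase_reference_truth <- function(condition = "TBC-DEG:TBCC:tubulin", ...) {
  ref <- gtpase_reference_conditions()
  row <- ref[ref$condition == condition, ]
  if (nrow(row) != 1) {
    stop("unknown condition; see gtpase_reference_conditions()$condition")
  }
  kinetic_truth(Km = row$Km_uM, kcat = row$kcat_per_min, ...)
}
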