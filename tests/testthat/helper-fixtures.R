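# fixture builders shared across test files; everything is generated in code

# Noiseless piecewise-linear trace from a phase plan.
# plan: data.frame(kind = "growth"|"shrink"|"pause", n_int = intervals,
#                  rate = um/min signed)
# Returns the trace plus the ground-truth phase boundaries (sample indices).
make_piecewise_trace <- function(plan, dt = 4, l0 = 1) {
  l <- l0
  lengths <- l0
  bounds <- data.frame(kind = character(0), start = integer(0), end = integer(0))
  idx <- 1L
  for (k in seq_len(nrow(plan))) {
    step <- plan$rate[k] / 60 * dt
    seg <- l + cumsum(rep(step, plan$n_int[k]))
    lengths <- c(lengths, seg)
    bounds <- rbind(bounds, data.frame(kind = plan$kind[k], start = idx,
                                       end = idx + plan$n_int[k]))
    idx <- idx + plan$n_int[k]
    l <- seg[length(seg)]
  }
  stopifnot(all(lengths >= 0))
  tr <- data.frame(cell_id = "c1", mt_id = "m1",
                   time_s = seq(0, by = dt, length.out = length(lengths)),
                   length_um = lengths)
  attr(tr, "bounds") <- bounds
  tr
}

# random super-threshold phase plan for the oracle-equivalence property:
# alternating growth/shrink legs with optional pauses, every leg well above
# the event threshold and every pause long and exactly flat
random_phase_plan <- function(n_phases = 6) {
  kinds <- character(n_phases)
  k <- sample(c("growth", "shrink"), 1)
  for (i in seq_len(n_phases)) {
    kinds[i] <- k
    k <- if (k == "pause") sample(c("growth", "shrink"), 1)
         else sample(c("pause", if (k == "growth") "shrink" else "growth"), 1)
  }
  data.frame(
    kind = kinds,
    n_int = ifelse(kinds == "pause", sample(4:8, n_phases, replace = TRUE),
                   sample(8:15, n_phases, replace = TRUE)),
    rate = vapply(kinds, function(kk) {
      switch(kk, growth = runif(1, 1.2, 3), shrink = -runif(1, 1.2, 3.5),
             pause = 0)
    }, numeric(1))
  )
}

wt_targets <- function() mt_reference_targets("wild_type")
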