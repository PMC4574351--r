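# per-microtubule and per-condition statistics

# segmentation + trace with known content: growth, pause, shrink, pause
fixture_seg <- function() {
  plan <- data.frame(kind = c("growth", "pause", "shrink", "pause"),
                     n_int = c(15, 6, 8, 5),
                     rate = c(2, 0, -3, 0))
  tr <- make_piecewise_trace(plan, dt = 4, l0 = 2)
  list(tr = tr, seg = classify_trace(tr))
}

test_that("frequencies follow the defining ratios exactly", {
  fx <- fixture_seg()
  dyn <- summarize_mt(fx$seg, fx$tr)
  # catastrophe: one growth->(pause)->shrink chain; denominator is
  # assembly + pause time
  expect_equal(dyn$n_catastrophes, 1)
  expect_equal(dyn$n_rescues, 0)
  expect_equal(dyn$t_assembly, 60)
  expect_equal(dyn$t_pause, (6 + 5) * 4)
  expect_equal(dyn$t_disassembly, 32)
  expect_equal(dyn$catastrophe_freq, 1 / ((60 + 44) / 60))
  expect_equal(dyn$rescue_freq, 0)
  expect_equal(dyn$mean_length, mean(fx$tr$length_um))
  # identity holds as stored
  expect_equal(dyn$catastrophe_freq,
               dyn$n_catastrophes / ((dyn$t_assembly + dyn$t_pause) / 60))
})

test_that("three events in 200 s of assembly+pause give 0.9 per minute", {
  # arithmetic of the frequency definition on a hand-built summary
  expect_equal(3 / (200 / 60), 0.9)
})

test_that("a pause-only trace has zero frequencies with positive denominators", {
  tr <- data.frame(time_s = seq(0, by = 4, length.out = 20),
                   length_um = rep(1, 20))
  dyn <- summarize_mt(classify_trace(tr), tr)
  expect_equal(dyn$catastrophe_freq, 0)
  expect_equal(dyn$rescue_freq, 0)
  expect_gt(dyn$t_pause, 0)
  expect_equal(dyn$n_pauses, 1)
})

test_that("condition summary gives mean and SEM with NA dropped per statistic", {
  dyn <- data.frame(cell_id = c("a", "a", "b", "b"), mt_id = 1:4,
                    mean_length = c(1, 2, 1.5, 2.5),
                    assembly_rate = c(1.2, 1.6, NA, 1.4),
                    assembly_duration = c(40, 50, 45, 55),
                    disassembly_rate = c(3, 3.2, 2.8, 3),
                    disassembly_duration = c(25, 30, 20, 25),
                    catastrophe_freq = c(0.8, 1.0, NA, NA),
                    rescue_freq = c(1.4, 1.6, 1.5, NA),
                    pause_duration = c(18, NA, NA, NA))
  cs <- suppressWarnings(summarize_condition(dyn, "demo"))
  st <- cs$stats
  get <- function(s, f) st[[f]][st$statistic == s]
  expect_equal(get("catastrophe_freq", "mean"), 0.9)
  expect_equal(get("catastrophe_freq", "sem"), 0.1)
  expect_equal(get("catastrophe_freq", "n"), 2)
  expect_equal(get("assembly_rate", "n"), 3)
  # single surviving value: SEM undefined for that statistic only
  expect_equal(get("pause_duration", "n"), 1)
  expect_true(is.na(get("pause_duration", "sem")))
  expect_false(is.na(get("rescue_freq", "sem")))
  expect_warning(summarize_condition(dyn, "few-cells"), "cell")
  expect_error(summarize_condition(dyn[0, ], "empty"))
})

test_that("aggregation is permutation invariant", {
  h <- hazards_from_summary(wt_targets()$targets)
  p <- sim_params(v_g = 1.4, v_s = 3.06, hazards = h, l0 = 0.9)
  dyn <- summarize_cohort(simulate_cohort(20, p, seed = 3))
  cs1 <- suppressWarnings(summarize_condition(dyn, "x"))
  cs2 <- suppressWarnings(summarize_condition(dyn[sample(nrow(dyn)), ], "x"))
  expect_equal(cs1$stats$mean, cs2$stats$mean)
  expect_equal(cs1$stats$sem, cs2$stats$sem)
})

test_that("identical cohorts compare as indistinguishable", {
  h <- hazards_from_summary(wt_targets()$targets)
  p <- sim_params(v_g = 1.4, v_s = 3.06, hazards = h, l0 = 0.9)
  dyn <- summarize_cohort(simulate_cohort(10, p, seed = 8))
  cmp <- compare_conditions(dyn, dyn, alpha = 0.05)
  ok <- !is.na(cmp$p_value)
  expect_true(all(cmp$p_value[ok] > 1 - 1e-9))
  expect_false(any(cmp$significant[ok]))
})

test_that("zero-variance cohorts fall back to exact mean comparison", {
  base <- data.frame(cell_id = "a", mt_id = 1:3, mean_length = 1,
                     assembly_rate = 2, assembly_duration = 40,
                     disassembly_rate = 3, disassembly_duration = 25,
                     catastrophe_freq = 0.9, rescue_freq = 1.5,
                     pause_duration = 18)
  other <- base; other$assembly_rate <- 2.5
  w <- capture_warnings(cmp <- compare_conditions(base, other, alpha = 0.05))
  expect_true(any(grepl("zero variance", w)))
  expect_equal(cmp$p_value[cmp$statistic == "assembly_rate"], 0)
  expect_equal(cmp$p_value[cmp$statistic == "mean_length"], 1)
})

test_that("cohorts with distinct rescue frequencies are usually flagged", {
  # power check on the chain-level per-microtubule frequencies (state
  # ledger, free of classification censoring): rescue 1.5 vs 0.66 min^-1,
  # n = 10 per cohort, alpha 0.01
  ledger_freqs <- function(traces) {
    do.call(rbind, lapply(traces, function(tr) {
      st <- attr(tr, "states")
      dur <- st$t1_s - st$t0_s
      n_res <- sum(st$state[-1] == "growth" &
                     st$state[-nrow(st)] %in% c("shrink", "pause"))
      data.frame(rescue_freq = n_res /
                   (sum(dur[st$state %in% c("shrink", "pause")]) / 60))
    }))
  }
  tg_hi <- wt_targets()
  tg_lo <- mt_reference_targets("cin4_Q73L")
  p_hi <- sim_params(v_g = 1.4, v_s = 3.06, l0 = 10, noise_sd = 0,
                     hazards = hazards_from_summary(tg_hi$targets))
  p_lo <- sim_params(v_g = 1.5, v_s = 3.00, l0 = 10, noise_sd = 0,
                     hazards = hazards_from_summary(tg_lo$targets))
  hits <- vapply(1:9, function(r) {
    a <- ledger_freqs(simulate_cohort(10, p_hi, seed = 100 + r))
    b <- ledger_freqs(simulate_cohort(10, p_lo, seed = 200 + r))
    cmp <- compare_conditions(a, b, alpha = 0.01)
    cmp$significant[cmp$statistic == "rescue_freq"]
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
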