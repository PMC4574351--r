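# phase classification of length traces

test_that("a growth leg followed by a shrink leg gives one catastrophe", {
  # 60 s at +1.4 um/min then 30 s at -3.06 um/min, dt = 4, noiseless
  plan <- data.frame(kind = c("growth", "shrink"), n_int = c(15, 7),
                     rate = c(1.4, -3.06))
  tr <- make_piecewise_trace(plan, dt = 4, l0 = 0.2)
  seg <- classify_trace(tr)
  ev <- seg$phases[seg$phases$kind != "undetermined", ]
  expect_equal(ev$kind, c("assembly", "disassembly"))
  expect_equal(ev$net_um[1], 1.4, tolerance = 1e-9)
  expect_equal(ev$rate_um_min[1], 1.4, tolerance = 1e-9)
  expect_equal(ev$rate_um_min[2], -3.06, tolerance = 1e-9)
  expect_equal(seg$transitions$kind, "catastrophe")
  expect_equal(seg$transitions$index, 16)
})

test_that("a constant trace is a single pause with no transitions", {
  tr <- data.frame(time_s = seq(0, by = 4, length.out = 20),
                   length_um = rep(1.2, 20))
  seg <- classify_trace(tr)
  expect_equal(seg$phases$kind, "pause")
  expect_equal(nrow(seg$phases), 1)
  expect_equal(seg$phases$duration_s, 19 * 4)
  expect_equal(nrow(seg$transitions), 0)
})

test_that("sub-threshold zig-zags produce no assembly or disassembly", {
  # legs of 0.3 um net, below the 0.5 um event threshold
  plan <- data.frame(kind = rep(c("growth", "shrink"), 4),
                     n_int = rep(5, 8), rate = rep(c(0.9, -0.9), 4))
  tr <- make_piecewise_trace(plan, dt = 4, l0 = 2)
  seg <- classify_trace(tr)
  expect_false(any(seg$phases$kind %in% c("assembly", "disassembly")))
  expect_equal(nrow(seg$transitions), 0)
})

test_that("non-uniform sampling and too-short traces are rejected", {
  tr <- data.frame(time_s = c(0, 4, 8, 13, 16), length_um = 1:5 / 2)
  expect_error(classify_trace(tr), "non-uniform")
  tr2 <- data.frame(time_s = c(0, 4, 8), length_um = c(1, 2, 3))
  expect_error(classify_trace(tr2), "shorter")
})

test_that("phase durations always tile the trace duration", {
  h <- hazards_from_summary(wt_targets()$targets)
  p <- sim_params(v_g = 1.4, v_s = 3.06, hazards = h, l0 = 0.9)
  traces <- simulate_cohort(50, p, seed = 17)
  for (tr in traces) {
    seg <- classify_trace(tr)
    expect_equal(sum(seg$phases$duration_s), tr$time_s[nrow(tr)] - tr$time_s[1],
                 tolerance = 1e-9)
    # intervals are covered exactly once: consecutive phases share boundaries
    ph <- seg$phases[order(seg$phases$start), ]
    expect_equal(ph$start[1], 1)
    expect_equal(ph$end[nrow(ph)], nrow(tr))
    if (nrow(ph) > 1) {
      expect_true(all(ph$start[-1] == ph$end[-nrow(ph)]))
    }
  }
})

test_that("classification is deterministic", {
  h <- hazards_from_summary(wt_targets()$targets)
  p <- sim_params(v_g = 1.4, v_s = 3.06, hazards = h, l0 = 0.9, seed = 23)
  tr <- simulate_trace(p)
  expect_identical(classify_trace(tr), classify_trace(tr))
})

test_that("raising the net-change threshold never adds events", {
  h <- hazards_from_summary(wt_targets()$targets)
  p <- sim_params(v_g = 1.4, v_s = 3.06, hazards = h, l0 = 0.9)
  traces <- simulate_cohort(20, p, seed = 29)
  for (tr in traces) {
    counts <- vapply(c(0.3, 0.5, 0.8, 1.2), function(th) {
      cfg <- classifier_config(min_net_change = th)
      seg <- classify_trace(tr, cfg)
      sum(seg$phases$kind %in% c("assembly", "disassembly"))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("noiseless super-threshold phase plans are recovered exactly", {
  set.seed(41)
  for (rep in 1:30) {
    plan <- random_phase_plan(sample(3:7, 1))
    tr <- make_piecewise_trace(plan, dt = 4, l0 = 25)
    bounds <- attr(tr, "bounds")
    seg <- classify_trace(tr)
    got <- seg$phases[seg$phases$kind != "undetermined", ]
    want_kind <- c(growth = "assembly", shrink = "disassembly",
                   pause = "pause")[plan$kind]
    expect_equal(got$kind, unname(want_kind))
    # boundaries within one sample of the construction
    expect_true(all(abs(got$start - bounds$start) <= 1))
    expect_true(all(abs(got$end - bounds$end) <= 1))
    # transition counts match the plan exactly
    want_cat <- sum(plan$kind[-1] == "shrink" &
                      plan$kind[-nrow(plan)] %in% c("growth", "pause"))
    want_res <- sum(plan$kind[-1] == "growth" &
                      plan$kind[-nrow(plan)] %in% c("shrink", "pause"))
    expect_equal(sum(seg$transitions$kind == "catastrophe"), want_cat)
    expect_equal(sum(seg$transitions$kind == "rescue"), want_res)
  }
})

test_that("phase tables round-trip through text exactly", {
  plan <- data.frame(kind = c("growth", "pause", "shrink"),
                     n_int = c(10, 6, 8), rate = c(1.7, 0, -2.2))
  tr <- make_piecewise_trace(plan, dt = 4, l0 = 3)
  seg <- classify_trace(tr)
  tab <- phase_table(seg)
  f <- tempfile(fileext = ".tsv")
  mtdynamics:::write_tsv(tab, f)
  back <- mtdynamics:::read_tsv(f)
  expect_equal(nrow(back), nrow(tab))
  for (cl in names(tab)) {
    expect_equal(as.vector(back[[cl]], mode = mode(tab[[cl]])), tab[[cl]])
  }
  expect_equal(sum(tab$duration_s), tr$time_s[nrow(tr)])
})
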