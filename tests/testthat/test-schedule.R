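test_that("zero crossing matches the closed form and a root-finder oracle", {
  expect_equal(first_zero_crossing(38), 1 / 76)
  expect_equal(first_zero_crossing(50), 0.010)
  for (j in c(35, 38, 50, 11.7)) {
    root <- uniroot(function(t) cos(pi * j * t), c(1e-6, 1 / j),
                    tol = 1e-12)$root
    expect_equal(first_zero_crossing(j), root, tolerance = 1e-9)
  }
  expect_error(first_zero_crossing(0), "positive")
  expect_error(first_zero_crossing(-5), "positive")
})

test_that("switch time reproduces the delay-switch arithmetic and limits", {
  expect_equal(switch_time(hsqc_params()), 1 / 76 - 2e-3 - 2e-3)
  expect_equal(switch_time(hnca_params()), 1 / 70 - 20e-6 - 2e-3)
  # margin -> 0, delta_A -> 0 limit approaches the zero crossing itself
  p <- acq_params(35, 0, 2e-3, 1e-6, 38e-3, 64, 1)
  expect_equal(switch_time(p), first_zero_crossing(35) - 1e-6)
  # J too large for the chosen delays
  expect_error(switch_time(acq_params(500, 1e-3, 3e-3, 2e-3, 20e-3, 16, 1)),
               "too large")
})

test_that("ideal weight follows 1/|cos| with delay switch, phase flip, cap", {
  p <- hnca_params()
  w0 <- ideal_weight(0, p)
  expect_equal(w0$ideal_weight, 1, tolerance = 1e-4)
  expect_identical(w0$delta_used, "A")
  expect_identical(w0$phase_sign, 1)

  w9 <- ideal_weight(9e-3, p)
  expect_identical(w9$delta_used, "A")
  expect_equal(w9$ideal_weight, 1 / cos(pi * 35 * (9e-3 + 20e-6)),
               tolerance = 1e-12)
  expect_identical(w9$phase_sign, 1)

  # past the switch: delta_B, effective time 16.3 ms, inverted phase
  w12 <- ideal_weight(12.3e-3, hnca_params(cap = "after-1/J"))
  expect_identical(w12$delta_used, "B")
  expect_equal(w12$t_eff_s, 16.3e-3)
  expect_identical(w12$phase_sign, -1)
  expect_equal(w12$ideal_weight, 1 / abs(cos(pi * 35 * 16.3e-3)),
               tolerance = 1e-12)

  # under the default cap the same row is not boosted
  wcap <- ideal_weight(12.3e-3, p)
  expect_identical(wcap$ideal_weight, 1)
  expect_identical(wcap$phase_sign, -1)
})

test_that("SR schedules satisfy bookkeeping, phase and skip invariants", {
  for (p in list(hnca_params(), hsqc_params(),
                 hnca_params(cap = "after-1/J"),
                 hnca_params(cap = "no-cap"))) {
    s <- build_schedule(p, "sr")
    r <- s$rows
    # uniform strictly increasing grid
    expect_true(all(diff(r$t1_s) > 0))
    expect_equal(diff(r$t1_s), rep(diff(r$t1_s)[1], nrow(r) - 1))
    # bookkeeping identity: base * weight = n * residual, exactly
    expect_equal(p$base_scans * r$ideal_weight, r$n_scans * r$residual,
                 tolerance = 1e-12)
    expect_true(all(r$n_scans >= p$base_scans))
    expect_true(all(r$residual > 0.5 & r$residual < 2))
    # phase sign tracks the cosine
    expect_true(all(r$phase_sign * cos(pi * p$j_hz * r$t_eff_s) >= 0))
    # skip region: A rows stop a margin short of the crossing, B rows
    # clear it by the delay-jump clearance
    zc <- first_zero_crossing(p$j_hz)
    a <- r$delta_used == "A"
    expect_true(all(r$t_eff_s[a] <= zc - p$switch_margin_s + 1e-12))
    b_clear <- 2 * (p$delta_b_s - p$delta_a_s) - p$switch_margin_s
    expect_true(all(r$t_eff_s[!a] >= zc + b_clear - 1e-12))
  }
})

test_that("conventional schedule is the fixed point of the weighting", {
  s <- build_schedule(hnca_params(), "conventional")
  expect_true(all(s$rows$ideal_weight == 1))
  expect_true(all(s$rows$phase_sign == 1))
  expect_true(all(s$rows$delta_used == "A"))
  expect_true(all(s$rows$n_scans == 4L))
  b <- scan_budget(s)
  expect_identical(b$total_scans, 4L * 96L)
  expect_equal(b$mean_scans, 4)
  expect_equal(b$time_ratio, 1)
})

test_that("rounding produces the documented scan counts and residuals", {
  # grid chosen so t1 = 12.2 ms is an increment
  p <- acq_params(35, 10e-6, 2e-3, 2e-3, 38e-3, 191L, 4L)
  s <- build_schedule(p)
  i <- which.min(abs(s$rows$t1_s - 12.2e-3))
  expect_equal(s$rows$t1_s[i], 12.2e-3, tolerance = 1e-9)
  expect_equal(s$rows$ideal_weight[i], 4.43, tolerance = 0.01)
  expect_identical(s$rows$n_scans[i], 18L)
  expect_equal(s$rows$residual[i], 4 * s$rows$ideal_weight[i] / 18,
               tolerance = 1e-12)

  pm <- acq_params(35, 10e-6, 2e-3, 2e-3, 38e-3, 191L, 4L,
                   rounding_mode = "nearest-multiple")
  sm <- build_schedule(pm)
  expect_true(all(sm$rows$n_scans %% 4L == 0L))
  expect_equal(4 * sm$rows$ideal_weight, sm$rows$n_scans * sm$rows$residual,
               tolerance = 1e-12)
})

test_that("HNCA preset scan budget lands near the printed average", {
  b <- scan_budget(build_schedule(sr_preset("hnca-sr")))
  expect_gte(b$mean_scans, 4.5)
  expect_lte(b$mean_scans, 5.5)
  expect_equal(b$time_ratio, b$mean_scans / 4)
})

test_that("no zero crossing inside the grid yields a monotone schedule", {
  # J * t1max < 1/2: the crossing is never reached, no switch occurs
  p <- acq_params(10, 1e-3, 3e-3, 2e-3, 20e-3, 32L, 2L)
  s <- build_schedule(p)
  expect_true(all(s$rows$delta_used == "A"))
  expect_true(all(s$rows$phase_sign == 1))
  expect_true(all(diff(s$rows$ideal_weight) >= 0))
})

test_that("residual correction factors restore the ideal weighting", {
  s <- build_schedule(hnca_params(cap = "after-1/J"))
  f <- residual_correction_vector(s)
  expect_equal(f, s$rows$residual)
  # weight-1 and capped rows need no correction
  expect_true(all(f[s$rows$ideal_weight == 1] == 1))
  # corrected scan count is exactly base * weight
  expect_equal(s$rows$n_scans * f, 4 * s$rows$ideal_weight,
               tolerance = 1e-12)
})

test_that("schedule TSV export is byte-stable and round-trips", {
  s <- build_schedule(acq_params(50, 1e-3, 3e-3, 2e-3, 20e-3, 11L, 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_schedule_tsv(s, path)
  expect_identical(readLines(path), readLines(test_path("golden-schedule.tsv")))
  back <- read_schedule_tsv(path)
  expect_equal(back$t1_s, s$rows$t1_s)
  expect_equal(back$n_scans, s$rows$n_scans)
  expect_identical(attr(back, "params")$j_hz, "50")

  jpath <- withr::local_tempfile(fileext = ".json")
  write_schedule_json(s, jpath)
  obj <- jsonlite::fromJSON(jpath)
  expect_equal(obj$params$j_hz, 50)
  expect_equal(obj$rows$n_scans, s$rows$n_scans)
})
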