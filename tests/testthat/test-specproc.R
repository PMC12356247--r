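test_that("zero input gives a zero spectrum of the documented length", {
  s <- build_schedule(hnca_params(n = 64L), "conventional")
  fid <- simulate_interferogram(spin_group(0, numeric(), 0.1), s)
  fid$values[] <- 0 + 0i
  sp <- process_interferogram(fid)
  expect_equal(length(sp$intensity), 64L * 2L * 2L)
  expect_true(all(sp$intensity == 0))
})

test_that("a pure exponential decay transforms to a Lorentzian of 1/(pi*T2)", {
  # T2 = 31.83 ms -> 10.0 Hz FWHM; long acquisition, no apodization
  p <- acq_params(35, 10e-6, 2e-3, 2e-3, 1.0, 2048L, 1L)
  s <- build_schedule(p, "conventional")
  fid <- simulate_interferogram(spin_group(0, numeric(), 0.03183), s)
  sp <- process_interferogram(fid, processing_params(apodization = "none"))
  expect_equal(measure_fwhm(sp, c(-80, 80)), 10.0, tolerance = 0.02)
})

test_that("spectral integral is invariant under zero filling", {
  s <- build_schedule(hnca_params(n = 64L), "conventional")
  fid <- simulate_interferogram(spin_group(55, 35, 0.1), s)
  integrals <- vapply(c(1L, 2L, 4L), function(zf) {
    sp <- process_interferogram(fid, processing_params(zero_fill_factor = zf))
    sum(sp$intensity) * spectral_bin_hz(sp)
  }, 0)
  expect_equal(integrals[2] / integrals[1], 1, tolerance = 1e-9)
  expect_equal(integrals[3] / integrals[1], 1, tolerance = 1e-9)
})

test_that("truncation merges a doublet that a long acquisition resolves", {
  spn <- spin_group(0, 38, 0.1)
  short <- build_schedule(acq_params(38, 10e-6, 2e-3, 2e-3, 8e-3, 42L, 1L),
                          "conventional")
  sp_short <- process_interferogram(simulate_interferogram(spn, short))
  expect_identical(count_components(sp_short, c(-150, 150), 0.2), 1L)

  long <- build_schedule(acq_params(38, 10e-6, 2e-3, 2e-3, 42e-3, 332L, 1L),
                         "conventional")
  sp_long <- process_interferogram(simulate_interferogram(spn, long))
  expect_identical(count_components(sp_long, c(-120, 120), 0.2), 2L)
  expect_lt(abs(estimate_splitting(sp_long, c(-120, 120)) - 38),
            spectral_bin_hz(sp_long))
})

test_that("FWHM measurement is accurate and symmetric on clean peaks", {
  p <- acq_params(35, 10e-6, 2e-3, 2e-3, 0.5, 1024L, 1L)
  s <- build_schedule(p, "conventional")
  for (off in c(-200, 200)) {
    fid <- simulate_interferogram(spin_group(off, numeric(), 0.03183), s)
    sp <- process_interferogram(fid, processing_params(apodization = "none"))
    expect_equal(measure_fwhm(sp, c(off - 90, off + 90)), 10.0,
                 tolerance = 0.2)
    # the maximum sits within one bin of the true offset
    idx <- which.max(sp$intensity)
    expect_lt(abs(sp$axis_hz[idx] - off), spectral_bin_hz(sp))
  }
  # mirrored peaks give identical widths: processing has no asymmetry
  fidp <- simulate_interferogram(spin_group(200, numeric(), 0.03183), s)
  fidm <- simulate_interferogram(spin_group(-200, numeric(), 0.03183), s)
  spp <- process_interferogram(fidp, processing_params(apodization = "none"))
  spm <- process_interferogram(fidm, processing_params(apodization = "none"))
  expect_equal(measure_fwhm(spp, c(110, 290)), measure_fwhm(spm, c(-290, -110)),
               tolerance = 1e-9)
})

test_that("measure_fwhm rejects windows that do not bracket the half height", {
  p <- acq_params(35, 10e-6, 2e-3, 2e-3, 0.2, 256L, 1L)
  s <- build_schedule(p, "conventional")
  fid <- simulate_interferogram(spin_group(0, numeric(), 0.03183), s)
  sp <- process_interferogram(fid, processing_params(apodization = "none"))
  expect_error(measure_fwhm(sp, c(-4, 4)), "bracketed|maximum")
  expect_error(measure_fwhm(sp, c(500, 600)), "maximum|bracketed")
  expect_error(process_interferogram(fid,
    processing_params(effective_points = 1000L)), "exceeds")
})

test_that("FWHM is non-increasing in the acquisition length", {
  widths <- vapply(c(8e-3, 16e-3, 24e-3, 33e-3), function(tm) {
    n <- max(16L, round(tm / 33e-3 * 128))
    p <- acq_params(38, 1e-3, 3e-3, 2e-3, tm, as.integer(n), 1L)
    s <- build_schedule(p, "conventional")
    fid <- simulate_interferogram(spin_group(0, numeric(), 0.1), s)
    measure_fwhm(process_interferogram(fid), c(-400, 400))
  }, 0)
  expect_true(all(diff(widths) <= 0))
})

test_that("SR removes the scheduled coupling but not a passive one", {
  # Ca with Cb (35 Hz, decoupled) and C' (52 Hz, still active): a doublet
  s <- build_schedule(hnca_params(n = 200L, cap = "after-1/J"))
  fid <- simulate_interferogram(spin_group(0, c(35, 52), 0.1), s)
  sp <- process_interferogram(fid)
  expect_identical(count_components(sp, c(-150, 150), 0.2), 2L)
  expect_equal(estimate_splitting(sp, c(-150, 150)), 52,
               tolerance = 2 * spectral_bin_hz(sp) / 52)
  # fully decoupled singlet for the single-coupling spin
  fid1 <- simulate_interferogram(spin_group(0, 35, 0.1), s)
  sp1 <- process_interferogram(fid1)
  expect_identical(count_components(sp1, c(-100, 100), 0.2), 1L)
})

test_that("an uncoupled spin shows the doublet artifact under SR only", {
  gly <- spin_group(0, numeric(), 0.1)
  s_sr <- build_schedule(sr_preset("hnca-sr"))
  sp_sr <- process_interferogram(simulate_interferogram(gly, s_sr))
  expect_gte(count_components(sp_sr, c(-150, 150), 0.1), 2L)
  s_conv <- build_schedule(sr_preset("hnca-conv"), "conventional")
  sp_conv <- process_interferogram(simulate_interferogram(gly, s_conv))
  expect_identical(count_components(sp_conv, c(-150, 150), 0.1), 1L)
})

test_that("spectrum TSV export writes a calibrated axis", {
  s <- build_schedule(hnca_params(n = 32L), "conventional")
  sp <- process_interferogram(simulate_interferogram(
    spin_group(100, numeric(), 0.1), s))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(sp, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), length(sp$intensity))
  expect_equal(tab$axis_ppm, tab$axis_hz / 176.05, tolerance = 1e-6)
})
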