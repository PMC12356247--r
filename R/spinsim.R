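#' One resonance in the indirect dimension
#'
#' A spin group is a single resonance characterised by its offset from the
#' carrier, the passive scalar couplings that split it, its transverse
#' relaxation time and an amplitude. Couplings may be empty: a glycine
#' \eqn{^{13}C^\alpha} has no \eqn{C^\beta} partner, which is exactly the
#' case that produces the doublet-with-sinc-wiggles artifact under an SR
#' schedule tuned for a coupling it does not have.
#'
#' @param offset_hz chemical-shift offset from the carrier, Hz.
#' @param couplings_hz numeric vector of passive couplings, Hz (may be
#'   empty).
#' @param t2_s transverse relaxation time, seconds (> 0).
#' @param amplitude real amplitude.
#' @param label optional text label.
#' @return An object of class `spin_group`.
#' @examples
#' spin_group(offset_hz = 0, couplings_hz = 35, t2_s = 0.1, label = "Ca")
#' @export
spin_group <- function(offset_hz, couplings_hz = numeric(), t2_s,
                       amplitude = 1, label = "") {
  stopifnot(is.numeric(offset_hz), length(offset_hz) == 1L,
            is.numeric(couplings_hz), is.numeric(amplitude),
            length(amplitude) == 1L)
  if (!is.numeric(t2_s) || length(t2_s) != 1L || t2_s <= 0)
    stop("`t2_s` must be a single positive number", call. = FALSE)
  structure(list(offset_hz = offset_hz, couplings_hz = couplings_hz,
                 t2_s = t2_s, amplitude = amplitude, label = label),
            class = "spin_group")
}

# run expr with a temporarily seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.as_spin_list <- function(spins) {
  if (inherits(spins, "spin_group")) list(spins)
  else if (is.list(spins) && all(vapply(spins, inherits, TRUE, "spin_group")))
    spins
  else stop("`spins` must be a spin_group or a list of spin_group objects",
            call. = FALSE)
}

# noiseless accumulated signal of one spin on a schedule with given scan
# counts: chemical shift evolves during t1 only, couplings during t_eff
.spin_signal <- function(spin, rows) {
  coup <- rep(1, nrow(rows))
  for (j in spin$couplings_hz) coup <- coup * cos(pi * j * rows$t_eff_s)
  spin$amplitude * exp(2i * pi * spin$offset_hz * rows$t1_s) * coup *
    exp(-rows$t1_s / spin$t2_s)
}

#' Simulate the indirect-dimension interferogram
#'
#' Accumulates, per increment, `n_scans` scans of every spin with the
#' schedule's phase sign applied, i.e.
#' \deqn{v_i = n_i s_i \sum_k a_k e^{2\pi i \Omega_k t_{1,i}}
#'       \prod_J \cos(\pi J t_{eff,i}) e^{-t_{1,i}/T_{2,k}} + \epsilon_i,}
#' where the chemical shift \eqn{\Omega} evolves during \eqn{t_1} only while
#' couplings evolve during the effective time \eqn{t_{eff}} (they are active
#' during the delay element as well). Noise \eqn{\epsilon_i} is complex
#' Gaussian with per-component standard deviation
#' \eqn{\sigma\sqrt{n_i}}, statistically identical to summing \eqn{n_i}
#' independent per-scan draws; set `per_scan = TRUE` to do the literal sum.
#'
#' @param spins a [spin_group()] or list of them.
#' @param schedule an `sr_schedule` from [build_schedule()].
#' @param noise_sigma per-scan noise standard deviation (>= 0).
#' @param seed optional integer seed; runs are bit-reproducible under it.
#' @param per_scan if `TRUE`, draw noise scan by scan instead of using the
#'   \eqn{\sigma\sqrt{n}} shortcut.
#' @return An object of class `interferogram`: list with `values` (complex,
#'   one per increment), `schedule`, `noise_sigma`, `seed`.
#' @examples
#' sched <- build_schedule(sr_preset("hnca-sr"))
#' fid <- simulate_interferogram(spin_group(0, 35, 0.1), sched)
#' @export
simulate_interferogram <- function(spins, schedule, noise_sigma = 0,
                                   seed = NULL, per_scan = FALSE) {
  stopifnot(inherits(schedule, "sr_schedule"))
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  spins <- .as_spin_list(spins)
  rows <- schedule$rows
  vals <- rep(0 + 0i, nrow(rows))
  for (sp in spins) vals <- vals + .spin_signal(sp, rows)
  vals <- vals * rows$n_scans * rows$phase_sign
  if (noise_sigma > 0) {
    vals <- vals + .with_seed(seed, {
      if (per_scan) {
        vapply(rows$n_scans, function(ns)
          sum(stats::rnorm(ns, 0, noise_sigma)), 0) +
          1i * vapply(rows$n_scans, function(ns)
            sum(stats::rnorm(ns, 0, noise_sigma)), 0)
      } else {
        sdv <- noise_sigma * sqrt(rows$n_scans)
        stats::rnorm(nrow(rows), 0, sdv) + 1i * stats::rnorm(nrow(rows), 0, sdv)
      }
    })
  }
  structure(list(values = vals, schedule = schedule,
                 noise_sigma = noise_sigma, seed = seed),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d increments, %s schedule, sigma = %g\n",
              length(x$values), x$schedule$mode, x$noise_sigma))
  invisible(x)
}

#' Constant-scan acquisition with post hoc 1/cos window multiplication
#'
#' The alternative to scan weighting: acquire every increment with
#' `base_scans` scans on the same skip-aware delay grid and multiply the
#' recorded points by the window \eqn{1/\cos(\pi J t_{eff})} afterwards. At
#' zero noise this equals the SR acquisition after residual correction, but
#' the window multiplies the noise as well, so the pointwise noise standard
#' deviation is worse than SR by \eqn{\sqrt{weight}} — SR buys back half the
#' sensitivity the window costs.
#'
#' @inheritParams simulate_interferogram
#' @param params an [acq_params()] object; the SR delay pattern is derived
#'   from it so the window is never evaluated at a singularity. If any grid
#'   point still lands within 1e-6 of a cosine zero, an error instructs use
#'   of a skip-aware grid.
#' @return An `interferogram` whose values carry the window.
#' @export
simulate_windowed_reference <- function(spins, params, noise_sigma = 0,
                                        seed = NULL) {
  stopifnot(inherits(params, "sr_acq_params"))
  sched <- build_schedule(params, "sr")
  rows <- sched$rows
  cosv <- cos(pi * params$j_hz * rows$t_eff_s)
  if (any(abs(cosv) < 1e-6))
    stop("1/cos window is singular on this grid; use a skip-aware grid ",
         "(delta switch) so no t_eff falls on a cosine zero", call. = FALSE)
  spins <- .as_spin_list(spins)
  vals <- rep(0 + 0i, nrow(rows))
  for (sp in spins) vals <- vals + .spin_signal(sp, rows)
  vals <- vals * params$base_scans
  if (noise_sigma > 0) {
    sdv <- noise_sigma * sqrt(params$base_scans)
    vals <- vals + .with_seed(seed,
      stats::rnorm(nrow(rows), 0, sdv) + 1i * stats::rnorm(nrow(rows), 0, sdv))
  }
  vals <- vals / cosv
  const <- sched
  const$rows$n_scans <- params$base_scans
  const$rows$phase_sign <- 1
  const$rows$ideal_weight <- 1
  const$rows$residual <- 1
  const$mode <- "conventional"
  structure(list(values = vals, schedule = const, noise_sigma = noise_sigma,
                 seed = seed, windowed = TRUE),
            class = "interferogram")
}

#' Simulate a 2D strip (indirect x direct)
#'
#' Outer product of each spin's indirect-dimension interferogram with a
#' decaying complex exponential in the (always conventionally acquired)
#' direct dimension; renders strip-plot style data.
#'
#' @param spins2d list of entries `list(spin = spin_group,
#'   direct_offset_hz =, direct_t2_s =)`.
#' @param schedule indirect-dimension `sr_schedule`.
#' @param direct list with `n_points` and `sw_hz` for the direct dimension.
#' @inheritParams simulate_interferogram
#' @return Complex matrix with `nrow(schedule$rows)` rows (indirect) and
#'   `direct$n_points` columns, with attribute `"direct_dwell_s"`.
#' @export
simulate_strip <- function(spins2d, schedule, direct, noise_sigma = 0,
                           seed = NULL) {
  stopifnot(inherits(schedule, "sr_schedule"),
            is.list(direct), !is.null(direct$n_points), !is.null(direct$sw_hz))
  dt2 <- 1 / direct$sw_hz
  t2 <- (seq_len(direct$n_points) - 1) * dt2
  out <- matrix(0 + 0i, nrow(schedule$rows), direct$n_points)
  for (entry in spins2d) {
    ind <- simulate_interferogram(entry$spin, schedule)$values
    dir <- exp(2i * pi * entry$direct_offset_hz * t2 - t2 / entry$direct_t2_s)
    out <- out + outer(ind, dir)
  }
  if (noise_sigma > 0) {
    ns <- sqrt(schedule$rows$n_scans)
    out <- out + .with_seed(seed, {
      matrix(stats::rnorm(length(out), 0, noise_sigma * ns), nrow(out)) +
        1i * matrix(stats::rnorm(length(out), 0, noise_sigma * ns), nrow(out))
    })
  }
  attr(out, "direct_dwell_s") <- dt2
  out
}
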