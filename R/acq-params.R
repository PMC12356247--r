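#' Acquisition parameters for one indirect-dimension experiment
#'
#' Bundles everything that defines a single acquisition of the indirect
#' \eqn{^{13}}C dimension, either conventional (fixed scan count) or
#' super-resolution (SR, scan-weighted pseudo-decoupling): the homonuclear
#' coupling to be decoupled, the two selectable pulse-sequence delays
#' \eqn{\delta_A} (short) and \eqn{\delta_B} (long), the half-width of the
#' evolution-time window skipped around the cosine zero crossing, the maximal
#' evolution time, the number of complex increments, and the scan count of
#' the conventional reference.
#'
#' The coupling evolves during the effective time
#' \eqn{t_{eff} = t_1 + 2\delta}, so switching from \eqn{\delta_A} to
#' \eqn{\delta_B} jumps \eqn{t_{eff}} across the zero crossing of
#' \eqn{\cos(\pi J t_{eff})} without removing any point from the uniform
#' \eqn{t_1} grid.
#'
#' @param j_hz scalar coupling constant to pseudo-decouple, Hz.
#' @param delta_a_s short delay \eqn{\delta_A}, seconds.
#' @param delta_b_s long delay \eqn{\delta_B}, seconds; must exceed
#'   `delta_a_s`.
#' @param switch_margin_s half-width of the skipped effective-time window on
#'   the near side of the zero crossing, seconds (default 2 ms).
#' @param t1_max_s maximal evolution time, seconds.
#' @param n_increments number of complex points in the indirect dimension.
#' @param base_scans integer scans per increment of the conventional
#'   reference.
#' @param rounding_mode `"nearest-integer"` rounds `base_scans * weight` to
#'   the nearest integer (floored at `base_scans`); `"nearest-multiple"`
#'   rounds the weight itself and multiplies by `base_scans`, so every scan
#'   count is a full phase cycle.
#' @param boost_cap where the scan boost stops: `"after-zero-crossing"`
#'   (default; scans are not increased once \eqn{t_{eff}} has passed
#'   \eqn{1/(2J)}, letting the signal decay naturally), `"after-1/J"`
#'   (boosting continues through the inverted lobe up to
#'   \eqn{t_{eff} = 1/J}), or `"no-cap"`.
#' @param metadata optional named list carried through to schedule exports
#'   (e.g. phase-cycle tables, transfer delays); never used in computation.
#'
#' @return An object of class `sr_acq_params`.
#' @seealso [sr_preset()] for ready-made parameter sets, [build_schedule()].
#' @examples
#' p <- acq_params(j_hz = 35, delta_a_s = 10e-6, delta_b_s = 2e-3,
#'                 t1_max_s = 38e-3, n_increments = 200, base_scans = 4)
#' switch_time(p) * 1e3  # ms
#' @export
acq_params <- function(j_hz, delta_a_s, delta_b_s, switch_margin_s = 2e-3,
                       t1_max_s, n_increments, base_scans = 1L,
                       rounding_mode = c("nearest-integer", "nearest-multiple"),
                       boost_cap = c("after-zero-crossing", "after-1/J",
                                     "no-cap"),
                       metadata = list()) {
  rounding_mode <- match.arg(rounding_mode)
  boost_cap <- match.arg(boost_cap)
  if (!is.numeric(j_hz) || length(j_hz) != 1L || !is.finite(j_hz) || j_hz <= 0)
    stop("`j_hz` must be a single positive number", call. = FALSE)
  if (delta_a_s < 0 || delta_b_s <= delta_a_s)
    stop("delays must satisfy 0 <= delta_a_s < delta_b_s", call. = FALSE)
  if (switch_margin_s <= 0)
    stop("`switch_margin_s` must be > 0", call. = FALSE)
  if (t1_max_s <= 0)
    stop("`t1_max_s` must be > 0", call. = FALSE)
  n_increments <- as.integer(n_increments)
  base_scans <- as.integer(base_scans)
  if (is.na(n_increments) || n_increments < 2L)
    stop("`n_increments` must be >= 2", call. = FALSE)
  if (is.na(base_scans) || base_scans < 1L)
    stop("`base_scans` must be >= 1", call. = FALSE)
  # clearance of t_eff past the zero crossing once delta_B is in use
  b_clearance <- 2 * (delta_b_s - delta_a_s) - switch_margin_s
  if (b_clearance <= 0)
    stop("2*(delta_b_s - delta_a_s) must exceed `switch_margin_s`: ",
         "the delay jump would land t_eff on the zero crossing", call. = FALSE)
  structure(
    list(j_hz = j_hz, delta_a_s = delta_a_s, delta_b_s = delta_b_s,
         switch_margin_s = switch_margin_s, t1_max_s = t1_max_s,
         n_increments = n_increments, base_scans = base_scans,
         rounding_mode = rounding_mode, boost_cap = boost_cap,
         metadata = metadata),
    class = "sr_acq_params")
}

#' @export
print.sr_acq_params <- function(x, ...) {
  cat("<sr_acq_params>\n")
  cat(sprintf("  J = %g Hz, delta_A = %g us, delta_B = %g us, margin = %g ms\n",
              x$j_hz, x$delta_a_s * 1e6, x$delta_b_s * 1e6,
              x$switch_margin_s * 1e3))
  cat(sprintf("  t1max = %g ms, %d increments, base scans = %d\n",
              x$t1_max_s * 1e3, x$n_increments, x$base_scans))
  cat(sprintf("  rounding = %s, boost cap = %s\n",
              x$rounding_mode, x$boost_cap))
  invisible(x)
}

#' Built-in experiment presets
#'
#' Parameter sets for the two experiments the method was designed around,
#' plus the short conventional references they are compared with:
#'
#' \describe{
#'   \item{`"hsqc-sr"`}{methyl \eqn{[^{13}C,^1H]}-HSQC pseudo-decoupling the
#'     38 Hz \eqn{^1J_{CC}} coupling; \eqn{\delta_A} = 1 ms,
#'     \eqn{\delta_B} = 3 ms, t1max = 33 ms.}
#'   \item{`"hnca-sr"`}{TROSY-HNCA decoupling the 35 Hz
#'     \eqn{^1J_{C\alpha C\beta}} coupling; \eqn{\delta_A} = 10 us,
#'     \eqn{\delta_B} = 2 ms, t1max = 38 ms.}
#'   \item{`"hsqc-conv"`, `"hnca-conv"`}{conventional references with the
#'     coupling-limited t1max of 8 ms.}
#' }
#'
#' Increment counts give the same dwell time within each pair; transfer
#' delays and phase-cycle tables of the source pulse sequences are carried as
#' metadata only.
#'
#' @param name preset name.
#' @return An `sr_acq_params` object.
#' @examples
#' sr_preset("hnca-sr")
#' @export
sr_preset <- function(name = c("hsqc-sr", "hsqc-conv", "hnca-sr",
                               "hnca-conv")) {
  name <- match.arg(name)
  hsqc_meta <- list(
    transfer_delays_s = c(tau = 1.7e-3, tau1 = 0.86e-3),
    phase_cycle = list(phi1 = c("x", "x", "-x", "-x"),
                       phiA = c("x", "-x"), phiB = c("-x", "x"),
                       phi2 = c("x", "x", "-x", "-x"),
                       phi3 = c("y", "y", "-y", "-y"),
                       phirec = c("x", "-x", "-x", "x")))
  hnca_meta <- list(
    transfer_delays_s = c(tau = 2.3e-3, tau1 = 12e-3, T = 24e-3),
    phase_cycle = list(phiA = c("x", "x", "x", "x"),
                       phiB = c("-x", "-x", "-x", "-x"),
                       phi1 = c("-x", "x", "y", "-y"),
                       phi2 = c("-x", "x", "-y", "y"),
                       phirec = c("y", "-y", "-x", "x")))
  switch(name,
    "hsqc-sr" = acq_params(38, 1e-3, 3e-3, 2e-3, 33e-3, 256L, 4L,
                           metadata = hsqc_meta),
    "hsqc-conv" = acq_params(38, 1e-3, 3e-3, 2e-3, 8e-3, 62L, 4L,
                             metadata = hsqc_meta),
    "hnca-sr" = acq_params(35, 10e-6, 2e-3, 2e-3, 38e-3, 200L, 4L,
                           metadata = hnca_meta),
    "hnca-conv" = acq_params(35, 10e-6, 2e-3, 2e-3, 8e-3, 42L, 4L,
                             metadata = hnca_meta))
}
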