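#' First zero crossing of the coupling cosine
#'
#' The accumulated signal of a doublet evolves as \eqn{\cos(\pi J t_{eff})};
#' its first zero lies at \eqn{t_{eff} = 1/(2J)}. Scan weighting diverges
#' there, which is why a window around it is skipped by switching delays.
#'
#' @param j_hz coupling constant, Hz.
#' @return First zero crossing in effective time, seconds.
#' @examples
#' first_zero_crossing(38) * 1e3  # 13.16 ms
#' @export
first_zero_crossing <- function(j_hz) {
  if (!is.numeric(j_hz) || any(!is.finite(j_hz)) || any(j_hz <= 0))
    stop("`j_hz` must be positive and finite", call. = FALSE)
  1 / (2 * j_hz)
}

#' Evolution time at which the schedule switches delay and phase
#'
#' Returns the smallest \eqn{t_1} from which \eqn{\delta_B} (and the flipped
#' receiver-side phase) is used:
#' \eqn{t_1^{switch} = 1/(2J) - 2\delta_A - m}, where \eqn{m} is the skip
#' margin. Below the switch, \eqn{t_{eff} = t_1 + 2\delta_A} stays at least
#' \eqn{m} short of the zero crossing; at and above it,
#' \eqn{t_{eff} = t_1 + 2\delta_B} clears the crossing by at least
#' \eqn{2(\delta_B-\delta_A) - m > 0}.
#'
#' @param params an [acq_params()] object.
#' @return Switch evolution time, seconds.
#' @examples
#' switch_time(sr_preset("hnca-sr")) * 1e3  # 12.27 ms
#' @export
switch_time <- function(params) {
  stopifnot(inherits(params, "sr_acq_params"))
  st <- first_zero_crossing(params$j_hz) - 2 * params$delta_a_s -
    params$switch_margin_s
  if (st <= 0)
    stop("switch time is not positive: J = ", params$j_hz,
         " Hz is too large for the chosen delta_A/margin", call. = FALSE)
  st
}

#' Ideal scan weight, phase sign and delay choice at given evolution times
#'
#' Evaluates the dynamic-weighting rule at one or more evolution times:
#' the delay is \eqn{\delta_A} below [switch_time()] and \eqn{\delta_B} at or
#' above it; the ideal (real-valued) weight is
#' \eqn{1/|\cos(\pi J t_{eff})|}, set to 1 wherever the boost cap applies;
#' the phase sign is \eqn{sign(\cos(\pi J t_{eff}))}, so that flipping the
#' pulse phase past the zero crossing neutralises the coupling sign change.
#'
#' @param t1_s evolution time(s), seconds, within `[0, t1_max_s]`.
#' @param params an [acq_params()] object.
#' @return A data frame with columns `t1_s`, `delta_used` (`"A"`/`"B"`),
#'   `t_eff_s`, `ideal_weight`, `phase_sign`.
#' @examples
#' ideal_weight(c(0, 9e-3, 12.3e-3), sr_preset("hnca-sr"))
#' @export
ideal_weight <- function(t1_s, params) {
  stopifnot(inherits(params, "sr_acq_params"))
  if (any(t1_s < 0 | t1_s > params$t1_max_s + 1e-12))
    stop("`t1_s` must lie in [0, t1_max_s]", call. = FALSE)
  st <- switch_time(params)
  use_b <- t1_s >= st - 1e-12
  t_eff <- t1_s + 2 * ifelse(use_b, params$delta_b_s, params$delta_a_s)
  .assert_clear_of_crossing(t_eff, use_b, params)
  cosv <- cos(pi * params$j_hz * t_eff)
  w <- 1 / abs(cosv)
  zc <- first_zero_crossing(params$j_hz)
  capped <- switch(params$boost_cap,
    "after-zero-crossing" = t_eff > zc,
    "after-1/J" = t_eff > 1 / params$j_hz,
    "no-cap" = rep(FALSE, length(t_eff)))
  w[capped] <- 1
  sing <- which(!capped & abs(cosv) < 1e-6)
  if (length(sing))
    stop("uncapped weight is singular (|cos| < 1e-6) at increment(s) ",
         paste(sing, collapse = ", "),
         ": a later zero crossing falls on the grid; cap the boost or ",
         "shorten t1_max_s", call. = FALSE)
  data.frame(t1_s = t1_s,
             delta_used = ifelse(use_b, "B", "A"),
             t_eff_s = t_eff,
             ideal_weight = w,
             phase_sign = ifelse(cosv >= 0, 1, -1))
}

# Skip-region invariant: t_eff keeps clear of the first zero crossing.
# A-side rows must stay >= margin short of it; B-side rows clear it by
# >= 2*(deltaB-deltaA) - margin (20 us less than the margin for the HNCA
# parameters, where the delay jump is marginally shorter than 2 margins).
.assert_clear_of_crossing <- function(t_eff, use_b, params) {
  zc <- first_zero_crossing(params$j_hz)
  m <- params$switch_margin_s
  b_clear <- 2 * (params$delta_b_s - params$delta_a_s) - m
  eps <- 1e-12
  bad_a <- !use_b & (t_eff > zc - m + eps)
  bad_b <- use_b & (t_eff < zc + b_clear - eps)
  bad <- which(bad_a | bad_b)
  if (length(bad))
    stop("t_eff falls inside the skipped window around the cosine zero ",
         "crossing at increment(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Build a per-increment acquisition schedule
#'
#' Lays a uniform grid of `n_increments` evolution times on
#' `[0, t1_max_s]` and, in SR mode, attaches to each increment the delay
#' choice, effective time, phase sign, ideal weight, integer scan count and
#' rounding residual. The conventional mode is the fixed point of the method:
#' every weight is 1, the phase never flips, and \eqn{\delta_A} is used
#' throughout.
#'
#' The integer scan count is `max(base_scans, round(base_scans * weight))`
#' under the default rounding mode, or `base_scans * max(1, round(weight))`
#' under `"nearest-multiple"`; the residual `base_scans * weight / n_scans`
#' records the mismatch corrected later in processing (see
#' [residual_correction_vector()]).
#'
#' @param params an [acq_params()] object.
#' @param mode `"sr"` or `"conventional"`.
#' @return An object of class `sr_schedule`: a list with elements `params`,
#'   `mode` and `rows` (data frame with columns `index`, `t1_s`,
#'   `delta_used`, `t_eff_s`, `phase_sign`, `ideal_weight`, `n_scans`,
#'   `residual`).
#' @examples
#' sched <- build_schedule(sr_preset("hnca-sr"))
#' scan_budget(sched)
#' @export
build_schedule <- function(params, mode = c("sr", "conventional")) {
  stopifnot(inherits(params, "sr_acq_params"))
  mode <- match.arg(mode)
  t1 <- seq(0, params$t1_max_s, length.out = params$n_increments)
  if (mode == "conventional") {
    rows <- data.frame(index = seq_along(t1), t1_s = t1, delta_used = "A",
                       t_eff_s = t1 + 2 * params$delta_a_s, phase_sign = 1,
                       ideal_weight = 1, n_scans = params$base_scans,
                       residual = 1)
  } else {
    iw <- ideal_weight(t1, params)
    n_scans <- switch(params$rounding_mode,
      "nearest-integer" = pmax(params$base_scans,
                               round(params$base_scans * iw$ideal_weight)),
      "nearest-multiple" = params$base_scans * pmax(1, round(iw$ideal_weight)))
    residual <- params$base_scans * iw$ideal_weight / n_scans
    bad <- which(residual <= 0.5 | residual >= 2)
    if (length(bad))
      stop("rounding residual outside (0.5, 2) at increment(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    rows <- data.frame(index = seq_along(t1), t1_s = t1,
                       delta_used = iw$delta_used, t_eff_s = iw$t_eff_s,
                       phase_sign = iw$phase_sign,
                       ideal_weight = iw$ideal_weight,
                       n_scans = as.integer(n_scans), residual = residual)
  }
  structure(list(params = params, mode = mode, rows = rows),
            class = "sr_schedule")
}

#' @export
print.sr_schedule <- function(x, ...) {
  b <- scan_budget(x)
  cat(sprintf("<sr_schedule> %s, J = %g Hz, %d increments, t1max = %g ms\n",
              x$mode, x$params$j_hz, nrow(x$rows), x$params$t1_max_s * 1e3))
  cat(sprintf("  scans: total %d, mean %.2f/increment, %.2fx conventional\n",
              b$total_scans, b$mean_scans, b$time_ratio))
  invisible(x)
}

#' Scan budget of a schedule
#'
#' Totals the integer scan counts and reports the experimental-time cost of
#' the SR weighting relative to a conventional acquisition with the same
#' increment count.
#'
#' @param schedule an `sr_schedule`.
#' @return A list with `total_scans`, `mean_scans` and `time_ratio`
#'   (total scans divided by `base_scans * n_increments`).
#' @export
scan_budget <- function(schedule) {
  stopifnot(inherits(schedule, "sr_schedule"), nrow(schedule$rows) > 0)
  total <- sum(schedule$rows$n_scans)
  list(total_scans = as.integer(total),
       mean_scans = total / nrow(schedule$rows),
       time_ratio = total /
         (schedule$params$base_scans * nrow(schedule$rows)))
}

#' Per-increment residual correction factors
#'
#' The integer scan count cannot follow the real-valued weight exactly; the
#' multiplicative factor `base_scans * ideal_weight / n_scans` per increment
#' restores, when applied to the accumulated noiseless signal of the coupled
#' spin, a smooth exponential envelope wherever the boost is active
#' (it is exactly 1 on capped and conventional rows).
#'
#' @param schedule an `sr_schedule`.
#' @return Numeric vector of factors, one per increment.
#' @export
residual_correction_vector <- function(schedule) {
  stopifnot(inherits(schedule, "sr_schedule"))
  schedule$rows$residual
}
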