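#' Fire surface forcing parameters
#'
#' Describes the prescribed surface temperature history driving a burn:
#' a linear ramp from the basal temperature to the maximum, a hold at the
#' maximum (the torch dwell), and an exponential decay back toward basal.
#' The defaults reproduce a torch burn that takes 600 s to reach its
#' maximum, dwells there for 60 s, and cools over 1800 s; the two severity
#' treatments use maxima of 450 degC (low) and 600 degC (high).
#'
#' @param t_max Maximum surface temperature, degC.
#' @param t_basal Basal (ambient) temperature, degC. Default 20.
#' @param t_ramp Ramp duration, s. Default 600.
#' @param t_hold Hold duration at `t_max`, s. Default 60.
#' @param t_decay Decay duration, s. Default 1800.
#' @param dt Sampling interval, s. Default 1.
#' @return An object of class `fire_forcing_params`.
#' @examples
#' fire_forcing_params(600)
#' @export
fire_forcing_params <- function(t_max, t_basal = 20, t_ramp = 600,
                                t_hold = 60, t_decay = 1800, dt = 1) {
  for (f in c("t_max", "t_basal", "t_ramp", "t_hold", "t_decay", "dt")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_param(f, "must be a single finite number")
    }
  }
  if (t_max < t_basal) stop_param("t_max", "must be >= t_basal")
  if (t_ramp < 0) stop_param("t_ramp", "must be >= 0")
  if (t_hold < 0) stop_param("t_hold", "must be >= 0")
  if (t_decay < 0) stop_param("t_decay", "must be >= 0")
  if (dt <= 0) stop_param("dt", "must be > 0")
  structure(
    list(t_max = t_max, t_basal = t_basal, t_ramp = t_ramp,
         t_hold = t_hold, t_decay = t_decay, dt = dt),
    class = "fire_forcing_params"
  )
}

#' @export
print.fire_forcing_params <- function(x, ...) {
  cat(sprintf(
    "<fire_forcing_params> basal %g degC -> max %g degC; ramp %g s, hold %g s, decay %g s (dt %g s)\n",
    x$t_basal, x$t_max, x$t_ramp, x$t_hold, x$t_decay, x$dt))
  invisible(x)
}

#' Build the ramp-hold-decay surface forcing curve
#'
#' Constructs the right-skewed surface temperature time series used as the
#' top boundary condition of the heat simulation. The curve rises linearly
#' from `t_basal` to `t_max` over `t_ramp` seconds, holds at `t_max` for
#' `t_hold` seconds, then decays exponentially,
#' `T(t) = T_basal + (T_max - T_basal) * exp(-k (t - t_ramp - t_hold))`
#' with `k = log(100) / t_decay`, so the residual above basal is exactly 1%
#' of the rise at the end of the decay. With the default phases the decay is
#' three times longer than the ramp, giving the right skew typical of a
#' surface fire temperature pulse.
#'
#' Samples are placed every `dt` seconds starting at 0; if a phase boundary
#' is not a multiple of `dt` it is inserted, so the curve attains `t_max`
#' exactly at `t_ramp` and holds it through `t_ramp + t_hold`.
#'
#' @param params A [fire_forcing_params()] object.
#' @param extend_to Optional time, s. If beyond the forcing duration, the
#'   curve is extended by clamping to its final value.
#' @return An object of class `forcing_curve`: list with `times` (s),
#'   `temps` (degC) and `params`.
#' @examples
#' fc <- build_forcing_curve(fire_forcing_params(600))
#' range(fc$temps)
#' @export
build_forcing_curve <- function(params, extend_to = NULL) {
  stopifnot(inherits(params, "fire_forcing_params"))
  p <- params
  total <- p$t_ramp + p$t_hold + p$t_decay
  times <- seq(0, total, by = p$dt)
  boundaries <- c(p$t_ramp, p$t_ramp + p$t_hold, total)
  times <- sort(unique(c(times, boundaries[boundaries <= total])))
  if (!is.null(extend_to) && extend_to > total) {
    extra <- seq(total, extend_to, by = p$dt)[-1]
    times <- c(times, extra, if (max(extra) < extend_to) extend_to)
    times <- sort(unique(times))
  }
  temps <- forcing_at(p, times)
  structure(list(times = times, temps = temps, params = p),
            class = "forcing_curve")
}

# Evaluate the piecewise forcing law at arbitrary times (clamped past the
# end of the decay to its final value).
forcing_at <- function(p, t) {
  total <- p$t_ramp + p$t_hold + p$t_decay
  rise <- p$t_max - p$t_basal
  t_eff <- pmin(t, total)
  out <- numeric(length(t))
  in_ramp <- t_eff < p$t_ramp
  in_hold <- !in_ramp & t_eff <= p$t_ramp + p$t_hold
  in_decay <- !in_ramp & !in_hold
  if (p$t_ramp > 0) {
    out[in_ramp] <- p$t_basal + rise * (t_eff[in_ramp] / p$t_ramp)
  } else {
    out[in_ramp] <- p$t_max
  }
  out[in_hold] <- p$t_max
  if (any(in_decay)) {
    if (p$t_decay > 0) {
      k <- log(100) / p$t_decay
      out[in_decay] <- p$t_basal +
        rise * exp(-k * (t_eff[in_decay] - p$t_ramp - p$t_hold))
    } else {
      out[in_decay] <- p$t_basal
    }
  }
  out
}

#' @export
print.forcing_curve <- function(x, ...) {
  cat(sprintf("<forcing_curve> %d samples over %g s; %g..%g degC\n",
              length(x$times), max(x$times), min(x$temps), max(x$temps)))
  invisible(x)
}

#' @export
as.data.frame.forcing_curve <- function(x, ...) {
  data.frame(time_s = x$times, temp_C = x$temps)
}

#' Write a forcing curve to CSV
#'
#' Two columns, `time_s,temp_C`, one row per sample.
#'
#' @param curve A `forcing_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forcing_csv <- function(curve, path) {
  stopifnot(inherits(curve, "forcing_curve"))
  readr::write_csv(tibble::tibble(time_s = curve$times, temp_C = curve$temps),
                   path)
  invisible(path)
}
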