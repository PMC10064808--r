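#' Exposure analysis configuration
#'
#' @param window Averaging window from the start of the burn, s. Default
#'   1800 (the first 30 min, covering ramp-up and early cooling).
#' @param thresholds Temperatures (degC, ascending) for time-above and
#'   degree-seconds-above metrics. Default `c(50, 60, 100)`.
#' @param lethal_peak_threshold Peak temperature (degC) at or above which a
#'   depth bin is classified as within the heat mortality zone. Default 100.
#' @return An object of class `exposure_config`.
#' @export
exposure_config <- function(window = 1800, thresholds = c(50, 60, 100),
                            lethal_peak_threshold = 100) {
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop_param("window", "must be > 0")
  }
  if (!is.numeric(thresholds) || is.unsorted(thresholds, strictly = TRUE)) {
    stop_param("thresholds", "must be ascending temperatures")
  }
  if (!is.numeric(lethal_peak_threshold) || lethal_peak_threshold <= 0) {
    stop_param("lethal_peak_threshold", "must be > 0")
  }
  structure(list(window = window, thresholds = thresholds,
                 lethal_peak_threshold = lethal_peak_threshold),
            class = "exposure_config")
}

#' Per-depth heat-exposure summary
#'
#' Reduces a simulated temperature field to per-depth metrics: peak
#' temperature and its time, mean temperature over the analysis window, and
#' time (and degree-seconds) spent at or above each threshold. "Temperature
#' at d cm" is the grid node at exactly d cm; time-above metrics count
#' output samples times `dt_out` over the whole record.
#'
#' @param field A `temperature_field`.
#' @param cfg An [exposure_config()]. The window is truncated to the run
#'   length with a warning if it extends past the simulation.
#' @param depths Depths (cm) to report. Default whole centimetres 1-10.
#' @return A tibble of class `exposure_summary` with one row per depth:
#'   `depth_cm`, `peak_C`, `t_peak_s`, `mean_window_C`, then `t_above_<x>_s`
#'   and `degsec_above_<x>` per threshold. The window and thresholds used
#'   are stored as attributes.
#' @export
summarize_exposure <- function(field, cfg = exposure_config(),
                               depths = 1:10) {
  stopifnot(inherits(field, "temperature_field"),
            inherits(cfg, "exposure_config"))
  if (length(field$times) == 0 || length(field$depths) == 0) {
    stop_data("data error: empty temperature field")
  }
  window <- cfg$window
  if (window > max(field$times)) {
    warning(sprintf(
      "analysis window %g s exceeds simulation length %g s; truncated",
      window, max(field$times)), call. = FALSE)
    window <- max(field$times)
  }
  in_window <- field$times <= window
  dt <- field$dt_out
  rows <- lapply(depths, function(d) {
    ts <- field_slice(field, d)
    i_peak <- which.max(ts)
    row <- tibble::tibble(
      depth_cm = d,
      peak_C = ts[i_peak],
      t_peak_s = field$times[i_peak],
      mean_window_C = mean(ts[in_window])
    )
    for (th in cfg$thresholds) {
      above <- ts >= th
      row[[sprintf("t_above_%g_s", th)]] <- sum(above) * dt
      row[[sprintf("degsec_above_%g", th)]] <- sum(pmax(ts - th, 0)) * dt
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "window") <- window
  attr(out, "thresholds") <- cfg$thresholds
  attr(out, "lethal_peak_threshold") <- cfg$lethal_peak_threshold
  class(out) <- c("exposure_summary", class(out))
  out
}

#' Classify the heat mortality zone
#'
#' The mortality zone is the depth interval `[0, D]` where `D` is the
#' deepest whole-centimetre bin whose peak temperature meets or exceeds the
#' lethal threshold. Classification uses peak temperature only;
#' degree-second metrics are reported by [summarize_exposure()] but do not
#' enter the zone definition. If super-threshold bins are non-contiguous
#' (possible under exotic forcings) the zone still extends to the deepest
#' qualifying bin and a warning lists the gaps.
#'
#' @param summary An [summarize_exposure()] result (or any data frame with
#'   `depth_cm` and `peak_C`).
#' @param lethal_peak_threshold Lethal peak temperature, degC. Defaults to
#'   the threshold stored on `summary`, else 100.
#' @return An object of class `mortality_zone`: list with `threshold_C`,
#'   `qualifying_depths_cm`, `deepest_cm` (`NA` when no bin qualifies),
#'   `interval_cm` (`c(0, deepest)` or `numeric(0)`), and `empty`.
#' @export
mortality_zone <- function(summary, lethal_peak_threshold = NULL) {
  stopifnot(is.data.frame(summary),
            all(c("depth_cm", "peak_C") %in% names(summary)))
  thr <- lethal_peak_threshold %||%
    attr(summary, "lethal_peak_threshold") %||% 100
  qual <- sort(summary$depth_cm[summary$peak_C >= thr])
  if (length(qual) == 0) {
    z <- list(threshold_C = thr, qualifying_depths_cm = numeric(0),
              deepest_cm = NA_real_, interval_cm = numeric(0), empty = TRUE)
    return(structure(z, class = "mortality_zone"))
  }
  deepest <- max(qual)
  expected <- sort(summary$depth_cm[summary$depth_cm <= deepest])
  gaps <- setdiff(expected, qual)
  if (length(gaps)) {
    warning(sprintf(
      "mortality zone is non-contiguous: sub-threshold bins at %s cm above the deepest qualifying bin",
      paste(gaps, collapse = ", ")), call. = FALSE)
  }
  structure(list(threshold_C = thr, qualifying_depths_cm = qual,
                 deepest_cm = deepest, interval_cm = c(0, deepest),
                 empty = FALSE),
            class = "mortality_zone")
}

#' @export
print.mortality_zone <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<mortality_zone> empty (no bin with peak >= %g degC)\n",
                x$threshold_C))
  } else {
    cat(sprintf("<mortality_zone> 0-%g cm (peak >= %g degC)\n",
                x$deepest_cm, x$threshold_C))
  }
  invisible(x)
}

#' Write an exposure summary to CSV
#'
#' @param summary An `exposure_summary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exposure_csv <- function(summary, path) {
  readr::write_csv(tibble::as_tibble(summary), path)
  invisible(path)
}
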