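#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, as used to compare thermocouple temperatures
#' between cover types. Wraps [stats::t.test()].
#'
#' @param a,b Numeric samples (each with at least two finite values, and
#'   positive variance in at least one).
#' @return List with `t`, `dof`, `p`.
#' @examples
#' welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_data("data error: each sample needs at least 2 finite values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, dof = length(a) + length(b) - 2, p = 1))
    stop_data("degenerate-data error: both samples have zero variance")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Compare cover types per (depth, fire) stratum
#'
#' For each combination of nominal probe depth and fire temperature, pools
#' all samples recorded within the analysis window across replicates for
#' each cover type, and runs a Welch t-test of bare vs biocrust along with
#' per-cover means and maxima. Per-second samples are treated as
#' independent observations; with strongly autocorrelated traces the
#' p-values are anti-conservative and should be read as descriptive.
#' No multiple-testing correction is applied.
#'
#' @param traces Tibble of thermocouple samples with columns `time_s`,
#'   `depth_cm` (nominal), `temp_C`, `cover` (`"bare"`/`"biocrust"`),
#'   `fire_temp`, `replicate`.
#' @param window Pooling window from t = 0, s. Default 1800.
#' @return Tibble with one row per (fire_temp, depth): `fire_temp`,
#'   `depth_cm`, `t_statistic`, `dof`, `p_value`, `mean_bare`, `mean_bsc`,
#'   `max_bare`, `max_bsc`. Strata missing a cover (or with fewer than two
#'   valid samples in a group) are skipped with a warning.
#' @export
compare_treatments <- function(traces, window = 1800) {
  req <- c("time_s", "depth_cm", "temp_C", "cover", "fire_temp", "replicate")
  if (!all(req %in% names(traces))) {
    stop_data(sprintf("data error: traces need columns %s",
                      paste(req, collapse = ", ")))
  }
  traces <- traces[is.finite(traces$temp_C) & traces$time_s <= window, ]
  strata <- unique(traces[, c("fire_temp", "depth_cm")])
  strata <- strata[order(strata$fire_temp, strata$depth_cm), ]
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    ft <- strata$fire_temp[[i]]
    d <- strata$depth_cm[[i]]
    sub <- traces[traces$fire_temp == ft & traces$depth_cm == d, ]
    bare <- sub$temp_C[sub$cover == "bare"]
    bsc <- sub$temp_C[sub$cover == "biocrust"]
    if (length(bare) < 2 || length(bsc) < 2) {
      warning(sprintf(
        "stratum (fire %s, depth %g cm) skipped: missing cover or < 2 samples",
        ft, d), call. = FALSE)
      next
    }
    wt <- welch_t(bare, bsc)
    rows[[length(rows) + 1]] <- tibble::tibble(
      fire_temp = ft, depth_cm = d,
      t_statistic = wt$t, dof = wt$dof, p_value = wt$p,
      mean_bare = mean(bare), mean_bsc = mean(bsc),
      max_bare = max(bare), max_bsc = max(bsc))
  }
  if (!length(rows)) return(tibble::tibble(
    fire_temp = character(), depth_cm = numeric(), t_statistic = numeric(),
    dof = numeric(), p_value = numeric(), mean_bare = numeric(),
    mean_bsc = numeric(), max_bare = numeric(), max_bsc = numeric()))
  dplyr::bind_rows(rows)
}

#' Model-vs-observation depth-offset diagnostic
#'
#' Compares a thermocouple trace to the simulated field at its nominal
#' depth, then searches depth offsets (grid-resolution steps within
#' `max_offset` cm) for the shift minimizing RMSE — quantifying probe
#' placement error of the kind that leaves observed traces about a
#' centimetre off the model. Ties are broken toward the smaller absolute
#' offset.
#'
#' @param field A `temperature_field`.
#' @param trace Tibble with `time_s` and `temp_C` (a single probe), plus a
#'   nominal depth given by `depth_nominal` (argument overrides a
#'   `depth_cm` column).
#' @param depth_nominal Nominal probe depth, cm. Defaults to the unique
#'   `depth_cm` value in `trace`.
#' @param max_offset Half-width of the offset search, cm. Default 2.
#' @return List with `rmse_at_nominal`, `best_offset`, `rmse_at_best`.
#' @export
model_vs_observed <- function(field, trace, depth_nominal = NULL,
                              max_offset = 2) {
  stopifnot(inherits(field, "temperature_field"))
  if (is.null(depth_nominal)) {
    depth_nominal <- unique(trace$depth_cm)
    if (length(depth_nominal) != 1) {
      stop_data("data error: trace must have a single nominal depth")
    }
  }
  keep <- trace$time_s >= min(field$times) & trace$time_s <= max(field$times) &
    is.finite(trace$temp_C)
  if (!any(keep)) stop_data("data error: no time overlap between trace and field")
  tt <- trace$time_s[keep]
  ty <- trace$temp_C[keep]
  rmse_at <- function(d) {
    pred <- stats::approx(field$times, field_slice(field, d), xout = tt)$y
    sqrt(mean((ty - pred)^2))
  }
  offsets <- seq(-max_offset, max_offset, by = field$dz)
  cand <- depth_nominal + offsets
  ok <- cand >= min(field$depths) & cand <= max(field$depths)
  offsets <- offsets[ok]
  rmses <- vapply(depth_nominal + offsets, rmse_at, numeric(1))
  ord <- order(rmses, abs(offsets), offsets)
  list(rmse_at_nominal = rmse_at(depth_nominal),
       best_offset = offsets[ord[1]],
       rmse_at_best = rmses[ord[1]])
}

#' Read / write thermocouple trace CSVs
#'
#' Long-format CSV with columns
#' `time_s,depth_cm,temp_C,cover,fire_temp,replicate`.
#'
#' @param path File path.
#' @return `read_traces_csv()`: a tibble; `write_traces_csv()`: `path`,
#'   invisibly.
#' @export
read_traces_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("time_s", "depth_cm", "temp_C", "cover", "fire_temp", "replicate")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop_data(sprintf("data error: trace file missing columns %s",
                      paste(missing, collapse = ", ")))
  }
  df
}

#' @param traces Tibble of trace samples.
#' @rdname read_traces_csv
#' @export
write_traces_csv <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' Published thermocouple comparison table (reference fixture)
#'
#' The printed per-depth Welch t-test results (t statistic, per-cover mean
#' and maximum temperatures over the first 30 min) from the original burn
#' experiment, for annotating reports. These values are a fixture only: the
#' raw thermocouple series behind them are not published, so they cannot be
#' recomputed here. `p_value` holds the printed upper bound (every stratum
#' was reported as p < 0.001), not an exact value.
#'
#' @return Tibble with columns `fire_temp`, `depth_cm`, `t_statistic`,
#'   `p_value`, `mean_bare_C`, `mean_bsc_C`, `max_bare_C`, `max_bsc_C`.
#' @export
table1_reference <- function() {
  path <- system.file("extdata", "table1_reference.csv", package = "pyrocosm",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
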