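#' Factorial design of the burn experiment
#'
#' The study design: two cover types (bare soil, biocrust) x three fire
#' levels (control, 450 degC, 600 degC) x ten 1-cm depth bins x six
#' replicates = 360 culture plates.
#'
#' @param covers Cover labels. Default `c("bare", "biocrust")`.
#' @param fire_levels Fire levels. Default `c("control", "450", "600")`.
#' @param depths Depth bins, cm. Default `1:10`.
#' @param replicates Replicates per treatment. Default 6.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(covers = c("bare", "biocrust"),
                        fire_levels = c("control", "450", "600"),
                        depths = 1:10, replicates = 6) {
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 0) {
    stop_param("replicates", "must be a non-negative count")
  }
  structure(list(covers = covers, fire_levels = fire_levels,
                 depths = depths, replicates = as.integer(replicates)),
            class = "design_spec")
}

#' Build the empty plate grid for a design
#'
#' One row per (cover, fire level, depth, replicate); `growth` is `NA`
#' until assigned.
#'
#' @param spec A [design_spec()].
#' @return Tibble with columns `cover`, `fire_temp`, `depth_cm`,
#'   `replicate`, `growth`.
#' @examples
#' nrow(build_design(design_spec())) # 360
#' @export
build_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  tidyr::expand_grid(
    cover = spec$covers,
    fire_temp = spec$fire_levels,
    depth_cm = spec$depths,
    replicate = seq_len(spec$replicates)
  ) |>
    dplyr::mutate(growth = NA_integer_)
}

#' Observation noise model for synthetic thermocouples
#'
#' Two error sources are emulated: per-sample Gaussian reading noise, and a
#' per-probe depth placement error (probes are placed by hand and can shift
#' when the mug is moved, so the true sensing depth differs from the
#' nominal one by a random, fixed-per-burn amount).
#'
#' @param temp_sd Reading noise standard deviation, degC. Default 2.
#' @param depth_jitter_sd Placement error standard deviation, cm. Default 0.5.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(temp_sd = 2, depth_jitter_sd = 0.5) {
  if (temp_sd < 0) stop_param("temp_sd", "must be >= 0")
  if (depth_jitter_sd < 0) stop_param("depth_jitter_sd", "must be >= 0")
  structure(list(temp_sd = temp_sd, depth_jitter_sd = depth_jitter_sd),
            class = "noise_model")
}

#' Logistic peak-temperature survival model
#'
#' Culturable survival probability as a smooth function of the peak
#' temperature a depth experienced:
#' `p = p_base * plogis((T50 - peak) / slope)`.
#' `T50` is the lethal-peak midpoint (survival half its baseline), `slope`
#' the logistic scale in degC, and `p_base` the baseline culturability of
#' unheated soil.
#'
#' @param T50 Lethal-peak midpoint, degC. Default 100 (coinciding with the
#'   default lethal-peak threshold of the mortality-zone classifier).
#' @param slope Logistic scale, degC. Default 10.
#' @param p_base Baseline culturability probability. Default 0.9.
#' @return An object of class `survival_model`.
#' @export
survival_model <- function(T50 = 100, slope = 10, p_base = 0.9) {
  if (slope <= 0) stop_param("slope", "must be > 0")
  if (p_base < 0 || p_base > 1) stop_param("p_base", "must be in [0, 1]")
  structure(list(T50 = T50, slope = slope, p_base = p_base),
            class = "survival_model")
}

survival_prob <- function(model, peak_C) {
  model$p_base * stats::plogis((model$T50 - peak_C) / model$slope)
}

#' Generate synthetic thermocouple traces from a simulated field
#'
#' Emulates the observation process: each probe samples the field at its
#' nominal depth plus one placement-jitter draw (fixed for that probe),
#' with independent Gaussian reading noise per sample; the trace keeps the
#' nominal depth label. An optional constant offset emulates a cover
#' effect (e.g. biocrust running cooler than bare soil). Each probe uses
#' its own random stream derived from `seed`, so adding replicates or
#' depths does not perturb earlier draws.
#'
#' @param field A `temperature_field`.
#' @param depths Nominal probe depths, cm. Default `c(2, 5, 8)`.
#' @param reps Replicates per depth. Default 6.
#' @param noise A [noise_model()].
#' @param cover Cover label written into the traces. Default `"bare"`.
#' @param fire_temp Fire level label. Default `"600"`.
#' @param cover_delta_C Constant subtracted from every sample, degC
#'   (e.g. biocrust cooling). Default 0.
#' @param seed Integer seed.
#' @return Tibble of samples: `time_s`, `depth_cm` (nominal), `temp_C`,
#'   `cover`, `fire_temp`, `replicate`.
#' @export
gen_thermocouple_traces <- function(field, depths = c(2, 5, 8), reps = 6,
                                    noise = noise_model(), cover = "bare",
                                    fire_temp = "600", cover_delta_C = 0,
                                    seed = 1L) {
  stopifnot(inherits(field, "temperature_field"),
            inherits(noise, "noise_model"))
  cover_i <- match(cover, c("bare", "biocrust"), nomatch = 3L)
  out <- list()
  for (di in seq_along(depths)) {
    for (r in seq_len(reps)) {
      set.seed(stream_seed(seed, cover_i, di, r))
      jitter <- stats::rnorm(1, 0, noise$depth_jitter_sd)
      actual <- depths[di] + jitter
      if (actual < min(field$depths) || actual > max(field$depths)) {
        warning(sprintf(
          "jittered depth %.2f cm outside the column; clipped", actual),
          call. = FALSE)
        actual <- min(max(actual, min(field$depths)), max(field$depths))
      }
      base <- field_slice(field, actual)
      temp <- base + stats::rnorm(length(base), 0, noise$temp_sd) - cover_delta_C
      out[[length(out) + 1]] <- tibble::tibble(
        time_s = field$times, depth_cm = depths[di], temp_C = temp,
        cover = cover, fire_temp = fire_temp, replicate = r)
    }
  }
  dplyr::bind_rows(out)
}

#' Control-treatment exposure at the initial temperature
#'
#' Exposure table for unburned controls: peak temperature equals the
#' initial soil temperature at every depth, so synthetic control plates
#' grow at the baseline culturability.
#'
#' @param T_init Initial temperature, degC. Default 20.
#' @param depths Depth bins, cm. Default `1:10`.
#' @return Tibble with `depth_cm` and `peak_C`.
#' @export
control_exposure <- function(T_init = 20, depths = 1:10) {
  tibble::tibble(depth_cm = depths, peak_C = T_init)
}

#' Generate a synthetic CFU presence/absence grid
#'
#' Draws plate outcomes independently as
#' `growth ~ Bernoulli(p_base * plogis((T50 - peak(depth)) / slope))`,
#' using the per-depth peak temperature of each fire level's exposure
#' summary (controls use peak = initial temperature, see
#' [control_exposure()]). Each plate has its own random stream derived from
#' `seed`, so enlarging the design does not perturb existing plates.
#'
#' @param exposure_by_fire Named list, one element per fire level in the
#'   design, each a data frame with `depth_cm` and `peak_C` (e.g. an
#'   [summarize_exposure()] result or [control_exposure()]).
#' @param model A [survival_model()].
#' @param spec A [design_spec()].
#' @param seed Integer seed.
#' @return A CFU grid tibble with `growth` filled in.
#' @export
gen_cfu_grid <- function(exposure_by_fire, model = survival_model(),
                         spec = design_spec(), seed = 1L) {
  stopifnot(inherits(model, "survival_model"), inherits(spec, "design_spec"))
  missing <- setdiff(spec$fire_levels, names(exposure_by_fire))
  if (length(missing)) {
    stop_data(sprintf("data error: no exposure for fire level(s) %s",
                      paste(missing, collapse = ", ")))
  }
  grid <- build_design(spec)
  peak_lookup <- function(fire, depth) {
    ex <- exposure_by_fire[[fire]]
    ex$peak_C[match(depth, ex$depth_cm)]
  }
  peaks <- mapply(peak_lookup, grid$fire_temp, grid$depth_cm)
  if (any(is.na(peaks))) {
    stop_data("data error: exposure tables must cover every design depth")
  }
  p <- survival_prob(model, peaks)
  cover_i <- match(grid$cover, spec$covers)
  fire_i <- match(grid$fire_temp, spec$fire_levels)
  growth <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    set.seed(stream_seed(seed, cover_i[i], fire_i[i], grid$depth_cm[i],
                         grid$replicate[i]))
    growth[i] <- stats::rbinom(1, 1, p[i])
  }
  grid$growth <- growth
  grid
}

#' Fit the lethal-peak midpoint from a CFU grid
#'
#' Maximum-likelihood estimate of `T50` under the Bernoulli survival model
#' with `slope` and `p_base` held fixed, by 1-D grid search over
#' `t50_grid` (default 20-400 degC at 1 degC steps); ties break toward the
#' lower `T50`. This turns the qualitative depth stratification of
#' culturable survival into a quantitative thermotolerance estimate.
#'
#' @param grid A CFU grid with scored `growth`.
#' @param exposure_by_fire Named list of per-fire exposure tables, as in
#'   [gen_cfu_grid()].
#' @param slope Logistic scale held fixed, degC. Default 10.
#' @param p_base Baseline culturability held fixed. Default 0.9.
#' @param t50_grid Candidate midpoints, degC. Default `seq(20, 400)`.
#' @return List with `t50` (degC), `loglik` at the estimate, and `flagged`
#'   (`TRUE` when the grid is all-positive or all-negative, in which case a
#'   boundary estimate is returned with a warning).
#' @export
fit_lethal_midpoint <- function(grid, exposure_by_fire, slope = 10,
                                p_base = 0.9, t50_grid = seq(20, 400, by = 1)) {
  grid <- validate_cfu_grid(grid)
  grid <- grid[!is.na(grid$growth), ]
  missing <- setdiff(unique(grid$fire_temp), names(exposure_by_fire))
  if (length(missing)) {
    stop_data(sprintf("data error: no exposure for fire level(s) %s",
                      paste(missing, collapse = ", ")))
  }
  peaks <- vapply(seq_len(nrow(grid)), function(i) {
    ex <- exposure_by_fire[[grid$fire_temp[i]]]
    ex$peak_C[match(grid$depth_cm[i], ex$depth_cm)]
  }, numeric(1))
  y <- grid$growth
  flagged <- all(y == 1) || all(y == 0)
  # log-likelihood over the candidate grid, vectorized: candidates x plates
  pm <- p_base * stats::plogis(outer(t50_grid, peaks, function(t50, pk) (t50 - pk) / slope))
  pm <- pmin(pmax(pm, 1e-12), 1 - 1e-12)
  ll <- as.vector(log(pm) %*% y + log(1 - pm) %*% (1 - y))
  best <- which(ll == max(ll))[1]  # ties toward lower T50 (grid is ascending)
  if (flagged) {
    warning("CFU grid is all-positive or all-negative; T50 estimate is a boundary value",
            call. = FALSE)
    # non-identifiable: the likelihood is monotone, so report the search bound
    best <- if (all(y == 1)) length(t50_grid) else 1L
  }
  list(t50 = t50_grid[best], loglik = ll[best], flagged = flagged)
}
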