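#' Validate a CFU presence/absence grid
#'
#' A CFU grid records, for every culture plate, whether any colony-forming
#' unit grew: one row per (cover, fire_temp, depth_cm, replicate) with a
#' 0/1 `growth` outcome. Depths are whole centimetres in 1-10.
#'
#' @param grid Data frame with columns `cover`, `fire_temp`, `depth_cm`,
#'   `replicate`, `growth`.
#' @return The validated grid as a tibble (invisibly usable in pipelines).
#' @export
validate_cfu_grid <- function(grid) {
  req <- c("cover", "fire_temp", "depth_cm", "replicate", "growth")
  missing <- setdiff(req, names(grid))
  if (length(missing)) {
    stop_data(sprintf("data error: CFU grid missing columns %s",
                      paste(missing, collapse = ", ")))
  }
  if (nrow(grid) == 0) stop_data("data error: empty CFU grid")
  if (!all(grid$depth_cm == round(grid$depth_cm)) ||
      any(grid$depth_cm < 1 | grid$depth_cm > 10)) {
    stop_data("data error: depth_cm must be whole centimetres in 1..10")
  }
  if (!all(grid$growth %in% c(0, 1, NA))) {
    stop_data("data error: growth must be 0/1")
  }
  key <- paste(grid$cover, grid$fire_temp, grid$depth_cm, grid$replicate)
  if (anyDuplicated(key)) {
    stop_data("data error: duplicate (cover, fire_temp, depth, replicate) keys")
  }
  tibble::as_tibble(grid)
}

#' Growth fractions across a CFU grid
#'
#' Overall, per-treatment and per-depth fractions of plates with growth.
#'
#' @param grid A validated CFU grid (see [validate_cfu_grid()]).
#' @return List with `overall` (`n_total`, `n_positive`, `fraction`,
#'   `percent` to one decimal), `by_treatment` (tibble keyed by cover and
#'   fire_temp) and `by_depth` (tibble keyed by depth).
#' @examples
#' g <- build_design(design_spec())
#' g$growth <- 1
#' growth_summary(g)$overall$percent
#' @export
growth_summary <- function(grid) {
  grid <- validate_cfu_grid(grid)
  grid <- grid[!is.na(grid$growth), ]
  if (nrow(grid) == 0) stop_data("data error: no scored plates in grid")
  overall <- list(
    n_total = nrow(grid),
    n_positive = sum(grid$growth),
    fraction = mean(grid$growth),
    percent = round(100 * mean(grid$growth), 1)
  )
  by_treatment <- grid |>
    dplyr::group_by(.data$cover, .data$fire_temp) |>
    dplyr::summarise(n = dplyr::n(), n_positive = sum(.data$growth),
                     fraction = mean(.data$growth), .groups = "drop")
  by_depth <- grid |>
    dplyr::group_by(.data$depth_cm) |>
    dplyr::summarise(n = dplyr::n(), n_positive = sum(.data$growth),
                     fraction = mean(.data$growth), .groups = "drop")
  list(overall = overall, by_treatment = by_treatment, by_depth = by_depth)
}

#' Chi-squared test on CFU presence/absence
#'
#' Pearson chi-squared (no continuity correction) on the contingency table
#' of a design factor against growth/no-growth, pooling over depths and the
#' other factor — the two tests reported for plate grids are by fire
#' temperature (3 x 2) and by cover type (2 x 2).
#'
#' @param grid A validated CFU grid.
#' @param factor `"fire_temp"` or `"cover"`.
#' @return List with `chi2`, `dof`, `p` and the contingency `table`.
#' @export
chi_squared_presence <- function(grid, factor = c("fire_temp", "cover")) {
  grid <- validate_cfu_grid(grid)
  factor <- match.arg(factor)
  grid <- grid[!is.na(grid$growth), ]
  tab <- table(grid[[factor]], factor(grid$growth, levels = c(0, 1)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_data("degenerate-table error: a row or column total is zero")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), dof = unname(ct$parameter),
       p = unname(ct$p.value), table = tab)
}

#' Shallowest depth with growth for a treatment
#'
#' @param grid A validated CFU grid.
#' @param cover Cover type label.
#' @param fire_temp Fire level label.
#' @return Shallowest depth (cm) with at least one positive replicate, or
#'   `NA` if the treatment shows no growth at any depth.
#' @export
min_growth_depth <- function(grid, cover, fire_temp) {
  grid <- validate_cfu_grid(grid)
  sub <- grid[grid$cover == cover & grid$fire_temp == fire_temp, ]
  if (nrow(sub) == 0) {
    stop_data(sprintf("key error: treatment (%s, %s) not present in grid",
                      cover, fire_temp))
  }
  pos <- sub$depth_cm[!is.na(sub$growth) & sub$growth == 1]
  if (length(pos) == 0) return(NA_real_)
  min(pos)
}

#' Read / write CFU grid CSVs
#'
#' CSV with columns `cover,fire_temp,depth_cm,replicate,growth`.
#'
#' @param path File path.
#' @return `read_cfu_csv()`: a validated tibble; `write_cfu_csv()`: `path`,
#'   invisibly.
#' @export
read_cfu_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(fire_temp = readr::col_character()))
  for (col in c("depth_cm", "replicate", "growth")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  validate_cfu_grid(df)
}

#' @param grid A CFU grid tibble.
#' @rdname read_cfu_csv
#' @export
write_cfu_csv <- function(grid, path) {
  readr::write_csv(grid, path)
  invisible(path)
}
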