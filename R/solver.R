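#' Simulation grid for the soil column
#'
#' Discretization of the soil column: 0.1 cm depth steps over a 15 cm
#' column, output every second. The column must reach at least 10 cm so the
#' full 1-10 cm sampling range is covered.
#'
#' @param dz Depth step, cm. Default 0.1.
#' @param depth_total Column depth, cm. Default 15. Must be >= 10.
#' @param dt_out Output time step, s. Default 1.
#' @param duration Simulated duration, s. `NULL` (default) uses the forcing
#'   curve's duration.
#' @return An object of class `simulation_grid`.
#' @export
simulation_grid <- function(dz = 0.1, depth_total = 15, dt_out = 1,
                            duration = NULL) {
  if (!is.numeric(dz) || length(dz) != 1L || dz <= 0) {
    stop_param("dz", "must be > 0")
  }
  if (!is.numeric(depth_total) || length(depth_total) != 1L ||
      depth_total < 10) {
    stop_param("depth_total", "must be >= 10 cm to cover the 1-10 cm sampling range")
  }
  if (!is.numeric(dt_out) || length(dt_out) != 1L || dt_out <= 0) {
    stop_param("dt_out", "must be > 0")
  }
  if (!is.null(duration) && (!is.numeric(duration) || duration <= 0)) {
    stop_param("duration", "must be > 0")
  }
  structure(list(dz = dz, depth_total = depth_total, dt_out = dt_out,
                 duration = duration),
            class = "simulation_grid")
}

#' Simulate heat conduction through the soil column
#'
#' Solves the 1-D heat equation `C dT/dt = d/dz (k dT/dz)` through the soil
#' column, with the surface temperature prescribed by the forcing curve
#' (Dirichlet top boundary) and, by default, the bottom of the column held
#' at the initial temperature (Dirichlet at `depth_total`, emulating the
#' sand tray heat sink beneath the mug). Time stepping is Crank-Nicolson;
#' the constant tridiagonal system is LU-factored once and re-solved per
#' step, so the scheme is unconditionally stable at the default resolution
#' (dz 0.1 cm, dt 1 s), where the explicit stability number alpha*dt/dz^2
#' is about 2.
#'
#' If the requested duration exceeds the forcing curve, the surface forcing
#' is clamped to its final value.
#'
#' @param forcing A [build_forcing_curve()] result.
#' @param props A [thermal_properties()] object.
#' @param grid A [simulation_grid()].
#' @param T_init Initial (and bottom-boundary) temperature, degC. Default 20.
#' @param bottom `"dirichlet"` (default; bottom fixed at `T_init`) or
#'   `"neumann"` (zero flux).
#' @param latent_heat If `TRUE`, apply an evaporative energy sink: while a
#'   node at 100 degC still holds water, incoming heat depletes a per-node
#'   water store (`theta * 1000 kg m^-3 * 2.26 MJ kg^-1`) before the
#'   temperature rises further (enthalpy clipping after each step). Default
#'   `FALSE`.
#' @param theta Volumetric water content used for the latent-heat store;
#'   only consulted when `latent_heat = TRUE`. Default 0.10.
#' @param n_substeps Internal time substeps per output step. Default 1.
#' @return An object of class `temperature_field`: list with `depths` (cm),
#'   `times` (s), `temps` (matrix, depth x time, degC), `T_init`, `dz`,
#'   `dt_out`.
#' @examples
#' fc <- build_forcing_curve(fire_forcing_params(450))
#' fld <- simulate_heat_transfer(fc, thermal_properties())
#' max(field_slice(fld, 3))
#' @export
simulate_heat_transfer <- function(forcing, props, grid = simulation_grid(),
                                   T_init = 20,
                                   bottom = c("dirichlet", "neumann"),
                                   latent_heat = FALSE, theta = 0.10,
                                   n_substeps = 1L) {
  stopifnot(inherits(forcing, "forcing_curve"),
            inherits(props, "thermal_properties"),
            inherits(grid, "simulation_grid"))
  bottom <- match.arg(bottom)
  if (!is.numeric(n_substeps) || n_substeps < 1) {
    stop_param("n_substeps", "must be >= 1")
  }
  n_substeps <- as.integer(n_substeps)

  duration <- grid$duration %||% max(forcing$times)
  times <- seq(0, duration, by = grid$dt_out)
  depths <- seq(0, grid$depth_total, by = grid$dz)
  nz <- length(depths)
  nt <- length(times)

  alpha <- props$diffusivity
  dz_m <- grid$dz / 100
  dt_in <- grid$dt_out / n_substeps
  r <- alpha * dt_in / dz_m^2

  # unknown nodes: interior (dirichlet bottom) or interior + bottom (neumann)
  n_unknown <- if (bottom == "dirichlet") nz - 2L else nz - 1L
  main <- rep(1 + r, n_unknown)
  lower <- rep(-r / 2, n_unknown - 1L)
  upper <- rep(-r / 2, n_unknown - 1L)
  if (bottom == "neumann") {
    # zero-gradient bottom via mirrored neighbour: lap_N = 2 (T_{N-1} - T_N)
    lower[n_unknown - 1L] <- -r
  }
  A <- Matrix::bandSparse(n_unknown, k = c(-1L, 0L, 1L),
                          diagonals = list(lower, main, upper))
  fa <- Matrix::lu(A)

  # latent-heat store per node, J m^-2 (water mass per unit area x 2.26 MJ/kg)
  store <- if (latent_heat) rep(theta * 1000 * 2.26e6 * dz_m, nz) else NULL
  C_J <- props$heat_capacity * 1e6

  temps <- matrix(NA_real_, nrow = nz, ncol = nt)
  state <- rep(T_init, nz)
  state[1] <- forcing_at(forcing$params, 0)
  temps[, 1] <- state

  lap <- function(v, g_top, g_bot) {
    # discrete Laplacian on unknown nodes given boundary values
    n <- length(v)
    left <- c(g_top, v[-n])
    if (bottom == "dirichlet") {
      right <- c(v[-1], g_bot)
      left + right - 2 * v
    } else {
      right <- c(v[-1], v[n - 1])  # mirror
      left + right - 2 * v
    }
  }

  for (j in 2:nt) {
    for (s in seq_len(n_substeps)) {
      t_new <- times[j - 1] + s * dt_in
      g_top_old <- state[1]
      g_top_new <- forcing_at(forcing$params, t_new)
      u <- if (bottom == "dirichlet") state[2:(nz - 1)] else state[2:nz]
      b <- u + (r / 2) * lap(u, g_top_old, T_init)
      b[1] <- b[1] + (r / 2) * g_top_new
      if (bottom == "dirichlet") b[length(b)] <- b[length(b)] + (r / 2) * T_init
      u_new <- as.numeric(Matrix::solve(fa, b))
      if (any(!is.finite(u_new))) {
        stop_data(sprintf("numerical error: non-finite solution at t = %g s", t_new))
      }
      state <- if (bottom == "dirichlet") c(g_top_new, u_new, T_init)
               else c(g_top_new, u_new)
      if (latent_heat) {
        hot <- which(state > 100 & store > 0)
        if (length(hot)) {
          q <- C_J * (state[hot] - 100) * dz_m
          used <- pmin(q, store[hot])
          store[hot] <- store[hot] - used
          state[hot] <- 100 + (q - used) / (C_J * dz_m)
        }
      }
    }
    temps[, j] <- state
  }

  structure(list(depths = depths, times = times, temps = temps,
                 T_init = T_init, dz = grid$dz, dt_out = grid$dt_out,
                 forcing_params = forcing$params),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf(
    "<temperature_field> %d depths (0..%g cm) x %d times (0..%g s); %g..%g degC\n",
    length(x$depths), max(x$depths), length(x$times), max(x$times),
    min(x$temps), max(x$temps)))
  invisible(x)
}

#' Extract the temperature time series at a depth
#'
#' Linear interpolation between the two bracketing grid nodes; depths
#' outside the column are clamped to its range.
#'
#' @param field A `temperature_field`.
#' @param depth_cm Depth, cm.
#' @return Numeric vector of temperatures, one per field time point.
#' @export
field_slice <- function(field, depth_cm) {
  stopifnot(inherits(field, "temperature_field"))
  d <- min(max(depth_cm, min(field$depths)), max(field$depths))
  i <- findInterval(d, field$depths, rightmost.closed = TRUE)
  if (field$depths[i] == d || i == length(field$depths)) {
    return(field$temps[i, ])
  }
  w <- (d - field$depths[i]) / (field$depths[i + 1] - field$depths[i])
  (1 - w) * field$temps[i, ] + w * field$temps[i + 1, ]
}

#' Analytic half-space step-heating oracle
#'
#' Temperature in a semi-infinite solid whose surface is stepped from
#' `T_init` to `T_surface` at t = 0:
#' `T(z, t) = T_init + (T_surface - T_init) * erfc(z / (2 sqrt(alpha t)))`.
#' Used as an independent closed-form check on the numerical solver.
#'
#' @param z Depth, m (>= 0).
#' @param t Time, s (> 0).
#' @param alpha Thermal diffusivity, m^2 s^-1 (> 0).
#' @param T_init Initial temperature, degC.
#' @param T_surface Surface temperature after the step, degC.
#' @return Temperature, degC (vectorized over `z` and `t`).
#' @examples
#' halfspace_step_oracle(0.02, 600, 2e-6, 20, 120) # ~88.3
#' @export
halfspace_step_oracle <- function(z, t, alpha, T_init, T_surface) {
  if (any(t <= 0)) stop_param("t", "must be > 0")
  if (any(z < 0)) stop_param("z", "must be >= 0")
  if (any(alpha <= 0)) stop_param("alpha", "must be > 0")
  arg <- z / (2 * sqrt(alpha * t))
  erfc <- 2 * stats::pnorm(-arg * sqrt(2))
  T_init + (T_surface - T_init) * erfc
}

#' Write a temperature field to CSV
#'
#' Long format by default (`time_s,depth_cm,temp_C`); `format = "matrix"`
#' writes a compact matrix with a `time_s` column followed by one column
#' per depth.
#'
#' @param field A `temperature_field`.
#' @param path Output file path.
#' @param format `"long"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path, format = c("long", "matrix")) {
  stopifnot(inherits(field, "temperature_field"))
  format <- match.arg(format)
  if (format == "long") {
    df <- tibble::tibble(
      time_s = rep(field$times, each = length(field$depths)),
      depth_cm = rep(field$depths, times = length(field$times)),
      temp_C = as.vector(field$temps)
    )
  } else {
    df <- tibble::as_tibble(t(field$temps), .name_repair = "minimal")
    names(df) <- sprintf("d%g", field$depths)
    df <- dplyr::bind_cols(tibble::tibble(time_s = field$times), df)
  }
  readr::write_csv(df, path)
  invisible(path)
}
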