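# shared fixtures built in code

# hand-assembled temperature field (depth x time matrix)
make_field <- function(depths, times, temps, T_init = 20) {
  structure(list(depths = depths, times = times, temps = temps,
                 T_init = T_init,
                 dz = if (length(depths) > 1) diff(depths)[1] else 1,
                 dt_out = if (length(times) > 1) diff(times)[1] else 1),
            class = "temperature_field")
}

# analytic half-space field: step surface heating, exact at every node
make_halfspace_field <- function(depths_cm = seq(0, 10, by = 0.1),
                                 times_s = 0:600, alpha = 2e-6,
                                 T_init = 20, T_surface = 120) {
  temps <- outer(depths_cm / 100, times_s, function(z, t) {
    ifelse(t == 0, ifelse(z == 0, T_surface, T_init),
           halfspace_step_oracle(z, pmax(t, 1e-9), alpha, T_init, T_surface))
  })
  make_field(depths_cm, times_s, temps, T_init)
}

# step forcing curve: surface jumps to T_surface at t = 0 and stays there
step_forcing <- function(T_surface, T_basal = 20, duration = 600, dt = 1) {
  p <- fire_forcing_params(t_max = T_surface, t_basal = T_basal,
                           t_ramp = 0, t_hold = duration, t_decay = 0,
                           dt = dt)
  build_forcing_curve(p)
}

# independent chi-squared oracle: brute-force sum over cells
chi2_brute <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# independent Welch oracle from first principles
welch_brute <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
}

default_600_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fc <- build_forcing_curve(fire_forcing_params(600))
      cache <<- simulate_heat_transfer(fc, thermal_properties())
    }
    cache
  }
})
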