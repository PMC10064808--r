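test_that("the factorial design enumerates every plate", {
  expect_equal(nrow(build_design(design_spec())), 360)
  expect_equal(nrow(build_design(design_spec(replicates = 0))), 0)
  expect_equal(nrow(build_design(design_spec(covers = "bare",
                                             fire_levels = "600",
                                             replicates = 1))), 10)
  d <- build_design(design_spec())
  key <- paste(d$cover, d$fire_temp, d$depth_cm, d$replicate)
  expect_equal(anyDuplicated(key), 0)
})

test_that("noise-free traces equal exact field slices", {
  fld <- make_halfspace_field()
  tr <- gen_thermocouple_traces(fld, depths = c(2, 5), reps = 2,
                                noise = noise_model(0, 0), seed = 1)
  for (d in c(2, 5)) {
    one <- tr[tr$depth_cm == d & tr$replicate == 1, ]
    expect_equal(one$temp_C, field_slice(fld, d))
  }
})

test_that("per-sample reading noise has the configured spread", {
  fld <- make_field(depths = 0:10, times = 0:999,
                    temps = matrix(40, nrow = 11, ncol = 1000))
  tr <- gen_thermocouple_traces(fld, depths = 5, reps = 3,
                                noise = noise_model(temp_sd = 2,
                                                    depth_jitter_sd = 0),
                                seed = 2)
  for (r in 1:3) {
    resid <- tr$temp_C[tr$replicate == r] - 40
    # chi-square bounds on a sample sd of n = 1000 draws at sd = 2
    expect_gt(sd(resid), 1.8)
    expect_lt(sd(resid), 2.2)
  }
})

test_that("placement jitter shows up as a recoverable depth offset", {
  fld <- make_halfspace_field()
  recovered <- drawn <- numeric(6)
  for (r in 1:6) {
    tr <- gen_thermocouple_traces(fld, depths = 2, reps = r,
                                  noise = noise_model(0.5, 0.5), seed = 13)
    one <- tr[tr$replicate == r, ]
    set.seed(pyrocosm:::stream_seed(13, 1, 1, r))
    drawn[r] <- rnorm(1, 0, 0.5)
    recovered[r] <- model_vs_observed(fld, one, depth_nominal = 2)$best_offset
  }
  expect_lt(median(abs(recovered - drawn)), 0.2)
})

test_that("generators are deterministic and stream-stable under growth", {
  fld <- make_halfspace_field()
  a <- gen_thermocouple_traces(fld, reps = 2, seed = 4)
  b <- gen_thermocouple_traces(fld, reps = 2, seed = 4)
  expect_identical(a, b)
  more <- gen_thermocouple_traces(fld, reps = 4, seed = 4)
  expect_equal(a, more[more$replicate <= 2, ], ignore_attr = TRUE)
  ex <- list(control = control_exposure(),
             "450" = control_exposure(), "600" = control_exposure())
  g1 <- gen_cfu_grid(ex, seed = 6)
  g2 <- gen_cfu_grid(ex, seed = 6)
  expect_identical(g1, g2)
  g3 <- gen_cfu_grid(ex, spec = design_spec(replicates = 12), seed = 6)
  merged <- dplyr::inner_join(
    g1, g3, by = c("cover", "fire_temp", "depth_cm", "replicate"))
  expect_equal(merged$growth.x, merged$growth.y)
})

test_that("an unreachable midpoint reduces the grid to baseline growth", {
  ex <- list(control = control_exposure(),
             "450" = tibble::tibble(depth_cm = 1:10, peak_C = seq(300, 30, length.out = 10)),
             "600" = tibble::tibble(depth_cm = 1:10, peak_C = seq(450, 40, length.out = 10)))
  g <- gen_cfu_grid(ex, survival_model(T50 = 1e6), seed = 8)
  se <- sqrt(0.9 * 0.1 / nrow(g))
  expect_lt(abs(mean(g$growth) - 0.9), 3 * se)
})

test_that("a zero midpoint with steep slope kills every plate", {
  ex <- list(control = control_exposure(),
             "450" = control_exposure(), "600" = control_exposure())
  g <- gen_cfu_grid(ex, survival_model(T50 = 0, slope = 1), seed = 8)
  expect_true(all(g$growth == 0))
})

test_that("mean growth matches the analytic expectation over many seeds", {
  peaks <- seq(470, 90, length.out = 10)
  ex600 <- tibble::tibble(depth_cm = 1:10, peak_C = peaks)
  model <- survival_model(T50 = 100, slope = 10, p_base = 0.9)
  spec <- design_spec(covers = "bare", fire_levels = "600", replicates = 6)
  p_expect <- mean(0.9 * plogis((100 - peaks) / 10))
  fracs <- sapply(1:200, function(s) {
    mean(gen_cfu_grid(list("600" = ex600), model, spec, seed = s)$growth)
  })
  n_draws <- 200 * 60
  se <- sqrt(p_expect * (1 - p_expect) / n_draws)
  expect_lt(abs(mean(fracs) - p_expect), 3 * se)
})

test_that("marginal growth probability is monotone in peak temperature", {
  peaks <- seq(20, 400, by = 20)
  model <- survival_model()
  p <- pyrocosm:::survival_prob(model, peaks)
  expect_true(all(diff(p) < 0))
})

test_that("T50 recovery sharpens as replication grows", {
  exposure <- list(
    control = control_exposure(),
    "450" = tibble::tibble(depth_cm = 1:10, peak_C = seq(360, 60, length.out = 10)),
    "600" = tibble::tibble(depth_cm = 1:10, peak_C = seq(470, 87, length.out = 10)))
  err_for <- function(R, seeds) {
    spec <- design_spec(replicates = R)
    ests <- sapply(seeds, function(s) {
      g <- gen_cfu_grid(exposure, survival_model(T50 = 100), spec, seed = s)
      fit_lethal_midpoint(g, exposure)$t50
    })
    median(abs(ests - 100))
  }
  errs <- c(err_for(6, 1:20), err_for(24, 1:20), err_for(96, 1:10))
  expect_lte(errs[3], errs[1])
  expect_lte(errs[1], 10)
})

test_that("likelihood peaks near the true midpoint for a large grid", {
  exposure <- list(
    "600" = tibble::tibble(depth_cm = 1:10, peak_C = seq(470, 87, length.out = 10)))
  spec <- design_spec(covers = "bare", fire_levels = "600", replicates = 100)
  g <- gen_cfu_grid(exposure, survival_model(T50 = 100), spec, seed = 3)
  ll_at <- function(t50) {
    fit_lethal_midpoint(g, exposure, t50_grid = t50)$loglik
  }
  expect_gte(ll_at(100), ll_at(50))
  expect_gte(ll_at(100), ll_at(150))
})

test_that("non-identifiable grids return flagged boundary estimates", {
  ex <- list(control = control_exposure(),
             "450" = control_exposure(), "600" = control_exposure())
  g <- build_design(design_spec())
  g$growth <- 1L
  expect_warning(fit <- fit_lethal_midpoint(g, ex), "boundary")
  expect_equal(fit$t50, 400)
  expect_true(fit$flagged)
  g$growth <- 0L
  expect_warning(fit0 <- fit_lethal_midpoint(g, ex), "boundary")
  expect_equal(fit0$t50, 20)
})

test_that("missing exposure for a fire level is a data error", {
  ex <- list(control = control_exposure())
  expect_error(gen_cfu_grid(ex, seed = 1), "450")
})
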