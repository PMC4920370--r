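test_that("beta_from_moments solves the moment equations", {
  kd <- beta_from_moments(0.5, 0.125)
  expect_equal(kd$alpha, 0.5)
  expect_equal(kd$beta, 0.5)
  u <- beta_from_moments(0.5, 1 / 12)
  expect_equal(u$alpha, 1)
  expect_equal(u$beta, 1)
  s <- beta_from_moments(0.927, 0.00128)
  expect_equal(s$alpha, 48.1, tolerance = 0.01)
  expect_equal(s$beta, 3.79, tolerance = 0.01)
  # round trip: implied moments equal the inputs
  expect_equal(s$mean, 0.927)
  expect_equal(s$var, 0.00128)
  expect_error(beta_from_moments(0.5, 0.3), "overdispersed")
  expect_error(beta_from_moments(1.2, 0.01), "in \\(0, 1\\)")
})

test_that("simulated logistic trajectories match the closed form", {
  gp <- growth_params(r = 1.0, K = 1)
  tr <- simulate_trajectory(gp, 0.5, years = 3, time_step = 0.25)
  expect_equal(tr$density, logistic_closed_form(0.5, 1.0, tr$time),
               tolerance = 1e-3)
  # carrying capacity is a fixed point
  at_k <- simulate_trajectory(gp, 1, years = 2)
  expect_true(all(at_k$density == 1))
  # bounds: trajectories stay in (0, K]
  low <- simulate_trajectory(gp, 1e-4, years = 30)
  expect_true(all(low$density > 0 & low$density <= 1))
})

test_that("closed-form recovery time behaves as the formula dictates", {
  gp <- growth_params(1.0)
  expect_equal(recovery_time_closed_form(gp, 0.95, 0.95), 0)
  expect_equal(recovery_time_closed_form(gp, 0.073, 0.95), 5.49,
               tolerance = 0.002)
  # halving r doubles the time; doubling r halves it
  t1 <- recovery_time_closed_form(gp, 0.05, 0.95)
  expect_equal(recovery_time_closed_form(growth_params(0.5), 0.05, 0.95), 2 * t1)
  expect_equal(recovery_time_closed_form(growth_params(2), 0.05, 0.95), t1 / 2)
  # numeric cross-check against the step simulator
  tr <- simulate_trajectory(gp, 0.073, years = 8, time_step = 0.25)
  first <- tr$time[min(which(tr$density >= 0.95))]
  expect_equal(first, recovery_time_closed_form(gp, 0.073, 0.95),
               tolerance = 0.01)
})

test_that("doubling r halves the simulated time to a fixed threshold", {
  hit_time <- function(r) {
    tr <- simulate_trajectory(growth_params(r), 0.05, years = 20,
                              time_step = 0.25)
    tr$time[min(which(tr$density >= 0.9))]
  }
  expect_equal(hit_time(2) / hit_time(1), 0.5, tolerance = 0.01)
})

test_that("monte_carlo_recovery with a degenerate kill matches the closed form", {
  gp <- growth_params(1.0)
  kd <- kill_distribution(fixed = 0.927)
  cfg <- sim_config(n_runs = 10, seed = 5)
  r <- monte_carlo_recovery(gp, kd, cfg)
  expect_equal(r$sd_years, 0)
  expect_equal(r$mean_years, recovery_time_closed_form(gp, 0.073, 0.95),
               tolerance = 2 * cfg$time_step / 365)
})

test_that("beta draws reproduce the fitted moments", {
  kd <- beta_from_moments(0.927, 0.00128)
  set.seed(31)
  x <- draw_kill(kd, 2e5)
  expect_equal(mean(x), 0.927, tolerance = 3 * sqrt(0.00128 / 2e5))
  expect_equal(var(x), 0.00128, tolerance = 0.05)
  expect_true(all(x > 0 & x < 1))
})

test_that("monte_carlo_recovery is reproducible and sanely summarised", {
  gp <- growth_params(1.0)
  kd <- beta_from_moments(0.927, 0.00128)
  cfg <- sim_config(n_runs = 300, seed = 17)
  a <- monte_carlo_recovery(gp, kd, cfg)
  b <- monte_carlo_recovery(gp, kd, cfg)
  expect_identical(a$years, b$years)
  expect_true(all(diff(a$quantiles) >= 0))
  expect_gte(a$mean_years, min(a$years, na.rm = TRUE))
  expect_lte(a$mean_years, max(a$years, na.rm = TRUE))
  expect_equal(a$runs_not_recovered, 0)
})

test_that("runs beyond the horizon are excluded with a warning", {
  gp <- growth_params(0.2)
  kd <- kill_distribution(fixed = 0.99)
  cfg <- sim_config(n_runs = 5, seed = 1, max_horizon = 3)
  expect_warning(r <- monte_carlo_recovery(gp, kd, cfg), "not recovered")
  expect_equal(r$runs_not_recovered, 5)
})

test_that("seasonal growth concentrates increase in the breeding window", {
  gp <- growth_params(1.0, seasonal = list(start_day = 245, end_day = 60))
  # outside the window the population must not grow
  tr <- simulate_trajectory(gp, 0.1, years = 1, start_day = 100)
  before_window <- tr$density[tr$time <= (245 - 100) / 365]
  expect_equal(max(before_window), 0.1)
  # annual rate integral is preserved: one full year of seasonal growth
  # from low density is close to one year at constant r (logistic is not
  # exactly exchangeable in time, so allow a modest tolerance)
  full <- simulate_trajectory(gp, 0.05, years = 1, start_day = 245)
  const <- simulate_trajectory(growth_params(1.0), 0.05, years = 1)
  expect_equal(full$density[nrow(full)], const$density[nrow(const)],
               tolerance = 0.05)
})

test_that("the four-scenario runner obeys its fixed ordering and r-halving", {
  kills <- list(strip = kill_distribution(fixed = 0.927),
                broadcast = kill_distribution(fixed = 0.94))
  cfg <- sim_config(n_runs = 5, seed = 2)
  out <- run_recovery_scenarios(1.0, kills, cfg)
  expect_named(out, c("pre_strip", "pre_broadcast", "post_strip",
                      "post_broadcast"))
  # fixed kill: post-epidemic times are double the pre-epidemic ones
  expect_equal(out$post_strip$mean_years / out$pre_strip$mean_years, 2,
               tolerance = 0.01)
  expect_gt(out$pre_broadcast$mean_years, out$pre_strip$mean_years)
})
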