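#' Population growth parameters
#'
#' Parameters of the density-dependent growth model used to project
#' post-control recovery: the instantaneous annual rate of increase `r`
#' (1/yr) and the carrying capacity `K`, which defaults to 1 so that
#' densities are expressed as fractions of the pre-control level. An
#' optional seasonal breeding window confines growth to part of the year:
#' outside the window the effective rate is 0, inside it the rate is
#' rescaled so that the integral of the rate over a full year still equals
#' `r`.
#'
#' @param r Instantaneous annual rate of increase, 1/yr (> 0).
#' @param K Carrying capacity; defaults to the normalised pre-control
#'   density 1.
#' @param seasonal Optional list `list(start_day =, end_day =)` giving the
#'   breeding window in days of a 365-day year; the window may wrap the
#'   year end (`start_day > end_day`).
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(r, K = 1, seasonal = NULL) {
  if (!is.numeric(r) || r <= 0) stop("r must be positive")
  if (!is.numeric(K) || K <= 0) stop("K must be positive")
  if (!is.null(seasonal)) {
    if (is.null(seasonal$start_day) || is.null(seasonal$end_day)) {
      stop("seasonal config needs start_day and end_day")
    }
    len <- (seasonal$end_day - seasonal$start_day) %% 365
    if (len == 0) stop("seasonal breeding window has zero length")
    seasonal$window_days <- len
  }
  structure(list(r = r, K = K, seasonal = seasonal), class = "growth_params")
}

# Effective growth rate at a vector of days-of-year (0-based, [0, 365)).
# Non-seasonal: constant r. Seasonal: 0 outside the window, r * 365/window
# inside, so the annual integral equals r.
effective_rate <- function(gp, day_of_year) {
  if (is.null(gp$seasonal)) return(rep(gp$r, length(day_of_year)))
  s <- gp$seasonal$start_day %% 365
  e <- gp$seasonal$end_day %% 365
  inside <- if (s < e) {
    day_of_year >= s & day_of_year < e
  } else {
    day_of_year >= s | day_of_year < e
  }
  ifelse(inside, gp$r * 365 / gp$seasonal$window_days, 0)
}

#' Beta distribution of control efficacy
#'
#' The kill fraction achieved by one control operation is modelled as a
#' beta random variable on (0, 1). A degenerate (fixed-kill) law is
#' available for analytic cross-checks via the `fixed` argument.
#'
#' @param alpha,beta Positive shape parameters.
#' @param fixed Optional fixed kill fraction in (0, 1); when given the
#'   "distribution" is a point mass and `alpha`/`beta` are ignored.
#' @return Object of class `kill_distribution` with elements `alpha`,
#'   `beta` (or `fixed`), plus `mean` and `var`.
#' @export
kill_distribution <- function(alpha = NULL, beta = NULL, fixed = NULL) {
  if (!is.null(fixed)) {
    if (fixed <= 0 || fixed >= 1) stop("fixed kill must be in (0, 1)")
    return(structure(list(fixed = fixed, mean = fixed, var = 0),
                     class = "kill_distribution"))
  }
  if (is.null(alpha) || is.null(beta) || alpha <= 0 || beta <= 0) {
    stop("alpha and beta must be positive")
  }
  m <- alpha / (alpha + beta)
  v <- alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1))
  structure(list(alpha = alpha, beta = beta, mean = m, var = v),
            class = "kill_distribution")
}

#' @export
print.kill_distribution <- function(x, ...) {
  if (!is.null(x$fixed)) {
    cat(sprintf("Fixed kill: %.1f%%\n", 100 * x$fixed))
  } else {
    cat(sprintf("Beta(%.3g, %.3g) kill: mean %.1f%%, SD %.2f%% points\n",
                x$alpha, x$beta, 100 * x$mean, 100 * sqrt(x$var)))
  }
  invisible(x)
}

#' Fit a beta efficacy law by the method of moments
#'
#' Given the mean and variance of the kill fraction observed across
#' replicate operations, solves for the beta shape parameters:
#' `alpha = m * (m(1-m)/v - 1)`, `beta = (1-m) * (m(1-m)/v - 1)`.
#'
#' @param mean_kill Mean kill fraction, in (0, 1).
#' @param var_kill Variance of the kill fraction; must be positive and
#'   below `mean_kill * (1 - mean_kill)`.
#' @return A [kill_distribution()].
#' @export
#' @examples
#' beta_from_moments(0.927, 0.00128)  # alpha ~ 48.1, beta ~ 3.79
beta_from_moments <- function(mean_kill, var_kill) {
  if (mean_kill <= 0 || mean_kill >= 1) stop("mean kill must be in (0, 1)")
  if (var_kill <= 0) stop("variance must be positive")
  if (var_kill >= mean_kill * (1 - mean_kill)) {
    stop("overdispersed for beta: variance must be below m(1-m)")
  }
  nu <- mean_kill * (1 - mean_kill) / var_kill - 1
  kill_distribution(alpha = mean_kill * nu, beta = (1 - mean_kill) * nu)
}

#' Draw kill fractions from an efficacy law
#'
#' @param kd A [kill_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of kill fractions in (0, 1).
#' @export
draw_kill <- function(kd, n) {
  if (!is.null(kd$fixed)) return(rep(kd$fixed, n))
  rbeta(n, kd$alpha, kd$beta)
}

#' Simulation configuration for the recovery model
#'
#' @param n_runs Number of Monte-Carlo replicates (default 10,000).
#' @param control_day Day of year on which control is applied; default 182
#'   (1 July).
#' @param q Recovery threshold as a fraction of pre-control density
#'   (default 0.95). "Recovered to pre-control density" is asymptotically
#'   unreachable under logistic growth, so a threshold slightly below 1 is
#'   required; sensitivity to `q` should be reported alongside results.
#' @param max_horizon Maximum years simulated per run (default 50).
#' @param time_step Integration step in days (default 1).
#' @param seed Optional integer RNG seed for reproducibility.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_runs = 10000, control_day = 182, q = 0.95,
                       max_horizon = 50, time_step = 1, seed = NULL) {
  if (n_runs < 1) stop("n_runs must be at least 1")
  if (q <= 0 || q >= 1) stop("recovery threshold q must be in (0, 1)")
  if (time_step <= 0) stop("time step must be positive")
  if (max_horizon <= 0) stop("max horizon must be positive")
  structure(
    list(n_runs = as.integer(n_runs), control_day = control_day, q = q,
         max_horizon = max_horizon, time_step = time_step, seed = seed),
    class = "sim_config"
  )
}

#' Simulate one population trajectory
#'
#' Discrete-time logistic growth, `dN = r_eff * N * (1 - N/K) * dt`, with
#' `dt` in days and an optional seasonal breeding window (see
#' [growth_params()]). The configuration must satisfy `r * dt < 1` (checked),
#' which keeps trajectories within (0, K].
#'
#' @param gp [growth_params()].
#' @param start_density Initial density in (0, K].
#' @param years Length of the simulated period, years.
#' @param time_step Step, days (default 1).
#' @param start_day Day of year at the start (matters only with a seasonal
#'   window); default 182.
#' @return Data frame with columns `time` (years since start) and
#'   `density`.
#' @export
simulate_trajectory <- function(gp, start_density, years, time_step = 1,
                                start_day = 182) {
  if (time_step <= 0) stop("time step must be positive")
  if (start_density <= 0 || start_density > gp$K) {
    stop("start density must be in (0, K]")
  }
  dt <- time_step / 365
  r_max <- if (is.null(gp$seasonal)) gp$r else gp$r * 365 / gp$seasonal$window_days
  if (r_max * dt >= 1) stop("time step too large: r * dt must be below 1")
  n_steps <- ceiling(years * 365 / time_step)
  dens <- numeric(n_steps + 1)
  dens[1] <- start_density
  days <- (start_day + (0:(n_steps - 1)) * time_step) %% 365
  rates <- effective_rate(gp, days)
  N <- start_density
  for (i in seq_len(n_steps)) {
    N <- N + rates[i] * N * (1 - N / gp$K) * dt
    dens[i + 1] <- N
  }
  data.frame(time = (0:n_steps) * dt, density = dens)
}

#' Closed-form recovery time under non-seasonal logistic growth
#'
#' For continuous logistic growth from a survivor fraction `s` of carrying
#' capacity to a threshold fraction `q`, the time is
#' `t = (1/r) * log(q * (1 - s) / (s * (1 - q)))`. Used as the analytic
#' oracle for the stochastic simulator; returns 0 when `s >= q` (already
#' recovered).
#'
#' @param gp Non-seasonal [growth_params()].
#' @param survivor_fraction Post-control density as a fraction of K, in
#'   (0, 1).
#' @param q Recovery threshold fraction, in (0, 1).
#' @return Years to recovery.
#' @export
recovery_time_closed_form <- function(gp, survivor_fraction, q = 0.95) {
  if (!is.null(gp$seasonal)) stop("closed form applies to non-seasonal growth only")
  if (any(survivor_fraction <= 0)) stop("survivor fraction must be positive")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  s <- survivor_fraction
  t <- (1 / gp$r) * log(q * (1 - s) / (s * (1 - q)))
  pmax(t, 0)
}

#' Monte-Carlo distribution of years to population recovery
#'
#' Each run draws a kill fraction from the efficacy law, knocks the
#' population down to `K * (1 - kill)` on the control day, and grows it
#' forward under discrete-time logistic dynamics until it first reaches
#' `q * K`. Runs still below the threshold at `max_horizon` are counted in
#' `runs_not_recovered` and excluded from the moments with a warning.
#'
#' @param gp [growth_params()].
#' @param kd [kill_distribution()].
#' @param cfg [sim_config()].
#' @return Object of class `recovery_summary`: `mean_years`, `sd_years`,
#'   `quantiles` (2.5/50/97.5%), `runs_not_recovered`, `n_runs`, `q`, and
#'   the vector of per-run `years` (NA where not recovered).
#' @export
monte_carlo_recovery <- function(gp, kd, cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dt <- cfg$time_step / 365
  r_max <- if (is.null(gp$seasonal)) gp$r else gp$r * 365 / gp$seasonal$window_days
  if (r_max * dt >= 1) stop("time step too large: r * dt must be below 1")

  kills <- draw_kill(kd, cfg$n_runs)
  N <- gp$K * (1 - kills)
  years <- rep(NA_real_, cfg$n_runs)
  threshold <- cfg$q * gp$K

  done <- N >= threshold
  years[done] <- 0
  active <- which(!done)

  n_steps <- ceiling(cfg$max_horizon * 365 / cfg$time_step)
  step <- 0L
  while (length(active) > 0L && step < n_steps) {
    step <- step + 1L
    day <- (cfg$control_day + (step - 1L) * cfg$time_step) %% 365
    r_eff <- effective_rate(gp, day)
    if (r_eff > 0) {
      Na <- N[active]
      Na <- Na + r_eff * Na * (1 - Na / gp$K) * dt
      N[active] <- Na
      hit <- Na >= threshold
      if (any(hit)) {
        years[active[hit]] <- step * dt
        active <- active[!hit]
      }
    }
  }
  not_rec <- sum(is.na(years))
  if (not_rec > 0L) {
    warning(not_rec, " run(s) had not recovered within ", cfg$max_horizon,
            " years; excluded from summary moments")
  }
  rec <- years[!is.na(years)]
  structure(
    list(
      mean_years = mean(rec),
      sd_years = sd(rec),
      quantiles = quantile(rec, c(0.025, 0.5, 0.975), names = TRUE),
      runs_not_recovered = not_rec,
      n_runs = cfg$n_runs,
      q = cfg$q,
      years = years
    ),
    class = "recovery_summary"
  )
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf(
    "Recovery to %.0f%% of pre-control density: mean %.2f yr (SD %.2f), median %.2f yr\n",
    100 * x$q, x$mean_years, x$sd_years, x$quantiles[["50%"]]))
  if (x$runs_not_recovered > 0L) {
    cat(sprintf("  %d of %d runs not recovered within the horizon\n",
                x$runs_not_recovered, x$n_runs))
  }
  invisible(x)
}

#' Run the four standard recovery scenarios
#'
#' Simulates recovery under the cross of population state (pre-epidemic
#' growth rate `r_pre`, and post-epidemic at exactly half that rate) and
#' sowing treatment (each with its own efficacy law), in the fixed order
#' pre/strip, pre/broadcast, post/strip, post/broadcast. Each scenario uses
#' its own seed derived from `cfg$seed` so scenarios are independently
#' reproducible.
#'
#' @param r_pre Pre-epidemic instantaneous rate of increase, 1/yr.
#' @param kills Named list with `strip` and `broadcast`
#'   [kill_distribution()]s.
#' @param cfg [sim_config()].
#' @param K Carrying capacity (default 1).
#' @param seasonal Optional seasonal window passed to [growth_params()].
#' @return Named list of four `recovery_summary` objects:
#'   `pre_strip`, `pre_broadcast`, `post_strip`, `post_broadcast`.
#' @export
run_recovery_scenarios <- function(r_pre, kills, cfg = sim_config(), K = 1,
                                   seasonal = NULL) {
  if (is.null(kills$strip) || is.null(kills$broadcast)) {
    stop("kills must name 'strip' and 'broadcast' distributions")
  }
  grid <- list(
    pre_strip = list(r = r_pre, kd = kills$strip),
    pre_broadcast = list(r = r_pre, kd = kills$broadcast),
    post_strip = list(r = r_pre / 2, kd = kills$strip),
    post_broadcast = list(r = r_pre / 2, kd = kills$broadcast)
  )
  out <- vector("list", length(grid))
  names(out) <- names(grid)
  for (i in seq_along(grid)) {
    scen_cfg <- cfg
    if (!is.null(cfg$seed)) scen_cfg$seed <- cfg$seed + i - 1L
    gp <- growth_params(r = grid[[i]]$r, K = K, seasonal = seasonal)
    out[[i]] <- monte_carlo_recovery(gp, grid[[i]]$kd, scen_cfg)
  }
  out
}
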