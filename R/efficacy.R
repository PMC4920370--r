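#' Treatment-level kill summary
#'
#' Mean percentage kill across the replicates of one treatment, with the
#' sample standard deviation and a symmetric 95% confidence interval using
#' the Student t quantile, `mean +/- t(0.975, n - 1) * sd / sqrt(n)`. The
#' t quantile (rather than the normal) matters at the replicate counts
#' typical of field trials (n around 10).
#'
#' @param results Data frame of per-replicate results (as from
#'   [replicate_results()]), or a numeric vector of percentage kills.
#' @param treatment Treatment to summarise (`"strip"` or `"broadcast"`);
#'   ignored when `results` is a numeric vector.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list of class `treatment_summary`: `treatment`, `n`,
#'   `mean_kill`, `sd_kill`, `ci95` (lower, upper).
#' @export
treatment_summary <- function(results, treatment = NULL, conf_level = 0.95) {
  if (is.numeric(results)) {
    kills <- results
    trt <- if (is.null(treatment)) NA_character_ else treatment
  } else {
    if (is.null(treatment)) stop("treatment must be given for a results table")
    kills <- results$percent_kill[results$treatment == treatment]
    trt <- treatment
  }
  n <- length(kills)
  if (n < 2L) stop("cannot form CI: need at least 2 replicates")
  m <- mean(kills)
  s <- sd(kills)
  half <- qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
  structure(
    list(treatment = trt, n = n, mean_kill = m, sd_kill = s,
         ci95 = c(lower = m - half, upper = m + half)),
    class = "treatment_summary"
  )
}

#' @export
print.treatment_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, mean kill = %.1f%% (95%% CI %.1f; %.1f), SD = %.2f\n",
              x$treatment, x$n, x$mean_kill, x$ci95[["lower"]],
              x$ci95[["upper"]], x$sd_kill))
  invisible(x)
}

#' Replicate-weighted combined mean kill
#'
#' Pools treatment-level means into one overall mean, weighting each group
#' by its number of replicates: `sum(n_i * mean_i) / sum(n_i)`.
#'
#' @param summaries List of `treatment_summary` objects, or a list of lists
#'   each holding `mean_kill` and `n`.
#' @return Overall mean percentage kill.
#' @export
combined_mean <- function(summaries) {
  if (length(summaries) == 0L) stop("no summaries to combine")
  ns <- vapply(summaries, function(s) s$n, numeric(1))
  ms <- vapply(summaries, function(s) s$mean_kill, numeric(1))
  sum(ns * ms) / sum(ns)
}

#' Welch two-sample t-test on percentage kills
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, comparing the per-replicate kills of two
#' treatments. When both groups are constant and equal the statistic is 0
#' and the p-value 1 by convention.
#'
#' @param group_a,group_b Numeric vectors of percentage kills (each n >= 2).
#' @return A list of class `welch_result`: `t_stat`, `df`, `p_value`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 replicates")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(structure(list(t_stat = 0, df = NA_real_, p_value = 1),
                       class = "welch_result"))
    }
    stop("both groups constant with different means: t undefined")
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  structure(
    list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.2f, df = %.2f, P = %.2f\n", x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Logit transform with boundary adjustment
#'
#' Transforms proportions in (0, 1] to the logit scale, `log(y / (1 - y))`.
#' Proportions exactly equal to 1 would map to infinity; for those, `1 - y`
#' is replaced by the smallest non-zero `1 - y` observed in the input before
#' transforming, so kill proportions of exactly 100% stay on the scale of
#' the rest of the sample.
#'
#' @param proportions Numeric vector with all values in (0, 1].
#' @return Numeric vector of logits, same length.
#' @export
logit_adjusted <- function(proportions) {
  if (any(proportions <= 0)) stop("proportions must be positive")
  if (any(proportions > 1)) stop("proportions cannot exceed 1")
  comp <- 1 - proportions
  nz <- comp[comp > 0]
  at_one <- comp == 0
  if (any(at_one)) {
    if (length(nz) == 0L) stop("adjustment undefined: all proportions are 1")
    comp[at_one] <- min(nz)
  }
  log(proportions / comp)
}

#' Survivor regression: do more rabbits survive where more started?
#'
#' Ordinary least squares of log post-control index on log pre-control
#' index, treatment, and their interaction, an analysis of covariance
#' asking whether the number of survivors grows with the initial
#' population, and whether that relationship differs between sowing
#' treatments (which would indicate one treatment deployed too little bait
#' at high density). Blocks with a post-control index of zero are offset by
#' `zero_offset` before the log (half the smallest index a single sighting
#' on one of eight transect-nights could produce).
#'
#' @param results Per-replicate results table (from [replicate_results()]).
#' @param zero_offset Value added to zero post-control indices before the
#'   log transform; default `0.5 * 1/8`.
#' @return A list of class `survivor_fit`: `coefficients` (with standard
#'   errors), `anova` (sequential F-tests per term), and the underlying
#'   `lm` fit.
#' @export
survivor_model <- function(results, zero_offset = 0.5 / 8) {
  if (nrow(results) < 5L) stop("need at least 5 replicates")
  if (length(unique(results$treatment[!is.na(results$treatment)])) < 2L) {
    stop("both treatments must be present")
  }
  post <- results$post_index
  post[post == 0] <- post[post == 0] + zero_offset
  dat <- data.frame(
    log_post = log(post),
    log_pre = log(results$pre_index),
    treatment = factor(results$treatment)
  )
  fit <- lm(log_post ~ log_pre * treatment, data = dat)
  if (any(is.na(coef(fit)))) stop("collinear design: coefficients not estimable")
  ct <- summary(fit)$coefficients
  structure(
    list(
      coefficients = ct[, "Estimate"],
      std_errors = ct[, "Std. Error"],
      anova = anova(fit),
      fit = fit
    ),
    class = "survivor_fit"
  )
}

#' @export
print.survivor_fit <- function(x, ...) {
  cat("Survivors vs initial abundance (log-log ANCOVA)\n")
  print(round(cbind(estimate = x$coefficients, se = x$std_errors), 4))
  invisible(x)
}
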