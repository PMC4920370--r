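#' Design of a synthetic sowing trial
#'
#' Describes the replicated before-after spotlight-count design emulated by
#' the synthetic generator: block counts per treatment, transects and
#' nights per block, the range of true pre-control densities, the efficacy
#' law per treatment, and the count-noise structure. Defaults emulate a
#' semi-arid trial programme of 9 strip-sown and 10 broadcast blocks with
#' 4 transects surveyed on 2 consecutive nights before and after control,
#' pre-control means between roughly 10 and 155 rabbits per transect, and
#' kill laws fitted by moments to group means of 92.7% and 94.0%.
#'
#' Count noise has two layers: true per-transect abundance is negative
#' binomial around the block density (`transect_dispersion`, spatial
#' heterogeneity), and each night's count is negative binomial around that
#' abundance (`night_dispersion`, observation noise). The default
#' `night_dispersion` of 32 reproduces a night-to-night mean absolute
#' difference of about 18 rabbits at a pre-control mean of about 76.
#' Setting both dispersions to `Inf` switches off all sampling noise:
#' counts equal their (possibly non-integer) expectations, which with a
#' fixed kill law makes the estimated kill recover the true kill exactly.
#'
#' @param n_strip,n_broadcast Replicates per treatment (defaults 9, 10).
#' @param transects_per_block,nights Survey layout (defaults 4, 2).
#' @param pre_mean_range Range of true pre-control densities
#'   (rabbits/transect), drawn log-uniformly; default `c(10, 155)`.
#' @param kill_strip,kill_broadcast [kill_distribution()]s; defaults are
#'   moment fits at means 0.927/0.940 with variances back-derived from
#'   field confidence intervals (0.00128, 0.00387).
#' @param transect_dispersion,night_dispersion Negative-binomial size
#'   parameters (larger = less overdispersed; `Inf` = noise-free).
#' @param outlier_kill Optional kill fraction forced onto one broadcast
#'   block (e.g. `0.77`) to emulate an anomalous low-kill operation; off by
#'   default.
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(n_strip = 9, n_broadcast = 10,
                         transects_per_block = 4, nights = 2,
                         pre_mean_range = c(10, 155),
                         kill_strip = beta_from_moments(0.927, 0.00128),
                         kill_broadcast = beta_from_moments(0.940, 0.00387),
                         transect_dispersion = 10, night_dispersion = 32,
                         outlier_kill = NULL) {
  if (n_strip < 0 || n_broadcast < 0 || n_strip + n_broadcast < 1) {
    stop("need at least one block")
  }
  if (transects_per_block < 1 || nights < 1) stop("invalid survey layout")
  if (length(pre_mean_range) != 2L || any(pre_mean_range <= 0) ||
      pre_mean_range[1] > pre_mean_range[2]) {
    stop("pre_mean_range must be a positive increasing pair")
  }
  if (!is.null(outlier_kill) && (outlier_kill <= 0 || outlier_kill >= 1)) {
    stop("outlier kill must be in (0, 1)")
  }
  structure(
    list(n_strip = n_strip, n_broadcast = n_broadcast,
         transects_per_block = transects_per_block, nights = nights,
         pre_mean_range = pre_mean_range,
         kill_strip = kill_strip, kill_broadcast = kill_broadcast,
         transect_dispersion = transect_dispersion,
         night_dispersion = night_dispersion,
         outlier_kill = outlier_kill),
    class = "trial_design"
  )
}

# NB draw around mu with size k; k = Inf means no noise (returns mu).
rnbinom_mu <- function(n, mu, size) {
  if (is.infinite(size)) return(mu)
  out <- numeric(n)
  pos <- mu > 0
  out[pos] <- rnbinom(sum(pos), size = size, mu = mu[pos])
  out
}

#' Generate a synthetic sowing trial
#'
#' Draws one complete trial dataset under a [trial_design()]: for each
#' block a true pre-control density (log-uniform over the design range), a
#' true kill from the treatment's efficacy law, latent per-transect
#' abundances, and nightly counts before and after control. Post-control
#' latent abundance is a binomial thinning of the pre-control abundance by
#' the true kill. Returns both the observable count table and the latent
#' truths so that estimator calibration can be measured.
#'
#' @param design A [trial_design()].
#' @param seed Optional integer seed.
#' @return List with `counts` (a transect count table, see
#'   [validate_transect_counts()]) and `truth` (data frame of `block_id`,
#'   `treatment`, `true_pre_density`, `true_kill`).
#' @export
generate_trial <- function(design = trial_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  noise_free <- is.infinite(design$transect_dispersion) &&
    is.infinite(design$night_dispersion)
  blocks <- data.frame(
    block_id = c(sprintf("S%02d", seq_len(design$n_strip)),
                 sprintf("B%02d", seq_len(design$n_broadcast))),
    treatment = rep(c("strip", "broadcast"),
                    c(design$n_strip, design$n_broadcast)),
    stringsAsFactors = FALSE
  )
  nb <- nrow(blocks)
  lo <- log(design$pre_mean_range[1])
  hi <- log(design$pre_mean_range[2])
  blocks$true_pre_density <- exp(runif(nb, lo, hi))
  blocks$true_kill <- ifelse(
    blocks$treatment == "strip",
    draw_kill(design$kill_strip, nb),
    draw_kill(design$kill_broadcast, nb)
  )
  if (!is.null(design$outlier_kill)) {
    bcast <- which(blocks$treatment == "broadcast")
    if (length(bcast) == 0L) stop("outlier kill needs a broadcast block")
    blocks$true_kill[bcast[1L]] <- design$outlier_kill
  }

  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    D <- blocks$true_pre_density[b]
    k <- blocks$true_kill[b]
    nt <- design$transects_per_block
    # latent true abundance per transect (spatial heterogeneity)
    N_t <- rnbinom_mu(nt, rep(D, nt), design$transect_dispersion)
    # latent survivors: binomial thinning by the true kill
    S_t <- if (noise_free) N_t * (1 - k) else rbinom(nt, N_t, 1 - k)
    per_transect <- lapply(seq_len(nt), function(tr) {
      pre <- rnbinom_mu(design$nights, rep(N_t[tr], design$nights),
                        design$night_dispersion)
      post <- rnbinom_mu(design$nights, rep(S_t[tr], design$nights),
                         design$night_dispersion)
      data.frame(
        block_id = blocks$block_id[b],
        treatment = blocks$treatment[b],
        transect_id = tr,
        night = rep(seq_len(design$nights), 2L),
        period = rep(c("pre", "post"), each = design$nights),
        count = c(pre, post),
        stringsAsFactors = FALSE
      )
    })
    rows[[b]] <- do.call(rbind, per_transect)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  list(
    counts = validate_transect_counts(counts),
    truth = blocks
  )
}

#' Generate synthetic bait masses under a fragmentation model
#'
#' Bait is cut to a nominal mass but a fraction of pieces fragment during
#' aerial deployment. Each bait starts as an intact dice with mass
#' `Normal(intact_mean, intact_sd)` (truncated positive); with probability
#' `fragmentation_prob` only a `Beta(2, 2)`-distributed fraction of the
#' dice survives as the recovered piece. The defaults place roughly 46% of
#' pieces below 4 g, 36% at 4-6 g and 18% above 6 g, the size spectrum
#' observed on the ground after fixed-wing deployment of nominal 6 g dices.
#'
#' @param n Number of baits.
#' @param fragmentation_prob Probability a bait fragments (default 0.64;
#'   0 disables fragmentation).
#' @param intact_mean,intact_sd Intact dice mass distribution, g (defaults
#'   6 and 0.5).
#' @param fragment_shape Two positive shape parameters of the beta law for
#'   the surviving mass fraction (default `c(2, 2)`).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` positive masses, g.
#' @export
generate_bait_masses <- function(n, fragmentation_prob = 0.64,
                                 intact_mean = 6, intact_sd = 0.5,
                                 fragment_shape = c(2, 2), seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (fragmentation_prob < 0 || fragmentation_prob > 1) {
    stop("fragmentation probability must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  masses <- rnorm(n, intact_mean, intact_sd)
  while (any(masses <= 0)) {
    bad <- masses <= 0
    masses[bad] <- rnorm(sum(bad), intact_mean, intact_sd)
  }
  frag <- runif(n) < fragmentation_prob
  if (any(frag)) {
    masses[frag] <- masses[frag] *
      rbeta(sum(frag), fragment_shape[1], fragment_shape[2])
  }
  masses
}
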