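#' Define an aerial bait-sowing plan
#'
#' A sowing plan captures the geometry and loading of one aerial baiting
#' treatment: the sowing pattern (`strip` leaves unbaited gaps between
#' flight lines, `broadcast` covers the whole block), the bait application
#' rate averaged over the whole treated area, the flight-path spacing (FPS,
#' distance between successive flight lines), the width of the baited swath
#' laid along each line, the toxin mass fraction of the bait, and the mean
#' individual bait mass.
#'
#' @param pattern `"strip"` or `"broadcast"`.
#' @param sowing_rate Bait applied per treated hectare, kg/ha (whole-block
#'   average including any gaps).
#' @param fps Flight-path spacing, m.
#' @param swath Baited swath width, m. For broadcast sowing this defaults
#'   to `fps` (complete coverage) and must equal it.
#' @param toxin_conc Toxin mass fraction of the bait, e.g. `2e-4` for a
#'   0.02% w/w coating.
#' @param mean_bait_mass Mean mass of one bait, g.
#' @return An object of class `sowing_plan`.
#' @export
#' @examples
#' strip <- sowing_plan("strip", sowing_rate = 10, fps = 75, swath = 10)
#' broadcast <- sowing_plan("broadcast", sowing_rate = 30, fps = 25)
sowing_plan <- function(pattern = c("strip", "broadcast"), sowing_rate, fps,
                        swath = NULL, toxin_conc = 2e-4, mean_bait_mass = 6) {
  pattern <- match.arg(pattern)
  if (!is.numeric(fps) || fps <= 0) stop("flight-path spacing must be positive")
  if (is.null(swath)) {
    if (pattern == "broadcast") swath <- fps else stop("strip plan needs a swath width")
  }
  if (swath <= 0) stop("swath width must be positive")
  if (pattern == "strip" && swath > fps) {
    stop("strip swath cannot exceed the flight-path spacing")
  }
  if (pattern == "broadcast" && swath != fps) {
    stop("broadcast sowing requires swath = fps (complete coverage)")
  }
  if (!is.numeric(sowing_rate) || sowing_rate <= 0) stop("sowing rate must be positive")
  if (toxin_conc <= 0 || toxin_conc >= 1) stop("toxin concentration must be in (0, 1)")
  if (mean_bait_mass <= 0) stop("mean bait mass must be positive")
  structure(
    list(pattern = pattern, sowing_rate = sowing_rate, fps = fps,
         swath = swath, toxin_conc = toxin_conc,
         mean_bait_mass = mean_bait_mass),
    class = "sowing_plan"
  )
}

#' @export
print.sowing_plan <- function(x, ...) {
  cat(sprintf("%s sowing plan: %.4g kg/ha, FPS %.4g m, swath %.4g m\n",
              x$pattern, x$sowing_rate, x$fps, x$swath))
  cat(sprintf("  coverage %.1f%%, gap %.4g m\n",
              100 * area_fraction_baited(x), gap_width(x)))
  cat(sprintf("  within-swath density %.3g g/m2 = %.3g baits/m2 (at %.3g g/bait)\n",
              within_strip_density(x)[["g_per_m2"]],
              within_strip_density(x)[["baits_per_m2"]], x$mean_bait_mass))
  cat(sprintf("  toxin loading %.3g g/ha\n", toxin_per_ha(x)))
  invisible(x)
}

#' Fraction of the block that receives bait
#'
#' `swath / fps`, capped at 1. Broadcast plans return exactly 1 (complete
#' coverage, no unbaited gaps).
#'
#' @param plan A [sowing_plan()].
#' @return Scalar in (0, 1].
#' @export
area_fraction_baited <- function(plan) {
  min(plan$swath / plan$fps, 1)
}

#' Width of the unbaited gap between swaths
#'
#' `fps - swath`: the distance between the outer extremities of successive
#' baited swaths. Zero for broadcast sowing.
#'
#' @param plan A [sowing_plan()].
#' @return Gap width, m.
#' @export
gap_width <- function(plan) {
  max(plan$fps - plan$swath, 0)
}

#' Bait density within the baited swath
#'
#' Concentrating the whole-block sowing rate into the baited fraction of
#' the area gives the local density a foraging animal actually encounters
#' inside a swath: `g/m2 = (sowing_rate * 1000 / 10000) /
#' area_fraction_baited`, and baits per square metre by dividing by the
#' mean bait mass.
#'
#' @param plan A [sowing_plan()].
#' @return Named numeric vector with `g_per_m2` and `baits_per_m2`.
#' @export
within_strip_density <- function(plan) {
  if (plan$mean_bait_mass <= 0) stop("mean bait mass must be positive")
  g_m2 <- (plan$sowing_rate * 1000 / 1e4) / area_fraction_baited(plan)
  c(g_per_m2 = g_m2, baits_per_m2 = g_m2 / plan$mean_bait_mass)
}

#' Active toxin applied per hectare
#'
#' `sowing_rate * 1000 * toxin_conc`, grams of active ingredient per
#' treated hectare (whole-block average).
#'
#' @param plan A [sowing_plan()].
#' @return g active ingredient per hectare.
#' @export
toxin_per_ha <- function(plan) {
  plan$sowing_rate * 1000 * plan$toxin_conc
}

#' Bait mass size-class fractions
#'
#' Classifies individual bait masses into the field size classes
#' below 4 g, 4-6 g inclusive, and above 6 g, and returns the fraction in
#' each. Boundary masses (exactly 4 or 6 g) fall in the middle class.
#'
#' @param bait_masses Numeric vector of positive bait masses, g.
#' @return List of class `bait_mass_bins`: `fractions` (named, summing to
#'   1) and `n_baits`.
#' @export
mass_bins <- function(bait_masses) {
  if (length(bait_masses) == 0L) stop("no bait masses")
  if (any(bait_masses <= 0)) stop("bait masses must be positive")
  n <- length(bait_masses)
  f <- c(
    under_4g = sum(bait_masses < 4) / n,
    g4_to_6g = sum(bait_masses >= 4 & bait_masses <= 6) / n,
    over_6g = sum(bait_masses > 6) / n
  )
  structure(list(fractions = f, n_baits = n), class = "bait_mass_bins")
}

#' @export
print.bait_mass_bins <- function(x, ...) {
  cat(sprintf("n = %d baits: %.0f%% < 4 g, %.0f%% 4-6 g, %.0f%% > 6 g\n",
              x$n_baits, 100 * x$fractions[["under_4g"]],
              100 * x$fractions[["g4_to_6g"]], 100 * x$fractions[["over_6g"]]))
  invisible(x)
}

#' Read a sowing plan from a flat key-value config file
#'
#' Plan files are plain text, one `key = value` (or `key: value`) pair per
#' line, with units embedded in the key names to prevent unit mistakes:
#' `pattern`, `sowing_rate_kg_ha`, `fps_m`, `swath_m` (optional for
#' broadcast), `toxin_conc`, `mean_bait_mass_g`. Lines starting with `#`
#' are comments.
#'
#' @param path Path to the plan file.
#' @return A [sowing_plan()].
#' @export
read_sowing_plan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[=:]", perl = TRUE)
  bad <- vapply(kv, length, integer(1)) < 2L
  if (any(bad)) stop("malformed plan line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = ":"), character(1)))
  cfg <- setNames(as.list(vals), keys)
  num <- function(key, default = NULL) {
    if (!is.null(cfg[[key]])) as.numeric(cfg[[key]]) else default
  }
  if (is.null(cfg$pattern)) stop("plan file must set 'pattern'")
  sowing_plan(
    pattern = cfg$pattern,
    sowing_rate = num("sowing_rate_kg_ha"),
    fps = num("fps_m"),
    swath = num("swath_m"),
    toxin_conc = num("toxin_conc", 2e-4),
    mean_bait_mass = num("mean_bait_mass_g", 6)
  )
}
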