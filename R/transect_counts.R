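#' Read a spotlight transect count table
#'
#' Reads a CSV of night-time spotlight counts from a replicated
#' before-after baiting trial. Each row is one walked 800 m transect on one
#' night, either before (`pre`) or after (`post`) the control operation.
#'
#' @param path Path to a CSV file with header
#'   `block_id,treatment,transect_id,night,period,count`.
#' @return A validated data frame of transect counts with `treatment` and
#'   `period` as factors.
#' @export
read_transect_counts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_transect_counts(df)
}

#' Validate a transect count table
#'
#' Checks the schema and invariants of a spotlight count table: required
#' columns, non-negative counts, known treatment and period levels, and at
#' most one row per (block, transect, night, period) combination.
#'
#' @param df Data frame with columns `block_id`, `treatment`, `transect_id`,
#'   `night`, `period`, `count`.
#' @return The data frame, with `treatment` and `period` converted to
#'   factors with levels `strip`/`broadcast` and `pre`/`post`.
#' @export
validate_transect_counts <- function(df) {
  needed <- c("block_id", "treatment", "transect_id", "night", "period", "count")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("count table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no counts")
  if (!all(df$treatment %in% c("strip", "broadcast"))) {
    stop("treatment must be 'strip' or 'broadcast'")
  }
  if (!all(df$period %in% c("pre", "post"))) {
    stop("period must be 'pre' or 'post'")
  }
  if (!is.numeric(df$count) || any(is.na(df$count)) || any(df$count < 0)) {
    stop("counts must be non-negative numbers")
  }
  key <- paste(df$block_id, df$transect_id, df$night, df$period, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (block, transect, night, period) combinations")
  }
  one_trt <- tapply(df$treatment, df$block_id, function(x) length(unique(x)))
  if (any(one_trt > 1L)) stop("a block cannot receive two treatments")
  df$treatment <- factor(df$treatment, levels = c("strip", "broadcast"))
  df$period <- factor(df$period, levels = c("pre", "post"))
  df
}

#' Replicate-level spotlight count index
#'
#' Collapses the counts for one block and one period into a single relative
#' abundance index: counts are first averaged over nights within each
#' transect, then across transects. For a balanced block (all transects
#' surveyed the same number of nights) this equals the plain mean of all
#' counts; under missing nights the two-stage average keeps each transect
#' equally weighted.
#'
#' @param counts Data frame of transect counts for a single block and a
#'   single period (columns `transect_id`, `count`; `period` and `block_id`
#'   are checked for homogeneity if present).
#' @return Mean rabbits per transect (non-negative scalar).
#' @export
#' @examples
#' x <- data.frame(transect_id = rep(1:4, each = 2), night = rep(1:2, 4),
#'                 count = c(10, 14, 20, 20, 5, 7, 30, 30))
#' replicate_index(x)  # 17
replicate_index <- function(counts) {
  if (is.null(counts) || nrow(counts) == 0L) stop("no counts")
  if (!is.null(counts$period) && length(unique(as.character(counts$period))) > 1L) {
    stop("counts mix pre- and post-control periods")
  }
  if (!is.null(counts$block_id) && length(unique(counts$block_id)) > 1L) {
    stop("counts come from more than one block")
  }
  if (any(counts$count < 0)) stop("counts must be non-negative")
  per_transect <- tapply(counts$count, counts$transect_id, mean)
  mean(per_transect)
}

#' Percentage kill from pre- and post-control indices
#'
#' The relative reduction in the spotlight count index,
#' `100 * (pre - post) / pre`. Negative values indicate the index rose after
#' control; values cannot exceed 100.
#'
#' @param pre_index Pre-control index, must be positive.
#' @param post_index Post-control index, non-negative.
#' @return Percentage kill (scalar, at most 100).
#' @export
percent_kill <- function(pre_index, post_index) {
  if (any(pre_index <= 0)) stop("undefined kill: pre-control index must be positive")
  if (any(post_index < 0)) stop("post-control index must be non-negative")
  100 * (pre_index - post_index) / pre_index
}

#' Per-replicate kill estimates from a count table
#'
#' Applies [replicate_index()] to every block and period and combines the
#' results into one row per treatment block: pre- and post-control indices
#' and the percentage kill.
#'
#' @param counts Validated transect count table (see
#'   [validate_transect_counts()]).
#' @return Data frame with columns `block_id`, `treatment`, `pre_index`,
#'   `post_index`, `percent_kill`, one row per block.
#' @export
replicate_results <- function(counts) {
  counts <- validate_transect_counts(counts)
  blocks <- unique(counts$block_id)
  rows <- lapply(blocks, function(b) {
    sub <- counts[counts$block_id == b, , drop = FALSE]
    pre <- sub[sub$period == "pre", , drop = FALSE]
    post <- sub[sub$period == "post", , drop = FALSE]
    if (nrow(pre) == 0L || nrow(post) == 0L) {
      stop("block ", b, " lacks a pre or post survey")
    }
    pre_i <- replicate_index(pre)
    post_i <- replicate_index(post)
    data.frame(
      block_id = b,
      treatment = as.character(sub$treatment[1L]),
      pre_index = pre_i,
      post_index = post_i,
      percent_kill = percent_kill(pre_i, post_i),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$treatment <- factor(out$treatment, levels = c("strip", "broadcast"))
  rownames(out) <- NULL
  out
}
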