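# Rescale a vector to exact sample mean m and sample SD s.
scale_to_moments <- function(x, m, s) {
  m + (x - mean(x)) / sd(x) * s
}

# Welch statistic from summary moments (independent hand formula).
welch_from_moments <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df)
}

# Continuous-time logistic density at time t from start fraction n0 (K = 1).
logistic_closed_form <- function(n0, r, t) {
  1 / (1 + exp(-r * t) * (1 / n0 - 1))
}

# A small balanced count table: 2 strip + 2 broadcast blocks, exact counts.
make_counts <- function(pre = c(40, 80, 60, 100), kill = c(0.9, 0.95, 0.92, 0.88)) {
  stopifnot(length(pre) == 4, length(kill) == 4)
  blocks <- c("S1", "S2", "B1", "B2")
  trt <- c("strip", "strip", "broadcast", "broadcast")
  rows <- list()
  for (b in 1:4) {
    for (tr in 1:4) {
      for (p in c("pre", "post")) {
        cnt <- if (p == "pre") pre[b] else pre[b] * (1 - kill[b])
        rows[[length(rows) + 1L]] <- data.frame(
          block_id = blocks[b], treatment = trt[b], transect_id = tr,
          night = 1:2, period = p, count = cnt, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
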