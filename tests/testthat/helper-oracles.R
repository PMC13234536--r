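# Independent brute-force oracles used across the suite.

# Flex peaks by splitting the stream at samples < resting and taking run maxima
# (samples strictly above resting only); a trailing run not terminated by a
# below-resting sample emits nothing.
flex_oracle <- function(v, resting) {
  below <- v < resting
  grp <- cumsum(below)
  peaks <- integer(0)
  for (g in unique(grp)) {
    idx <- which(grp == g & !below)
    if (!length(idx)) next
    if (max(idx) == length(v)) next # still open at end-of-stream
    if (any(v[idx] > resting)) peaks <- c(peaks, max(v[idx]))
  }
  peaks
}

# Zone by linear scan over intervals [lower, upper)
zone_oracle <- function(peak, thresholds) {
  b <- zone_bounds(thresholds)
  for (i in seq_len(nrow(b))) {
    if (peak >= b$lower[i] && peak < b$upper[i]) return(i)
  }
  NA_integer_
}

# Tie-corrected Kruskal-Wallis H from the rank-sum formula
kw_oracle <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  t <- table(x)
  h / (1 - sum(t^3 - t) / (n^3 - n))
}

# Mann-Whitney U as the pair count (a > b, ties half)
u_oracle <- function(a, b) {
  cmp <- outer(a, b, function(x, y) (x > y) + 0.5 * (x == y))
  sum(cmp)
}

# Spearman rho via average ranks
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

random_threshold_set <- function() {
  resting <- sample(0:200, 1)
  k <- sample(1:5, 1)
  mins <- sort(sample((resting + 1):1023, k))
  threshold_set(mins, resting = resting)
}
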