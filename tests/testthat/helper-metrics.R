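# Metric helpers for recovery scoring.

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxidx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxidx - expected)
}

cosine_sim <- function(u, v) {
  if (all(u == 0) || all(v == 0)) return(NA_real_)
  sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

# Intersection-over-union of two pixel masks.
iou <- function(a, b) sum(a & b) / sum(a | b)
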