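# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive each quantity from its definition with
# plain loops, independent of the package's vectorised implementations.

# direct evaluation of the MTD formula: z-scored first derivatives multiplied
# pairwise, then a w-sample moving average starting at each valid time point
mtd_oracle <- function(x, i, j, w) {
  dt <- apply(x, 2, diff)
  dz_i <- dt[, i] / sd(dt[, i])
  dz_j <- dt[, j] / sd(dt[, j])
  prod <- dz_i * dz_j
  nv <- length(prod) - w + 1
  vapply(seq_len(nv), function(t) mean(prod[t:(t + w - 1)]), 0)
}

# term-by-term signed modularity with the asymmetric positive/negative
# weighting and degree-based null
q_oracle <- function(W, memb, gamma = 1) {
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  sp <- rowSums(Wp)
  sn <- rowSums(Wn)
  vp <- sum(sp)
  vn <- sum(sn)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] != memb[j]) next
    if (vp > 0) q <- q + (Wp[i, j] - gamma * sp[i] * sp[j] / vp) / vp
    if (vn > 0) q <- q - (Wn[i, j] - gamma * sn[i] * sn[j] / vn) / (vp + vn)
  }
  q
}

# every set partition of n elements, as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx, i) {
    if (i > n) {
      out[[length(out) + 1]] <<- a
      return(invisible())
    }
    for (v in seq_len(mx + 1)) rec(c(a, v), max(mx, v), i + 1)
  }
  rec(integer(0), 0L, 1L)
  out
}

# exhaustive two-sample KS statistic by scanning both empirical CDFs
ks_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(p) abs(mean(x <= p) - mean(y <= p)), 0))
}

# random symmetric signed graph
random_signed_graph <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- rnorm(sum(ut))
  W + t(W)
}

# two disconnected positive cliques of size k each
two_cliques <- function(k = 3, weight = 1) {
  n <- 2 * k
  W <- matrix(0, n, n)
  W[seq_len(k), seq_len(k)] <- weight
  W[(k + 1):n, (k + 1):n] <- weight
  diag(W) <- 0
  W
}

# tiny cohort configuration used where full atlas scale is unnecessary
tiny_config <- function(...) {
  sim_config(n_subjects = 2, n_cortical = 20, n_cerebellar = 6, n_blocks = 3,
             ...)
}
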