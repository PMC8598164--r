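# Independent oracles used to cross-check the package's numerics. These
# deliberately avoid the code paths they verify.

# Exhaustive profiled grid search for the single-guide NB selection
# coefficient: for every beta on the grid the guide's baseline abundance is
# profiled out by vectorized Newton on log(mu), and the best grid point by
# log-likelihood is returned.
grid_fit_beta <- function(y, cond, sf, alpha, lo = -8, hi = 8, step = 0.001) {
  grid <- seq(lo, hi, by = step)
  r <- 1 / alpha
  d <- as.numeric(cond)
  u <- rep(log(max(mean(y / sf), 0.5)), length(grid))
  ym <- matrix(rep(y, each = length(grid)), nrow = length(grid))
  for (it in 1:60) {
    m <- exp(outer(u, log(sf), "+") + log(2) * outer(grid, d))
    W1 <- ym - m * (ym + r) / (m + r)
    W2 <- m * r * (ym + r) / (m + r)^2
    u <- u + rowSums(W1) / pmax(rowSums(W2), 1e-12)
  }
  m <- exp(outer(u, log(sf), "+") + log(2) * outer(grid, d))
  ll <- rowSums(dnbinom(ym, size = r, mu = m, log = TRUE))
  grid[which.max(ll)]
}

# Naive running-sum enrichment score: walk the full list step by step.
es_brute <- function(stats, set, p = 1) {
  stats <- sort(stats, decreasing = TRUE)
  hit <- names(stats) %in% set
  nh <- sum(hit)
  N <- length(stats)
  nr <- sum(abs(stats[hit])^p)
  run <- 0
  trace <- numeric(N)
  for (i in seq_len(N)) {
    run <- if (hit[i]) {
      run + if (nr > 0) abs(stats[i])^p / nr else 1 / nh
    } else {
      run - 1 / (N - nh)
    }
    trace[i] <- run
  }
  hi <- max(trace); lo <- min(trace)
  unname(if (hi >= -lo - 1e-12) hi else lo)  # ties resolve positive
}

# Exact upper-tail binomial probability by enumerating all 2^n equally
# weighted success/failure outcomes (p0 = 0.5 only).
binom_tail_enum <- function(x, n) {
  stopifnot(n <= 12)
  outcomes <- expand.grid(rep(list(0:1), n))
  mean(rowSums(outcomes) >= x)
}
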