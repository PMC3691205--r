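# Independent oracles used to pin expected values. These deliberately avoid
# the package's own code paths.

# Exact two-sided rank-sum p-value by enumeration of all C(m+n, m)
# assignments of the pooled mid-ranks to the case side.
exact_rank_sum_p <- function(case_values, control_values) {
  m <- length(case_values)
  pooled <- c(case_values, control_values)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  sums <- combn(r, m, sum)
  lo <- mean(sums <= w_obs)
  hi <- mean(sums >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Benjamini-Hochberg step-up computed by hand from the definition.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Clopper-Pearson bounds from the binomial tail definition, found
# numerically (no beta quantiles).
cp_tail_oracle <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  c(lower = lower, upper = upper)
}

# All-pairs brute-force clustering oracle: link any two peaks of different
# samples that pass the pairwise tolerance test (ppm at the pair's mean
# mass, time window at the pair's mean time), then take connected
# components. Agrees with the greedy algorithm on well-separated instances.
brute_cluster_oracle <- function(peaks, params = clustering_params()) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (peaks$sample_id[i] == peaks$sample_id[j]) next
      mm <- (peaks$mass[i] + peaks$mass[j]) / 2
      if (abs(peaks$mass[i] - peaks$mass[j]) / mm * 1e6 >
            mass_tolerance(mm, params)) next
      tt <- (peaks$time[i] + peaks$time[j]) / 2
      if (abs(peaks$time[i] - peaks$time[j]) >
            time_window_fraction(tt, params) * tt / 2) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Canonical partition signature: set of member-key sets, order-free.
partition_signature <- function(keys, assignment) {
  sig <- split(keys, assignment)
  sig <- lapply(sig, sort)
  sort(unname(vapply(sig, paste, character(1), collapse = "|")))
}

# A small, well-separated multi-sample peak set: peptide spacing is much
# larger than the tolerances, jitter much smaller, so greedy and
# connected-component clustering must coincide.
separated_instance <- function(seed, n_peptides = 40, n_samples = 5,
                               dropout = 0.2) {
  set.seed(seed)
  mass <- 10^seq(log10(900), log10(5000), length.out = n_peptides)
  time <- seq(20, 44, length.out = n_peptides)[sample(n_peptides)]
  grid <- expand.grid(pep = seq_len(n_peptides),
                      sample = seq_len(n_samples))
  keep <- runif(nrow(grid)) > dropout
  grid <- grid[keep, ]
  tibble::tibble(
    sample_id = sprintf("S%02d", grid$sample),
    peak_id = grid$pep,
    mass = mass[grid$pep] * (1 + rnorm(nrow(grid), 0, 3e-6)),
    time = time[grid$pep] + rnorm(nrow(grid), 0, 0.02),
    amplitude = 10^rnorm(nrow(grid), 3, 0.4))
}
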