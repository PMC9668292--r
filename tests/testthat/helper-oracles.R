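# Independent oracles and generators used across the suite. Oracles are
# deliberately naive (nested loops, exhaustive matching) so they share no
# code path with the implementation they check.

# Brute-force EMG synthesis: loop over discharges and add the shifted
# per-channel waveform sample by sample.
oracle_synthesize <- function(templates, spikes, fs) {
  d <- dim(templates$waveforms)
  L <- d[3]
  K <- round(spikes$duration * fs)
  x <- matrix(0, nrow = K, ncol = d[2])
  for (tr in spikes$trains) {
    i <- match(tr$mu_id, templates$mu_ids)
    for (t0 in tr$discharge_times) {
      k0 <- floor(t0 * fs) + 1L
      for (c in seq_len(d[2])) {
        for (l in seq_len(L)) {
          k <- k0 + l - 1L
          if (k <= K) x[k, c] <- x[k, c] + templates$waveforms[i, c, l]
        }
      }
    }
  }
  x
}

# Maximum-cardinality bipartite matching within tolerance (igraph),
# the optimal counterpart of the greedy matcher.
oracle_max_matching <- function(a, b, tol) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  edges <- integer(0)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (abs(a[i] - b[j]) <= tol + 1e-12) {
        edges <- c(edges, i, length(a) + j)
      }
    }
  }
  if (length(edges) == 0L) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, length(a)), rep(TRUE, length(b))),
    edges = edges
  )
  igraph::max_bipartite_match(g)$matching_size
}

# Brute-force pooled forward-recurrence histogram: explicit loops over
# every reference discharge and target MU.
oracle_cross_histogram <- function(reference_set, target_set, bin = 0.001,
                                   max_lag = 0.1) {
  n_bins <- ceiling(max_lag / bin)
  counts <- integer(n_bins)
  for (rt in reference_set$trains) {
    for (t0 in rt$discharge_times) {
      for (tt in target_set$trains) {
        later <- tt$discharge_times[tt$discharge_times > t0]
        if (length(later)) {
          lag <- min(later) - t0
          if (lag < max_lag) {
            counts[floor(lag / bin) + 1L] <- counts[floor(lag / bin) + 1L] + 1L
          }
        }
      }
    }
  }
  counts
}

# Random quasi-regular spike train: gamma-distributed ISIs around a mean
# rate, with a hard refractory floor so matched pairs are unambiguous.
random_train <- function(mu_id, rate, duration, cv = 0.2,
                        refractory = 0.005) {
  shape <- 1 / cv^2
  tt <- numeric(0)
  t <- stats::rgamma(1, shape, shape * rate)
  while (t < duration) {
    tt <- c(tt, t)
    t <- t + max(stats::rgamma(1, shape, shape * rate), refractory)
  }
  spike_train(mu_id, tt, duration)
}

random_train_set <- function(n, rate = 14, duration = 10, cv = 0.2) {
  spike_train_set(lapply(seq_len(n), function(i) {
    random_train(i, rate * stats::runif(1, 0.8, 1.2), duration, cv)
  }), duration = duration)
}

# Perturb a train: jitter + random drops and insertions, for matcher tests.
perturb_train <- function(train, jitter_sd = 2e-4, p_drop = 0.05,
                          p_add = 0.05) {
  tt <- train$discharge_times
  keep <- stats::runif(length(tt)) > p_drop
  tt <- tt[keep] + stats::rnorm(sum(keep), 0, jitter_sd)
  n_add <- stats::rbinom(1, length(train$discharge_times), p_add)
  tt <- sort(c(tt, stats::runif(n_add, 0, train$duration)))
  tt <- tt[tt >= 0 & tt < train$duration]
  ok <- c(TRUE, diff(tt) >= 2e-3)   # keep well-separated for the oracle
  spike_train(train$mu_id, tt[ok], train$duration)
}
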