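test_that("rate split sends faster units to R1 and keeps everyone", {
  mk <- function(id, rate) {
    spike_train(id, seq(0.05, 9.95, length.out = rate * 10), 10)
  }
  s <- spike_train_set(lapply(seq_along(c(10, 12, 14, 16)), function(i) {
    mk(i, c(10, 12, 14, 16)[i])
  }))
  halves <- split_by_rate(s)
  expect_setequal(vapply(halves$R1$trains, `[[`, integer(1), "mu_id"),
                  c(3L, 4L))
  expect_setequal(vapply(halves$R2$trains, `[[`, integer(1), "mu_id"),
                  c(1L, 2L))

  ## odd pool: extra unit goes to R2
  s5 <- spike_train_set(lapply(1:5, function(i) mk(i, 10 + i)))
  h5 <- split_by_rate(s5)
  expect_equal(length(h5$R1), 2L)
  expect_equal(length(h5$R2), 3L)
  expect_equal(length(h5$R1) + length(h5$R2), 5L)

  same <- spike_train_set(lapply(1:4, function(i) mk(i, 12)))
  expect_warning(ht <- split_by_rate(same), "equal")
  expect_setequal(vapply(ht$R1$trains, `[[`, integer(1), "mu_id"),
                  c(1L, 2L))
  expect_error(split_by_rate(spike_train_set(list(mk(1, 10)))), "at least 2")
})

test_that("forward recurrence counts first subsequent discharges only", {
  ref <- spike_train_set(list(spike_train(1, 0.0, 1)), duration = 1)
  tgt <- spike_train_set(list(spike_train(2, c(0.005, 0.050), 1)),
                         duration = 1)
  h <- pooled_cross_histogram(ref, tgt)
  expect_equal(sum(h$counts), 1L)
  expect_equal(which(h$counts == 1L), 6L)     # bin [5, 6) ms

  none <- spike_train_set(list(spike_train(2, 0.5, 1)), duration = 1)
  ref2 <- spike_train_set(list(spike_train(1, 0.9, 1)), duration = 1)
  h2 <- pooled_cross_histogram(ref2, none)
  expect_equal(sum(h2$counts), 0L)

  ## simultaneous discharges are excluded but logged
  sim <- spike_train_set(list(spike_train(2, c(0.0, 0.010), 1)),
                         duration = 1)
  h3 <- pooled_cross_histogram(ref, sim)
  expect_equal(h3$n_simultaneous, 1L)
  expect_equal(which(h3$counts == 1L), 11L)   # falls through to 10 ms

  expect_error(pooled_cross_histogram(ref, ref), "disjoint")
})

test_that("pooled cross-histogram equals the brute-force oracle", {
  set.seed(37)
  for (i in 1:5) {
    ref <- random_train_set(2, rate = 12, duration = 4)
    tgt <- spike_train_set(lapply(3:5, function(id) {
      random_train(id, 12, 4)
    }), duration = 4)
    h <- pooled_cross_histogram(ref, tgt)
    expect_identical(h$counts, oracle_cross_histogram(ref, tgt))
    ## each (reference, partner) pair contributes at most one count
    expect_lte(sum(h$counts),
               h$n_reference_discharges * h$n_target_mus)
  }
})

test_that("histogram mass declines beyond the mean inter-pulse interval", {
  s <- simulate_if_pool(if_model_params(n_neurons = 30, duration = 15),
                        seed = 41)
  halves <- split_by_rate(s)
  h <- pooled_cross_histogram(halves$R1, halves$R2)
  mean_ipi_ms <- 1000 / mean(discharge_rates(s))
  centres <- h$bin_edges[-length(h$bin_edges)] + 0.5
  expect_gt(mean(h$counts[centres < mean_ipi_ms]),
            mean(h$counts[centres > mean_ipi_ms]))
})

test_that("dip localization picks the minimum and respects ties", {
  mk_hist <- function(counts) {
    structure(list(bin_edges = seq(0, length(counts)), counts = counts,
                   normalized = counts / sum(counts),
                   direction = "R1->R2",
                   n_reference_discharges = sum(counts),
                   n_target_mus = 1L, n_simultaneous = 0L, bin_ms = 1),
              class = "cross_histogram")
  }
  counts <- rep(100L, 60)
  counts[15:17] <- c(60L, 20L, 60L)
  d <- find_dip(mk_hist(counts))
  expect_equal(d$dip_ms, 15.5)
  expect_true(d$significant)

  expect_warning(df <- find_dip(mk_hist(rep(50L, 60))), "flat")
  expect_equal(df$dip_ms, 5.5)
  expect_false(df$significant)
  expect_error(find_dip(mk_hist(counts), search_window = c(200, 300)),
               "window")
})

test_that("KS comparison around the dip behaves at its limits", {
  mk_hist <- function(counts) {
    structure(list(bin_edges = seq(0, length(counts)), counts = counts,
                   normalized = counts / (sum(counts)),
                   direction = "x", n_reference_discharges = sum(counts),
                   n_target_mus = 1L, n_simultaneous = 0L, bin_ms = 1),
              class = "cross_histogram")
  }
  a_counts <- rep(100L, 60)
  a_counts[11:20] <- 10:19                # shallow window
  b_counts <- rep(100L, 60)
  b_counts[11:20] <- seq(300L, 480L, by = 20L)  # much denser window
  a <- mk_hist(a_counts)
  k <- ks_compare(a, a, center = 15)
  expect_equal(k$statistic, 0)
  expect_equal(k$p_value, 1)

  b <- mk_hist(b_counts)                  # disjoint normalized support
  k2 <- ks_compare(a, b, center = 15)
  expect_equal(k2$statistic, 1)
  expect_lt(k2$p_value, 0.05)

  expect_error(ks_compare(a, b, center = 2), "support")
})
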