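make_emg <- function(x, fs = 10240) multichannel_emg(x, sampling_rate = fs)

test_that("preprocess removes DC and preserves the passband", {
  fs <- 10240
  t <- seq_len(fs) / fs
  x <- cbind(5 + 0 * t, sin(2 * pi * 1000 * t))
  out <- preprocess_emg(make_emg(x))
  expect_lt(abs(mean(out$samples[, 1])), 1e-6)
  ## 1-kHz tone amplitude preserved within ripple (interior samples)
  mid <- 2000:8000
  expect_equal(sd(out$samples[mid, 2]), sd(x[mid, 2]), tolerance = 0.01)
  zero <- preprocess_emg(make_emg(matrix(0, 2048, 2)))
  expect_true(all(zero$samples == 0))
  expect_error(preprocess_emg(make_emg(x), highpass_hz = 6000), "Nyquist")
})

test_that("extension stacks delayed channel copies", {
  x <- matrix(rnorm(200 * 3), ncol = 3)
  ext <- extend_observation(make_emg(x), R = 4)
  expect_equal(nrow(ext$matrix), 3L * 5L)
  ## brute-force shift oracle on every (channel, delay) row
  for (c in 1:3) {
    for (r in 0:4) {
      row <- ext$matrix[(c - 1L) * 5L + r + 1L, ]
      expected <- c(rep(0, r), x[seq_len(200 - r), c])
      expect_identical(row, expected)
    }
  }
  ext0 <- extend_observation(make_emg(x), R = 0)
  expect_identical(ext0$matrix, t(x))
  expect_error(extend_observation(make_emg(x), R = -1), "R must")
})

test_that("whitening yields identity covariance and an exact inverse", {
  set.seed(1)
  mix <- matrix(rnorm(16), 4) %*% matrix(rnorm(4 * 5000), 4)
  ext <- extend_observation(make_emg(t(mix)), R = 0)
  w <- whiten_observation(ext)
  Z <- w$matrix
  C <- tcrossprod(Z) / ncol(Z)
  expect_equal(C, diag(nrow(Z)), tolerance = 1e-6)
  ## stored inverse reconstructs the centred input
  back <- w$unwhitening %*% Z + w$row_means
  expect_equal(back, ext$matrix, tolerance = 1e-6)
})

test_that("duplicated channels reduce the retained subspace", {
  set.seed(2)
  x <- matrix(rnorm(3000 * 3), ncol = 3)
  x <- cbind(x, x[, 1])                 # exact duplicate channel
  w <- whiten_observation(extend_observation(make_emg(x), R = 0))
  expect_equal(w$retained, 3L)
  expect_error(
    whiten_observation(extend_observation(make_emg(matrix(0, 100, 2)), 0)),
    "zero")
})

test_that("PNR behaves at its limit cases", {
  s <- numeric(1000)
  s[c(100, 300, 700)] <- 1
  expect_equal(compute_pnr(s, c(100L, 300L, 700L)), 200)  # capped at ceiling
  flat <- rep(1, 1000)
  expect_equal(compute_pnr(flat, c(100L, 300L)), 0)
  expect_error(compute_pnr(s, integer(0)), "undefined")
})

test_that("segmentation separates bimodal peaks and enforces refractoriness", {
  fs <- 10240
  s <- numeric(fs)
  big <- seq(500, fs - 500, by = 700)
  small <- big + 350
  s[big] <- 1
  s[small] <- 0.2
  seg <- segment_source(s, fs)
  expect_setequal(seg$discharge_samples, big)

  expect_equal(segment_source(rep(3, 1000), fs)$discharge_samples,
               integer(0))
  expect_error(segment_source(numeric(0), fs), "empty")

  ## two peaks 2 ms apart: only the larger survives the refractory gate
  s2 <- numeric(fs)
  s2[c(1000, 1000 + 20)] <- c(1, 0.9)
  s2[seq(3000, 9000, by = 700)] <- 1
  seg2 <- segment_source(s2, fs)
  expect_true(1000 %in% seg2$discharge_samples)
  expect_false(1020 %in% seg2$discharge_samples)
})

test_that("noise-free mixtures decompose to perfect pulse trains", {
  p <- if_model_params(n_neurons = 5, duration = 5)
  truth <- simulate_if_pool(p, seed = 3)
  tpl <- generate_muap_templates(5, n_channels = 12, seed = 11)
  emg <- synthesize_emg(tpl, truth, noise_rms = 0)
  dec <- ckc_decompose(preprocess_emg(emg), R = 10, max_sources = 30,
                       pnr_accept_db = 20, seed = 1)
  expect_gte(length(dec), 4L)
  v <- validate_against_truth(truth, as_spike_train_set(dec, 5), dec)
  expect_true(all(v$RoA == 100))
  expect_gte(length(unique(v$mu_ref)), 4L)

  ## deflation: no two accepted sources share >= 75% of discharges
  if (length(dec) >= 2) {
    dset <- as_spike_train_set(dec, 5)
    groups <- find_duplicates(dset, 0.75, 5e-4, align_max_lag = 0.01)
    expect_equal(length(groups), length(dec))
  }
})

test_that("accuracy degrades monotonically with synthetic noise", {
  p <- if_model_params(n_neurons = 4, duration = 4)
  tpl <- generate_muap_templates(4, n_channels = 10, seed = 31)
  noise_grid <- c(0, 8, 40)
  med <- matrix(NA_real_, nrow = 10, ncol = 3)
  for (sd_i in 1:10) {
    truth <- simulate_if_pool(p, seed = 100 + sd_i)
    for (ni in seq_along(noise_grid)) {
      emg <- synthesize_emg(tpl, truth, noise_rms = noise_grid[ni],
                            seed = sd_i)
      dec <- ckc_decompose(preprocess_emg(emg), R = 8, max_sources = 15,
                           pnr_accept_db = 10, min_discharges = 20,
                           seed = 1)
      v <- validate_against_truth(truth, as_spike_train_set(dec, 4), dec)
      med[sd_i, ni] <- if (nrow(v)) {
        ## score every truth MU; missed MUs count 0
        per_mu <- vapply(1:4, function(id) {
          r <- v$RoA[v$mu_ref == id]
          if (length(r)) max(r) else 0
        }, numeric(1))
        median(per_mu)
      } else 0
    }
  }
  m <- apply(med, 2, median)
  ## non-increasing within one rank swap
  expect_true(m[1] >= m[2] - 1e-9 || m[2] >= m[3] - 1e-9)
  expect_gte(m[1], m[3])
})

test_that("decomposition rejects inputs smaller than the extended dimension", {
  small <- make_emg(matrix(rnorm(50 * 4), ncol = 4))
  expect_error(ckc_decompose(small, R = 20), "extended dimension")
})
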