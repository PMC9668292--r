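tr <- function(times, id = 1, dur = 10) spike_train(id, times, dur)

test_that("matching within tolerance produces the stated counts", {
  m <- match_trains(tr(c(1.0, 2.0)), tr(c(1.0004, 2.0), 2))
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))

  m2 <- match_trains(tr(1.0), tr(1.001, 2))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 1L, 1L))

  m3 <- match_trains(tr(numeric(0)), tr(1.0, 2))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0L, 1L, 0L))

  expect_error(match_trains(tr(1), tr(1, 2), tolerance = -1), "tolerance")
})

test_that("match_result bookkeeping invariants hold", {
  set.seed(3)
  for (i in 1:20) {
    a <- random_train(1, 14, 5)
    b <- perturb_train(a)
    m <- match_trains(a, b)
    expect_equal(m$tp, nrow(m$matched_pairs))
    expect_equal(m$tp + m$fn, length(a$discharge_times))
    expect_equal(m$tp + m$fp, length(b$discharge_times))
  }
})

test_that("RoA, sensitivity and precision follow their definitions", {
  m <- list(tp = 90, fp = 5, fn = 5, tolerance = 5e-4,
            matched_pairs = matrix(0, 90, 2))
  class(m) <- "match_result"
  expect_equal(roa(m), 90)
  sp <- sensitivity_precision(m)
  expect_equal(unname(sp["sensitivity"]), 100 * 90 / 95)
  expect_equal(unname(sp["precision"]), 100 * 90 / 95)

  perfect <- list(tp = 100, fp = 0, fn = 0, tolerance = 5e-4,
                  matched_pairs = matrix(0, 100, 2))
  class(perfect) <- "match_result"
  expect_equal(roa(perfect), 100)
  expect_equal(unname(sensitivity_precision(perfect)), c(100, 100))

  zero <- list(tp = 0, fp = 1, fn = 3, tolerance = 5e-4,
               matched_pairs = matrix(0, 0, 2))
  class(zero) <- "match_result"
  expect_equal(roa(zero), 0)

  none <- list(tp = 0, fp = 0, fn = 0, tolerance = 5e-4,
               matched_pairs = matrix(0, 0, 2))
  class(none) <- "match_result"
  expect_error(roa(none), "undefined")
})

test_that("RoA is symmetric and bounded by sensitivity and precision", {
  set.seed(7)
  for (i in 1:30) {
    a <- random_train(1, runif(1, 8, 20), 5)
    b <- perturb_train(random_train(2, runif(1, 8, 20), 5),
                       jitter_sd = 5e-4, p_drop = 0.2, p_add = 0.2)
    mab <- match_trains(a, b)
    mba <- match_trains(b, a)
    expect_equal(roa(mab), roa(mba), tolerance = 1e-12)
    if (mab$tp + mab$fn > 0 && mab$tp + mab$fp > 0) {
      sp <- sensitivity_precision(mab)
      expect_lte(roa(mab), min(sp) + 1e-12)
    }
  }
})

test_that("greedy matching equals optimal bipartite matching on refractory trains", {
  set.seed(11)
  tol <- 5e-4
  for (i in 1:200) {
    a <- random_train(1, runif(1, 8, 25), 2)
    b <- perturb_train(a, jitter_sd = 3e-4, p_drop = 0.15, p_add = 0.15)
    m <- match_trains(a, b, tolerance = tol)
    opt <- oracle_max_matching(a$discharge_times, b$discharge_times, tol)
    expect_equal(m$tp, opt)
  }
})

test_that("duplicate grouping follows the agreement fraction", {
  a <- random_train(1, 14, 10)
  same <- spike_train(2, a$discharge_times, 10)
  g <- find_duplicates(spike_train_set(list(a, same)))
  expect_equal(length(g), 1L)
  expect_setequal(g[[1]], c(1L, 2L))

  half <- spike_train(3, a$discharge_times[seq(1, length(a$discharge_times),
                                               by = 2)] + 0.01, 10)
  g2 <- find_duplicates(spike_train_set(list(a, half)))
  expect_equal(length(g2), 2L)
})

test_that("independent trains show only chance-level agreement", {
  set.seed(21)
  s <- random_train_set(10, rate = 14, duration = 20)
  g <- find_duplicates(s, tolerance = 5e-4)
  expect_equal(length(g), 10L)     # all singletons
  fr <- c()
  for (i in 1:9) {
    for (j in (i + 1):10) {
      m <- match_trains(s$trains[[i]], s$trains[[j]])
      fr <- c(fr, 100 * m$tp / min(m$tp + m$fn, m$tp + m$fp))
    }
  }
  expect_lt(median(fr), 11)        # chance-synchronization regime
})

test_that("spike-triggered averaging recovers templates exactly without noise", {
  tpl <- generate_muap_templates(1, n_channels = 6, L = 41, seed = 13)
  fs <- tpl$sampling_rate
  truth <- spike_train_set(list(random_train(1, 12, 4)), duration = 4)
  emg <- synthesize_emg(tpl, truth, noise_rms = 0)
  sta <- spike_triggered_average(emg, truth$trains[[1]], support = 0.020)
  L_sta <- dim(sta$waveforms)[3]
  centre <- (L_sta + 1) / 2
  ## template starts at the discharge sample = STA centre
  for (c in 1:6) {
    got <- sta$waveforms[1, c, centre:(centre + 40)]
    expect_equal(got, tpl$waveforms[1, c, ], tolerance = 1e-12)
  }
})

test_that("cross-triggered averages of unrelated activity stay at noise level", {
  set.seed(17)
  tpl <- generate_muap_templates(1, n_channels = 6, L = 41, seed = 14)
  truth <- spike_train_set(list(random_train(1, 12, 6)), duration = 6)
  emg <- synthesize_emg(tpl, truth, noise_rms = 5, seed = 2)
  unrelated <- random_train(2, 12, 6)
  sta <- spike_triggered_average(emg, unrelated)
  n <- attr(sta, "n_used")
  peak_emg <- max(abs(tpl$waveforms))
  ## averaged unrelated activity is far below the action-potential scale
  expect_lt(max(abs(sta$waveforms)), 0.2 * peak_emg)
})

test_that("STA noise residual scales like sigma over sqrt(n)", {
  set.seed(19)
  tpl <- generate_muap_templates(1, n_channels = 4, L = 31, seed = 15)
  sigma <- 20
  truth <- spike_train_set(list(random_train(1, 14, 8)), duration = 8)
  emg0 <- synthesize_emg(tpl, truth, noise_rms = 0)
  emg <- synthesize_emg(tpl, truth, noise_rms = sigma, seed = 4)
  sta0 <- spike_triggered_average(emg0, truth$trains[[1]])
  sta <- spike_triggered_average(emg, truth$trains[[1]])
  resid <- sta$waveforms - sta0$waveforms
  n <- attr(sta, "n_used")
  expect_equal(sqrt(mean(resid^2)), sigma / sqrt(n), tolerance = 0.25)
})

test_that("suprathreshold channel counting uses a strict inequality", {
  wf <- array(0, dim = c(1, 3, 11))
  wf[1, 1, ] <- seq(-5, 5)            # p2p = 10
  wf[1, 2, ] <- seq(-6, 6, length.out = 11)
  sta <- structure(list(waveforms = wf, sampling_rate = 10240,
                        mu_ids = 1L,
                        geometry = electrode_array_geometry(3)),
                   class = "muap_templates")
  expect_equal(count_suprathreshold_channels(sta, baseline_rms = 1,
                                             factor = 10), 1L)
  zero <- sta
  zero$waveforms[] <- 0
  expect_equal(count_suprathreshold_channels(zero, 1), 0L)
})

test_that("baseline noise RMS matches the analytic filter gain", {
  fs <- 10240
  ## analytic power gain of the zero-lag (squared-magnitude) band-pass
  bf <- signal::butter(3, c(100, 4400) / (fs / 2), type = "pass")
  H <- signal::freqz(bf$b, bf$a, n = 4096)
  gain <- sqrt(mean(Mod(H$h)^4))
  set.seed(23)
  sigma <- 10
  emg <- multichannel_emg(matrix(rnorm(fs * 4 * 4, 0, sigma), ncol = 4))
  got <- baseline_noise_rms(emg, segment = 4)
  expect_equal(got, sigma * gain, tolerance = 0.05)

  zero <- multichannel_emg(matrix(0, fs * 4, 2))
  expect_equal(baseline_noise_rms(zero), 0)
  short <- multichannel_emg(matrix(0, 100, 2))
  expect_error(baseline_noise_rms(short), "shorter")
})

test_that("a target baseline level is recovered from scaled noise", {
  fs <- 10240
  bf <- signal::butter(3, c(100, 4400) / (fs / 2), type = "pass")
  H <- signal::freqz(bf$b, bf$a, n = 4096)
  gain <- sqrt(mean(Mod(H$h)^4))
  set.seed(29)
  target <- 15.8
  emg <- multichannel_emg(matrix(rnorm(fs * 4 * 8, 0, target / gain),
                                 ncol = 8))
  expect_equal(baseline_noise_rms(emg), target, tolerance = 0.4)
})

test_that("doublet detection flags short preceding intervals", {
  iv <- c(70, 70, 10, 130, 70) / 1000
  tt <- cumsum(c(0.1, iv))
  d <- detect_doublets(spike_train(1, tt, 1))
  expect_equal(d, 4L)          # the discharge ending the 10-ms interval

  reg <- spike_train(1, seq(0.1, 0.9, by = 0.07), 1)
  expect_length(detect_doublets(reg), 0L)

  expect_warning(out <- detect_doublets(spike_train(1, c(0.1, 0.2), 1)),
                 "few")
  expect_length(out, 0L)
})
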