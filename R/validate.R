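## One-to-one greedy matching of two sorted time vectors: candidate pairs
## within `tol` are accepted in ascending order of |time difference|,
## each time used at most once. Returns a two-column matrix (time_a,
## time_b) of matched pairs.
greedy_match_pairs <- function(a, b, tol) {
  if (length(a) == 0L || length(b) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("time_a", "time_b"))))
  }
  ## each a can only match the b immediately before/after it
  lo <- findInterval(a, b)
  cand_i <- c(seq_along(a), seq_along(a))
  cand_j <- c(lo, lo + 1L)
  ok <- cand_j >= 1L & cand_j <= length(b)
  cand_i <- cand_i[ok]
  cand_j <- cand_j[ok]
  d <- abs(a[cand_i] - b[cand_j])
  ok <- d <= tol + 1e-12
  cand_i <- cand_i[ok]
  cand_j <- cand_j[ok]
  d <- d[ok]
  if (length(d) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("time_a", "time_b"))))
  }
  ord <- order(d, cand_i)
  used_a <- logical(length(a))
  used_b <- logical(length(b))
  out_i <- integer(0)
  out_j <- integer(0)
  for (k in ord) {
    i <- cand_i[k]
    j <- cand_j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      out_i <- c(out_i, i)
      out_j <- c(out_j, j)
    }
  }
  cbind(time_a = a[out_i], time_b = b[out_j])
}

## Constant-lag alignment: search a lag grid for the shift of `test`
## that maximizes matches with `reference` within tol.
estimate_alignment_lag <- function(reference, test, tol,
                                   max_lag = 0.01) {
  if (length(reference) == 0L || length(test) == 0L || max_lag <= 0) {
    return(0)
  }
  lags <- seq(-max_lag, max_lag, by = tol / 2)
  counts <- vapply(lags, function(l) {
    greedy_match_count(reference, test + l, tol)
  }, integer(1))
  best <- max(counts)
  cand <- lags[counts == best]
  cand[which.min(abs(cand))]
}

#' Match the discharges of two spike trains
#'
#' One-to-one greedy nearest-neighbour matching within a time tolerance.
#' A reference discharge matched by a test discharge within the tolerance
#' is a true positive (TP); unmatched test discharges are false positives
#' (FP); unmatched reference discharges are false negatives (FN).
#'
#' @param reference,test [spike_train] objects on the same time base.
#' @param tolerance Matching tolerance in seconds (default 0.0005, i.e.
#'   +/-0.5 ms).
#' @param align If `TRUE`, compensate a constant lag between the two
#'   trains (chosen to maximize matches over `[-max_lag, max_lag]`)
#'   before matching, as when comparing decompositions whose timing
#'   reference differs.
#' @param max_lag Lag search bound in seconds (default 0.01).
#' @return Object of class `match_result`: list with `tp`, `fp`, `fn`,
#'   `tolerance`, `matched_pairs` (two-column matrix), `lag` (applied
#'   alignment lag).
#' @export
match_trains <- function(reference, test, tolerance = 0.0005,
                         align = FALSE, max_lag = 0.01) {
  stopifnot(inherits(reference, "spike_train"),
            inherits(test, "spike_train"))
  if (tolerance < 0) stop("tolerance must be >= 0")
  a <- reference$discharge_times
  b <- test$discharge_times
  lag <- if (align) estimate_alignment_lag(a, b, tolerance, max_lag) else 0
  pairs <- greedy_match_pairs(a, b + lag, tolerance)
  if (nrow(pairs)) pairs[, "time_b"] <- pairs[, "time_b"] - lag
  tp <- nrow(pairs)
  structure(
    list(tp = tp, fp = length(b) - tp, fn = length(a) - tp,
         tolerance = tolerance, matched_pairs = pairs, lag = lag),
    class = "match_result"
  )
}

#' Rate of agreement between two discharge patterns
#'
#' `RoA = 100 * TP / (TP + FN + FP)`: the percentage of discharges common
#' to both patterns among all discharges of either.
#'
#' @param m A [match_trains()] result.
#' @return RoA in percent, in `[0, 100]`.
#' @export
roa <- function(m) {
  stopifnot(inherits(m, "match_result"))
  den <- m$tp + m$fn + m$fp
  if (den == 0) stop("RoA undefined: no discharges in either train")
  100 * m$tp / den
}

#' Sensitivity and precision of a discharge-pattern comparison
#'
#' Sensitivity `= 100 * TP / (TP + FN)` (fraction of reference discharges
#' recovered); precision `= 100 * TP / (TP + FP)` (fraction of test
#' discharges that are correct).
#'
#' @param m A [match_trains()] result.
#' @return Named numeric vector `c(sensitivity =, precision =)` in
#'   percent.
#' @export
sensitivity_precision <- function(m) {
  stopifnot(inherits(m, "match_result"))
  if (m$tp + m$fn == 0 || m$tp + m$fp == 0) {
    stop("sensitivity/precision undefined: zero denominator")
  }
  c(sensitivity = 100 * m$tp / (m$tp + m$fn),
    precision = 100 * m$tp / (m$tp + m$fp))
}

#' Group duplicate discharge patterns within a set
#'
#' Two trains are considered the same motor unit when more than
#' `agreement_fraction` of the smaller train's discharges coincide within
#' `tolerance`. Grouping is the transitive closure of this pairwise
#' relation.
#'
#' @param set A non-empty [spike_train_set].
#' @param agreement_fraction Shared-discharge fraction above which two
#'   trains are duplicates (default 0.75).
#' @param tolerance Coincidence tolerance in seconds (default 1e-3, the
#'   within-decomposition merging rule; use 5e-4 for cross-procedure
#'   comparison).
#' @param align_max_lag If positive, allow a constant lag up to this many
#'   seconds when computing the shared fraction (default 0).
#' @return List of integer vectors of `mu_id`s, one per group.
#' @export
find_duplicates <- function(set, agreement_fraction = 0.75,
                            tolerance = 1e-3, align_max_lag = 0) {
  stopifnot(inherits(set, "spike_train_set"))
  n <- length(set$trains)
  if (n == 0L) stop("set must be nonempty")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sh <- shared_fraction(set$trains[[i]]$discharge_times,
                            set$trains[[j]]$discharge_times,
                            tolerance, align_max_lag)
      if (sh > agreement_fraction) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- vapply(set$trains, `[[`, integer(1), "mu_id")
  unname(lapply(split(ids, roots), as.integer))
}

#' Spike-triggered average of multichannel EMG
#'
#' Averages, per channel, EMG windows centred on the discharges of one
#' motor unit, recovering the unit's multichannel action-potential
#' template. Discharges whose window does not fit inside the record are
#' skipped and counted.
#'
#' @param emg A [multichannel_emg].
#' @param train A [spike_train] on the same time base.
#' @param support Window length in seconds, centred on the discharge
#'   (default 0.020, i.e. -10 to +10 ms).
#' @return A `muap_templates` object with one MU whose `L` is the window
#'   length in samples; attributes `n_used` and `n_skipped` count the
#'   contributing and skipped discharges.
#' @export
spike_triggered_average <- function(emg, train, support = 0.020) {
  stopifnot(inherits(emg, "multichannel_emg"),
            inherits(train, "spike_train"), support > 0)
  fs <- emg$sampling_rate
  half <- floor(support * fs / 2)
  L <- 2L * half + 1L
  K <- nrow(emg$samples)
  centre <- floor(train$discharge_times * fs) + 1L
  ok <- centre - half >= 1L & centre + half <= K
  if (!any(ok)) stop("no discharge has full support inside the record")
  idx <- centre[ok]
  acc <- matrix(0, nrow = L, ncol = emg$n_channels)
  for (k in idx) {
    acc <- acc + emg$samples[(k - half):(k + half), , drop = FALSE]
  }
  avg <- acc / length(idx)
  wf <- array(0, dim = c(1L, emg$n_channels, L))
  wf[1L, , ] <- t(avg)
  out <- structure(
    list(waveforms = wf, sampling_rate = fs, mu_ids = train$mu_id,
         geometry = emg$geometry),
    class = "muap_templates"
  )
  attr(out, "n_used") <- sum(ok)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Count channels on which a template exceeds the noise floor
#'
#' Number of channels where the peak-to-peak amplitude of the averaged
#' action potential is strictly greater than `factor` times the baseline
#' noise RMS.
#'
#' @param sta A `muap_templates` object with one MU (e.g. from
#'   [spike_triggered_average()]).
#' @param baseline_rms Baseline noise RMS in uV.
#' @param factor Multiplier on the baseline (default 10).
#' @return Integer channel count.
#' @export
count_suprathreshold_channels <- function(sta, baseline_rms, factor = 10) {
  stopifnot(inherits(sta, "muap_templates"), baseline_rms >= 0)
  wf <- sta$waveforms
  stopifnot(dim(wf)[1] == 1L)
  pp <- apply(wf[1L, , , drop = FALSE], 2L, function(w) max(w) - min(w))
  sum(pp > factor * baseline_rms)
}

#' Baseline noise of a resting EMG recording
#'
#' Band-pass filters the signal (100-4400 Hz, third-order Butterworth,
#' zero-lag) and returns the average across channels of the RMS of a
#' segment of stated length.
#'
#' @param emg_rest A [multichannel_emg] recorded at rest.
#' @param segment Segment length in seconds (default 4).
#' @param band Passband in Hz (default `c(100, 4400)`).
#' @return Average RMS in the units of the input (uV).
#' @export
baseline_noise_rms <- function(emg_rest, segment = 4,
                               band = c(100, 4400)) {
  stopifnot(inherits(emg_rest, "multichannel_emg"))
  fs <- emg_rest$sampling_rate
  n <- round(segment * fs)
  if (nrow(emg_rest$samples) < n) stop("record shorter than the segment")
  nyq <- fs / 2
  bf <- signal::butter(3, pmin(band, nyq * 0.999) / nyq, type = "pass")
  x <- emg_rest$samples[seq_len(n), , drop = FALSE]
  rms <- vapply(seq_len(ncol(x)), function(c) {
    y <- signal::filtfilt(bf, x[, c])
    sqrt(mean(y^2))
  }, numeric(1))
  mean(rms)
}

#' Detect doublet discharges in a spike train
#'
#' Flags discharges whose preceding inter-spike interval is below
#' `ratio` times the mean interval. The mean is refined once by
#' excluding the flagged intervals and re-applying the rule.
#'
#' @param train A [spike_train] with at least 3 discharges.
#' @param ratio Interval threshold as a fraction of the mean ISI
#'   (default 0.3).
#' @return Integer indices (into `discharge_times`) of the second
#'   discharge of each doublet; empty (with a warning) when the train is
#'   too short.
#' @export
detect_doublets <- function(train, ratio = 0.3) {
  stopifnot(inherits(train, "spike_train"), ratio > 0)
  tt <- train$discharge_times
  if (length(tt) < 3L) {
    warning("too few discharges to detect doublets")
    return(integer(0))
  }
  iv <- diff(tt)
  flag <- iv < ratio * mean(iv)
  if (any(flag) && any(!flag)) {
    flag <- iv < ratio * mean(iv[!flag])   # one refinement pass
  }
  which(flag) + 1L
}
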