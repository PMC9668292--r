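#' Surrogate spike trains with uniformly distributed discharge times
#'
#' Control condition (i): for each MU, the same number of discharges is
#' redrawn uniformly over the record, destroying all temporal structure
#' while conserving the discharge rate.
#'
#' @param set A non-empty [spike_train_set].
#' @param seed Integer seed.
#' @return A [spike_train_set] with provenance `"surrogate-uniform"`.
#' @export
surrogate_uniform <- function(set, seed = NULL) {
  stopifnot(inherits(set, "spike_train_set"))
  if (length(set$trains) == 0L) stop("set must be nonempty")
  with_seed(seed, {
    trains <- lapply(set$trains, function(tr) {
      n <- length(tr$discharge_times)
      if (n == 0L) return(tr)
      res <- tr$time_resolution
      ## draw on the sample grid, then de-duplicate and top up so the
      ## discharge count is conserved at the stated time resolution
      n_slots <- floor(tr$duration / res)
      idx <- unique(sort(sample.int(n_slots, n)))
      while (length(idx) < n) {
        extra <- sample.int(n_slots, n - length(idx))
        idx <- unique(sort(c(idx, extra)))
      }
      spike_train(tr$mu_id, (idx - 1L) * res, tr$duration, res)
    })
    spike_train_set(trains, duration = set$duration,
                    provenance = "surrogate-uniform")
  })
}

#' Surrogate spike trains with equal inter-pulse intervals
#'
#' Control condition (ii): each MU discharges perfectly periodically with
#' interval `duration / count`, anchored at the first original discharge
#' time modulo the interval. Discharge count and mean rate are conserved;
#' interval variability is removed entirely.
#'
#' @param set A non-empty [spike_train_set].
#' @return A [spike_train_set] with provenance `"surrogate-equal-ipi"`.
#' @export
surrogate_equal_ipi <- function(set) {
  stopifnot(inherits(set, "spike_train_set"))
  if (length(set$trains) == 0L) stop("set must be nonempty")
  trains <- lapply(set$trains, function(tr) {
    n <- length(tr$discharge_times)
    if (n <= 1L) return(tr)
    interval <- tr$duration / n
    phase <- tr$discharge_times[1L] %% interval
    tt <- phase + interval * (seq_len(n) - 1L)
    tt <- pmin(tt, tr$duration - tr$time_resolution)
    spike_train(tr$mu_id, tt, tr$duration, tr$time_resolution)
  })
  spike_train_set(trains, duration = set$duration,
                  provenance = "surrogate-equal-ipi")
}

#' Surrogate spike trains shifted as a whole
#'
#' Control condition (iii): each MU's whole train is shifted by a single
#' uniform draw in `[0, max_shift]` (a different shift per MU, the same
#' for all discharges of that MU). Shifting is circular modulo the record
#' duration so the discharge count is conserved; the inter-spike-interval
#' multiset is preserved except at the wrap point.
#'
#' @param set A non-empty [spike_train_set].
#' @param max_shift Maximum shift in seconds (default 0.070).
#' @param seed Integer seed.
#' @return A [spike_train_set] with provenance `"surrogate-shift"`.
#' @export
surrogate_shift <- function(set, max_shift = 0.070, seed = NULL) {
  stopifnot(inherits(set, "spike_train_set"))
  if (length(set$trains) == 0L) stop("set must be nonempty")
  if (max_shift < 0) stop("max_shift must be >= 0")
  with_seed(seed, {
    trains <- lapply(set$trains, function(tr) {
      n <- length(tr$discharge_times)
      shift <- runif(1, 0, max_shift)
      if (n == 0L) return(tr)
      tt <- sort((tr$discharge_times + shift) %% tr$duration)
      ## circular wrap can land two discharges within one sample; nudge
      res <- tr$time_resolution
      if (length(tt) > 1L) {
        for (k in 2:length(tt)) {
          if (tt[k] - tt[k - 1L] < res) tt[k] <- tt[k - 1L] + res
        }
        tt <- tt[tt < tr$duration]
      }
      spike_train(tr$mu_id, tt, tr$duration, res)
    })
    spike_train_set(trains, duration = set$duration,
                    provenance = "surrogate-shift")
  })
}

#' Inject doublet discharges into spike trains
#'
#' A doublet is a second action potential following a discharge at an
#' interval below 30% of the mean inter-spike interval. This inserts
#' extra discharges after randomly chosen reference discharges, at
#' intervals drawn uniformly from `interval_range`. The default range of
#' 7.0 to 22.1 ms covers physiologically observed doublets.
#'
#' @param set A non-empty [spike_train_set].
#' @param rate Expected fraction of discharges that receive a doublet
#'   (default 0.01).
#' @param interval_range Two-element numeric, doublet interval bounds in
#'   seconds (default `c(0.0070, 0.0221)`). Must lie within
#'   `(0, 0.3 * mean ISI)` for every train.
#' @param seed Integer seed.
#' @return The modified [spike_train_set]; attribute `injected` is a
#'   data frame with columns `mu_id` and `time` of the inserted
#'   discharges.
#' @export
inject_doublets <- function(set, rate = 0.01,
                            interval_range = c(0.0070, 0.0221),
                            seed = NULL) {
  stopifnot(inherits(set, "spike_train_set"), rate >= 0,
            length(interval_range) == 2L)
  if (length(set$trains) == 0L) stop("set must be nonempty")
  if (interval_range[1] <= 0 || interval_range[2] < interval_range[1]) {
    stop("interval_range must be positive and increasing")
  }
  for (tr in set$trains) {
    iv <- isi(tr)
    if (length(iv) && interval_range[2] >= 0.3 * mean(iv)) {
      stop(sprintf(
        "interval_range exceeds 30%% of the mean ISI for MU %d", tr$mu_id))
    }
  }
  with_seed(seed, {
    injected <- list()
    trains <- lapply(set$trains, function(tr) {
      tt <- tr$discharge_times
      n <- length(tt)
      if (n < 2L || rate == 0) return(tr)
      k <- rbinom(1L, n, rate)
      if (k == 0L) return(tr)
      refs <- sort(sample.int(n, k))
      gaps <- runif(k, interval_range[1], interval_range[2])
      new_t <- tt[refs] + gaps
      new_t <- new_t[new_t < tr$duration]
      tt2 <- sort(unique(c(tt, new_t)))
      ## drop insertions that violate the sample-grid spacing
      res <- tr$time_resolution
      ok <- c(TRUE, diff(tt2) >= res)
      tt2 <- tt2[ok]
      added <- setdiff(tt2, tt)
      if (length(added)) {
        injected[[length(injected) + 1L]] <<-
          data.frame(mu_id = tr$mu_id, time = added)
      }
      spike_train(tr$mu_id, tt2, tr$duration, res)
    })
    out <- spike_train_set(trains, duration = set$duration,
                           provenance = set$provenance)
    attr(out, "injected") <- if (length(injected)) {
      do.call(rbind, injected)
    } else {
      data.frame(mu_id = integer(), time = numeric())
    }
    out
  })
}
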