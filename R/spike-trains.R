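#' Construct a motor-unit spike train
#'
#' A spike train holds the discharge times of one motor unit (MU) over a
#' recording of known duration. Times are in seconds on the interval
#' `[0, duration)` and must be strictly increasing with a minimum
#' inter-discharge interval of one sample at `time_resolution`.
#'
#' @param mu_id Integer label of the motor unit.
#' @param discharge_times Numeric vector of discharge times in seconds,
#'   strictly increasing, all in `[0, duration)`. May be empty.
#' @param duration Recording duration in seconds.
#' @param time_resolution Time base in seconds (default one sample at
#'   10,240 Hz).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(mu_id, discharge_times, duration,
                        time_resolution = 1 / 10240) {
  stopifnot(length(mu_id) == 1L, is.numeric(duration), duration > 0,
            time_resolution > 0)
  discharge_times <- as.numeric(discharge_times)
  if (anyNA(discharge_times)) {
    stop("discharge_times must not contain NA")
  }
  if (length(discharge_times) > 0L) {
    if (any(discharge_times < 0) || any(discharge_times >= duration)) {
      stop("discharge_times must lie in [0, duration)")
    }
    if (is.unsorted(discharge_times, strictly = TRUE)) {
      stop("discharge_times must be strictly increasing")
    }
    d <- diff(discharge_times)
    if (length(d) && min(d) < time_resolution - 1e-12) {
      stop("minimum inter-discharge interval is below time_resolution")
    }
  }
  structure(
    list(mu_id = as.integer(mu_id),
         discharge_times = discharge_times,
         duration = as.numeric(duration),
         time_resolution = as.numeric(time_resolution)),
    class = "spike_train"
  )
}

#' Construct a set of spike trains sharing one time base
#'
#' @param trains List of [spike_train] objects with equal durations and
#'   unique `mu_id`s.
#' @param duration Common duration in seconds; defaults to the duration of
#'   the first train.
#' @param provenance Tag recording how the set was produced, one of
#'   `"simulated"`, `"surrogate-uniform"`, `"surrogate-equal-ipi"`,
#'   `"surrogate-shift"`, `"decomposed"`, `"file"`.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, duration = NULL,
                            provenance = c("simulated", "surrogate-uniform",
                                           "surrogate-equal-ipi",
                                           "surrogate-shift", "decomposed",
                                           "file")) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(trains))
  if (!all(vapply(trains, inherits, logical(1), "spike_train"))) {
    stop("all elements of `trains` must be spike_train objects")
  }
  if (is.null(duration)) {
    if (length(trains) == 0L) stop("duration required for an empty set")
    duration <- trains[[1L]]$duration
  }
  durs <- vapply(trains, `[[`, numeric(1), "duration")
  if (length(durs) && any(abs(durs - duration) > 1e-9)) {
    stop("all member trains must share the set duration")
  }
  ids <- vapply(trains, `[[`, integer(1), "mu_id")
  if (anyDuplicated(ids)) stop("mu_id must be unique within a set")
  structure(
    list(trains = trains, duration = as.numeric(duration),
         provenance = provenance),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> MU %d: %d discharges over %.3f s (%.2f pps)\n",
              x$mu_id, length(x$discharge_times), x$duration,
              length(x$discharge_times) / x$duration))
  invisible(x)
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- vapply(x$trains, function(tr) length(tr$discharge_times), integer(1))
  cat(sprintf(
    "<spike_train_set> %d MUs over %.3f s (%s); mean rate %.2f pps\n",
    length(x$trains), x$duration, x$provenance,
    if (length(n)) mean(n) / x$duration else NA_real_))
  invisible(x)
}

#' @export
length.spike_train_set <- function(x) length(x$trains)

#' Mean discharge rate of each train in a set
#'
#' @param set A [spike_train_set].
#' @return Named numeric vector of rates in pulses per second; names are
#'   `mu_id`s.
#' @export
discharge_rates <- function(set) {
  stopifnot(inherits(set, "spike_train_set"))
  r <- vapply(set$trains,
              function(tr) length(tr$discharge_times) / tr$duration,
              numeric(1))
  names(r) <- vapply(set$trains, `[[`, integer(1), "mu_id")
  r
}

#' Inter-spike intervals of a train
#'
#' @param train A [spike_train].
#' @return Numeric vector of inter-spike intervals in seconds.
#' @export
isi <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  diff(train$discharge_times)
}

#' Keep only the motor units active over the whole interval
#'
#' Population analyses (coherence, cross-histograms) consider only MUs
#' that discharged for the entire selected interval. A train qualifies if
#' it has at least `min_count` discharges and its first and last
#' discharges fall within `edge` seconds of the record limits.
#'
#' @param set A [spike_train_set].
#' @param edge Margin in seconds at each end of the record (default 1 s).
#' @param min_count Minimum number of discharges (default 50, the cutoff
#'   below which discharge-rate estimates are unreliable).
#' @return The filtered [spike_train_set].
#' @export
filter_active <- function(set, edge = 1, min_count = 50L) {
  stopifnot(inherits(set, "spike_train_set"))
  keep <- vapply(set$trains, function(tr) {
    tt <- tr$discharge_times
    length(tt) >= min_count && tt[1L] <= edge &&
      tt[length(tt)] >= tr$duration - edge
  }, logical(1))
  spike_train_set(set$trains[keep], duration = set$duration,
                  provenance = set$provenance)
}

#' Binarize a spike train at a given sampling rate
#'
#' Represents the discharge pattern as a vector of 0s and 1s at time
#' resolution `1/fs`, with a 1 at each sample containing a discharge.
#' Two discharges falling in the same sample are counted once, with a
#' warning.
#'
#' @param train A [spike_train].
#' @param fs Sampling rate in Hz (default 10,240).
#' @return Integer vector of length `round(duration * fs)`.
#' @export
binarize <- function(train, fs = 10240) {
  stopifnot(inherits(train, "spike_train"), fs > 0)
  n <- round(train$duration * fs)
  v <- integer(n)
  if (length(train$discharge_times)) {
    idx <- floor(train$discharge_times * fs) + 1L
    idx <- pmin(idx, n)
    if (anyDuplicated(idx)) {
      warning("discharges collided within one sample; counted once")
      idx <- unique(idx)
    }
    v[idx] <- 1L
  }
  v
}

#' Cumulative discharge pattern of a group of motor units
#'
#' Element-wise sum of the binarized discharge patterns of all trains in
#' the set: the pooled output of the group, whose coherence with another
#' group reflects their common synaptic input.
#'
#' @param subset A non-empty [spike_train_set].
#' @param fs Sampling rate in Hz.
#' @return Integer vector of per-sample discharge counts.
#' @export
cumulative_train <- function(subset, fs = 10240) {
  stopifnot(inherits(subset, "spike_train_set"))
  if (length(subset$trains) == 0L) stop("subset must be nonempty")
  out <- integer(round(subset$duration * fs))
  for (tr in subset$trains) {
    out <- out + binarize(tr, fs)
  }
  out
}
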