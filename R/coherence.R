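## Welch magnitude-squared coherence between two equally long vectors:
## nonoverlapping windows of `win` samples, Hanning taper, per-window
## mean removal, transform length `nfft` (zero padding when nfft > win).
## Returns list(frequency, coherence, n_segments).
welch_coherence <- function(x, y, fs, win, nfft) {
  K <- min(length(x), length(y))
  n_seg <- K %/% win
  if (n_seg < 1L) stop("signal shorter than one window")
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))  # Hanning
  sxx <- syy <- numeric(nfft)
  sxy <- complex(nfft)
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1L) * win + 1L):(s * win)
    xs <- x[idx] - mean(x[idx])
    ys <- y[idx] - mean(y[idx])
    X <- fft(c(h * xs, numeric(nfft - win)))
    Y <- fft(c(h * ys, numeric(nfft - win)))
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  half <- seq_len(nfft %/% 2 + 1L)
  den <- sxx[half] * syy[half]
  coh <- ifelse(den > 0, Mod(sxy[half])^2 / den, 0)
  list(frequency = (half - 1L) * fs / nfft,
       coherence = pmin(coh, 1),
       n_segments = n_seg)
}

#' Analytic confidence level for coherence estimates
#'
#' The 100*alpha% significance threshold for magnitude-squared coherence
#' estimated from `n_segments` independent windows:
#' `CL = 1 - (1 - alpha)^(1 / (n_segments - 1))`.
#'
#' @param alpha Confidence level in `[0, 1)` (default 0.95).
#' @param n_segments Number of windows used in the estimate (>= 2).
#' @return Threshold in `[0, 1)`.
#' @export
confidence_level <- function(alpha = 0.95, n_segments) {
  if (n_segments < 2) stop("n_segments must be >= 2")
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  1 - (1 - alpha)^(1 / (n_segments - 1))
}

#' Pooled coherence between random groups of motor units
#'
#' For each group size `g` and each of `n_reps` repetitions, two disjoint
#' random subsets of `g` MUs are drawn, their cumulative discharge
#' patterns formed, and the magnitude-squared coherence estimated on
#' nonoverlapping Hanning windows (default 0.5 s) with transform length
#' equal to the sampling rate (1-Hz bins). Spectra are averaged over the
#' repetitions.
#'
#' @param set A [spike_train_set]; include only MUs active over the whole
#'   interval (see [filter_active()]). Needs at least
#'   `2 * max(group_sizes)` trains.
#' @param group_sizes Integer vector of group sizes; each must not exceed
#'   half the pool.
#' @param n_reps Random allocations per group size (default 25).
#' @param window Window length in seconds (default 0.5).
#' @param fs Sampling rate in Hz (default 10,240); also the transform
#'   length.
#' @param alpha Confidence level (default 0.95).
#' @param max_freq Highest frequency retained in the result (default
#'   520 Hz), to keep the stored spectra small.
#' @param seed Integer seed for the random allocations.
#' @return Object of class `coherence_result`: list with `frequencies`,
#'   `coherence_by_group_size` (named list of averaged spectra),
#'   `n_segments`, `confidence_level`, `n_repetitions`, `seed`.
#' @export
pooled_coherence <- function(set, group_sizes, n_reps = 25L, window = 0.5,
                             fs = 10240, alpha = 0.95, max_freq = 520,
                             seed = NULL) {
  stopifnot(inherits(set, "spike_train_set"))
  n <- length(set$trains)
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 1L)) stop("group sizes must be >= 1")
  if (max(group_sizes) > n %/% 2L) {
    stop("group size exceeds half the pool")
  }
  win <- round(window * fs)
  nfft <- round(fs)
  n_seg <- round(set$duration * fs) %/% win
  cl <- confidence_level(alpha, n_seg)
  bins <- lapply(set$trains, binarize, fs = fs)
  with_seed(seed, {
    spectra <- list()
    freqs <- NULL
    for (g in group_sizes) {
      acc <- NULL
      for (rep in seq_len(n_reps)) {
        pick <- sample.int(n, 2L * g)
        x <- Reduce(`+`, bins[pick[seq_len(g)]])
        y <- Reduce(`+`, bins[pick[(g + 1L):(2L * g)]])
        w <- welch_coherence(x, y, fs, win, nfft)
        if (is.null(acc)) {
          keep <- w$frequency <= max_freq
          freqs <- w$frequency[keep]
          acc <- numeric(sum(keep))
        }
        acc <- acc + w$coherence[keep]
      }
      spectra[[as.character(g)]] <- acc / n_reps
    }
    structure(
      list(frequencies = freqs, coherence_by_group_size = spectra,
           n_segments = n_seg, confidence_level = cl,
           n_repetitions = n_reps, alpha = alpha, seed = seed),
      class = "coherence_result"
    )
  })
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf(
    "<coherence_result> group sizes {%s}, %d reps, %d segments, CL = %.4f\n",
    paste(names(x$coherence_by_group_size), collapse = ", "),
    x$n_repetitions, x$n_segments, x$confidence_level))
  invisible(x)
}

#' Highest frequency with significant pooled coherence
#'
#' Scans the averaged spectrum for contiguous runs of at least
#' `min_run` bins above the confidence level and returns the highest
#' frequency at which such a run ends. Bins at 0-2 Hz are excluded (they
#' reflect slow rate drift, not oscillatory common input).
#'
#' @param result A [pooled_coherence()] result.
#' @param group_size Which group size's spectrum to use.
#' @param min_run Minimum run length in bins (default 3).
#' @return Frequency in Hz; 0 when nothing exceeds the confidence level.
#' @export
significant_bandwidth <- function(result, group_size, min_run = 3L) {
  stopifnot(inherits(result, "coherence_result"))
  key <- as.character(group_size)
  coh <- result$coherence_by_group_size[[key]]
  if (is.null(coh)) stop("group size not present in the result")
  f <- result$frequencies
  above <- coh > result$confidence_level & f > 2
  r <- rle(above)
  ends <- cumsum(r$lengths)
  sig <- which(r$values & r$lengths >= min_run)
  if (length(sig) == 0L) return(0)
  max(f[ends[sig]])
}

#' Frequency of the peak pooled coherence
#'
#' @param result A [pooled_coherence()] result.
#' @param group_size Which group size's spectrum to use.
#' @param band Two-element search band in Hz (default `c(3, 500)`).
#' @return List with `frequency` (Hz), `coherence`, and `significant`
#'   (above the confidence level).
#' @export
coherence_peak <- function(result, group_size, band = c(3, 500)) {
  stopifnot(inherits(result, "coherence_result"))
  coh <- result$coherence_by_group_size[[as.character(group_size)]]
  if (is.null(coh)) stop("group size not present in the result")
  f <- result$frequencies
  in_band <- f >= band[1] & f <= band[2]
  i <- which(in_band)[which.max(coh[in_band])]
  list(frequency = f[i], coherence = coh[i],
       significant = coh[i] > result$confidence_level)
}
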