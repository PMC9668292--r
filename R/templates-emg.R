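#' Geometry of the double-sided intramuscular electrode array
#'
#' The array carries two rows of electrodes on the two faces of a thin
#' filament, each row with 1-mm pitch and the rows offset by 0.5 mm, so
#' the assembly behaves as a linear array with 0.5-mm effective spacing.
#'
#' @param n_channels Number of electrodes (default 40).
#' @param pitch_mm Within-row inter-electrode distance in mm (default 1).
#' @return Data frame with columns `channel`, `position_mm` (along the
#'   array) and `side` (`"top"` or `"bottom"`).
#' @export
electrode_array_geometry <- function(n_channels = 40L, pitch_mm = 1) {
  stopifnot(n_channels >= 1L, pitch_mm > 0)
  ch <- seq_len(n_channels)
  data.frame(
    channel = ch,
    position_mm = (ch - 1L) * pitch_mm / 2,
    side = ifelse(ch %% 2L == 1L, "top", "bottom"),
    stringsAsFactors = FALSE
  )
}

## Second-order Hermite-Rodriguez function, a standard biphasic MUAP
## shape model: (1 - 2 (t/lambda)^2) exp(-(t/lambda)^2).
hermite_rodriguez2 <- function(t, lambda) {
  u <- t / lambda
  (1 - 2 * u^2) * exp(-u^2)
}

#' Generate synthetic multichannel MUAP templates
#'
#' Each motor unit gets a second-order Hermite-Rodriguez waveform whose
#' time scale varies per MU, multiplied by a spatial amplitude profile
#' that decays exponentially with electrode distance from a random
#' territory centre. The defaults produce MUs visible (peak-to-peak above
#' 10x a unit noise RMS) on a handful up to all channels, matching the
#' spread seen with real intramuscular arrays.
#'
#' @param n_mus Number of motor units.
#' @param n_channels Number of channels (default 40).
#' @param L Template length in samples (default 31, about 3 ms at
#'   10,240 Hz).
#' @param geometry Electrode geometry as from
#'   [electrode_array_geometry()]; defaults to `n_channels` electrodes.
#' @param fs Sampling rate in Hz (default 10,240).
#' @param amplitude_range Peak amplitude bounds in signal units (uV),
#'   drawn log-uniformly (default `c(100, 400)`).
#' @param decay_range_mm Spatial decay constant bounds in mm (default
#'   `c(1, 5)`).
#' @param lambda_range_ms Waveform time-scale bounds in ms (default
#'   `c(0.3, 0.8)`).
#' @param seed Integer seed.
#' @return Object of class `muap_templates`: list with `waveforms` (an
#'   `n_mus x n_channels x L` array), `sampling_rate`, `mu_ids`,
#'   `geometry`.
#' @export
generate_muap_templates <- function(n_mus, n_channels = 40L, L = 31L,
                                    geometry = NULL, fs = 10240,
                                    amplitude_range = c(100, 400),
                                    decay_range_mm = c(1, 5),
                                    lambda_range_ms = c(0.3, 0.8),
                                    seed = NULL) {
  stopifnot(n_mus >= 1L, n_channels >= 1L, L >= 1L)
  if (is.null(geometry)) geometry <- electrode_array_geometry(n_channels)
  stopifnot(nrow(geometry) == n_channels)
  with_seed(seed, {
    pos <- geometry$position_mm
    span <- range(pos)
    wf <- array(0, dim = c(n_mus, n_channels, L))
    t_axis <- (seq_len(L) - (L + 1) / 2) / fs   # centred support
    for (i in seq_len(n_mus)) {
      centre <- runif(1, span[1], span[2])
      decay <- runif(1, decay_range_mm[1], decay_range_mm[2])
      amp <- exp(runif(1, log(amplitude_range[1]), log(amplitude_range[2])))
      lambda <- runif(1, lambda_range_ms[1], lambda_range_ms[2]) / 1000
      shape <- hermite_rodriguez2(t_axis, lambda)
      profile <- amp * exp(-abs(pos - centre) / decay)
      wf[i, , ] <- outer(profile, shape)
    }
    structure(
      list(waveforms = wf, sampling_rate = fs, mu_ids = seq_len(n_mus),
           geometry = geometry),
      class = "muap_templates"
    )
  })
}

#' @export
print.muap_templates <- function(x, ...) {
  d <- dim(x$waveforms)
  cat(sprintf(
    "<muap_templates> %d MUs x %d channels, L = %d samples at %g Hz\n",
    d[1], d[2], d[3], x$sampling_rate))
  invisible(x)
}

#' Construct a multichannel EMG object
#'
#' @param samples Numeric matrix, time samples by channels, in uV.
#' @param sampling_rate Sampling rate in Hz.
#' @param geometry Optional channel geometry data frame (see
#'   [electrode_array_geometry()]).
#' @return Object of class `multichannel_emg`.
#' @export
multichannel_emg <- function(samples, sampling_rate = 10240,
                             geometry = NULL) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), sampling_rate > 0)
  if (is.null(geometry)) geometry <- electrode_array_geometry(ncol(samples))
  if (nrow(geometry) != ncol(samples)) {
    stop("geometry rows must match the number of channels")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         n_channels = ncol(samples), geometry = geometry),
    class = "multichannel_emg"
  )
}

#' @export
print.multichannel_emg <- function(x, ...) {
  cat(sprintf("<multichannel_emg> %d channels x %.3f s at %g Hz\n",
              x$n_channels, nrow(x$samples) / x$sampling_rate,
              x$sampling_rate))
  invisible(x)
}

#' Synthesize multichannel EMG as a convolutive mixture
#'
#' Builds each channel as the superposition, over motor units, of the
#' unit's channel-specific action-potential template placed at every
#' discharge time (a convolution of the template with the binary pulse
#' train), plus white Gaussian noise of stated RMS. Overlapping action
#' potentials add linearly.
#'
#' @param templates A [generate_muap_templates()] object.
#' @param spikes A [spike_train_set] whose `mu_id`s all exist in
#'   `templates`.
#' @param noise_rms Baseline noise RMS in uV (default 0).
#' @param fs Sampling rate in Hz; must equal the template sampling rate.
#' @param seed Integer seed for the additive noise.
#' @return A [multichannel_emg] of duration equal to the spike set's.
#' @export
synthesize_emg <- function(templates, spikes, noise_rms = 0,
                           fs = templates$sampling_rate, seed = NULL) {
  stopifnot(inherits(templates, "muap_templates"),
            inherits(spikes, "spike_train_set"), noise_rms >= 0)
  if (abs(fs - templates$sampling_rate) > 1e-9) {
    stop("fs must match the template sampling rate")
  }
  ids <- vapply(spikes$trains, `[[`, integer(1), "mu_id")
  if (!all(ids %in% templates$mu_ids)) {
    stop("spike set contains MU ids without templates")
  }
  d <- dim(templates$waveforms)
  n_channels <- d[2]
  L <- d[3]
  K <- round(spikes$duration * fs)
  x <- matrix(0, nrow = K, ncol = n_channels)
  for (tr in spikes$trains) {
    i <- match(tr$mu_id, templates$mu_ids)
    if (length(tr$discharge_times) == 0L) next
    h <- t(templates$waveforms[i, , , drop = TRUE])    # L x channels
    if (n_channels == 1L) h <- matrix(h, ncol = 1L)
    start <- floor(tr$discharge_times * fs) + 1L
    ## sparse placement: accumulate template samples per channel with
    ## rowsum so that overlapping action potentials superpose exactly
    idx <- as.vector(outer(0:(L - 1L), start, `+`))    # L x n_spikes
    keep <- idx <= K
    for (c in seq_len(n_channels)) {
      vals <- rep(h[, c], times = length(start))[keep]
      agg <- rowsum(vals, idx[keep])
      rows <- as.integer(rownames(agg))
      x[rows, c] <- x[rows, c] + agg[, 1L]
    }
  }
  if (noise_rms > 0) {
    x <- x + with_seed(seed, matrix(rnorm(K * n_channels, 0, noise_rms),
                                    nrow = K))
  }
  multichannel_emg(x, sampling_rate = fs, geometry = templates$geometry)
}
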