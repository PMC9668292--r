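#' Configuration for the full analysis pipeline
#'
#' Collects the stage parameters with defaults matching the standard
#' recording and analysis settings: 10,240 Hz sampling, 250-Hz high-pass
#' before decomposition, 150-source cap, 0.5-ms matching tolerance,
#' 0.5-s coherence windows with 25 repetitions, 1-ms cross-histogram
#' bins, surrogate shifts up to 70 ms.
#'
#' @param n_mus Number of simulated motor units (default 15; the
#'   integrate-and-fire pool size for connectivity analyses is set in
#'   `if_params`).
#' @param if_params An [if_model_params] for the spike-train simulation.
#' @param n_channels Number of EMG channels (default 40).
#' @param noise_rms EMG baseline noise RMS in uV (default 10).
#' @param fs Sampling rate in Hz (default 10,240).
#' @param highpass_hz Decomposition high-pass cutoff (default 250).
#' @param R Extension factor (default 10).
#' @param max_sources Source cap (default 150).
#' @param pnr_accept_db PNR acceptance threshold in dB (default 20).
#' @param tolerance Matching tolerance in seconds (default 5e-4).
#' @param group_sizes Coherence group sizes; `NULL` means
#'   `c(1, seq(5, floor(n/2), by 5))` chosen at run time.
#' @param n_reps Coherence repetitions (default 25).
#' @param coherence_window Coherence window length in seconds (default
#'   0.5).
#' @param alpha Coherence confidence level (default 0.95).
#' @param bin Cross-histogram bin in seconds (default 0.001).
#' @param max_lag Cross-histogram extent in seconds (default 0.1).
#' @param max_shift Surrogate shift bound in seconds (default 0.070).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_mus = 15L,
                            if_params = if_model_params(n_neurons = n_mus,
                                                        duration = 20),
                            n_channels = 40L, noise_rms = 10,
                            fs = 10240, highpass_hz = 250,
                            R = 10L, max_sources = 150L,
                            pnr_accept_db = 20, tolerance = 5e-4,
                            group_sizes = NULL, n_reps = 25L,
                            coherence_window = 0.5, alpha = 0.95,
                            bin = 0.001, max_lag = 0.1, max_shift = 0.070,
                            seed = 1L) {
  cfg <- list(n_mus = as.integer(n_mus), if_params = if_params,
              n_channels = as.integer(n_channels), noise_rms = noise_rms, fs = fs, highpass_hz = highpass_hz,
              R = as.integer(R), max_sources = as.integer(max_sources),
              pnr_accept_db = pnr_accept_db, tolerance = tolerance,
              group_sizes = group_sizes, n_reps = as.integer(n_reps),
              coherence_window = coherence_window, alpha = alpha,
              bin = bin, max_lag = max_lag, max_shift = max_shift,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full simulate-decompose-analyse pipeline
#'
#' Simulates ground-truth motor-neuron activity, synthesizes multichannel
#' EMG, decomposes it blindly, scores the decomposition against the
#' ground truth, and runs both population analyses (pooled coherence and
#' directional cross-histograms with a Kolmogorov-Smirnov dip
#' comparison). Fully reproducible from `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, spike trains, EMG and a
#'   summary table are written there.
#' @return List with elements `truth`, `emg`, `decomposition`,
#'   `decomposed_set`, `validation` (data frame: mu_ref, mu_test, TP, FP,
#'   FN, RoA, sensitivity, precision, PNR), `coherence`, `histograms`,
#'   `dip`, `ks`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  n_pool <- cfg$if_params$n_neurons
  if (!is.null(cfg$group_sizes) &&
      max(cfg$group_sizes) > n_pool %/% 2L) {
    stop("config error: max group size exceeds half the pool")
  }

  ## stage 1: ground-truth spike trains
  truth <- simulate_if_pool(cfg$if_params, seed = child_seed(cfg$seed, 1L))

  ## stage 2: EMG synthesis (first n_mus units drive the EMG)
  emg_ids <- seq_len(min(cfg$n_mus, n_pool))
  emg_set <- spike_train_set(truth$trains[emg_ids],
                             duration = truth$duration,
                             provenance = "simulated")
  templates <- generate_muap_templates(length(emg_ids), n_channels = cfg$n_channels,
                                       fs = cfg$fs,
                                       seed = child_seed(cfg$seed, 2L))
  emg <- synthesize_emg(templates, emg_set, noise_rms = cfg$noise_rms,
                        fs = cfg$fs, seed = child_seed(cfg$seed, 3L))

  ## stage 3: blind decomposition
  emg_f <- preprocess_emg(emg, cfg$highpass_hz)
  dec <- ckc_decompose(emg_f, R = cfg$R, max_sources = cfg$max_sources,
                       pnr_accept_db = cfg$pnr_accept_db,
                       seed = child_seed(cfg$seed, 4L))
  dec_set <- as_spike_train_set(dec, duration = truth$duration)

  ## stage 4: validation against ground truth
  validation <- validate_against_truth(emg_set, dec_set, dec,
                                       tolerance = cfg$tolerance)

  ## stage 5: pooled coherence on the full simulated pool
  gs <- cfg$group_sizes
  if (is.null(gs)) {
    gs <- unique(pmax(1L, c(1L, seq(5L, n_pool %/% 2L, by = 5L))))
  }
  coh <- pooled_coherence(truth, group_sizes = gs, n_reps = cfg$n_reps,
                          window = cfg$coherence_window, fs = cfg$fs,
                          alpha = cfg$alpha,
                          seed = child_seed(cfg$seed, 5L))

  ## stage 6: directional cross-histograms + KS dip comparison
  halves <- split_by_rate(truth)
  h12 <- pooled_cross_histogram(halves$R1, halves$R2, bin = cfg$bin,
                                max_lag = cfg$max_lag,
                                direction = "R1->R2")
  h21 <- pooled_cross_histogram(halves$R2, halves$R1, bin = cfg$bin,
                                max_lag = cfg$max_lag,
                                direction = "R2->R1")
  dip <- find_dip(h12)
  ks <- ks_compare(h12, h21, center = dip$dip_ms)

  g_top <- max(gs)
  summary <- data.frame(
    n_truth = length(emg_set$trains),
    n_decomposed = length(dec_set$trains),
    median_roa = if (nrow(validation)) median(validation$RoA) else NA_real_,
    significant_bandwidth_hz = significant_bandwidth(coh, g_top),
    coherence_peak_hz = coherence_peak(coh, g_top)$frequency,
    dip_ms = dip$dip_ms,
    dip_significant = dip$significant,
    ks_p = ks$p_value
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_spike_trains(truth, file.path(out_dir, "truth_trains.tsv"))
    write_spike_trains(dec_set, file.path(out_dir, "decomposed_trains.tsv"))
    write_emg(emg, file.path(out_dir, "emg.f32"))
    write.table(validation, file.path(out_dir, "validation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  list(truth = truth, emg = emg, decomposition = dec,
       decomposed_set = dec_set, validation = validation, coherence = coh,
       histograms = list(r1_to_r2 = h12, r2_to_r1 = h21), dip = dip,
       ks = ks, summary = summary)
}

#' Score a decomposition against ground truth
#'
#' Matches every decomposed train to its best ground-truth counterpart
#' (highest rate of agreement at the stated tolerance, allowing a
#' constant alignment lag) and tabulates the agreement metrics.
#'
#' @param truth_set,test_set [spike_train_set]s.
#' @param dec Optional `ckc_decomposition` supplying per-source PNR.
#' @param tolerance Matching tolerance in seconds (default 5e-4).
#' @param align Compensate a constant lag per pair (default `TRUE`).
#' @return Data frame with one row per test train: `mu_ref`, `mu_test`,
#'   `TP`, `FP`, `FN`, `RoA`, `sensitivity`, `precision`, `PNR`.
#' @export
validate_against_truth <- function(truth_set, test_set, dec = NULL,
                                   tolerance = 5e-4, align = TRUE) {
  stopifnot(inherits(truth_set, "spike_train_set"),
            inherits(test_set, "spike_train_set"))
  rows <- list()
  for (j in seq_along(test_set$trains)) {
    te <- test_set$trains[[j]]
    best <- NULL
    best_roa <- -1
    best_id <- NA_integer_
    for (tr in truth_set$trains) {
      m <- match_trains(tr, te, tolerance = tolerance, align = align)
      r <- if (m$tp + m$fp + m$fn > 0) roa(m) else 0
      if (r > best_roa) {
        best_roa <- r
        best <- m
        best_id <- tr$mu_id
      }
    }
    if (is.null(best)) next
    sp <- tryCatch(sensitivity_precision(best),
                   error = function(e) c(sensitivity = NA_real_,
                                         precision = NA_real_))
    rows[[j]] <- data.frame(
      mu_ref = best_id, mu_test = te$mu_id, TP = best$tp, FP = best$fp,
      FN = best$fn, RoA = best_roa, sensitivity = sp[["sensitivity"]],
      precision = sp[["precision"]],
      PNR = if (!is.null(dec)) dec[[j]]$pnr_db else NA_real_
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(mu_ref = integer(), mu_test = integer(),
                      TP = integer(), FP = integer(), FN = integer(),
                      RoA = numeric(), sensitivity = numeric(),
                      precision = numeric(), PNR = numeric()))
  }
  do.call(rbind, rows)
}
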