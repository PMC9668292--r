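#' Write a spike train set to delimited text
#'
#' Two tab-separated columns `mu_id` and `time_s` (6+ decimals) with a
#' header line, plus a companion key-value file `<path>.meta` holding the
#' set duration, time resolution and provenance.
#'
#' @param set A [spike_train_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(set, path) {
  stopifnot(inherits(set, "spike_train_set"))
  rows <- do.call(rbind, lapply(set$trains, function(tr) {
    if (length(tr$discharge_times) == 0L) return(NULL)
    data.frame(mu_id = tr$mu_id, time_s = tr$discharge_times)
  }))
  if (is.null(rows)) rows <- data.frame(mu_id = integer(), time_s = numeric())
  rows$time_s <- sprintf("%.7f", rows$time_s)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- if (length(set$trains)) set$trains[[1L]]$time_resolution else 1 / 10240
  ids <- vapply(set$trains, `[[`, integer(1), "mu_id")
  meta <- c(
    sprintf("duration_s=%.7f", set$duration),
    sprintf("time_resolution_s=%.10f", res),
    sprintf("provenance=%s", set$provenance),
    sprintf("mu_ids=%s", paste(ids, collapse = ","))
  )
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a spike train set from delimited text
#'
#' Expects the format written by [write_spike_trains()]. Times must be
#' sorted (strictly increasing) within each MU; violations raise an error
#' naming the offending line.
#'
#' @param path File path; the sidecar `<path>.meta` is read when present,
#'   otherwise the duration defaults to the maximum time plus one sample.
#' @return A [spike_train_set] with provenance `"file"`.
#' @export
read_spike_trains <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "numeric"))
  meta_path <- paste0(path, ".meta")
  duration <- NA_real_
  res <- 1 / 10240
  all_ids <- NULL
  if (file.exists(meta_path)) {
    kv <- strsplit(readLines(meta_path), "=", fixed = TRUE)
    meta <- stats::setNames(
      vapply(kv, `[`, character(1), 2L),
      vapply(kv, `[`, character(1), 1L))
    if (!is.na(meta["duration_s"])) duration <- as.numeric(meta["duration_s"])
    if (!is.na(meta["time_resolution_s"])) {
      res <- as.numeric(meta["time_resolution_s"])
    }
    if (!is.na(meta["mu_ids"]) && nzchar(meta["mu_ids"])) {
      all_ids <- as.integer(strsplit(meta["mu_ids"], ",")[[1L]])
    }
  }
  if (nrow(df) == 0L && is.null(all_ids)) {
    warning("empty spike train file")
    return(spike_train_set(list(),
                           duration = if (is.na(duration)) 1 else duration,
                           provenance = "file"))
  }
  if (is.na(duration)) {
    duration <- if (nrow(df)) max(df$time_s) + res else 1
  }
  ids <- if (is.null(all_ids)) sort(unique(df$mu_id)) else all_ids
  trains <- lapply(ids, function(id) {
    tt <- df$time_s[df$mu_id == id]
    if (length(tt) && is.unsorted(tt, strictly = TRUE)) {
      first_bad <- which(diff(tt) <= 0)[1L]
      line <- which(df$mu_id == id)[first_bad + 1L] + 1L  # +1 for header
      stop(sprintf("non-monotone discharge times for MU %d at line %d",
                   id, line))
    }
    spike_train(id, tt, duration, res)
  })
  spike_train_set(trains, duration = duration, provenance = "file")
}

#' Write multichannel EMG to raw binary with a JSON sidecar
#'
#' Samples are stored as little-endian 32-bit floats in channel-major
#' frames (all channels of sample 1, then sample 2, ...). The sidecar
#' `<path>.json` records `n_channels`, `sampling_rate_hz`, `units` and
#' the channel geometry.
#'
#' @param emg A [multichannel_emg].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_emg <- function(emg, path) {
  stopifnot(inherits(emg, "multichannel_emg"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(emg$samples)), con, size = 4L, endian = "little")
  sidecar <- list(
    n_channels = emg$n_channels,
    sampling_rate_hz = emg$sampling_rate,
    units = "uV",
    dtype = "float32_le",
    frame_order = "channel_major",
    channel_geometry = emg$geometry
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read multichannel EMG written by [write_emg()]
#'
#' @param path Binary file path.
#' @param sidecar Sidecar path (default `<path>.json`).
#' @return A [multichannel_emg]. Note the samples are float32 on disk, so
#'   a write-read round trip is exact only at single precision.
#' @export
read_emg <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_ch <- as.integer(meta$n_channels)
  n_bytes <- file.info(path)$size
  if (n_bytes %% (4L * n_ch) != 0) {
    stop("binary length is not a whole number of ", n_ch, "-channel frames")
  }
  n_vals <- n_bytes / 4L
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n_vals, size = 4L, endian = "little")
  x <- matrix(v, ncol = n_ch, byrow = TRUE)
  geom <- if (!is.null(meta$channel_geometry)) {
    as.data.frame(meta$channel_geometry)
  } else {
    NULL
  }
  multichannel_emg(x, sampling_rate = meta$sampling_rate_hz,
                   geometry = geom)
}
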