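#' Multichannel amperometric recording container
#'
#' Holds current traces for a set of electrode channels together with the
#' sampling metadata the analysis chain needs. Channels are 0-based and map
#' row-major onto the electrode grid unless an explicit map is given.
#'
#' @param traces Numeric matrix, channels x samples, current in pA.
#' @param sample_rate Sampling rate in Hz.
#' @param channel_map Data frame with columns `channel`, `row`, `col`
#'   (0-based). Defaults to a row-major map over a 32 x 32 grid restricted
#'   to the channels present.
#' @param channels Integer vector of channel indices (0-based) for the rows
#'   of `traces`; defaults to `0:(nrow(traces) - 1)`.
#' @param metadata Named list of free-form metadata (e.g. `potential_mv`,
#'   `group`, `session`).
#' @param n_rows,n_cols Grid geometry used for the default channel map.
#' @return An object of class `recording_array`.
#' @export
recording_array <- function(traces, sample_rate, channel_map = NULL,
                            channels = NULL, metadata = list(),
                            n_rows = 32L, n_cols = 32L) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  stopifnot(is.matrix(traces), is.numeric(traces))
  if (!all(is.finite(traces))) stop("all trace samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number (Hz)")
  }
  if (is.null(channels)) channels <- seq_len(nrow(traces)) - 1L
  channels <- as.integer(channels)
  stopifnot(length(channels) == nrow(traces), !anyDuplicated(channels))
  if (is.null(channel_map)) {
    channel_map <- default_channel_map(n_rows, n_cols)
    channel_map <- channel_map[channel_map$channel %in% channels, ,
                               drop = FALSE]
  }
  stopifnot(all(c("channel", "row", "col") %in% names(channel_map)))
  if (anyDuplicated(channel_map$channel) ||
      anyDuplicated(paste(channel_map$row, channel_map$col))) {
    stop("`channel_map` must be injective")
  }
  if (!all(channels %in% channel_map$channel)) {
    stop("every trace channel must appear in `channel_map`")
  }
  structure(
    list(traces = traces, sample_rate = sample_rate, channels = channels,
         channel_map = as.data.frame(channel_map), metadata = metadata),
    class = "recording_array"
  )
}

#' Row-major channel -> (row, col) map for a rectangular array
#'
#' @param n_rows,n_cols Grid dimensions (default 32 x 32, i.e. 1024
#'   electrodes).
#' @return Data frame with 0-based `channel`, `row`, `col`.
#' @export
default_channel_map <- function(n_rows = 32L, n_cols = 32L) {
  ch <- seq_len(n_rows * n_cols) - 1L
  data.frame(channel = ch, row = ch %/% n_cols, col = ch %% n_cols)
}

#' @export
print.recording_array <- function(x, ...) {
  cat(sprintf(
    "<recording_array> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$traces), ncol(x$traces), x$sample_rate,
    ncol(x$traces) / x$sample_rate))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param x A `recording_array`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(x) ncol(x$traces) / x$sample_rate

#' Write a recording to long-format CSV with a YAML metadata sidecar
#'
#' The CSV holds one row per (channel, sample) pair with columns `channel`,
#' `sample`, `current_pA`; the sidecar `<path>.yaml` records `sample_rate_hz`,
#' grid geometry, the channel map and free-form metadata. Currents are
#' stored with 6 significant digits.
#'
#' @param x A `recording_array`.
#' @param path Output CSV path; the sidecar is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "recording_array"))
  long <- data.table::data.table(
    channel = rep(x$channels, each = ncol(x$traces)),
    sample = rep(seq_len(ncol(x$traces)) - 1L, nrow(x$traces)),
    current_pA = signif(as.vector(t(x$traces)), 6)
  )
  data.table::fwrite(long, path)
  side <- list(
    sample_rate_hz = x$sample_rate,
    n_samples = ncol(x$traces),
    channel_map = lapply(seq_len(nrow(x$channel_map)), function(i)
      as.list(x$channel_map[i, c("channel", "row", "col")])),
    metadata = x$metadata
  )
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path (sidecar expected at `<path>.yaml`).
#' @param format Only `"csv"` is supported in this build; the HDF5 layout is
#'   not available because no HDF5 interface is installed.
#' @return A `recording_array`.
#' @export
read_recording <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("HDF5 recordings are not supported in this build; use format = \"csv\"")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  long <- data.table::fread(path)
  required <- c("channel", "sample", "current_pA")
  missing_cols <- setdiff(required, names(long))
  if (length(missing_cols)) {
    stop("recording CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  side_path <- paste0(path, ".yaml")
  if (!file.exists(side_path)) stop("metadata sidecar not found: ", side_path)
  side <- yaml::read_yaml(side_path)
  if (is.null(side$sample_rate_hz)) {
    stop("metadata sidecar lacks required key `sample_rate_hz`")
  }
  channels <- sort(unique(long$channel))
  n_samp <- if (!is.null(side$n_samples)) side$n_samples else
    max(long$sample) + 1L
  traces <- matrix(0, nrow = length(channels), ncol = n_samp)
  for (i in seq_along(channels)) {
    sub <- long[long$channel == channels[i]]
    traces[i, sub$sample + 1L] <- sub$current_pA
  }
  if (is.null(side$channel_map)) {
    warning("sidecar lacks a channel map; assuming row-major 32 x 32")
    cmap <- default_channel_map()
    cmap <- cmap[cmap$channel %in% channels, , drop = FALSE]
  } else {
    cmap <- do.call(rbind, lapply(side$channel_map, as.data.frame))
  }
  recording_array(traces, side$sample_rate_hz, channel_map = cmap,
                  channels = channels,
                  metadata = if (is.null(side$metadata)) list()
                             else side$metadata)
}
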