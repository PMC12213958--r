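#' Construct an epoched-EEG container
#'
#' @param data trials x channels x samples numeric array, μV.
#' @param condition Character vector of per-trial condition labels.
#' @param fs_hz Sampling rate in Hz.
#' @param t0_ms Time of the first sample relative to stimulus onset (ms).
#' @param channel Channel names, length = second array dimension.
#' @param subject_id Subject identifier string.
#' @param seed Seed the data were generated with (NA for measured data).
#' @return `smeloc_epochs` object.
#' @export
epochs_set <- function(data, condition, fs_hz, t0_ms, channel,
                       subject_id = "sub-01", seed = NA_integer_) {
  d <- dim(data)
  if (length(d) != 3L) stopf("epochs data must be trials x channels x samples")
  if (length(condition) != d[1]) stopf("one condition label per trial required")
  if (length(channel) != d[2]) stopf("one channel name per channel required")
  structure(list(data = data, condition = as.character(condition),
                 fs_hz = fs_hz, t0_ms = t0_ms, channel = as.character(channel),
                 subject_id = subject_id, seed = seed),
            class = "smeloc_epochs")
}

#' @export
print.smeloc_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<smeloc_epochs> %s: %d trials x %d channels x %d samples @ %g Hz, t0 %g ms\n",
              x$subject_id, d[1], d[2], d[3], x$fs_hz, x$t0_ms))
  print(table(x$condition))
  invisible(x)
}

#' Write / read an epochs set (flat float32 binary + JSON sidecar)
#'
#' The array is stored little-endian float32 in trial-major order with a
#' `<stem>.json` sidecar carrying shape and metadata; the round trip is
#' bit-exact at float32 precision.
#'
#' @param epochs An [epochs_set()]; @param stem path without extension.
#' @return `write_epochs` returns the two paths invisibly; `read_epochs`
#'   returns the epochs set.
#' @export
write_epochs <- function(epochs, stem) {
  bin <- paste0(stem, ".bin"); side <- paste0(stem, ".json")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con, size = 4L,
           endian = "little")
  jsonlite::write_json(list(
    subject_id = epochs$subject_id, fs_hz = epochs$fs_hz,
    t0_ms = epochs$t0_ms, channel_names = epochs$channel,
    condition = epochs$condition, seed = epochs$seed,
    shape = dim(epochs$data), order = "sample-fastest", dtype = "float32le"
  ), side, auto_unbox = TRUE, digits = NA)
  invisible(c(bin = bin, json = side))
}

#' @rdname write_epochs
#' @param stem Path stem previously given to `write_epochs`.
#' @export
read_epochs <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  shp <- as.integer(side$shape)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "numeric", n = prod(shp), size = 4L,
                 endian = "little")
  data <- aperm(array(raw, dim = rev(shp)), c(3, 2, 1))
  epochs_set(data, side$condition, side$fs_hz, side$t0_ms,
             side$channel_names, side$subject_id,
             if (is.null(side$seed)) NA_integer_ else as.integer(side$seed))
}
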