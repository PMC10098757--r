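# Minimal EDF (European Data Format) reader and writer.
#
# EDF stores 16-bit samples in fixed-duration data records with an ASCII
# header (256 bytes + 256 per signal). This implementation covers the subset
# the pipeline needs: uniform sampling rate across channels, 1-second data
# records, physical units in microvolts.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(signif(x, 7), format = "g", width = 0)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits. The physical range of each channel is
#' set to its observed absolute maximum plus 5% headroom, which avoids
#' clipping while keeping the quantization step small; the implied
#' quantization step bounds the round-trip error.
#'
#' @param rec An `eeg_recording` (microvolts). `fs` must be a positive
#'   integer and the duration is truncated to whole seconds.
#' @param path Output file path.
#' @param labels Optional raw signal labels to store (default: the
#'   recording's channel names); useful for writing prefixed or referenced
#'   labels such as `"EEG Fp1-A1"`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, labels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- length(rec$channels)
  n_rec <- floor(nrow(rec$samples) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  if (n_rec * fs < nrow(rec$samples)) {
    warning("truncating ", nrow(rec$samples) - n_rec * fs,
            " trailing sample(s) to whole-second EDF records")
  }
  x <- rec$samples[seq_len(n_rec * fs), , drop = FALSE]
  if (is.null(labels)) labels <- rec$channels

  pmax <- apply(abs(x), 2, max)
  pmax <- ifelse(pmax == 0, 1, pmax * 1.05)
  pmin <- -pmax
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("synthetic subject", 80),
    .edf_pad(paste("device:", rec$device), 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (ns + 1), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(1, 8), .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, .edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(labels, 16)
  field(rep("", ns), 80)                      # transducer
  field(rep("uV", ns), 8)                     # physical dimension
  writeChar(paste0(vapply(pmin, .edf_num, character(1), width = 8),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmax, .edf_num, character(1), width = 8),
                   collapse = ""), con, eos = NULL)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                      # prefiltering
  field(rep(fs, ns), 8)                       # samples per record
  field(rep("", ns), 32)

  # re-read the formatted physical ranges so the scaling we apply matches
  # what a reader will parse back (formatting may lose precision)
  pminf <- as.numeric(vapply(pmin, .edf_num, character(1), width = 8))
  pmaxf <- as.numeric(vapply(pmax, .edf_num, character(1), width = 8))

  dig <- matrix(0L, nrow(x), ncol(x))
  for (j in seq_len(ns)) {
    d <- round((x[, j] - pminf[j]) / (pmaxf[j] - pminf[j]) *
                 (dmax - dmin) + dmin)
    dig[, j] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(as.vector(dig[rows, ])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Samples are converted to microvolts with the stored physical/digital
#' scaling. Channel labels are normalized to canonical 10-20 names
#' ([normalize_channel_labels()]); a reference suffix such as `"-A1"` is
#' recorded separately in `references`.
#'
#' @param path Path to an EDF/EDF+ file with a uniform sampling rate across
#'   channels.
#' @param device Device tag to attach (default: taken from the recording
#'   identification field when it carries one).
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, device = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readChar(con, width, useBytes = TRUE)
    if (length(raw) == 0 || nchar(raw, type = "bytes") < width) {
      stop("not a valid EDF file (truncated header): ", path)
    }
    trimws(raw)
  }
  rd(8)                                   # version
  rd(80)                                  # patient id
  rec_id <- rd(80)
  rd(8); rd(8)                            # date, time
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1) {
    stop("not a valid EDF file (malformed header): ", path)
  }
  sf <- function(width) vapply(seq_len(ns), function(i) rd(width),
                               character(1))
  labels <- sf(16)
  sf(80)
  sf(8)                                   # dimension
  pmin <- as.numeric(sf(8)); pmax <- as.numeric(sf(8))
  dmin <- as.numeric(sf(8)); dmax <- as.numeric(sf(8))
  sf(80)
  spr <- as.integer(sf(8))
  sf(32)
  if (length(unique(spr)) != 1) {
    stop("unsupported layout: mixed sampling rates among channels: ",
         paste(labels[spr != spr[1]], collapse = ", "))
  }
  fs <- spr[1] / rec_dur
  vals <- readBin(con, integer(), n = n_rec * ns * spr[1], size = 2,
                  endian = "little")
  if (length(vals) < n_rec * ns * spr[1]) {
    stop("not a valid EDF file (truncated data): ", path)
  }
  x <- matrix(0, n_rec * spr[1], ns)
  dim(vals) <- c(spr[1], ns, n_rec)
  for (j in seq_len(ns)) {
    x[, j] <- as.vector(vals[, j, ]) # records concatenated in time
  }
  for (j in seq_len(ns)) {
    x[, j] <- (x[, j] - dmin[j]) * (pmax[j] - pmin[j]) /
      (dmax[j] - dmin[j]) + pmin[j]
  }
  lab <- normalize_channel_labels(labels)
  if (is.null(device)) {
    device <- sub("^device: ", "", rec_id)
    if (device == "") device <- "unknown"
  }
  new_recording(x, fs = fs, channels = lab$channel, device = device,
                references = lab$reference)
}
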