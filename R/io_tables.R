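# CSV-side I/O: OpenBCI-style sample tables and annotation files.

#' Read an OpenBCI-style CSV recording
#'
#' Comma-separated numeric samples, one row per sample, with header lines
#' prefixed by `%` ignored (the OpenBCI GUI dialect). Raw ADC counts are
#' converted to microvolts by `scale` (default 1, pass-through).
#'
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @param channel_names Channel labels, one per CSV column.
#' @param scale Multiplicative counts-to-microvolts factor.
#' @param device Device tag.
#' @return An `eeg_recording`.
#' @export
read_openbci_csv <- function(path, fs, channel_names, scale = 1.0,
                             device = "wearable") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*%", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no data rows in ", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1) stop("ragged CSV rows in ", path)
  if (ncols[1] != length(channel_names)) {
    stop(sprintf("schema error: %d data column(s) but %d channel name(s)",
                 ncols[1], length(channel_names)))
  }
  x <- matrix(as.numeric(unlist(parts)), nrow = length(lines),
              byrow = TRUE)
  if (anyNA(x)) stop("non-numeric values in ", path)
  new_recording(x * scale, fs = fs, channels = channel_names,
                device = device)
}

.format_schedule <- function(sched) {
  if (is.null(sched) || NROW(sched) == 0) return("")
  paste(sprintf("%g:%g", sched$freq, sched$duration), collapse = ";")
}

.parse_schedule <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(NULL)
  pairs <- strsplit(strsplit(trimws(s), ";", fixed = TRUE)[[1]], ":",
                    fixed = TRUE)
  if (any(lengths(pairs) != 2)) {
    stop("malformed photic schedule '", s, "' (expected f1:d1;f2:d2;...)")
  }
  m <- matrix(as.numeric(unlist(pairs)), ncol = 2, byrow = TRUE)
  tibble::tibble(freq = m[, 1], duration = m[, 2])
}

#' Read / write annotation files
#'
#' Annotation CSV schema: columns `label`, `t_start`, `t_end`,
#' `photic_schedule`, where the schedule is `"f1:d1;f2:d2;..."` (Hz:s pairs)
#' or empty. Intervals are seconds from recording start, half-open.
#' Round-trip stable; overlapping intervals raise an error naming the pair.
#'
#' @param path File path.
#' @return [read_annotations()]: an `eeg_annotations` tibble.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(photic_schedule = "character"))
  need <- c("label", "t_start", "t_end", "photic_schedule")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  }
  new_annotations(df$label, df$t_start, df$t_end,
                  lapply(df$photic_schedule, .parse_schedule))
}

#' @rdname read_annotations
#' @param ann An `eeg_annotations` tibble.
#' @return [write_annotations()]: `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  df <- data.frame(
    label = ann$label, t_start = ann$t_start, t_end = ann$t_end,
    photic_schedule = vapply(ann$photic_schedule, .format_schedule,
                             character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
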