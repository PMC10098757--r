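# Core containers: multichannel recordings and test annotations.

# Canonical 10-20 montage spellings handled by the pipeline. The wearable
# montage uses 16 of these, the clinical reference all 21; modern temporal
# aliases (T7/T8/P7/P8) are kept as their own canonical names.
.canonical_channels <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "T3", "C3", "Cz", "C4", "T4",
  "T5", "P3", "Pz", "P4", "T6",
  "O1", "O2", "A1", "A2",
  "T7", "T8", "P7", "P8"
)

#' Standard montages
#'
#' Channel label sets for the two simulated devices: a 16-channel wearable
#' montage (ear-referenced) and a 21-channel clinical montage.
#'
#' @param which `"wearable"` (16 channels) or `"clinical"` (21 channels).
#' @return Character vector of 10-20 labels.
#' @export
montage_channels <- function(which = c("wearable", "clinical")) {
  which <- match.arg(which)
  ch16 <- c("Fp1", "Fp2", "F7", "F3", "F4", "F8", "T3", "C3", "C4", "T4",
            "T5", "P3", "P4", "T6", "O1", "O2")
  if (which == "wearable") ch16
  else c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz", "C4",
         "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2", "A1", "A2")
}

#' Normalize an electrode label
#'
#' Strips an `"EEG "` prefix (case-insensitive), splits off a reference
#' suffix (`"Fp1-A1"` -> label `Fp1`, reference `A1`), and maps the label to
#' its canonical 10-20 spelling. Unknown labels are kept verbatim and
#' reported with a message rather than rejected, so montage differences
#' between devices are tolerated.
#'
#' @param labels Character vector of raw labels.
#' @return Data frame with columns `channel` and `reference` (`NA` if none).
#' @export
normalize_channel_labels <- function(labels) {
  raw <- trimws(sub("^\\s*EEG\\s+", "", labels, ignore.case = TRUE))
  parts <- strsplit(raw, "-", fixed = TRUE)
  chan <- vapply(parts, `[`, character(1), 1)
  ref <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                character(1))
  canon <- .canonical_channels[match(tolower(chan),
                                     tolower(.canonical_channels))]
  unknown <- is.na(canon)
  if (any(unknown)) {
    message("keeping non 10-20 channel label(s) verbatim: ",
            paste(chan[unknown], collapse = ", "))
    canon[unknown] <- chan[unknown]
  }
  ref_canon <- .canonical_channels[match(tolower(ref),
                                         tolower(.canonical_channels))]
  ref[!is.na(ref_canon)] <- ref_canon[!is.na(ref_canon)]
  data.frame(channel = canon, reference = ref, stringsAsFactors = FALSE)
}

#' Construct an EEG recording
#'
#' @param samples Numeric matrix, one column per channel, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Ordered, unique 10-20 channel labels (one per column).
#' @param device Free-text device tag (e.g. `"wearable"`, `"clinical"`).
#' @param start_time Seconds offset of the first sample (0 allowed).
#' @param references Optional per-channel reference labels.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(samples, fs, channels, device = "unknown",
                          start_time = 0, references = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  if (ncol(samples) != length(channels)) {
    stop("channel count mismatch: ", ncol(samples), " columns vs ",
         length(channels), " labels")
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  colnames(samples) <- channels
  structure(
    list(samples = samples, fs = fs, channels = as.character(channels),
         device = device, start_time = start_time, references = references),
    class = "eeg_recording")
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return `nrow(samples) / fs`.
#' @export
duration_seconds <- function(rec) nrow(rec$samples) / rec$fs

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> device=%s fs=%g Hz, %d channel(s), %.1f s\n",
              x$device, x$fs, length(x$channels), duration_seconds(x)))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

#' Construct a test annotation table
#'
#' Annotations are half-open intervals `[t_start, t_end)` in seconds from
#' recording start, labelled `BASELINE`, `EOC`, `HV` or `PS`. A `PS`
#' annotation carries a photic schedule: an ordered table of
#' (frequency Hz, duration s) steps.
#'
#' @param label Character vector of test labels.
#' @param t_start,t_end Numeric vectors, seconds.
#' @param photic_schedule List of data frames with columns `freq` and
#'   `duration` (or `NULL` entries for non-PS rows).
#' @return A tibble of class `eeg_annotations`.
#' @export
new_annotations <- function(label, t_start, t_end, photic_schedule = NULL) {
  valid <- c("BASELINE", "EOC", "HV", "PS")
  if (!all(label %in% valid)) {
    stop("labels must be among ", paste(valid, collapse = ", "))
  }
  n <- length(label)
  if (is.null(photic_schedule)) photic_schedule <- rep(list(NULL), n)
  ann <- tibble::tibble(label = label, t_start = t_start, t_end = t_end,
                        photic_schedule = photic_schedule)
  class(ann) <- c("eeg_annotations", class(ann))
  validate_annotations(ann)
  ann
}

#' Validate an annotation table
#'
#' Checks interval sanity, pairwise non-overlap, and photic schedule
#' consistency; optionally checks coverage against a recording duration.
#'
#' @param ann Annotation tibble.
#' @param duration Optional recording duration (seconds).
#' @return The validated table, invisibly.
#' @export
validate_annotations <- function(ann, duration = NULL) {
  if (any(ann$t_start < 0) || any(ann$t_end <= ann$t_start)) {
    stop("annotations require 0 <= t_start < t_end")
  }
  if (!is.null(duration) && any(ann$t_end > duration + 1e-9)) {
    bad <- which(ann$t_end > duration + 1e-9)[1]
    stop(sprintf("annotation %s [%g, %g) exceeds recording duration %g s",
                 ann$label[bad], ann$t_start[bad], ann$t_end[bad], duration))
  }
  if (nrow(ann) > 1) {
    o <- order(ann$t_start)
    s <- ann[o, ]
    for (i in seq_len(nrow(s) - 1)) {
      if (s$t_end[i] > s$t_start[i + 1] + 1e-9) {
        stop(sprintf("overlapping annotations: %s [%g, %g) and %s [%g, %g)",
                     s$label[i], s$t_start[i], s$t_end[i],
                     s$label[i + 1], s$t_start[i + 1], s$t_end[i + 1]))
      }
    }
  }
  for (i in seq_len(nrow(ann))) {
    sched <- ann$photic_schedule[[i]]
    if (ann$label[i] == "PS") {
      if (is.null(sched) || nrow(sched) == 0) {
        stop("PS annotation requires a photic schedule")
      }
      if (sum(sched$duration) > ann$t_end[i] - ann$t_start[i] + 1e-9) {
        stop("photic schedule durations exceed the PS interval")
      }
    } else if (!is.null(sched) && NROW(sched) > 0) {
      stop("photic_schedule only allowed on PS annotations")
    }
  }
  invisible(ann)
}
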