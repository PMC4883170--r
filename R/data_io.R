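#' Construct a single-channel EEG record
#'
#' @param amplitudes Integer-valued amplitude sequence (ADC units).
#' @param class_label `"healthy"` or `"ictal"`.
#' @param sampling_rate Sampling rate in Hz (metadata only; the Bonn corpus
#'   uses 173.61 Hz).
#' @param record_id Identifier string.
#' @return An object of class `"eeg_record"`.
#' @export
eeg_record <- function(amplitudes, class_label = c("healthy", "ictal"),
                       sampling_rate = 173.61, record_id = "") {
  class_label <- match.arg(class_label)
  if (length(amplitudes) == 0L)
    stop("amplitudes must be non-empty", call. = FALSE)
  if (anyNA(amplitudes) || any(!is.finite(amplitudes)))
    stop("amplitudes must be finite", call. = FALSE)
  structure(list(amplitudes = as.integer(round(amplitudes)),
                 class_label = class_label,
                 sampling_rate = sampling_rate,
                 record_id = as.character(record_id)),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("EEG record '%s' (%s): %d observations at %g Hz, range [%d, %d]\n",
              x$record_id, x$class_label, length(x$amplitudes),
              x$sampling_rate, min(x$amplitudes), max(x$amplitudes)))
  invisible(x)
}

#' @export
length.eeg_record <- function(x) length(x$amplitudes)

#' Read a Bonn-layout ASCII EEG record
#'
#' The Bonn epilepsy corpus distributes each record as a plain text file
#' with one signed integer amplitude per line (4097 lines per record at
#' 173.61 Hz).  Blank lines and surrounding whitespace are tolerated.
#'
#' @param path Path to the file.
#' @param class_label Class tag to attach (`"healthy"` or `"ictal"`).
#' @param record_id Identifier; defaults to the file name without extension.
#' @return An [eeg_record()].
#' @export
read_bonn_ascii <- function(path, class_label = c("healthy", "ictal"),
                            record_id = NULL) {
  class_label <- match.arg(class_label)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  raw <- trimws(lines)
  keep <- nzchar(raw)
  if (!any(keep)) stop("empty record file: ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(raw[keep]))
  bad <- which(!is.finite(vals) | vals != floor(vals))
  if (length(bad)) {
    line_no <- which(keep)[bad[1L]]
    stop(sprintf("cannot parse '%s' line %d as an integer: '%s'",
                 path, line_no, raw[keep][bad[1L]]), call. = FALSE)
  }
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  eeg_record(vals, class_label, sampling_rate = 173.61,
             record_id = record_id)
}

#' Write an EEG record in Bonn ASCII layout
#'
#' One integer per line; `read_bonn_ascii(write_bonn_ascii(r, p))`
#' reproduces `r`'s amplitudes exactly.
#'
#' @param record An [eeg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bonn_ascii <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  ok <- tryCatch({
    writeLines(format(record$amplitudes, scientific = FALSE, trim = TRUE),
               path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Synthetic two-class EEG generator configuration
#'
#' Defaults emulate the healthy-versus-ictal contrast of the Bonn corpus
#' (sets A and E): moderate-amplitude alpha-band oscillations against
#' high-amplitude ~3 Hz spike-and-wave discharges, both with additive
#' Gaussian noise and integer-quantised amplitudes.
#'
#' @param records_per_class Records generated per class.
#' @param record_length Observations per record.
#' @param sampling_rate Hz.
#' @param healthy_amplitude Peak amplitude of the healthy oscillation
#'   (ADC units).
#' @param ictal_amplitude_ratio Ictal peak amplitude as a multiple of
#'   `healthy_amplitude` (>= 1).
#' @param healthy_band Two-element frequency band (Hz) from which each
#'   healthy record's oscillation frequency is drawn.
#' @param ictal_spike_rate Spike-and-wave repetition rate (Hz).
#' @param noise_sd Gaussian noise standard deviation (ADC units).
#' @param seed Master seed; every record gets its own deterministic
#'   substream.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(records_per_class = 100L, record_length = 4097L,
                             sampling_rate = 173.61,
                             healthy_amplitude = 100,
                             ictal_amplitude_ratio = 6,
                             healthy_band = c(8, 13), ictal_spike_rate = 3,
                             noise_sd = 30, seed = 1L) {
  if (ictal_amplitude_ratio < 1)
    stop("'ictal_amplitude_ratio' must be >= 1", call. = FALSE)
  nyquist <- sampling_rate / 2
  if (max(healthy_band) >= nyquist || ictal_spike_rate >= nyquist)
    stop("signal frequencies must lie below the Nyquist frequency",
         call. = FALSE)
  structure(list(records_per_class = as.integer(records_per_class),
                 record_length = as.integer(record_length),
                 sampling_rate = sampling_rate,
                 healthy_amplitude = healthy_amplitude,
                 ictal_amplitude_ratio = ictal_amplitude_ratio,
                 healthy_band = healthy_band,
                 ictal_spike_rate = ictal_spike_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

synth_healthy <- function(cfg, t) {
  f <- stats::runif(1, cfg$healthy_band[1], cfg$healthy_band[2])
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- cfg$healthy_amplitude * stats::runif(1, 0.8, 1.2)
  amp * sin(2 * pi * f * t + phase) +
    stats::rnorm(length(t), sd = cfg$noise_sd)
}

synth_ictal <- function(cfg, t) {
  f <- cfg$ictal_spike_rate
  phase <- stats::runif(1, 0, 1 / f)
  peak <- cfg$ictal_amplitude_ratio * cfg$healthy_amplitude *
    stats::runif(1, 0.8, 1.2)
  # slow wave plus one sharp Gaussian transient per cycle (spike-and-wave)
  u <- (t + phase) * f
  cycle_pos <- u - floor(u)                 # position within cycle, [0,1)
  spike <- exp(-((cycle_pos - 0.5) / 0.05)^2)
  wave <- 0.45 * sin(2 * pi * u)
  sig <- wave + spike
  peak * sig / max(abs(sig)) + stats::rnorm(length(t), sd = cfg$noise_sd)
}

#' Generate a synthetic two-class EEG dataset
#'
#' Produces `records_per_class` healthy and ictal records in the Bonn
#' record layout: healthy records are band-limited oscillations (frequency
#' drawn per record from `healthy_band`), ictal records are rhythmic
#' spike-and-wave discharges at `ictal_spike_rate` with peak amplitude
#' `ictal_amplitude_ratio` times the healthy amplitude.  Output is
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return List of [eeg_record()] objects (class `"eeg_dataset"`), healthy
#'   records first.
#' @examples
#' ds <- generate_synthetic_dataset(synthetic_config(records_per_class = 2,
#'                                                   record_length = 256))
#' length(ds)  # 4 records
#' @export
generate_synthetic_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  t <- (seq_len(cfg$record_length) - 1) / cfg$sampling_rate
  classes <- c(healthy = 1L, ictal = 2L)
  out <- vector("list", 2L * cfg$records_per_class)
  i <- 0L
  for (cl in names(classes)) {
    for (r in seq_len(cfg$records_per_class)) {
      x <- with_local_seed(substream_seed(cfg$seed, classes[[cl]], r), {
        if (cl == "healthy") synth_healthy(cfg, t) else synth_ictal(cfg, t)
      })
      i <- i + 1L
      out[[i]] <- eeg_record(round(x), cl, cfg$sampling_rate,
                             sprintf("%s_%03d", toupper(substr(cl, 1, 1)), r))
    }
  }
  structure(out, class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  labs <- vapply(x, function(r) r$class_label, "")
  cat(sprintf("EEG dataset: %d records (%d healthy, %d ictal), %d observations each\n",
              length(x), sum(labs == "healthy"), sum(labs == "ictal"),
              length(x[[1]]$amplitudes)))
  invisible(x)
}

#' Write a dataset as a Bonn-style directory tree
#'
#' Creates `<root>/<class>/<record_id>.txt` for every record plus a
#' `manifest.json` listing the files.
#'
#' @param dataset List of [eeg_record()] objects.
#' @param root Output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_bonn_dataset <- function(dataset, root) {
  entries <- lapply(dataset, function(r) {
    dir.create(file.path(root, r$class_label), recursive = TRUE,
               showWarnings = FALSE)
    rel <- file.path(r$class_label, paste0(r$record_id, ".txt"))
    write_bonn_ascii(r, file.path(root, rel))
    list(record_id = r$record_id, class_label = r$class_label,
         path = rel, n = length(r$amplitudes))
  })
  jsonlite::write_json(entries, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(root)
}

#' Read a Bonn-style directory tree
#'
#' Expects `<root>/healthy/*.txt` and `<root>/ictal/*.txt` (the layout
#' written by [write_bonn_dataset()]).
#'
#' @param root Directory containing per-class subdirectories.
#' @return An `"eeg_dataset"` list of records.
#' @export
read_bonn_dataset <- function(root) {
  out <- list()
  for (cl in c("healthy", "ictal")) {
    files <- sort(list.files(file.path(root, cl), pattern = "\\.txt$",
                             full.names = TRUE))
    out <- c(out, lapply(files, read_bonn_ascii, class_label = cl))
  }
  if (!length(out)) stop("no record files found under ", root, call. = FALSE)
  structure(out, class = "eeg_dataset")
}
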