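# Readers and writers: delimited trial matrices with JSON sidecars, minimal
# EDF support, dictionary and event-table serialization, pipeline config.
#
# Conventions: delimited trial matrices are UTF-8, comma-separated, '.'
# decimal, one trial per row; the sample index implies time (0-based,
# left-closed). Seconds are the external unit; samples are internal, with
# the sampling rate always taken from metadata, never re-inferred.

#' Pipeline configuration
#'
#' Defaults mirror the high-gamma movement-task protocol: band 85-145 Hz,
#' analysis sampling rate 500 Hz, snippet length M = 50 samples (100 ms),
#' duration grid 50-100 ms in 10 ms steps, gamma' = 1, statistics window
#' -0.5 to 2 s relative to the cue.
#'
#' @param band numeric `c(low, high)` in Hz.
#' @param band_order Butterworth order per pass.
#' @param fs_out analysis sampling rate in Hz.
#' @param M snippet length in samples.
#' @param gamma_prime DET threshold multiplier.
#' @param delta_grid_ms candidate atom durations in ms.
#' @param window statistics window in seconds relative to the cue.
#' @param L quantization levels.
#' @param seed integer seed.
#' @param ... further fields kept verbatim (e.g. simulation settings).
#' @return object of class `pipeline_config` (a named list with a stable
#'   `hash`).
#' @export
pipeline_config <- function(band = c(85, 145), band_order = 4L, fs_out = 500,
                            M = 50L, gamma_prime = 1,
                            delta_grid_ms = seq(50, 100, by = 10),
                            window = c(-0.5, 2), L = 16L, seed = 1L, ...) {
  cfg <- list(band = band, band_order = band_order, fs_out = fs_out,
              M = as.integer(M), gamma_prime = gamma_prime,
              delta_grid_ms = delta_grid_ms, window = window,
              L = as.integer(L), seed = seed, ...)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  fnv1a32(jsonlite::toJSON(cfg, digits = NA, auto_unbox = TRUE))
}

#' @rdname pipeline_config
#' @param path JSON file to read or write.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$hash <- NULL
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read an ensemble as delimited matrix plus JSON sidecar
#'
#' `<prefix>.csv` holds the trial matrix (one trial per row, no header);
#' `<prefix>.json` holds the sampling rate, labels, alignment offset, the
#' ground-truth event table when present, and provenance stamps (seed,
#' config hash).
#'
#' @param ens a `burst_ensemble` (or any list with `traces`, `fs_hz`,
#'   `labels`, `t0_s`).
#' @param prefix path prefix without extension.
#' @param seed,config_hash optional provenance stamps for the sidecar.
#' @return the prefix, invisibly.
#' @export
write_ensemble <- function(ens, prefix, seed = NULL, config_hash = NULL) {
  write.table(format(ens$traces, digits = 10, trim = TRUE, scientific = TRUE),
              paste0(prefix, ".csv"), sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  meta <- list(fs_hz = ens$fs_hz, t0_s = ens$t0_s %||% 0,
               n_trials = nrow(ens$traces), trial_len = ncol(ens$traces),
               labels = ens$labels, seed = seed, config_hash = config_hash)
  if (!is.null(ens$plan)) meta$events <- ens$plan$events
  if (!is.null(ens$dictionary))
    meta$atoms <- lapply(ens$dictionary, function(a)
      list(atom_id = a$atom_id, duration_samples = a$duration_samples,
           center_freq_hz = a$center_freq_hz, waveform = a$waveform))
  jsonlite::write_json(meta, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(prefix)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(prefix) {
  rec <- read_recording(paste0(prefix, ".csv"), format = "delimited",
                        sidecar = paste0(prefix, ".json"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dict <- NULL
  if (!is.null(meta$atoms)) {
    dict <- lapply(seq_len(nrow(meta$atoms)), function(i)
      burst_atom(meta$atoms$waveform[[i]], fs_hz = meta$fs_hz,
                 atom_id = meta$atoms$atom_id[i],
                 center_freq_hz = meta$atoms$center_freq_hz[i] %||% NA_real_))
  }
  plan <- NULL
  if (!is.null(meta$events) && length(meta$events))
    plan <- event_plan(as.data.frame(meta$events))
  structure(list(traces = rec$traces, fs_hz = rec$fs_hz, labels = rec$labels,
                 plan = plan, dictionary = dict, noise = NULL,
                 t0_s = meta$t0_s %||% 0),
            class = "burst_ensemble")
}

#' Read a multi-trial recording
#'
#' Delimited format: one trial per row, comma-separated; sampling rate and
#' labels come from the JSON sidecar (`sidecar`, defaulting to the file
#' path with extension `.json`). EDF format: one data record per trial,
#' first signal.
#'
#' @param path recording file.
#' @param format `"delimited"` or `"edf"`.
#' @param sidecar JSON sidecar path (delimited format).
#' @param channel signal index to extract (EDF).
#' @return list with `traces` (trials x samples), `fs_hz`, `labels`,
#'   `t0_s`.
#' @export
read_recording <- function(path, format = c("delimited", "edf"),
                           sidecar = NULL, channel = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (format == "edf") {
    edf <- read_edf(path)
    if (channel > length(edf$signals))
      stop(sprintf("EDF has %d signal(s); channel %d requested",
                   length(edf$signals), channel))
    return(list(traces = edf$signals[[channel]], fs_hz = edf$fs_hz[channel],
                labels = NULL, t0_s = 0))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, ",", fixed = TRUE)
  lens <- lengths(fields)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != median(lens))
    stop(sprintf("inconsistent trial lengths in %s: row(s) %s have %s fields (expected %d)",
                 path, paste(bad, collapse = ", "),
                 paste(lens[bad], collapse = ", "), median(lens)))
  }
  traces <- matrix(as.numeric(unlist(fields)), nrow = length(fields),
                   byrow = TRUE)
  if (is.null(sidecar)) sidecar <- paste0(sub("\\.[^.]+$", "", path), ".json")
  if (!file.exists(sidecar))
    stop("no sampling-rate metadata: sidecar not found at ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs_hz)) stop("sidecar lacks the sampling rate (fs_hz)")
  labels <- meta$labels
  if (!is.null(labels) && length(labels) != nrow(traces))
    stop("sidecar labels do not match the number of trials")
  list(traces = traces, fs_hz = meta$fs_hz, labels = labels,
       t0_s = meta$t0_s %||% 0)
}

#' Event table I/O
#'
#' Events are written as delimited text with columns `trial`, `channel`,
#' `tau_s`, `tau_sample`, `alpha`, `atom_id`.
#'
#' @param train a [encode()] result.
#' @param path output file.
#' @param channel channel identifier recorded with every event.
#' @export
write_events <- function(train, path, channel = 1L) {
  ev <- train$events
  out <- data.frame(trial = ev$trial, channel = channel, tau_s = ev$tau_s,
                    tau_sample = ev$tau_sample, alpha = ev$alpha,
                    atom_id = ev$atom_id)
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param fs_hz,t0_s,n_trials train metadata to restore.
#' @export
read_events <- function(path, fs_hz, t0_s = 0, n_trials = NULL) {
  ev <- read.table(path, sep = ",", header = TRUE)
  events <- data.frame(trial = as.integer(ev$trial),
                       tau_sample = as.integer(ev$tau_sample),
                       tau_s = ev$tau_s, alpha = ev$alpha,
                       atom_id = as.integer(ev$atom_id),
                       score = NA_real_)
  if (is.null(n_trials)) n_trials <- if (nrow(events)) max(events$trial) else 0L
  ids <- sort(unique(events$atom_id))
  atoms <- lapply(ids, function(i)
    structure(list(waveform = c(1, 0), duration_samples = 2L, atom_id = i,
                   center_freq_hz = NA_real_, fs_hz = fs_hz),
              class = "burst_atom"))
  new_tmpp_train(events, atoms, fs_hz, t0_s, n_trials)
}

#' Dictionary I/O
#'
#' `<prefix>.json` carries K, durations, per-atom metadata, the learn log
#' and provenance; `<prefix>.csv` carries the atom waveforms, one atom per
#' row, padded with trailing empty fields to the longest duration.
#'
#' @param dict a `burst_dictionary` or list of [burst_atom()]s.
#' @param prefix path prefix without extension.
#' @param seed,config_hash optional provenance stamps.
#' @export
write_dictionary <- function(dict, prefix, seed = NULL, config_hash = NULL) {
  atoms <- dictionary_atoms(dict)
  durs <- vapply(atoms, function(a) a$duration_samples, integer(1))
  meta <- list(K = length(atoms),
               durations = durs,
               atom_id = vapply(atoms, function(a) a$atom_id, integer(1)),
               fs_hz = if (length(atoms)) atoms[[1]]$fs_hz else NA_real_,
               seed = seed, config_hash = config_hash)
  if (inherits(dict, "burst_dictionary")) meta$learn_log <- dict$learn_log
  jsonlite::write_json(meta, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  if (length(atoms)) {
    wide <- max(durs)
    rows <- vapply(atoms, function(a)
      paste(c(format(a$waveform, digits = 10, trim = TRUE),
              rep("", wide - a$duration_samples)), collapse = ","),
      character(1))
    writeLines(rows, paste0(prefix, ".csv"))
  } else writeLines(character(0), paste0(prefix, ".csv"))
  invisible(prefix)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (meta$K == 0L) return(list())
  lines <- readLines(paste0(prefix, ".csv"))
  lapply(seq_len(meta$K), function(i) {
    vals <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    vals <- as.numeric(vals[nzchar(vals)])
    burst_atom(vals, fs_hz = meta$fs_hz, atom_id = meta$atom_id[i])
  })
}

# ---- minimal EDF -----------------------------------------------------------

#' Minimal EDF reader and writer
#'
#' Supports plain EDF with 16-bit samples: enough to round-trip multi-trial
#' single-channel ensembles (one data record per trial). Not a full EDF+
#' implementation (no annotations, no discontinuous records).
#'
#' @param path EDF file.
#' @return `read_edf`: list with `signals` (one trials x samples matrix per
#'   signal), `fs_hz` (per signal), `labels` (signal labels),
#'   `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr(8L)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  hdr(80L); hdr(80L); hdr(8L); hdr(8L)        # patient, recording, date, time
  hdr(8L)                                      # header bytes
  hdr(44L)                                     # reserved
  n_records <- as.integer(hdr(8L))
  record_dur <- as.numeric(hdr(8L))
  ns <- as.integer(hdr(4L))
  fld <- function(n) vapply(seq_len(ns), function(i) hdr(n), character(1))
  labels <- fld(16L); fld(80L); fld(8L)
  phys_min <- as.numeric(fld(8L)); phys_max <- as.numeric(fld(8L))
  dig_min <- as.numeric(fld(8L)); dig_max <- as.numeric(fld(8L))
  fld(80L)
  spr <- as.integer(fld(8L))                  # samples per record per signal
  fld(32L)
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- matrix(0L, n_records, spr[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw[[i]][r, ] <- readBin(con, "integer", spr[i], size = 2L,
                               signed = TRUE, endian = "little")
    }
  }
  signals <- lapply(seq_len(ns), function(i) {
    g <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    phys_min[i] + g * (raw[[i]] - dig_min[i])
  })
  list(signals = signals, fs_hz = spr / record_dur, labels = labels,
       n_records = n_records)
}

#' @rdname read_edf
#' @param traces trials x samples matrix (one data record per trial).
#' @param fs_hz sampling rate in Hz.
#' @param label signal label stored in the header.
#' @export
write_edf <- function(traces, fs_hz, path, label = "chan1") {
  traces <- as_trial_matrix(traces)
  n_records <- nrow(traces); spr <- ncol(traces)
  record_dur <- spr / fs_hz
  pmin_ <- min(traces); pmax_ <- max(traces)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768; dmax <- 32767
  dig <- round((traces - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) {
    s <- substr(s, 1L, n)
    writeChar(sprintf(paste0("%-", n, "s"), s), con, eos = NULL)
  }
  pad("0", 8L); pad("X", 80L); pad("X", 80L)
  pad("01.01.26", 8L); pad("00.00.00", 8L)
  pad(as.character(256L + 256L), 8L)
  pad("", 44L)
  pad(as.character(n_records), 8L)
  pad(format(record_dur, digits = 6), 8L)
  pad("1", 4L)
  pad(label, 16L); pad("", 80L); pad("uV", 8L)
  pad(format(pmin_, digits = 6), 8L); pad(format(pmax_, digits = 6), 8L)
  pad(as.character(dmin), 8L); pad(as.character(dmax), 8L)
  pad("", 80L)
  pad(as.character(spr), 8L)
  pad("", 32L)
  for (r in seq_len(n_records))
    writeBin(as.integer(dig[r, ]), con, size = 2L, endian = "little")
  invisible(path)
}
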