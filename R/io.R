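#' Write a continuous recording in BrainVision format
#'
#' Emits the standard triplet: text header (`.vhdr`), text marker file
#' (`.vmrk`), and IEEE float-32 multiplexed binary data (`.eeg`, microvolt,
#' little-endian). Event types map to conventional marker descriptions:
#' `stim_onset` -> `S  1`, `stim_offset` -> `S  2`, `response` -> `R  1`
#' (marker positions are 1-based, as in the format).
#'
#' @param rec A `continuous_recording`.
#' @param basename Output path without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "continuous_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  stem <- basename(basename)

  n_ch <- nrow(rec$voltages)
  ch_lines <- sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), rec$ch_names)
  header <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    sprintf("MarkerFile=%s.vmrk", stem),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", n_ch),
    sprintf("SamplingInterval=%d", as.integer(round(1e6 / rec$sfreq))),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    ch_lines
  )
  writeLines(header, vhdr, useBytes = TRUE)

  desc <- c(stim_onset = "S  1", stim_offset = "S  2", response = "R  1")
  typ <- c(stim_onset = "Stimulus", stim_offset = "Stimulus",
           response = "Response")
  ev <- rec$events
  mk <- sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(ev)) + 1L,
                typ[ev$type], desc[ev$type], ev$sample + 1L)
  marker <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    mk
  )
  writeLines(marker, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  # multiplexed: all channels of sample 1, then sample 2, ...
  writeBin(as.numeric(rec$voltages), con, size = 4, endian = "little")
  invisible(vhdr)
}

parse_vhdr_ini <- function(lines) {
  lines <- lines[!grepl("^\\s*(;|$)", lines)]
  kv <- grep("=", lines, fixed = TRUE, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(vals, keys)
}

#' Read a BrainVision recording
#'
#' Supports the subset of the format written by [write_brainvision()]:
#' binary IEEE float-32 or INT_16 data, multiplexed or vectorized
#' orientation, with per-channel resolution applied. Marker descriptions
#' `S  1`/`S  2`/`R  1` are mapped back to `stim_onset`/`stim_offset`/
#' `response`; other markers are kept with their raw description.
#'
#' @param vhdr Path to the `.vhdr` header file.
#' @param condition Optional condition tag to attach to the recording.
#' @param montage Montage to attach (matched by channel name when possible).
#' @return A `continuous_recording`.
#' @export
read_brainvision <- function(vhdr, condition = "unknown",
                             montage = standard_montage_32()) {
  info <- parse_vhdr_ini(readLines(vhdr, warn = FALSE, encoding = "UTF-8"))
  dir <- dirname(vhdr)
  n_ch <- as.integer(info[["NumberOfChannels"]])
  sfreq <- 1e6 / as.numeric(info[["SamplingInterval"]])
  fmt <- info[["BinaryFormat"]] %||% "IEEE_FLOAT_32"
  orient <- toupper(info[["DataOrientation"]] %||% "MULTIPLEXED")

  ch_keys <- sprintf("Ch%d", seq_len(n_ch))
  ch_info <- strsplit(unname(info[ch_keys]), ",")
  ch_names <- vapply(ch_info, `[`, character(1), 1)
  resolution <- vapply(ch_info, function(x) {
    r <- suppressWarnings(as.numeric(x[3]))
    if (is.na(r) || r == 0) 1 else r
  }, numeric(1))

  eeg_path <- file.path(dir, info[["DataFile"]])
  sz <- file.info(eeg_path)$size
  if (fmt == "IEEE_FLOAT_32") {
    n_val <- sz / 4
    raw_vals <- readBin(eeg_path, "numeric", n = n_val, size = 4,
                        endian = "little")
  } else if (fmt == "INT_16") {
    n_val <- sz / 2
    raw_vals <- readBin(eeg_path, "integer", n = n_val, size = 2,
                        signed = TRUE, endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  n_samples <- length(raw_vals) %/% n_ch
  raw_vals <- raw_vals[seq_len(n_samples * n_ch)]
  v <- if (orient == "MULTIPLEXED") {
    matrix(raw_vals, nrow = n_ch)
  } else {
    t(matrix(raw_vals, nrow = n_samples))
  }
  v <- v * resolution
  rownames(v) <- ch_names

  events <- data.frame(sample = integer(0), type = character(0),
                       id = integer(0))
  vmrk_path <- file.path(dir, info[["MarkerFile"]] %||% "")
  if (!is.na(info["MarkerFile"]) && file.exists(vmrk_path)) {
    ml <- readLines(vmrk_path, warn = FALSE, encoding = "UTF-8")
    ml <- grep("^Mk[0-9]+=", ml, value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
    mtype <- vapply(parts, `[`, character(1), 1)
    mdesc <- vapply(parts, `[`, character(1), 2)
    mpos <- vapply(parts, function(x) as.integer(x[3]), integer(1))
    keep <- mtype %in% c("Stimulus", "Response")
    back <- c("S  1" = "stim_onset", "S  2" = "stim_offset",
              "R  1" = "response")
    typ <- ifelse(mdesc[keep] %in% names(back), back[mdesc[keep]],
                  mdesc[keep])
    events <- data.frame(sample = mpos[keep] - 1L, type = unname(typ),
                         id = NA_integer_)
    for (tt in unique(events$type)) {
      sel <- events$type == tt
      events$id[sel] <- order(order(events$sample[sel]))
    }
    events <- events[order(events$sample), ]
    rownames(events) <- NULL
  }

  rec <- list(voltages = v, sfreq = sfreq, ch_names = ch_names,
              events = events,
              veog_channel = if ("vEOG" %in% ch_names) "vEOG" else NA_character_,
              condition = condition,
              montage = montage[match(intersect(montage$name, ch_names),
                                      montage$name), , drop = FALSE],
              provenance = sprintf("read_brainvision(%s)", basename(vhdr)))
  class(rec) <- "continuous_recording"
  rec
}

#' Behavioral log as TSV
#'
#' Schema: `trial`, `condition`, `true_label`, `response_key`, `latency_ms`.
#'
#' @param responses Behavioral data.frame.
#' @param path Output path.
#' @param condition Condition tag written alongside each trial.
#' @return `write_behavioral_tsv()` returns `path` invisibly;
#'   `read_behavioral_tsv()` returns the data.frame.
#' @export
write_behavioral_tsv <- function(responses, path, condition = "ambiguity") {
  out <- data.frame(trial = responses$trial,
                    condition = responses$condition %||% condition,
                    true_label = responses$true_label,
                    response_key = responses$response_key,
                    latency_ms = responses$latency_ms)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavioral_tsv
#' @export
read_behavioral_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Reversal rates of the reference cohort
#'
#' Average reversals per minute for the 21 observers of the onset-paradigm
#' EEG study the pipeline models, as printed in its participant table.
#' Used to exercise the participant-exclusion rule (fewer than 5 reversals
#' per minute excluded).
#'
#' @return Named numeric vector (participants `A`..`U`).
#' @export
example_reversal_rates <- function() {
  path <- system.file("extdata", "cohort_reversal_rates.tsv",
                      package = "revforecast", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stats::setNames(tab$reversals_per_min, tab$participant)
}

#' Persist and reload an epoch set
#'
#' Writes a labeled epoch set as a float-32 little-endian binary array
#' (`<basename>.dat`, trials x channels x samples in column-major order)
#' with a JSON sidecar (`<basename>.json`) carrying the dimensions, time
#' axis, sampling rate, channel names, per-trial table (condition, label,
#' rejected flag), and provenance, so preprocessed epochs can be exchanged
#' between sessions without rerunning the chain.
#'
#' @param ep An `epoch_set`.
#' @param basename Output path without extension.
#' @return `write_epochs()` returns `basename` invisibly; `read_epochs()`
#'   returns the `epoch_set`.
#' @export
write_epochs <- function(ep, basename) {
  stopifnot(inherits(ep, "epoch_set"))
  sidecar <- list(
    dims = dim(ep$data),
    times = ep$times,
    sfreq = ep$sfreq,
    ch_names = ep$ch_names,
    info = ep$info,
    provenance = ep$provenance,
    format = "float32-le"
  )
  jsonlite::write_json(sidecar, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  con <- file(paste0(basename, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(ep$data), con, size = 4, endian = "little")
  invisible(basename)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(basename) {
  sidecar <- jsonlite::read_json(paste0(basename, ".json"),
                                 simplifyVector = TRUE)
  dims <- as.integer(sidecar$dims)
  vals <- readBin(paste0(basename, ".dat"), "numeric", n = prod(dims),
                  size = 4, endian = "little")
  dat <- array(vals, dims, dimnames = list(NULL, sidecar$ch_names, NULL))
  ep <- list(data = dat, times = sidecar$times,
             info = as.data.frame(sidecar$info),
             sfreq = sidecar$sfreq, ch_names = sidecar$ch_names,
             montage = standard_montage_32(),
             provenance = sidecar$provenance)
  class(ep) <- "epoch_set"
  ep
}
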