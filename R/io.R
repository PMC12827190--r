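#' Default temporal-channel selection pattern
#'
#' Regular expression matching the right/left temporal gradiometer labels
#' (MRT31-MRT58 and MLT31-MLT58 style names) that carry a strong cardiac
#' signature and are the default input to the ICA path.
#'
#' @return A character scalar (regular expression).
#' @export
temporal_channel_pattern <- function() {
  "^M[LR]T(3[1-9]|4[0-9]|5[0-8])$"
}

#' Load a multichannel recording
#'
#' Reads a recording from CSV (delimited text with a header naming channels,
#' optionally a leading time column), the package's own serialized container
#' (RDS), or native MEG formats (FIF, CTF .ds directory) via the installed
#' MNE-Python bridge. For native formats channel roles are inferred from the
#' format metadata; for CSV they default to \code{"other"} unless supplied.
#'
#' @param path file path (for \code{ctf_ds}, the .ds directory).
#' @param format one of \code{"csv"}, \code{"rds"}, \code{"fif"},
#'   \code{"ctf_ds"}; default guesses from the file extension.
#' @param rate sampling rate in Hz; required for CSV without a time column.
#' @param channel_roles optional roles vector overriding the default/inferred
#'   roles (CSV/RDS only).
#' @param ecg_channel optional channel name to mark with role
#'   \code{"ecg_bipolar"}.
#' @return A [multichannel_recording()].
#' @export
load_recording <- function(path, format = c("auto", "csv", "rds", "fif", "ctf_ds"),
                           rate = NULL, channel_roles = NULL, ecg_channel = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", rds = "rds", fif = "fif", ds = "ctf_ds",
                     stopf("cannot guess format from extension %s", ext,
                           class = "mecg_format_error"))
  }
  if (!file.exists(path))
    stopf("no such file: %s", path, class = "mecg_format_error")
  rec <- switch(format,
    csv = read_recording_csv(path, rate = rate),
    rds = {
      obj <- readRDS(path)
      if (!inherits(obj, "multichannel_recording"))
        stopf("%s does not contain a multichannel_recording", path,
              class = "mecg_format_error")
      obj
    },
    fif = read_recording_mne(path, "fif"),
    ctf_ds = read_recording_mne(path, "ctf_ds"))
  if (!is.null(channel_roles)) {
    if (format %in% c("fif", "ctf_ds"))
      stopf("channel_roles override is only supported for csv/rds input")
    rec$channel_roles <- rep(as.character(channel_roles), length.out = nrow(rec$samples))
  }
  if (!is.null(ecg_channel)) {
    i <- match(ecg_channel, rec$channel_names)
    if (is.na(i)) stopf("ecg_channel %s not found", ecg_channel)
    rec$channel_roles[i] <- "ecg_bipolar"
  }
  multichannel_recording(rec$samples, rec$rate, rec$channel_names, rec$channel_roles)
}

read_recording_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) == 0L) stopf("empty CSV", class = "mecg_empty_input")
  nm <- names(df)
  has_time <- tolower(nm[1]) %in% c("t", "time", "time_s", "t_s")
  if (has_time) {
    tcol <- df[[1]]
    dt <- diff(tcol)
    if (length(dt) < 1L || any(dt <= 0))
      stopf("time column must be strictly increasing", class = "mecg_format_error")
    rate <- 1 / stats::median(dt)
    df <- df[, -1, drop = FALSE]
    nm <- nm[-1]
  } else if (is.null(rate)) {
    stopf("CSV has no time column; supply rate explicitly", class = "mecg_format_error")
  }
  if (ncol(df) == 0L) stopf("CSV has zero channels", class = "mecg_empty_input")
  samples <- t(as.matrix(df))
  dimnames(samples) <- NULL
  list(samples = samples, rate = rate, channel_names = nm,
       channel_roles = rep("other", length(nm)))
}

# Native MEG formats through MNE-Python: the bridge script dumps a TSV matrix
# plus JSON metadata into a temp dir, which we read back. Requires a python
# with mne on the PATH.
read_recording_mne <- function(path, format) {
  script <- system.file("python", "export_recording.py", package = "mecg")
  if (script == "") stopf("bundled MNE bridge script not found")
  py <- Sys.which("python")
  if (py == "") stopf("python not found on PATH; FIF/CTF input needs MNE-Python",
                      class = "mecg_format_error")
  out <- tempfile("mecg_mne_")
  dir.create(out)
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  res <- suppressWarnings(
    system2(py, c(script, shQuote(path), format, shQuote(out)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stopf("MNE bridge failed reading %s:\n%s", path,
          paste(utils::tail(res, 5), collapse = "\n"), class = "mecg_format_error")
  meta <- jsonlite::read_json(file.path(out, "meta.json"), simplifyVector = TRUE)
  dat <- matrix(scan(file.path(out, "data.tsv"), quiet = TRUE),
                nrow = length(meta$channel_names), byrow = TRUE)
  list(samples = dat, rate = meta$rate, channel_names = meta$channel_names,
       channel_roles = meta$channel_roles)
}

#' Save a multichannel recording
#'
#' Writes CSV (leading \code{t} column in seconds; channel roles are not
#' representable in CSV) or the package's serialized container (RDS), which
#' round-trips samples, rate, names and roles exactly.
#'
#' @param rec a [multichannel_recording()].
#' @param path output file path.
#' @param format \code{"csv"} or \code{"rds"}; default from extension.
#' @return \code{path}, invisibly.
#' @export
save_recording <- function(rec, path, format = c("auto", "csv", "rds")) {
  stopifnot(inherits(rec, "multichannel_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), csv = "csv", rds = "rds",
                     stopf("cannot guess format from extension"))
  if (format == "rds") {
    saveRDS(rec, path)
  } else {
    n <- ncol(rec$samples)
    df <- data.frame(t = (seq_len(n) - 1) / rec$rate)
    for (i in seq_along(rec$channel_names)) df[[rec$channel_names[i]]] <- rec$samples[i, ]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Subset channels by glob pattern or explicit list
#'
#' @param rec a [multichannel_recording()].
#' @param pattern a glob pattern (e.g. \code{"MLT*"}), a regular expression
#'   when \code{regex = TRUE}, or a character vector of exact channel names.
#'   The default selects the temporal gradiometers (MRT/MLT 31-58).
#' @param regex treat \code{pattern} as a regular expression.
#' @return A [multichannel_recording()] with the matching channels, original
#'   order and rate preserved.
#' @export
select_channels <- function(rec, pattern = temporal_channel_pattern(),
                            regex = missing(pattern)) {
  stopifnot(inherits(rec, "multichannel_recording"))
  if (length(pattern) > 1L || (!regex && !grepl("[*?]", pattern))) {
    keep <- rec$channel_names %in% pattern
    if (length(pattern) > sum(keep) && !all(pattern %in% rec$channel_names))
      stopf("channel(s) not found: %s",
            paste(setdiff(pattern, rec$channel_names), collapse = ", "),
            class = "mecg_selection_error")
  } else if (regex) {
    keep <- grepl(pattern, rec$channel_names)
  } else {
    keep <- glob_match(pattern, rec$channel_names)
  }
  if (!any(keep))
    stopf("no channel matches pattern %s", paste(pattern, collapse = ","),
          class = "mecg_selection_error")
  multichannel_recording(rec$samples[keep, , drop = FALSE], rec$rate,
                         rec$channel_names[keep], rec$channel_roles[keep])
}

#' Extract the independently recorded ECG channel
#'
#' @param rec a [multichannel_recording()].
#' @param name optional channel name; required when zero or several channels
#'   carry role \code{"ecg_bipolar"}.
#' @return A [cardiac_trace()] with source \code{"I-ECG"}.
#' @export
extract_ecg_channel <- function(rec, name = NULL) {
  stopifnot(inherits(rec, "multichannel_recording"))
  if (is.null(name)) {
    i <- which(rec$channel_roles == "ecg_bipolar")
    if (length(i) != 1L)
      stopf("%d channels have role ecg_bipolar; supply name=", length(i),
            class = "mecg_ambiguity_error")
  } else {
    i <- match(name, rec$channel_names)
    if (is.na(i)) stopf("channel %s not found", name, class = "mecg_selection_error")
  }
  cardiac_trace(rec$samples[i, ], rec$rate, source = "I-ECG")
}
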