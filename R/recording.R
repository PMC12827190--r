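#' Multichannel electrophysiological recording
#'
#' Container for a sensor-by-time matrix with one shared sampling rate and a
#' role attached to every channel. Roles drive downstream channel selection:
#' \code{"meg_gradiometer"} channels feed the ICA path, \code{"reference"}
#' channels feed the reference-sensor path, and the \code{"ecg_bipolar"}
#' channel is the independently recorded ECG (I-ECG) used as comparator.
#'
#' @param samples numeric matrix, channels x timepoints.
#' @param rate sampling frequency in Hz (positive scalar).
#' @param channel_names character vector of unique channel labels, one per row.
#' @param channel_roles character vector, one of \code{"meg_gradiometer"},
#'   \code{"reference"}, \code{"ecg_bipolar"}, \code{"other"} per channel.
#'   Defaults to \code{"other"} everywhere.
#' @return An object of class \code{multichannel_recording}.
#' @export
multichannel_recording <- function(samples, rate, channel_names,
                                   channel_roles = rep("other", nrow(samples))) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stopf("samples must be a numeric matrix (channels x timepoints)")
  if (nrow(samples) == 0L)
    stopf("recording has zero channels", class = "mecg_empty_input")
  if (!is_scalar_num(rate) || rate <= 0)
    stopf("rate must be a positive scalar (Hz)")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(samples))
    stopf("channel_names length (%d) != channel count (%d)",
          length(channel_names), nrow(samples))
  if (anyDuplicated(channel_names))
    stopf("duplicate channel names: %s",
          paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  channel_roles <- as.character(channel_roles)
  if (length(channel_roles) != length(channel_names))
    stopf("channel_roles length != channel_names length")
  ok <- channel_roles %in% c("meg_gradiometer", "reference", "ecg_bipolar", "other")
  if (!all(ok))
    stopf("unknown channel role(s): %s", paste(unique(channel_roles[!ok]), collapse = ", "))
  structure(
    list(samples = samples, rate = as.numeric(rate),
         channel_names = channel_names, channel_roles = channel_roles),
    class = "multichannel_recording")
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("<multichannel_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate, ncol(x$samples) / x$rate))
  tab <- table(x$channel_roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.multichannel_recording <- function(x) dim(x$samples)

n_samples <- function(rec) ncol(rec$samples)

#' One-dimensional cardiac trace
#'
#' A single cardiac signal with its provenance: \code{"I-ECG"} (independently
#' recorded bipolar ECG), \code{"C-IC"} (cardiac independent component from
#' ICA), or \code{"REF"} (MEG reference sensor). Together C-IC and REF are the
#' M-ECG channels.
#'
#' @param values numeric vector of finite samples.
#' @param rate sampling frequency in Hz.
#' @param source provenance label: \code{"I-ECG"}, \code{"C-IC"} or \code{"REF"}.
#' @param normalized logical; \code{TRUE} after [baseline_normalize()], in
#'   which case \code{max(abs(values))} is 1.
#' @return An object of class \code{cardiac_trace}.
#' @export
cardiac_trace <- function(values, rate, source = c("I-ECG", "C-IC", "REF"),
                          normalized = FALSE) {
  source <- match.arg(source)
  values <- as.numeric(values)
  if (length(values) == 0L) stopf("empty trace", class = "mecg_empty_input")
  if (!all(is.finite(values))) stopf("trace contains non-finite values")
  if (!is_scalar_num(rate) || rate <= 0) stopf("rate must be a positive scalar (Hz)")
  if (isTRUE(normalized) && abs(max(abs(values)) - 1) > 1e-9)
    stopf("normalized trace must have max |value| == 1")
  structure(list(values = values, rate = as.numeric(rate),
                 source = source, normalized = isTRUE(normalized)),
            class = "cardiac_trace")
}

#' @export
print.cardiac_trace <- function(x, ...) {
  cat(sprintf("<cardiac_trace %s> %d samples @ %g Hz (%.1f s)%s\n",
              x$source, length(x$values), x$rate, length(x$values) / x$rate,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
length.cardiac_trace <- function(x) length(x$values)
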