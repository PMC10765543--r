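# Plain-text interchange: wide-CSV signal files (time_ms + one column per
# channel, channels named by the grid codec), annotation CSV, fiducials CSV.

#' Write / read multichannel signals as wide CSV
#'
#' One row per sample: \code{time_ms} followed by one column per channel,
#' columns named with the channel-label codec (see
#' [format_channel_label()]).
#'
#' @param signals named list of equal-length numeric vectors or
#'   [generate_egm()] results.
#' @param path output file.
#' @param fs_hz sampling rate (used when elements are bare vectors).
#' @return \code{path}, invisibly.
#' @export
write_signals_csv <- function(signals, path, fs_hz = 2048) {
  get_sig <- function(s) if (is.list(s)) s$signal else s
  if (is.list(signals[[1]]) && !is.null(signals[[1]]$fs_hz)) {
    fs_hz <- signals[[1]]$fs_hz
  }
  mat <- vapply(signals, get_sig, numeric(length(get_sig(signals[[1]]))))
  d <- data.frame(time_ms = (seq_len(nrow(mat)) - 1) / fs_hz * 1000)
  d <- cbind(d, as.data.frame(mat))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals_csv
#' @return for the reader: list with \code{signals} (named list),
#'   \code{fs_hz}, \code{t_ms}.
#' @export
read_signals_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  t_ms <- d$time_ms
  fs_hz <- 1000 / stats::median(diff(t_ms))
  sigs <- as.list(d[setdiff(names(d), "time_ms")])
  list(signals = sigs, fs_hz = fs_hz, t_ms = t_ms)
}

#' Write / read beat and event annotations as CSV
#'
#' Beats and events share one stream with columns \code{time_ms},
#' \code{beat_class} (PACED/ECTOPIC, empty for events),
#' \code{morphology_index}, \code{event_type} (e.g. DEFIB, empty for
#' beats) and \code{block_id}.
#'
#' @param beats,events data.frames as produced by [generate_beat_series()].
#' @param path file path.
#' @return \code{path} (writer) or a list with \code{beats}, \code{events}
#'   (reader).
#' @export
write_annotations_csv <- function(beats, events, path) {
  b <- data.frame(time_ms = beats$time_ms, beat_class = beats$beat_class,
                  morphology_index = beats$morphology_index,
                  event_type = "", block_id = beats$block_id)
  e <- if (nrow(events)) {
    data.frame(time_ms = events$time_ms, beat_class = "",
               morphology_index = NA_real_, event_type = events$event_type,
               block_id = events$block_id)
  } else NULL
  d <- rbind(b, e)
  d <- d[order(d$time_ms), ]
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  d <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  is_beat <- !is.na(d$beat_class) & d$beat_class != ""
  beats <- d[is_beat, c("time_ms", "beat_class", "morphology_index",
                        "block_id")]
  events <- d[!is_beat, c("time_ms", "event_type", "block_id")]
  rownames(beats) <- rownames(events) <- NULL
  list(beats = beats, events = events)
}

#' Write detected fiducials as CSV
#'
#' @param fiducials data.frame with \code{channel}, \code{at_ms},
#'   \code{rt_ms}, \code{rtc_ms}, \code{qc} (one beat per row).
#' @param path file path.
#' @export
write_fiducials_csv <- function(fiducials, path) {
  utils::write.csv(fiducials, path, row.names = FALSE, na = "")
  invisible(path)
}
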