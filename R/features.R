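# Activation/repolarization fiducials on unipolar electrograms and the
# channel rejection rules (injury current, flat T, noise, cavity potential).

#' Default analysis windows relative to the pacing stimulus
#'
#' QRS window [0, 150] ms; T window (150, 0.9 x RR] ms. The paced beat
#' reference is the stimulus time from the annotation stream.
#'
#' @param rr_ms paced cycle length (ms).
#' @param window_ms total beat window; defaults to 0.9 x RR.
#' @return list with \code{qrs} and \code{t} windows (ms).
#' @export
beat_windows <- function(rr_ms, window_ms = 0.9 * rr_ms) {
  list(qrs = c(0, 150), t = c(150, window_ms))
}

smoothed_derivative <- function(signal, fs_hz, smoothing_ms = 5) {
  k <- max(1L, round(smoothing_ms / 1000 * fs_hz))
  if (k %% 2L == 0L) k <- k + 1L
  if (length(signal) <= k + 2L) {
    stop("configuration error: signal shorter than smoothing kernel")
  }
  sm <- as.numeric(stats::filter(signal, rep(1 / k, k), sides = 2))
  dt_ms <- 1000 / fs_hz
  n <- length(sm)
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (2 * dt_ms)
  list(smooth = sm, deriv = d, dt_ms = dt_ms)
}

#' Detect activation and repolarization times
#'
#' Activation time (AT) is the time of minimum dV/dt within the QRS window;
#' repolarization time (RT) is the time of maximum dV/dt within the T-wave
#' window, irrespective of T-wave morphology (positive, negative or
#' biphasic). The derivative is a central first difference of the signal
#' after a centred moving-average smoother (default 5 ms), which makes both
#' fiducials exactly equivariant under sample shifts.
#'
#' @param signal numeric vector (one beat window, mV) or a
#'   [generate_egm()] result.
#' @param fs_hz sampling rate (ignored when \code{signal} carries its own).
#' @param windows a [beat_windows()] list; ms relative to window start.
#' @param smoothing_ms moving-average width (ms) for the QRS derivative.
#' @param t_smoothing_ms moving-average width for the T-wave derivative;
#'   the T deflection is an order of magnitude slower than the intrinsic
#'   deflection, so its derivative tolerates (and, under noise, needs) a
#'   wider smoother. The smoothers are symmetric, so neither fiducial is
#'   shifted.
#' @return one-row data.frame: \code{at_ms}, \code{rt_ms}, \code{ok}
#'   (FALSE with NA fiducials for degenerate/flat input), \code{note}.
#' @export
detect_fiducials <- function(signal, fs_hz = 2048,
                             windows = beat_windows(rr_ms = 1200),
                             smoothing_ms = 5, t_smoothing_ms = 4 * smoothing_ms) {
  if (is.list(signal)) {
    fs_hz <- signal$fs_hz
    signal <- signal$signal
  }
  stopifnot(fs_hz > 0)
  d_qrs <- smoothed_derivative(signal, fs_hz, smoothing_ms)
  d_t <- smoothed_derivative(signal, fs_hz, t_smoothing_ms)
  t_ms <- (seq_along(signal) - 1) * d_qrs$dt_ms
  if (max(signal) - min(signal) < 1e-9) {
    return(data.frame(at_ms = NA_real_, rt_ms = NA_real_, ok = FALSE,
                      note = "flat-line signal, no fiducials"))
  }
  in_qrs <- which(t_ms >= windows$qrs[1] & t_ms <= windows$qrs[2] &
                    !is.na(d_qrs$deriv))
  in_t <- which(t_ms > windows$t[1] & t_ms <= windows$t[2] & !is.na(d_t$deriv))
  if (!length(in_qrs) || !length(in_t)) {
    stop("configuration error: analysis windows lie outside the signal")
  }
  at <- t_ms[in_qrs[which.min(d_qrs$deriv[in_qrs])]]
  # T upstroke: coarse argmax, then sub-sample refinement by the vertex of
  # a local quadratic fit to the derivative (averages noise over the broad
  # T-derivative peak without shifting it)
  i0 <- in_t[which.max(d_t$deriv[in_t])]
  rt <- t_ms[i0] + quad_vertex_offset(d_t$deriv, i0, d_t$dt_ms, half_ms = 12)
  data.frame(at_ms = at, rt_ms = rt, ok = TRUE, note = "")
}

quad_vertex_offset <- function(deriv, i0, dt_ms, half_ms = 12) {
  w <- max(2L, round(half_ms / dt_ms))
  idx <- max(1L, i0 - w):min(length(deriv), i0 + w)
  idx <- idx[!is.na(deriv[idx])]
  if (length(idx) < 5L) return(0)
  x <- (idx - i0) * dt_ms
  co <- stats::lm.fit(cbind(1, x, x^2), deriv[idx])$coefficients
  if (!is.finite(co[3]) || co[3] >= 0) return(0)
  max(-half_ms, min(half_ms, -co[2] / (2 * co[3])))
}

#' Channel-rejection thresholds
#'
#' @param injury_fraction_threshold reject when the ST-TQ baseline shift
#'   exceeds this fraction of the T-wave amplitude (default 0.80).
#' @param flat_t_amplitude_threshold minimum T-wave peak-to-peak (mV).
#' @param noise_rms_ratio_threshold maximum ratio of high-band residual RMS
#'   to QRS amplitude.
#' @param cavity_amplitude_threshold maximum QRS peak-to-peak (mV) for a
#'   cavity potential.
#' @param cavity_qs_ratio_threshold minimum QS-morphology score (1 -
#'   positive excursion / QRS peak-to-peak) for a cavity potential.
#' @return list of class \code{qc_params}.
#' @export
qc_params <- function(injury_fraction_threshold = 0.80,
                      flat_t_amplitude_threshold = 0.1,
                      noise_rms_ratio_threshold = 0.05,
                      cavity_amplitude_threshold = 0.6,
                      cavity_qs_ratio_threshold = 0.9) {
  stopifnot(injury_fraction_threshold > 0, injury_fraction_threshold <= 1)
  structure(list(
    injury_fraction_threshold = injury_fraction_threshold,
    flat_t_amplitude_threshold = flat_t_amplitude_threshold,
    noise_rms_ratio_threshold = noise_rms_ratio_threshold,
    cavity_amplitude_threshold = cavity_amplitude_threshold,
    cavity_qs_ratio_threshold = cavity_qs_ratio_threshold
  ), class = "qc_params")
}

#' Quality metrics and rejection label for one channel
#'
#' Operationalizes the rejection rules for intramural needle recordings:
#' persistent major injury current (ST-TQ baseline shift > 80% of the
#' T-wave amplitude), noise, flat T waves, and cavity potentials from a
#' needle protruding into the ventricle. The injury metric is
#' \code{|median(ST) - median(TQ)| / T peak-to-peak}, with the ST segment
#' sampled 80-120 ms after AT and the TQ segment over the last 100 ms of
#' the beat window; being a ratio it is invariant to amplitude scaling.
#'
#' @param signal numeric beat window or [generate_egm()] result.
#' @param fs_hz sampling rate.
#' @param windows a [beat_windows()] list.
#' @param params a [qc_params()] object.
#' @return one-row data.frame with the metrics and \code{qc} in
#'   \{ACCEPT, REJECT_INJURY, REJECT_FLAT_T, REJECT_NOISE, REJECT_CAVITY\}.
#' @export
channel_qc_metrics <- function(signal, fs_hz = 2048,
                               windows = beat_windows(rr_ms = 1200),
                               params = qc_params()) {
  if (is.list(signal) && !is.null(signal$signal)) {
    fs_hz <- signal$fs_hz
    signal <- signal$signal
  }
  sd0 <- smoothed_derivative(signal, fs_hz)
  t_ms <- (seq_along(signal) - 1) * sd0$dt_ms
  sm <- sd0$smooth
  seg <- function(lo, hi) sm[!is.na(sm) & t_ms >= lo & t_ms <= hi]

  qrs_seg <- seg(windows$qrs[1], windows$qrs[2])
  t_seg <- seg(windows$t[1], windows$t[2])
  qrs_pp <- diff(range(qrs_seg))
  t_pp <- diff(range(t_seg))
  qs_score <- 1 - (max(qrs_seg) - stats::median(seg(0, 20))) / max(qrs_pp, 1e-9)

  in_qrs <- which(t_ms >= windows$qrs[1] & t_ms <= windows$qrs[2] &
                    !is.na(sd0$deriv))
  at <- t_ms[in_qrs[which.min(sd0$deriv[in_qrs])]]
  st_seg <- seg(at + 80, at + 120)
  tq_seg <- seg(max(t_ms) - 100, max(t_ms))
  injury_metric <- abs(stats::median(st_seg) - stats::median(tq_seg)) /
    max(t_pp, 1e-9)
  resid <- signal - sm
  noise_ratio <- sqrt(mean(resid^2, na.rm = TRUE)) / max(qrs_pp, 1e-9)

  qc <- if (qrs_pp < params$cavity_amplitude_threshold &&
              qs_score > params$cavity_qs_ratio_threshold) {
    "REJECT_CAVITY"
  } else if (noise_ratio > params$noise_rms_ratio_threshold) {
    "REJECT_NOISE"
  } else if (t_pp < params$flat_t_amplitude_threshold) {
    "REJECT_FLAT_T"
  } else if (injury_metric > params$injury_fraction_threshold) {
    "REJECT_INJURY"
  } else "ACCEPT"

  data.frame(qrs_pp_mv = qrs_pp, t_pp_mv = t_pp, qs_score = qs_score,
             injury_metric = injury_metric, noise_ratio = noise_ratio,
             qc = qc, stringsAsFactors = FALSE)
}

#' Apply channel rejection to a set of electrograms
#'
#' @param signals named list of beat windows (names = channel labels) or
#'   [generate_egm()] results.
#' @param fs_hz sampling rate for bare numeric signals.
#' @param windows a [beat_windows()] list.
#' @param params a [qc_params()] object.
#' @param grid optional [build_mapping_grid()]; needed for
#'   \code{mode = "needle"}.
#' @param mode \code{"channel"} rejects individual channels;
#'   \code{"needle"} additionally disregards a whole needle when at least
#'   \code{needle_reject_min} of its four channels are rejected.
#' @param needle_reject_min channels that must fail before the needle is
#'   disregarded in needle mode.
#' @return data.frame with one row per channel: \code{channel}, metrics,
#'   \code{qc} (after any needle-level disposition) and \code{channel_qc}
#'   (the per-channel label).
#' @export
channel_qc <- function(signals, fs_hz = 2048,
                       windows = beat_windows(rr_ms = 1200),
                       params = qc_params(), grid = NULL,
                       mode = c("channel", "needle"),
                       needle_reject_min = 2L) {
  mode <- match.arg(mode)
  labels <- names(signals)
  if (is.null(labels)) labels <- sprintf("ch%03d", seq_along(signals))
  out <- do.call(rbind, lapply(signals, channel_qc_metrics, fs_hz = fs_hz,
                               windows = windows, params = params))
  out <- cbind(channel = labels, out)
  rownames(out) <- NULL
  out$channel_qc <- out$qc
  if (mode == "needle") {
    if (is.null(grid)) stop("needle-mode QC needs the mapping grid")
    addr <- parse_channel_label(out$channel)
    needle_key <- paste(addr$wall, addr$level, addr$column)
    n_bad <- tapply(out$qc != "ACCEPT", needle_key, sum)
    bad_needles <- names(n_bad)[n_bad >= needle_reject_min]
    kill <- needle_key %in% bad_needles & out$qc == "ACCEPT"
    out$qc[kill] <- "REJECT_NEEDLE"
  }
  out
}

#' Van de Water rate correction of a repolarization time
#'
#' \code{RTc = RT - 0.087 x (RR - 1000)}, the heart-rate correction
#' optimized for the anesthetized dog; identical in form to the QTc
#' correction ([qtc_van_de_water()]). At RR = 1000 ms the correction is
#' zero.
#'
#' @param rt_ms repolarization time (ms).
#' @param rr_ms cycle length (ms), > 0.
#' @return corrected repolarization time (ms), full precision.
#' @export
#' @examples
#' correct_rt(453, 600)   # 487.8
#' correct_rt(573, 1200)  # 555.6
correct_rt <- function(rt_ms, rr_ms) {
  stopifnot(all(rr_ms > 0))
  rt_ms - 0.087 * (rr_ms - 1000)
}
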