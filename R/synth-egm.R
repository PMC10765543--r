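# Synthetic unipolar electrograms with analytically known fiducials.
# Deflections are built from logistic sigmoid steps: a steep step has its
# extreme slope exactly at its centre, so the constructed activation and
# repolarization times are the true argmin/argmax of dV/dt by design.

sigm <- function(t, center, tau) stats::plogis((t - center) / tau)

#' Channel quality labels
#'
#' \code{CLEAN}: intact intramural electrogram. \code{INJURY}: persistent
#' injury current, i.e. a DC shift between the TQ baseline and the ST
#' segment. \code{FLAT_T}: T wave attenuated below the detection floor.
#' \code{NOISY}: broadband noise. \code{CAVITY}: low-amplitude QS morphology
#' from an electrode protruding into the ventricular cavity.
#' @export
QUALITY_LABELS <- c("CLEAN", "INJURY", "FLAT_T", "NOISY", "CAVITY")

#' Generate one synthetic unipolar electrogram beat
#'
#' Builds one beat window of a unipolar electrogram whose steepest negative
#' slope within the QRS is exactly at \code{at_ms} and whose steepest
#' positive slope of the T deflection is exactly at \code{rt_ms} (both true
#' for positive and negative T waves). Quality corruptions are applied on
#' top of the clean waveform; ground-truth fiducials are returned alongside.
#'
#' The sampled window holds \code{floor(fs_hz * beat_window_ms / 1000)}
#' samples at times \code{(0:(n-1)) / fs_hz * 1000} ms.
#'
#' @param at_ms true activation time (ms after the pacing stimulus).
#' @param rt_ms true repolarization time (ms); must exceed \code{at_ms}.
#' @param quality one of [QUALITY_LABELS].
#' @param injury_fraction for \code{INJURY}: baseline (TQ-ST) offset as a
#'   fraction of the T-wave amplitude, in [0, 3].
#' @param t_polarity +1 for an upright T wave, -1 for a negative T wave.
#' @param fs_hz sampling frequency (default 2048 Hz).
#' @param beat_window_ms beat window length (ms); must exceed \code{rt_ms}.
#' @param noise_sd_mv SD of additive measurement noise applied to every
#'   channel (0 = noiseless); \code{NOISY} channels additionally receive
#'   broadband noise of \code{noisy_sd_mv}.
#' @param qrs_amplitude_mv,t_amplitude_mv deflection amplitudes.
#' @param noisy_sd_mv broadband noise SD used for \code{NOISY} channels.
#' @param flat_t_scale residual T amplitude fraction for \code{FLAT_T}.
#' @return list with \code{signal} (mV), \code{t_ms} (sample times),
#'   \code{fs_hz} and \code{truth} (at_ms, rt_ms, quality, injury_fraction,
#'   t_polarity, amplitudes).
#' @export
generate_egm <- function(at_ms, rt_ms, quality = "CLEAN",
                         injury_fraction = 0, t_polarity = 1,
                         fs_hz = 2048, beat_window_ms = 1000,
                         noise_sd_mv = 0,
                         qrs_amplitude_mv = 2, t_amplitude_mv = 0.5,
                         noisy_sd_mv = 0.25, flat_t_scale = 0.05) {
  if (!(at_ms > 0 && at_ms < rt_ms)) {
    stop("parameter error: need 0 < at_ms < rt_ms (got at=", at_ms,
         ", rt=", rt_ms, ")")
  }
  if (rt_ms >= beat_window_ms) {
    stop("parameter error: rt_ms must lie inside the beat window")
  }
  quality <- match.arg(quality, QUALITY_LABELS)
  stopifnot(injury_fraction >= 0, injury_fraction <= 3)

  n <- floor(fs_hz * beat_window_ms / 1000)
  t <- (seq_len(n) - 1) / fs_hz * 1000
  a_q <- qrs_amplitude_mv
  a_t <- t_amplitude_mv * if (quality == "FLAT_T") flat_t_scale else 1

  if (quality == "CAVITY") {
    # low-amplitude monophasic QS complex, essentially no T wave
    sig <- -0.12 * a_q * (sigm(t, at_ms, 4) - sigm(t, at_ms + 35, 12)) +
      0.02 * a_t * (sigm(t, rt_ms, 10) - sigm(t, rt_ms + 90, 35))
  } else {
    # small leading R wave well before the intrinsic deflection
    r_wave <- 0.35 * a_q * (sigm(t, at_ms - 22, 4) - sigm(t, at_ms - 12, 4))
    # steep negative intrinsic deflection centred at at_ms; recovery fast
    # enough that the ST segment (80-120 ms after AT) is back to baseline
    qrs <- -a_q * (sigm(t, at_ms, 2.5) - sigm(t, at_ms + 28, 7))
    # width of the slow limb of the T wave, compressed when the beat
    # window leaves little room after rt_ms
    t_off <- min(110, 0.35 * (beat_window_ms - rt_ms))
    t_tau <- 0.41 * t_off
    if (t_polarity >= 0) {
      # upright T: steep upstroke at rt_ms, wide return to baseline
      t_wave <- a_t * (sigm(t, rt_ms, 8) - sigm(t, rt_ms + t_off, t_tau))
    } else {
      # negative T: wide descent, steep terminal upstroke at rt_ms
      t_wave <- a_t * (sigm(t, rt_ms, 8) - sigm(t, rt_ms - t_off, t_tau))
    }
    sig <- r_wave + qrs + t_wave
    if (quality == "INJURY") {
      # TQ baseline sits at delta, dips to 0 between QRS end and T end:
      # a DC ST-TQ shift of injury_fraction x T amplitude
      delta <- injury_fraction * t_amplitude_mv
      sig <- sig + delta * (1 - (sigm(t, at_ms + 25, 5) -
                                   sigm(t, rt_ms + 1.35 * t_off, 0.09 * t_off)))
    }
  }
  if (quality == "NOISY") sig <- sig + stats::rnorm(n, 0, noisy_sd_mv)
  if (noise_sd_mv > 0) sig <- sig + stats::rnorm(n, 0, noise_sd_mv)

  list(signal = sig, t_ms = t, fs_hz = fs_hz,
       truth = list(at_ms = at_ms, rt_ms = rt_ms, quality = quality,
                    injury_fraction = injury_fraction,
                    t_polarity = t_polarity,
                    qrs_amplitude_mv = qrs_amplitude_mv,
                    t_amplitude_mv = t_amplitude_mv))
}
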