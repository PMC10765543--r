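# Synthetic rhythm streams: paced beats, ectopic beats and Torsade de
# Pointes episodes under the RVA50 -> RVA100 -> RVA80 -> RVA60 protocol,
# plus a surface-lead renderer with measurable QT.

#' Rhythm-stream parameters
#'
#' @param blocks data.frame with columns \code{label}, \code{rate_bpm}
#'   and \code{duration_s}, in protocol order. Defaults to the study
#'   protocol: RVA50 during dofetilide challenge (5 min), then RVA100,
#'   RVA80 and RVA60 for 2 min each.
#' @param ectopy_hazard named numeric: per-beat-slot probability of an
#'   isolated ectopic beat, one entry per block label.
#' @param tdp_episodes data.frame (or NULL) with columns \code{block}
#'   (label), \code{onset_s} (within block), \code{n_beats},
#'   \code{duration_s}, \code{n_defibs}, \code{polymorphic} (logical,
#'   default TRUE). Episodes lasting more than 10 s must be cardioverted
#'   (\code{n_defibs >= 1}).
#' @return list of class \code{rhythm_params}.
#' @export
rhythm_params <- function(blocks = data.frame(
                            label = c("RVA50", "RVA100", "RVA80", "RVA60"),
                            rate_bpm = c(50, 100, 80, 60),
                            duration_s = c(300, 120, 120, 120),
                            stringsAsFactors = FALSE),
                          ectopy_hazard = c(RVA50 = 0.25, RVA100 = 0.02,
                                            RVA80 = 0.05, RVA60 = 0.15),
                          tdp_episodes = NULL) {
  stopifnot(nrow(blocks) >= 1, all(blocks$rate_bpm > 0),
            all(blocks$duration_s > 0))
  if (!is.null(tdp_episodes) && nrow(tdp_episodes)) {
    if (is.null(tdp_episodes$polymorphic)) tdp_episodes$polymorphic <- TRUE
    if (!all(tdp_episodes$block %in% blocks$label)) {
      stop("specification error: episode assigned to unknown block")
    }
    bad <- tdp_episodes$duration_s > 10 & tdp_episodes$n_defibs < 1
    if (any(bad)) {
      stop("specification error: TdP lasting >10 s must be terminated by ",
           "cardioversion (n_defibs >= 1)")
    }
    dur <- blocks$duration_s[match(tdp_episodes$block, blocks$label)]
    if (any(tdp_episodes$onset_s + tdp_episodes$duration_s > dur)) {
      stop("specification error: episode extends beyond its pacing block")
    }
  }
  structure(list(blocks = blocks, ectopy_hazard = ectopy_hazard,
                 tdp_episodes = tdp_episodes), class = "rhythm_params")
}

#' Generate an annotated beat stream and event stream
#'
#' Paced beats are laid down at the block rate (inter-beat interval
#' 60000 / rate ms). Isolated ectopic beats are inserted between paced
#' beats as a Bernoulli process per beat slot. Torsade de Pointes episodes
#' replace pacing for their duration with a run of consecutive ectopic
#' beats whose scalar morphology index alternates in sign (every second
#' beat) as a surrogate for the twisting QRS axis; monomorphic runs keep a
#' constant sign. Defibrillation events are placed at the episode end, one
#' per second, per the episode's \code{n_defibs}.
#'
#' @param params an [rhythm_params()] object.
#' @param seed optional integer seed for a local RNG stream.
#' @return list with \code{beats} (time_ms, beat_class, morphology_index,
#'   block_id), \code{events} (time_ms, event_type, block_id) and
#'   \code{blocks} (block_id, label, rate_bpm, start_ms, end_ms).
#' @export
generate_beat_series <- function(params = rhythm_params(), seed = NULL) {
  stopifnot(inherits(params, "rhythm_params"))
  run <- function() {
    blocks <- params$blocks
    blocks$block_id <- seq_len(nrow(blocks))
    blocks$start_ms <- cumsum(c(0, head(blocks$duration_s, -1))) * 1000
    blocks$end_ms <- blocks$start_ms + blocks$duration_s * 1000
    beats <- list(); events <- list()
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      ibi <- 60000 / b$rate_bpm
      times <- seq(b$start_ms, b$end_ms - 1e-6, by = ibi)
      paced <- data.frame(time_ms = times, beat_class = "PACED",
                          morphology_index = 1, block_id = b$block_id,
                          stringsAsFactors = FALSE)
      haz <- params$ectopy_hazard[[b$label]]
      if (is.null(haz) || is.na(haz)) haz <- 0
      ect_slot <- stats::runif(length(times)) < haz
      n_ect <- sum(ect_slot)
      ect <- data.frame(
        time_ms = times[ect_slot] + ibi * stats::runif(n_ect, 0.35, 0.65),
        beat_class = rep("ECTOPIC", n_ect),
        morphology_index = 0.8 + 0.4 * stats::runif(n_ect),
        block_id = rep(b$block_id, n_ect), stringsAsFactors = FALSE)
      eps <- params$tdp_episodes
      eps <- if (is.null(eps)) NULL else eps[eps$block == b$label, , drop = FALSE]
      if (!is.null(eps) && nrow(eps)) {
        for (k in seq_len(nrow(eps))) {
          e <- eps[k, ]
          on_ms <- b$start_ms + e$onset_s * 1000
          off_ms <- on_ms + e$duration_s * 1000
          # episode replaces pacing (and isolated ectopy) in its window
          paced <- paced[paced$time_ms < on_ms | paced$time_ms > off_ms, ]
          ect <- ect[ect$time_ms < on_ms | ect$time_ms > off_ms, ]
          tt <- seq(on_ms, off_ms, length.out = e$n_beats)
          sign_seq <- if (isTRUE(e$polymorphic)) {
            rep(c(1, 1, -1, -1), length.out = e$n_beats)
          } else rep(1, e$n_beats)
          amp <- 0.8 + 0.4 * stats::runif(e$n_beats)
          beats[[length(beats) + 1L]] <- data.frame(
            time_ms = tt, beat_class = "ECTOPIC",
            morphology_index = sign_seq * amp, block_id = b$block_id,
            stringsAsFactors = FALSE)
          if (e$n_defibs > 0) {
            events[[length(events) + 1L]] <- data.frame(
              time_ms = off_ms + 1000 * seq_len(e$n_defibs),
              event_type = "DEFIB", block_id = b$block_id,
              stringsAsFactors = FALSE)
          }
        }
      }
      beats[[length(beats) + 1L]] <- paced
      if (nrow(ect)) beats[[length(beats) + 1L]] <- ect
    }
    beats <- do.call(rbind, beats)
    beats <- beats[order(beats$time_ms), ]
    rownames(beats) <- NULL
    events <- if (length(events)) {
      ev <- do.call(rbind, events)
      ev[order(ev$time_ms), ]
    } else {
      data.frame(time_ms = numeric(0), event_type = character(0),
                 block_id = integer(0), stringsAsFactors = FALSE)
    }
    rownames(events) <- NULL
    list(beats = beats, events = events,
         blocks = blocks[, c("block_id", "label", "rate_bpm",
                             "start_ms", "end_ms")])
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Render a lead-II-like surface signal from a beat stream
#'
#' Each beat gets a narrow R deflection at its annotated time (the QRS
#' onset) and a triangular T wave whose falling limb reaches the baseline
#' exactly \code{qt_ms} later, so the QT interval is measurable from the
#' known QRS onset to the detected T-wave end (the linear terminal limb
#' makes a threshold-crossing T-end estimate accurate to about 1 ms).
#'
#' @param beats beat stream data.frame (needs \code{time_ms}; a
#'   \code{morphology_index} column modulates ectopic QRS amplitude).
#' @param qt_ms true QT interval (ms); must be shorter than every
#'   inter-beat interval.
#' @param fs_hz sampling frequency of the rendered lead.
#' @param t_width_ms duration of the T wave (its end is the QT landmark).
#' @param noise_sd_mv additive noise SD.
#' @return list with \code{signal}, \code{t_ms}, \code{fs_hz},
#'   \code{truth} (qt_ms, beat times).
#' @export
generate_surface_lead <- function(beats, qt_ms, fs_hz = 1000,
                                  t_width_ms = 160, noise_sd_mv = 0) {
  if (nrow(beats) == 0) {
    return(list(signal = numeric(0), t_ms = numeric(0), fs_hz = fs_hz,
                truth = list(qt_ms = qt_ms, beat_times_ms = numeric(0))))
  }
  stopifnot(qt_ms > t_width_ms)
  tb <- sort(beats$time_ms)
  if (length(tb) > 1 && qt_ms >= min(diff(tb))) {
    stop("parameter error: qt_ms must be shorter than every inter-beat interval")
  }
  total_ms <- max(tb) + qt_ms + 200
  n <- floor(fs_hz * total_ms / 1000)
  t <- (seq_len(n) - 1) / fs_hz * 1000
  sig <- numeric(n)
  morph <- if (is.null(beats$morphology_index)) rep(1, nrow(beats)) else
    beats$morphology_index[order(beats$time_ms)]
  for (i in seq_along(tb)) {
    # R wave: narrow gaussian just after QRS onset
    idx <- which(t >= tb[i] - 40 & t <= tb[i] + qt_ms + 20)
    tt <- t[idx]
    r <- 1.2 * sign(morph[i]) * exp(-((tt - tb[i] - 12) / 6)^2)
    # T wave: triangular lobe peaking at qt - fall_ms, baseline at tb + qt
    fall_ms <- t_width_ms * 0.375
    rise_ms <- t_width_ms - fall_ms
    t_end <- tb[i] + qt_ms
    up <- (tt - (t_end - t_width_ms)) / rise_ms
    dn <- (t_end - tt) / fall_ms
    tw <- 0.35 * pmax(0, pmin(up, dn, 1))
    sig[idx] <- sig[idx] + r + tw
  }
  if (noise_sd_mv > 0) sig <- sig + stats::rnorm(n, 0, noise_sd_mv)
  list(signal = sig, t_ms = t, fs_hz = fs_hz,
       truth = list(qt_ms = qt_ms, beat_times_ms = tb))
}
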