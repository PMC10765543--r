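# Surface-ECG intervals, ectopic-beat and Torsade de Pointes detection,
# severity scoring and per-pacing-block summaries.

#' Van de Water rate-corrected QT
#'
#' \code{QTc = QT - 0.087 x (RR - 1000)}, the rate correction optimized for
#' the anesthetized dog. Reported tables round half-up to 1 ms
#' ([round_ms()]); the value returned here keeps full precision.
#'
#' @param qt_ms QT interval (ms).
#' @param rr_ms cycle length (ms), > 0.
#' @return QTc in ms.
#' @export
#' @examples
#' round_ms(qtc_van_de_water(453, 600))  # 488
#' round_ms(qtc_van_de_water(508, 750))  # 530
qtc_van_de_water <- function(qt_ms, rr_ms) {
  stopifnot(all(rr_ms > 0))
  qt_ms - 0.087 * (rr_ms - 1000)
}

#' Round half-up to whole milliseconds
#'
#' Table values are reported rounded half-up to 1 ms (so 487.5 reports as
#' 488), unlike R's banker's rounding.
#'
#' @param x numeric.
#' @return rounded numeric.
#' @export
round_ms <- function(x) floor(x + 0.5)

#' Measure RR and QT at a timepoint
#'
#' RR and QT are averaged over \code{n_beats} consecutive paced beats
#' ending at (or just before) the requested time. QT per beat is either
#' taken from a \code{qt_ms} annotation column or measured on a surface
#' lead ([generate_surface_lead()]-style) as the interval from the
#' annotated QRS onset to the detected T-wave end (interpolated threshold
#' crossing on the terminal limb).
#'
#' @param beats beat stream data.frame (\code{time_ms}, \code{beat_class};
#'   optionally \code{qt_ms}).
#' @param at_ms timepoint (ms); the measurement uses the last
#'   \code{n_beats} paced beats with \code{time_ms <= at_ms}.
#' @param lead optional surface-lead list with \code{signal}, \code{t_ms}.
#' @param n_beats consecutive beats to average (default 5).
#' @param t_end_threshold fraction of the T-wave peak used for T-end
#'   detection on the lead.
#' @return one-row data.frame of class amendment \code{interval_measurement}:
#'   \code{rr_ms}, \code{qt_ms}, \code{qtc_ms}, \code{n_beats_averaged}.
#' @export
measure_intervals <- function(beats, at_ms = max(beats$time_ms), lead = NULL,
                              n_beats = 5L, t_end_threshold = 0.015) {
  paced <- beats[beats$beat_class == "PACED" & beats$time_ms <= at_ms, ,
                 drop = FALSE]
  paced <- paced[order(paced$time_ms), ]
  if (nrow(paced) < n_beats) {
    stop("measurement error: fewer than ", n_beats,
         " consecutive paced beats available at t = ", at_ms, " ms")
  }
  sel <- paced[(nrow(paced) - n_beats + 1L):nrow(paced), ]
  rr <- mean(diff(sel$time_ms))
  if (is.na(rr)) stop("measurement error: need >= 2 beats for an RR interval")
  qt_per_beat <- if (!is.null(lead)) {
    vapply(sel$time_ms, function(tb) {
      measure_qt_on_lead(lead, tb, rr, threshold = t_end_threshold)
    }, numeric(1))
  } else if (!is.null(sel$qt_ms)) {
    sel$qt_ms
  } else {
    stop("measurement error: no lead signal and no qt_ms annotations")
  }
  qt <- mean(qt_per_beat)
  data.frame(rr_ms = rr, qt_ms = qt, qtc_ms = qtc_van_de_water(qt, rr),
             n_beats_averaged = n_beats)
}

# T-end on a rendered lead: last threshold crossing of the T lobe within
# (beat + 120, beat + 0.95 RR), linearly interpolated.
measure_qt_on_lead <- function(lead, beat_time_ms, rr_ms, threshold = 0.015) {
  t <- lead$t_ms
  idx <- which(t > beat_time_ms + 120 & t < beat_time_ms + 0.95 * rr_ms)
  if (!length(idx)) stop("measurement error: beat window outside lead signal")
  x <- lead$signal[idx]
  thr <- threshold * max(abs(x))
  above <- which(abs(x) > thr)
  if (!length(above)) stop("measurement error: no T wave found on lead")
  i <- above[length(above)]
  t_end <- if (i < length(x)) {
    # interpolate the downward crossing between samples i and i+1
    t[idx[i]] + (abs(x[i]) - thr) / (abs(x[i]) - abs(x[i + 1])) *
      (t[idx[i + 1]] - t[idx[i]])
  } else t[idx[i]]
  t_end - beat_time_ms
}

#' Detect Torsade de Pointes episodes in a beat stream
#'
#' A TdP episode is a maximal run of at least five consecutive ectopic
#' beats whose QRS morphology twists around the isoelectric line,
#' operationalized as at least one sign change of the per-beat morphology
#' index within the run. Shorter runs and monomorphic runs count as
#' ectopy only. Defibrillation events are attributed to the nearest
#' preceding episode whose end lies within \code{defib_window_s} seconds;
#' an episode with no attributed defibrillation is self-terminating.
#'
#' @param beats beat stream (\code{time_ms}, \code{beat_class},
#'   \code{morphology_index}, optionally \code{block_id}).
#' @param events event stream (\code{time_ms}, \code{event_type}); rows
#'   with \code{event_type == "DEFIB"} are attributed.
#' @param min_beats minimum run length for a TdP (default 5).
#' @param defib_window_s attribution window after episode end (default 5).
#' @return data.frame of class \code{tdp_episodes}, one row per episode:
#'   \code{start_ms}, \code{end_ms}, \code{n_beats}, \code{duration_s},
#'   \code{n_defibs}, \code{self_terminating}, \code{polymorphic},
#'   \code{block_id}.
#' @export
detect_tdp_episodes <- function(beats, events = NULL, min_beats = 5L,
                                defib_window_s = 5) {
  beats <- beats[order(beats$time_ms), ]
  r <- rle(beats$beat_class == "ECTOPIC")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_beats)
  rows <- lapply(runs, function(k) {
    i <- starts[k]:ends[k]
    s <- sign(beats$morphology_index[i])
    poly <- any(diff(s[s != 0]) != 0)
    if (!poly) return(NULL)  # monomorphic run: ectopy only, no episode
    data.frame(start_ms = beats$time_ms[i[1]],
               end_ms = beats$time_ms[i[length(i)]],
               n_beats = length(i),
               duration_s = (beats$time_ms[i[length(i)]] -
                               beats$time_ms[i[1]]) / 1000,
               polymorphic = TRUE,
               block_id = if (!is.null(beats$block_id))
                 beats$block_id[i[1]] else NA_integer_,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows)) {
    rows <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                       n_beats = integer(0), duration_s = numeric(0),
                       polymorphic = logical(0), block_id = integer(0),
                       stringsAsFactors = FALSE)
  }
  rows$n_defibs <- integer(nrow(rows))
  if (!is.null(events) && nrow(events)) {
    defibs <- events$time_ms[events$event_type == "DEFIB"]
    for (tm in defibs) {
      cand <- which(rows$end_ms <= tm &
                      tm - rows$end_ms <= defib_window_s * 1000)
      if (!length(cand)) {
        # also accept a defib landing inside the run itself
        cand <- which(rows$start_ms <= tm & tm <= rows$end_ms)
      }
      if (!length(cand)) {
        warning("defibrillation event at ", tm,
                " ms attributable to no episode; left unattributed")
        next
      }
      pick <- cand[which.max(rows$end_ms[cand])]
      rows$n_defibs[pick] <- rows$n_defibs[pick] + 1L
    }
  }
  rows$self_terminating <- rows$n_defibs == 0L
  rows <- rows[, c("start_ms", "end_ms", "n_beats", "duration_s", "n_defibs",
                   "self_terminating", "polymorphic", "block_id")]
  class(rows) <- c("tdp_episodes", "data.frame")
  rows
}

#' Severity score of one TdP episode
#'
#' Self-terminating episodes score their beat count; episodes requiring 1,
#' 2 or >= 3 defibrillations score 50, 75 or 100 points. A self-terminating
#' run of 50 or more beats would collide with the defibrillation codes, so
#' such scores are capped at 49 with a warning.
#'
#' @param episode one row of a [detect_tdp_episodes()] result (or any list
#'   with \code{n_beats}, \code{n_defibs}, \code{self_terminating},
#'   \code{polymorphic}).
#' @return integer score.
#' @export
tdp_score <- function(episode) {
  if (is.data.frame(episode)) {
    stopifnot(nrow(episode) == 1L)
    episode <- as.list(episode)
  }
  if (isFALSE(episode$polymorphic) || episode$n_beats < 5L) {
    stop("contract error: tdp_score() requires a classified TdP episode")
  }
  if (episode$n_defibs >= 3L) return(100L)
  if (episode$n_defibs == 2L) return(75L)
  if (episode$n_defibs == 1L) return(50L)
  n <- as.integer(episode$n_beats)
  if (n > 49L) {
    warning("self-terminating episode of ", n,
            " beats; score capped at 49 to stay below the defibrillation codes")
    n <- 49L
  }
  n
}

# Severity ordering: any defibrillated episode outranks any self-terminating
# one; among defibrillated, more defibrillations; among self-terminating,
# more beats.
episode_severity_key <- function(episodes) {
  order(episodes$n_defibs > 0, episodes$n_defibs, episodes$n_beats,
        decreasing = TRUE)
}

#' Per-pacing-block arrhythmia summary
#'
#' Counts ectopic beats (including those inside TdP runs) and TdP episodes
#' in the block window and scores the most severe episode. For the
#' dofetilide-challenge block (RVA50) the window must be anchored to the
#' first TdP: only the last 2 min before its onset are considered
#' ([rva50_window()]).
#'
#' @param beats beat stream.
#' @param episodes a [detect_tdp_episodes()] result.
#' @param block list or one-row data.frame with \code{block_id},
#'   \code{label}, \code{rate_bpm}, \code{start_ms}, \code{end_ms}.
#' @return one-row data.frame: \code{block_id}, \code{label},
#'   \code{rate_bpm}, \code{window_start_ms}, \code{window_end_ms},
#'   \code{n_ectopic_beats}, \code{n_tdp}, \code{tdp_score}.
#' @export
summarize_block <- function(beats, episodes, block) {
  if (is.data.frame(block)) block <- as.list(block)
  w0 <- block$start_ms; w1 <- block$end_ms
  in_win <- beats$time_ms >= w0 & beats$time_ms < w1
  n_ect <- sum(beats$beat_class[in_win] == "ECTOPIC")
  # beats use a half-open window; episode starts use a closed one so the
  # TdP that anchors a [window_start, TdP onset] challenge window is scored
  ep <- episodes[episodes$start_ms >= w0 & episodes$start_ms <= w1, ,
                 drop = FALSE]
  score <- 0L
  if (nrow(ep)) {
    score <- tdp_score(ep[episode_severity_key(ep)[1L], ])
  }
  data.frame(block_id = block$block_id, label = block$label,
             rate_bpm = block$rate_bpm, window_start_ms = w0,
             window_end_ms = w1, n_ectopic_beats = n_ect,
             n_tdp = nrow(ep), tdp_score = score,
             stringsAsFactors = FALSE)
}

#' Analysis window for the dofetilide-challenge (RVA50) block
#'
#' During dofetilide infusion only the last 2 min before the first TdP are
#' considered, so the block window is \code{[first TdP onset - 120 s,
#' first TdP onset)}.
#'
#' @param episodes a [detect_tdp_episodes()] result.
#' @param block the RVA50 block (list with \code{start_ms}, \code{end_ms},
#'   \code{block_id}, \code{label}, \code{rate_bpm}).
#' @param window_s window length before TdP onset (default 120 s).
#' @return the block with its window re-anchored.
#' @export
rva50_window <- function(episodes, block, window_s = 120) {
  if (is.data.frame(block)) block <- as.list(block)
  ep <- episodes[episodes$start_ms >= block$start_ms &
                   episodes$start_ms < block$end_ms, , drop = FALSE]
  if (!nrow(ep)) {
    stop("window undefined: no TdP episode in the dofetilide-challenge block")
  }
  onset <- min(ep$start_ms)
  block$start_ms <- max(block$start_ms, onset - window_s * 1000)
  block$end_ms <- onset
  block
}

#' Median (IQR width) formatting used in summary tables
#'
#' @param x numeric vector.
#' @return character like \code{"87 (104)"}.
#' @export
median_iqr <- function(x) {
  sprintf("%g (%g)", round_ms(stats::median(x)),
          round_ms(stats::IQR(x, type = 2)))
}
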