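# End-to-end run: simulate -> detect -> disperse -> score -> report.
# Deterministic under a fixed seed; emits a serial-comparison table shaped
# like the study's (rows = parameters, columns = timepoints).

#' Configuration for a pipeline run
#'
#' @param seed integer seed; mandatory (every downstream draw derives from
#'   it).
#' @param arm \code{"HRP"}: RVA50 challenge then RVA100/RVA80/RVA60 blocks;
#'   \code{"RVA60_retro"}: RVA50 challenge then RVA60 directly after
#'   defibrillation (the retrospective-control protocol).
#' @param geometry optional needle layout (data.frame or JSON path) for
#'   [build_mapping_grid()].
#' @param wrap passed to [build_mapping_grid()].
#' @param qc_mode \code{"channel"} or \code{"needle"} rejection
#'   granularity.
#' @param quality_fractions named numeric over [QUALITY_LABELS]: fraction
#'   of channels drawn with each quality (must sum to 1).
#' @param rhythm optional [rhythm_params()]; defaults to the arm's
#'   protocol with one defibrillated TdP during the challenge block.
#' @param timepoint_offset_s analysis time into each fixed-rate block
#'   (default 60 s).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed, arm = c("HRP", "RVA60_retro"), geometry = NULL,
                       wrap = c(RV = TRUE, LV = TRUE, SEPTUM = FALSE),
                       qc_mode = c("channel", "needle"),
                       quality_fractions = c(CLEAN = 0.90, INJURY = 0.03,
                                             FLAT_T = 0.03, NOISY = 0.02,
                                             CAVITY = 0.02),
                       rhythm = NULL, timepoint_offset_s = 60,
                       out_dir = NULL) {
  problems <- character(0)
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    problems <- c(problems, "seed is mandatory in synthesis mode")
  }
  arm <- match.arg(arm)
  qc_mode <- match.arg(qc_mode)
  if (abs(sum(quality_fractions) - 1) > 1e-6 ||
        !all(names(quality_fractions) %in% QUALITY_LABELS)) {
    problems <- c(problems,
                  "quality_fractions must be named over the quality labels and sum to 1")
  }
  if (is.null(rhythm)) {
    rhythm <- if (arm == "HRP") {
      rhythm_params(tdp_episodes = data.frame(
        block = "RVA50", onset_s = 242, n_beats = 30, duration_s = 14,
        n_defibs = 1, polymorphic = TRUE, stringsAsFactors = FALSE))
    } else {
      rhythm_params(
        blocks = data.frame(label = c("RVA50", "RVA60"),
                            rate_bpm = c(50, 60), duration_s = c(300, 120),
                            stringsAsFactors = FALSE),
        ectopy_hazard = c(RVA50 = 0.25, RVA60 = 0.15),
        tdp_episodes = data.frame(
          block = c("RVA50", "RVA60"), onset_s = c(242, 70),
          n_beats = c(30, 6), duration_s = c(14, 3), n_defibs = c(1, 0),
          polymorphic = TRUE, stringsAsFactors = FALSE))
    }
  }
  labels <- rhythm$blocks$label
  expected <- if (arm == "HRP") c("RVA50", "RVA100", "RVA80", "RVA60") else
    c("RVA50", "RVA60")
  if (!identical(labels, expected)) {
    problems <- c(problems, paste0(
      "protocol order must be ", paste(expected, collapse = " -> "),
      " (got ", paste(labels, collapse = " -> "), ")"))
  }
  if (length(problems)) {
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(list(seed = as.integer(seed), arm = arm, geometry = geometry,
                 wrap = wrap, qc_mode = qc_mode,
                 quality_fractions = quality_fractions, rhythm = rhythm,
                 timepoint_offset_s = timepoint_offset_s, out_dir = out_dir),
            class = "run_config")
}

# Simulate one timepoint's electrograms from a truth field and a fixed
# per-channel quality assignment, then detect, QC and rebuild the field
# from the measurements.
analyze_timepoint <- function(grid, truth_field, qualities, injury_fracs,
                              qc_mode = "channel", noise_sd_mv = 0.01) {
  rr <- truth_field$rr_ms
  window_ms <- 0.9 * rr
  win <- beat_windows(rr, window_ms)
  v <- truth_field$values
  n <- nrow(v)
  at_det <- rt_det <- rep(NA_real_, n)
  signals <- vector("list", n)
  for (i in seq_len(n)) {
    rt_i <- min(v$rt_ms[i], window_ms - 60)
    egm <- generate_egm(v$at_ms[i], rt_i, quality = qualities[i],
                        injury_fraction = injury_fracs[i],
                        beat_window_ms = window_ms, noise_sd_mv = noise_sd_mv)
    signals[[i]] <- egm
    fid <- detect_fiducials(egm, windows = win)
    if (fid$ok) {
      at_det[i] <- fid$at_ms
      rt_det[i] <- fid$rt_ms
    }
  }
  names(signals) <- v$channel
  qc <- channel_qc(signals, windows = win, grid = grid, mode = qc_mode)
  measured <- rt_field(grid, at_det, rt_det, qc = qc$qc, rr_ms = rr,
                       timepoint = truth_field$timepoint)
  list(field = measured, qc = qc, truth = truth_field)
}

#' Run the full mapping pipeline on synthetic data
#'
#' Simulates the pacing protocol (beat stream with ectopy and TdP under
#' the configured arm), generates ground-truthed repolarization fields and
#' unipolar electrograms at every analysis timepoint (just before the
#' first EB and TdP, and 60 s into each fixed-rate block), detects
#' fiducials, applies channel rejection, computes the four-orientation
#' dispersion statistics, dRT and wall summaries, measures RR/QT/QTc on a
#' rendered surface lead, scores arrhythmias per block, and fits the
#' restitution curves. When \code{config$out_dir} is set, the summary
#' table, per-unit dispersion values, fiducials, annotations, polar-map
#' layouts and a run manifest (seed + configuration digest) are written
#' there as CSV/JSON.
#'
#' @param config a [run_config()] object.
#' @return object of class \code{sdr_run}: list with \code{config},
#'   \code{grid}, \code{beats}, \code{events}, \code{episodes},
#'   \code{block_summaries}, \code{fields}, \code{qc}, \code{sdr} (per
#'   timepoint [sdr_summary()]), \code{intervals}, \code{restitution},
#'   \code{summary_table}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  grid <- build_mapping_grid(config$geometry, wrap = config$wrap)

  rhy <- generate_beat_series(config$rhythm)
  episodes <- detect_tdp_episodes(rhy$beats, rhy$events)
  blocks <- rhy$blocks
  block_summaries <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    if (b$label == "RVA50") b <- as.data.frame(rva50_window(episodes, b))
    summarize_block(rhy$beats, episodes, b)
  }))

  # persistent per-channel quality assignment for the whole experiment
  n_ch <- nrow(grid$electrodes)
  qualities <- sample(names(config$quality_fractions), n_ch, replace = TRUE,
                      prob = config$quality_fractions)
  injury_fracs <- ifelse(qualities == "INJURY", stats::runif(n_ch, 1.0, 2.0), 0)

  tps <- if (config$arm == "HRP") {
    c("EB", "TdP", "RVA100", "RVA80", "RVA60")
  } else c("EB", "TdP", "RVA60_retro")

  fields <- list(); qc <- list(); sdr <- list(); intervals <- list()
  for (tp in tps) {
    preset <- preset_field_params(tp)
    truth <- generate_rt_field(grid, preset$params, preset$rr_ms,
                               timepoint = tp)
    res <- analyze_timepoint(grid, truth, qualities, injury_fracs,
                             qc_mode = config$qc_mode)
    fields[[tp]] <- res$field
    qc[[tp]] <- res$qc
    sdr[[tp]] <- sdr_summary(res$field)
    lead_beats <- data.frame(
      time_ms = seq(0, by = preset$rr_ms, length.out = 7),
      beat_class = "PACED", morphology_index = 1)
    lead <- generate_surface_lead(lead_beats, qt_ms = preset$qt_ms)
    iv <- measure_intervals(lead_beats, lead = lead)
    iv$timepoint <- tp
    intervals[[tp]] <- iv
  }
  intervals <- do.call(rbind, intervals)
  rownames(intervals) <- NULL

  resti_tps <- setdiff(tps, "EB")
  resti <- if (length(unique(vapply(fields[resti_tps], `[[`, 0, "rr_ms"))) >= 2) {
    restitution(fields[resti_tps])
  } else NULL

  run <- structure(list(config = config, grid = grid, beats = rhy$beats,
                        events = rhy$events, episodes = episodes,
                        blocks = blocks, block_summaries = block_summaries,
                        fields = fields, qc = qc, sdr = sdr,
                        intervals = intervals, restitution = resti),
                   class = "sdr_run")
  run$summary_table <- summary_table(run)
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

# Serial-comparison table: rows = parameters, one column per timepoint.
summary_table <- function(run) {
  tps <- names(run$fields)
  bs <- run$block_summaries
  block_of <- function(tp) {
    lbl <- if (tp %in% c("EB", "TdP")) "RVA50" else tp
    lbl <- sub("_retro$", "", lbl)
    bs[bs$label == lbl, , drop = FALSE]
  }
  col_for <- function(tp) {
    iv <- run$intervals[run$intervals$timepoint == tp, ]
    ws <- wall_summaries(run$fields[[tp]])
    s <- run$sdr[[tp]]
    wsv <- function(w, col) if (w %in% ws$wall) ws[[col]][ws$wall == w] else NA
    arr <- if (tp == "EB") NULL else block_of(tp)
    c(`RR (ms)` = round_ms(iv$rr_ms),
      `QT (ms)` = round_ms(iv$qt_ms),
      `QTc (ms)` = round_ms(iv$qtc_ms),
      `RV-AT (ms)` = round_ms(wsv("RV", "at_mean")),
      `LV-AT (ms)` = round_ms(wsv("LV", "at_mean")),
      `RV-RT (ms)` = round_ms(wsv("RV", "rt_mean")),
      `LV-RT (ms)` = round_ms(wsv("LV", "rt_mean")),
      `dRT (ms)` = round_ms(s$drt_ms),
      `Transmural dispersion (ms)` =
        round_ms(s$sdr$mean_ms[s$sdr$orientation == "TRANSMURAL"]),
      `Vertical dispersion (ms)` =
        round_ms(s$sdr$mean_ms[s$sdr$orientation == "VERTICAL"]),
      `Horizontal dispersion (ms)` =
        round_ms(s$sdr$mean_ms[s$sdr$orientation == "HORIZONTAL"]),
      `Cubic dispersion (ms)` =
        round_ms(s$sdr$mean_ms[s$sdr$orientation == "CUBIC"]),
      `TdP occurrence` = if (is.null(arr)) NA else as.numeric(arr$n_tdp > 0),
      `n TdP` = if (is.null(arr)) NA else arr$n_tdp,
      `TdP score` = if (is.null(arr)) NA else arr$tdp_score,
      `n ectopy` = if (is.null(arr)) NA else arr$n_ectopic_beats)
  }
  cols <- lapply(tps, col_for)
  out <- data.frame(parameter = names(cols[[1]]), stringsAsFactors = FALSE)
  for (i in seq_along(tps)) out[[tps[i]]] <- unname(cols[[i]])
  out
}

#' @export
print.sdr_run <- function(x, ...) {
  cat(sprintf("Mapping pipeline run (arm %s, seed %d)\n",
              x$config$arm, x$config$seed))
  cat(sprintf("  %d beats, %d TdP episode(s)\n", nrow(x$beats),
              nrow(x$episodes)))
  print(x$summary_table, row.names = FALSE)
  invisible(x)
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$summary_table, file.path(out_dir, "summary_table.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(run$block_summaries,
                   file.path(out_dir, "block_summaries.csv"),
                   row.names = FALSE)
  per_unit <- do.call(rbind, lapply(names(run$fields), function(tp) {
    do.call(rbind, lapply(SDR_ORIENTATIONS, function(o) {
      u <- sdr_orientation(run$fields[[tp]], o)$units
      if (nrow(u)) cbind(timepoint = tp, orientation = o, u) else NULL
    }))
  }))
  utils::write.csv(per_unit, file.path(out_dir, "sdr_units.csv"),
                   row.names = FALSE)
  fid <- do.call(rbind, lapply(names(run$fields), function(tp) {
    v <- run$fields[[tp]]$values
    data.frame(timepoint = tp, channel = v$channel, at_ms = v$at_ms,
               rt_ms = v$rt_ms, rtc_ms = v$rtc_ms, qc = v$qc)
  }))
  write_fiducials_csv(fid, file.path(out_dir, "fiducials.csv"))
  write_annotations_csv(run$beats, run$events,
                        file.path(out_dir, "annotations.csv"))
  for (tp in names(run$fields)) {
    pm <- polar_map(run$fields[[tp]])
    jsonlite::write_json(pm$cells,
                         file.path(out_dir, sprintf("polar_map_%s.json", tp)),
                         dataframe = "rows", na = "null")
  }
  cfg <- run$config
  cfg$rhythm <- lapply(cfg$rhythm, function(x)
    if (is.data.frame(x)) as.list(x) else x)
  manifest <- list(seed = run$config$seed, arm = run$config$arm,
                   qc_mode = run$config$qc_mode,
                   n_needles = run$grid$n_needles,
                   config_digest = config_digest(run$config),
                   timepoints = names(run$fields))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

#' Compare two pipeline runs arm against arm
#'
#' Side-by-side descriptive comparison of two runs sharing the same grid
#' geometry; no inferential statistics. Useful for the high-rate-pacing
#' arm against the retrospective RVA60 control arm.
#'
#' @param run_a,run_b [run_pipeline()] results.
#' @param timepoint_a,timepoint_b timepoints to compare (defaults: the
#'   last fixed-rate timepoint of each arm).
#' @return data.frame: \code{parameter}, \code{value_a}, \code{value_b},
#'   \code{difference}.
#' @export
compare_arms <- function(run_a, run_b,
                         timepoint_a = utils::tail(names(run_a$fields), 1),
                         timepoint_b = utils::tail(names(run_b$fields), 1)) {
  stopifnot(inherits(run_a, "sdr_run"), inherits(run_b, "sdr_run"))
  if (!identical(run_a$grid$needles, run_b$grid$needles)) {
    stop("comparison error: runs use different grid geometries")
  }
  ta <- run_a$summary_table; tb <- run_b$summary_table
  if (!identical(ta$parameter, tb$parameter)) {
    stop("comparison error: summary schemas differ")
  }
  va <- ta[[timepoint_a]]; vb <- tb[[timepoint_b]]
  if (is.null(va) || is.null(vb)) stop("comparison error: unknown timepoint")
  data.frame(parameter = ta$parameter,
             value_a = va, value_b = vb, difference = va - vb,
             stringsAsFactors = FALSE)
}
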