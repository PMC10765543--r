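# Spatial dispersion of repolarization: per-unit max-min RT differences in
# transmural, vertical, horizontal and cubic orientation, averaged per
# orientation; interventricular dRT; polar-map layout export.

SDR_ORIENTATIONS <- c("TRANSMURAL", "VERTICAL", "HORIZONTAL", "CUBIC")

#' Repolarization field on a mapping grid
#'
#' Binds per-electrode activation/repolarization times and a QC mask to the
#' lattice for one analysis timepoint. Rate-corrected times
#' (\code{rtc_ms}, Van de Water) are attached automatically.
#'
#' @param grid a [build_mapping_grid()] object.
#' @param at_ms,rt_ms numeric vectors aligned with \code{grid$electrodes}
#'   (length 224 for the default grid).
#' @param qc per-electrode QC labels; only \code{"ACCEPT"} electrodes enter
#'   any statistic. Default: all accepted.
#' @param rr_ms paced cycle length of the measurement (ms).
#' @param timepoint label, e.g. \code{"EB"}, \code{"TdP"}, \code{"RVA100"}.
#' @return object of class \code{rt_field}: list with \code{grid},
#'   \code{values} (electrode table + at/rt/rtc/qc), \code{rr_ms},
#'   \code{timepoint}.
#' @export
rt_field <- function(grid, at_ms, rt_ms, qc = NULL, rr_ms, timepoint = "") {
  stopifnot(inherits(grid, "mapping_grid"), rr_ms > 0)
  n <- nrow(grid$electrodes)
  stopifnot(length(rt_ms) == n, length(at_ms) == n)
  if (is.null(qc)) qc <- rep("ACCEPT", n)
  stopifnot(length(qc) == n)
  v <- grid$electrodes
  v$at_ms <- ifelse(qc == "ACCEPT", at_ms, NA_real_)
  v$rt_ms <- ifelse(qc == "ACCEPT", rt_ms, NA_real_)
  v$rtc_ms <- correct_rt(v$rt_ms, rr_ms)
  v$qc <- qc
  structure(list(grid = grid, values = v, rr_ms = rr_ms,
                 timepoint = timepoint), class = "rt_field")
}

#' @export
print.rt_field <- function(x, ...) {
  acc <- sum(x$values$qc == "ACCEPT" & !is.na(x$values$rt_ms))
  cat(sprintf("Repolarization field '%s' (RR %g ms): %d/%d electrodes accepted\n",
              x$timepoint, x$rr_ms, acc, nrow(x$values)))
  invisible(x)
}

field_units <- function(field, orientation) {
  g <- field$grid
  switch(orientation,
    TRANSMURAL = lapply(g$needles$needle_id, function(i) i),
    VERTICAL = lapply(seq_len(nrow(g$vertical_pairs)),
                      function(i) g$vertical_pairs[i, ]),
    HORIZONTAL = lapply(seq_len(nrow(g$horizontal_pairs)),
                        function(i) g$horizontal_pairs[i, ]),
    CUBIC = lapply(seq_len(nrow(g$squares)), function(i) g$squares[i, ]),
    stop("unknown orientation: ", orientation)
  )
}

#' Spatial dispersion of repolarization in one orientation
#'
#' The spatial unit of each orientation is: TRANSMURAL, the four electrodes
#' of one needle; VERTICAL / HORIZONTAL, the eight electrodes of one
#' vertically / horizontally adjacent needle pair; CUBIC, the sixteen
#' electrodes of one 2 x 2 needle square. The per-unit value is the maximum
#' minus minimum RT over the accepted electrodes of the unit, and the
#' orientation's dispersion is the mean over eligible units. A unit is
#' eligible only if every member needle retains at least
#' \code{min_per_needle} accepted electrodes (default 2); incomplete units
#' are dropped, never imputed.
#'
#' @param field an [rt_field()] object.
#' @param orientation one of \code{"TRANSMURAL"}, \code{"VERTICAL"},
#'   \code{"HORIZONTAL"}, \code{"CUBIC"}.
#' @param min_per_needle minimum accepted electrodes per member needle.
#' @param use_corrected use rate-corrected RT (RTc) instead of RT.
#' @return list with \code{mean_ms} (NA when no eligible unit),
#'   \code{n_units}, and \code{units} (data.frame: unit id, needle ids,
#'   n_electrodes, value_ms).
#' @export
sdr_orientation <- function(field, orientation = SDR_ORIENTATIONS,
                            min_per_needle = 2L, use_corrected = FALSE) {
  stopifnot(inherits(field, "rt_field"))
  orientation <- match.arg(orientation)
  v <- field$values
  rtcol <- if (use_corrected) "rtc_ms" else "rt_ms"
  ok <- v$qc == "ACCEPT" & !is.na(v[[rtcol]])
  per_needle <- split(which(ok), v$needle_id[ok])
  units <- field_units(field, orientation)
  rows <- lapply(seq_along(units), function(i) {
    needles <- as.character(units[[i]])
    idx <- per_needle[needles]
    counts <- vapply(idx, function(x) if (is.null(x)) 0L else length(x), 1L)
    if (any(counts < min_per_needle)) return(NULL)
    vals <- v[[rtcol]][unlist(idx)]
    data.frame(unit = i, needles = paste(needles, collapse = "+"),
               n_electrodes = length(vals),
               value_ms = max(vals) - min(vals), stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows) || nrow(rows) == 0L) {
    return(list(mean_ms = NA_real_, n_units = 0L,
                units = data.frame(unit = integer(0), needles = character(0),
                                   n_electrodes = integer(0),
                                   value_ms = numeric(0))))
  }
  list(mean_ms = mean(rows$value_ms), n_units = nrow(rows), units = rows)
}

#' Interventricular repolarization difference (dRT)
#'
#' Mean LV repolarization time minus mean RV repolarization time over the
#' accepted electrodes; the septum does not contribute.
#'
#' @param field an [rt_field()] object.
#' @return dRT in ms.
#' @export
interventricular_drt <- function(field) {
  stopifnot(inherits(field, "rt_field"))
  v <- field$values
  ok <- v$qc == "ACCEPT" & !is.na(v$rt_ms)
  lv <- v$rt_ms[ok & v$wall == "LV"]
  rv <- v$rt_ms[ok & v$wall == "RV"]
  if (!length(lv) || !length(rv)) {
    side <- c("LV", "RV")[c(!length(lv), !length(rv))]
    stop("no accepted electrodes in ", paste(side, collapse = " and "))
  }
  mean(lv) - mean(rv)
}

#' Per-wall activation/repolarization summaries
#'
#' Simple means and SDs of AT and RT over accepted electrodes, per wall.
#' The septum is reported as its own row and never enters the RV/LV means.
#'
#' @param field an [rt_field()] object.
#' @return data.frame with one row per wall present: \code{wall}, \code{n},
#'   \code{at_mean}, \code{at_sd}, \code{rt_mean}, \code{rt_sd} (SD is 0
#'   with \code{n = 1}).
#' @export
wall_summaries <- function(field) {
  stopifnot(inherits(field, "rt_field"))
  v <- field$values
  ok <- v$qc == "ACCEPT" & !is.na(v$rt_ms)
  out <- lapply(WALLS, function(w) {
    sel <- ok & v$wall == w
    n <- sum(sel)
    if (n == 0L) return(NULL)
    data.frame(wall = w, n = n,
               at_mean = mean(v$at_ms[sel]),
               at_sd = if (n > 1) stats::sd(v$at_ms[sel]) else 0,
               rt_mean = mean(v$rt_ms[sel]),
               rt_sd = if (n > 1) stats::sd(v$rt_ms[sel]) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) stop("no accepted electrodes in any wall")
  rownames(out) <- NULL
  out
}

#' Full dispersion summary for one timepoint
#'
#' @param field an [rt_field()] object.
#' @param min_per_needle see [sdr_orientation()].
#' @return object of class \code{sdr_summary}: list with \code{timepoint},
#'   \code{rr_ms}, \code{sdr} (orientation table), \code{drt_ms},
#'   \code{walls} (wall summary table).
#' @export
sdr_summary <- function(field, min_per_needle = 2L) {
  sdr <- do.call(rbind, lapply(SDR_ORIENTATIONS, function(o) {
    s <- sdr_orientation(field, o, min_per_needle = min_per_needle)
    data.frame(orientation = o, mean_ms = s$mean_ms, n_units = s$n_units,
               stringsAsFactors = FALSE)
  }))
  structure(list(timepoint = field$timepoint, rr_ms = field$rr_ms,
                 sdr = sdr, drt_ms = interventricular_drt(field),
                 walls = wall_summaries(field)), class = "sdr_summary")
}

#' @export
print.sdr_summary <- function(x, ...) {
  cat(sprintf("SDR summary '%s' (RR %g ms)\n", x$timepoint, x$rr_ms))
  for (i in seq_len(nrow(x$sdr))) {
    cat(sprintf("  %-10s %6.1f ms  (%d units)\n", x$sdr$orientation[i],
                x$sdr$mean_ms[i], x$sdr$n_units[i]))
  }
  cat(sprintf("  dRT (LV - RV): %.1f ms\n", x$drt_ms))
  invisible(x)
}

#' Polar (bullseye) map layout of a repolarization field
#'
#' Lays the lattice out as one bullseye panel per wall: concentric rings
#' are base-to-apex levels (base outermost), sectors are circumferential
#' columns, and each cell carries the needle-mean RT (or RTc). Differences
#' between adjacent cells (vertical and horizontal needle pairs) are
#' exported for gradient annotation. The layout is deterministic for a
#' fixed grid.
#'
#' @param field an [rt_field()] object.
#' @param use_corrected plot rate-corrected RT (RTc) instead of RT.
#' @return object of class \code{polar_map}: list with \code{cells}
#'   (wall, level, column, n, value_ms), \code{deltas} (wall, orientation,
#'   needle_a, needle_b, delta_ms), \code{use_corrected},
#'   \code{timepoint}. Has a \code{plot()} method.
#' @export
polar_map <- function(field, use_corrected = FALSE) {
  stopifnot(inherits(field, "rt_field"))
  v <- field$values
  rtcol <- if (use_corrected) "rtc_ms" else "rt_ms"
  ok <- v$qc == "ACCEPT" & !is.na(v[[rtcol]])
  agg <- stats::aggregate(v[[rtcol]][ok],
                          by = list(needle_id = v$needle_id[ok]),
                          FUN = mean)
  names(agg)[2] <- "value_ms"
  nd <- merge(field$grid$needles, agg, by = "needle_id", all.x = TRUE)
  cnt <- stats::aggregate(rep(1L, sum(ok)),
                          by = list(needle_id = v$needle_id[ok]), FUN = sum)
  names(cnt)[2] <- "n"
  nd <- merge(nd, cnt, by = "needle_id", all.x = TRUE)
  nd$n[is.na(nd$n)] <- 0L
  nd <- nd[order(match(nd$wall, WALLS), nd$level, nd$column), ]
  rownames(nd) <- NULL

  val <- stats::setNames(nd$value_ms, nd$needle_id)
  pair_deltas <- function(pairs, orientation) {
    if (!nrow(pairs)) return(NULL)
    data.frame(orientation = orientation,
               needle_a = pairs[, 1L], needle_b = pairs[, 2L],
               delta_ms = val[as.character(pairs[, 2L])] -
                 val[as.character(pairs[, 1L])],
               stringsAsFactors = FALSE)
  }
  deltas <- rbind(pair_deltas(field$grid$vertical_pairs, "VERTICAL"),
                  pair_deltas(field$grid$horizontal_pairs, "HORIZONTAL"))
  if (is.null(deltas)) {
    deltas <- data.frame(orientation = character(0), needle_a = integer(0),
                         needle_b = integer(0), delta_ms = numeric(0),
                         stringsAsFactors = FALSE)
  }
  deltas$wall <- field$grid$needles$wall[match(deltas$needle_a,
                                               field$grid$needles$needle_id)]
  rownames(deltas) <- NULL
  structure(list(cells = nd[, c("needle_id", "wall", "level", "column",
                                "n", "value_ms")],
                 deltas = deltas, use_corrected = use_corrected,
                 timepoint = field$timepoint), class = "polar_map")
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf("Polar map '%s' (%s): %d cells, %d adjacency deltas\n",
              x$timepoint, if (x$use_corrected) "RTc" else "RT",
              nrow(x$cells), nrow(x$deltas)))
  invisible(x)
}

#' @export
plot.polar_map <- function(x, palette = grDevices::hcl.colors, ...) {
  cells <- x$cells
  walls <- intersect(WALLS, unique(cells$wall))
  rng <- range(cells$value_ms, na.rm = TRUE)
  if (diff(rng) < 1e-9) rng <- rng + c(-1, 1)
  ncol_pal <- 64L
  pal <- palette(ncol_pal, palette = "Viridis")
  col_of <- function(v) pal[pmax(1L, pmin(ncol_pal, 1L + floor(
    (v - rng[1]) / diff(rng) * (ncol_pal - 1L))))]
  old <- graphics::par(mfrow = c(1, length(walls)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (w in walls) {
    sub <- cells[cells$wall == w, ]
    levs <- sort(unique(sub$level))
    cols <- sort(unique(sub$column))
    graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("%s (%s)", w,
                                  if (x$use_corrected) "RTc" else "RT"))
    n_ring <- length(levs)
    for (i in seq_len(nrow(sub))) {
      ring <- match(sub$level[i], levs)        # base outermost
      r_out <- 1 - (ring - 1) / n_ring
      r_in <- 1 - ring / n_ring
      th <- 2 * pi * (match(sub$column[i], cols) - 1) / length(cols)
      th2 <- th + 2 * pi / length(cols)
      a <- seq(th, th2, length.out = 20)
      graphics::polygon(c(r_out * cos(a), rev(r_in * cos(a))),
                        c(r_out * sin(a), rev(r_in * sin(a))),
                        col = if (is.na(sub$value_ms[i])) "grey85" else
                          col_of(sub$value_ms[i]),
                        border = "white")
    }
  }
  invisible(x)
}
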