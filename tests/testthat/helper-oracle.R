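# Independent brute-force oracles and toy-lattice fixtures. These re-derive
# adjacency and dispersion directly from needle coordinates with plain
# loops, never touching the package's precomputed adjacency.

toy_layout <- function(walls = "LV", n_levels = 2, n_cols = 2) {
  rows <- list()
  id <- 0L
  for (w in walls) {
    for (lev in seq_len(n_levels)) {
      for (co in seq_len(n_cols)) {
        id <- id + 1L
        rows[[id]] <- data.frame(needle_id = id, wall = w, level = lev,
                                 column = co, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

toy_grid <- function(walls = "LV", n_levels = 2, n_cols = 2, wrap = TRUE) {
  wr <- c(RV = wrap, LV = wrap, SEPTUM = wrap)
  build_mapping_grid(toy_layout(walls, n_levels, n_cols), wrap = wr)
}

# Brute-force mean SDR for one orientation, straight from the definition.
bf_sdr <- function(field, orientation, min_per_needle = 2L) {
  v <- field$values
  v <- v[v$qc == "ACCEPT" & !is.na(v$rt_ms), ]
  wrap <- field$grid$wrap
  needle_sets <- list()
  if (orientation == "TRANSMURAL") {
    for (id in unique(field$grid$needles$needle_id)) {
      needle_sets[[length(needle_sets) + 1L]] <- id
    }
  } else {
    nd <- field$grid$needles
    for (w in unique(nd$wall)) {
      sub <- nd[nd$wall == w, ]
      ncol_w <- max(sub$column)
      for (lev in unique(sub$level)) {
        for (co in unique(sub$column)) {
          here <- sub$needle_id[sub$level == lev & sub$column == co]
          if (!length(here)) next
          if (orientation == "VERTICAL") {
            up <- sub$needle_id[sub$level == lev + 1 & sub$column == co]
            if (length(up)) {
              needle_sets[[length(needle_sets) + 1L]] <- c(here, up)
            }
          } else if (orientation == "HORIZONTAL") {
            nxt_col <- if (co == ncol_w && isTRUE(wrap[[w]])) 1 else co + 1
            nxt <- sub$needle_id[sub$level == lev & sub$column == nxt_col]
            if (length(nxt) && nxt != here) {
              needle_sets[[length(needle_sets) + 1L]] <- c(here, nxt)
            }
          } else if (orientation == "CUBIC") {
            nxt_col <- if (co == ncol_w && isTRUE(wrap[[w]])) 1 else co + 1
            b <- sub$needle_id[sub$level == lev & sub$column == nxt_col]
            c_ <- sub$needle_id[sub$level == lev + 1 & sub$column == co]
            d <- sub$needle_id[sub$level == lev + 1 & sub$column == nxt_col]
            quad <- c(here, b, c_, d)
            if (length(quad) == 4 && length(unique(quad)) == 4) {
              needle_sets[[length(needle_sets) + 1L]] <- quad
            }
          }
        }
      }
    }
    if (orientation == "CUBIC" && length(needle_sets)) {
      keys <- vapply(needle_sets,
                     function(s) paste(sort(s), collapse = "-"), "")
      needle_sets <- needle_sets[!duplicated(keys)]
    }
  }
  vals <- c()
  for (s in needle_sets) {
    counts <- vapply(s, function(id) sum(v$needle_id == id), 1L)
    if (any(counts < min_per_needle)) next
    rt <- v$rt_ms[v$needle_id %in% s]
    vals <- c(vals, max(rt) - min(rt))
  }
  if (!length(vals)) list(mean_ms = NA_real_, n_units = 0L)
  else list(mean_ms = mean(vals), n_units = length(vals))
}

# Field with iid random RT on a grid, optionally with random rejections.
random_field <- function(grid, seed, reject_frac = 0, rr_ms = 1000) {
  set.seed(seed)
  n <- nrow(grid$electrodes)
  qc <- rep("ACCEPT", n)
  if (reject_frac > 0) {
    qc[sample.int(n, round(reject_frac * n))] <- "REJECT_NOISE"
  }
  rt_field(grid, at_ms = runif(n, 20, 60), rt_ms = runif(n, 250, 450),
           qc = qc, rr_ms = rr_ms)
}

# Brute-force episode scan: sequential walk over beats, no rle().
bf_episodes <- function(beats, min_beats = 5L) {
  beats <- beats[order(beats$time_ms), ]
  out <- list()
  i <- 1L
  n <- nrow(beats)
  while (i <= n) {
    if (beats$beat_class[i] == "ECTOPIC") {
      j <- i
      while (j < n && beats$beat_class[j + 1L] == "ECTOPIC") j <- j + 1L
      if (j - i + 1L >= min_beats) {
        s <- sign(beats$morphology_index[i:j])
        s <- s[s != 0]
        if (any(diff(s) != 0)) {
          out[[length(out) + 1L]] <- c(start = beats$time_ms[i],
                                       end = beats$time_ms[j],
                                       n_beats = j - i + 1L)
        }
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}
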