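uniform_field <- function(grid, rt = 350, rr = 1000) {
  n <- nrow(grid$electrodes)
  rt_field(grid, at_ms = rep(40, n), rt_ms = rep(rt, n), rr_ms = rr)
}

test_that("uniform fields have zero dispersion in all four orientations", {
  g <- build_mapping_grid()
  f <- uniform_field(g)
  for (o in c("TRANSMURAL", "VERTICAL", "HORIZONTAL", "CUBIC")) {
    s <- sdr_orientation(f, o)
    expect_equal(s$mean_ms, 0)
    expect_gt(s$n_units, 0)
  }
  expect_equal(interventricular_drt(f), 0)
})

test_that("the transmural unit value is the max-min over one needle", {
  g <- toy_grid("LV", 1, 1)
  f <- rt_field(g, at_ms = rep(40, 4), rt_ms = c(300, 310, 320, 340),
                rr_ms = 1000)
  s <- sdr_orientation(f, "TRANSMURAL")
  expect_equal(s$mean_ms, 40)
  expect_equal(s$n_units, 1)
})

test_that("orientation means equal the brute-force oracle on random lattices", {
  grids <- list(toy_grid(c("LV", "RV"), 3, 3, wrap = TRUE),
                toy_grid("SEPTUM", 3, 4, wrap = FALSE))
  for (g in grids) {
    for (seed in 1:50) {
      f <- random_field(g, seed, reject_frac = if (seed %% 2) 0 else 0.15)
      for (o in c("TRANSMURAL", "VERTICAL", "HORIZONTAL", "CUBIC")) {
        got <- sdr_orientation(f, o)
        want <- bf_sdr(f, o)
        expect_equal(got$mean_ms, want$mean_ms, tolerance = 1e-12)
        expect_equal(got$n_units, want$n_units)
      }
    }
  }
})

test_that("dispersion is invariant under a constant RT shift", {
  g <- build_mapping_grid()
  f1 <- random_field(g, 9)
  f2 <- rt_field(g, at_ms = f1$values$at_ms, rt_ms = f1$values$rt_ms + 77,
                 qc = f1$values$qc, rr_ms = f1$rr_ms)
  for (o in c("TRANSMURAL", "VERTICAL", "HORIZONTAL", "CUBIC")) {
    expect_equal(sdr_orientation(f1, o)$mean_ms,
                 sdr_orientation(f2, o)$mean_ms, tolerance = 1e-12)
  }
  expect_equal(interventricular_drt(f2), interventricular_drt(f1),
               tolerance = 1e-12)
})

test_that("each cubic unit dominates its member needles and pairs", {
  g <- build_mapping_grid()
  f <- random_field(g, 4)
  tr <- sdr_orientation(f, "TRANSMURAL")$units
  vp <- sdr_orientation(f, "VERTICAL")$units
  hp <- sdr_orientation(f, "HORIZONTAL")$units
  cu <- sdr_orientation(f, "CUBIC")$units
  for (i in seq_len(nrow(cu))) {
    members <- as.integer(strsplit(cu$needles[i], "+", fixed = TRUE)[[1]])
    expect_true(all(cu$value_ms[i] >=
                      tr$value_ms[tr$needles %in% as.character(members)]))
    in_square <- function(u) vapply(strsplit(u$needles, "+", fixed = TRUE),
                                    function(p) all(as.integer(p) %in% members),
                                    TRUE)
    expect_true(all(cu$value_ms[i] >= vp$value_ms[in_square(vp)]))
    expect_true(all(cu$value_ms[i] >= hp$value_ms[in_square(hp)]))
  }
})

test_that("rejections never create units and eventually empty the result", {
  g <- toy_grid("LV", 2, 2, wrap = FALSE)
  n <- nrow(g$electrodes)
  set.seed(8)
  rt <- runif(n, 300, 400)
  n_units <- sapply(c(0, 0.2, 0.4, 0.6, 1), function(frac) {
    qc <- rep("ACCEPT", n)
    if (frac > 0) qc[seq_len(round(frac * n))] <- "REJECT_NOISE"
    f <- rt_field(g, at_ms = rep(40, n), rt_ms = rt, qc = qc, rr_ms = 1000)
    sdr_orientation(f, "CUBIC")$n_units
  })
  expect_true(all(diff(n_units) <= 0))
  # fully rejected: explicit empty result, not zero
  qc_all <- rep("REJECT_NOISE", n)
  f0 <- rt_field(g, at_ms = rep(40, n), rt_ms = rt, qc = qc_all, rr_ms = 1000)
  s0 <- sdr_orientation(f0, "CUBIC")
  expect_true(is.na(s0$mean_ms))
  expect_equal(s0$n_units, 0)
})

test_that("interventricular dRT reproduces the wall-mean arithmetic", {
  g <- build_mapping_grid()
  v <- g$electrodes
  mk <- function(lv, rv, sep = 420) {
    rt <- ifelse(v$wall == "LV", lv, ifelse(v$wall == "RV", rv, sep))
    rt_field(g, at_ms = rep(40, nrow(v)), rt_ms = rt, rr_ms = 1200)
  }
  expect_equal(interventricular_drt(mk(453, 363)), 90)
  expect_equal(interventricular_drt(mk(363, 330)), 33)
  # one ventricle fully rejected: error names the empty side
  qc <- ifelse(v$wall == "RV", "REJECT_NOISE", "ACCEPT")
  f <- rt_field(g, at_ms = rep(40, nrow(v)), rt_ms = rep(400, nrow(v)),
                qc = qc, rr_ms = 1000)
  expect_error(interventricular_drt(f), "RV")
})

test_that("wall summaries keep the septum separate and flag degenerate n", {
  g <- build_mapping_grid()
  v <- g$electrodes
  rt <- ifelse(v$wall == "LV", 480, ifelse(v$wall == "RV", 403, 440))
  f <- rt_field(g, at_ms = rep(40, nrow(v)), rt_ms = rt, rr_ms = 1200)
  ws <- wall_summaries(f)
  expect_equal(ws$rt_mean[ws$wall == "LV"], 480)
  expect_equal(ws$rt_mean[ws$wall == "RV"], 403)
  expect_equal(ws$rt_sd[ws$wall == "LV"], 0)
  # single accepted electrode per wall: SD 0 with n = 1
  qc <- rep("REJECT_NOISE", nrow(v))
  qc[match(c("RV", "LV", "SEPTUM"), v$wall)] <- "ACCEPT"
  f1 <- rt_field(g, at_ms = rep(40, nrow(v)), rt_ms = rt, qc = qc,
                 rr_ms = 1200)
  ws1 <- wall_summaries(f1)
  expect_true(all(ws1$n == 1))
  expect_true(all(ws1$rt_sd == 0))
  # septum-only field: RV/LV summaries absent
  gs <- toy_grid("SEPTUM", 2, 2, wrap = FALSE)
  fs <- uniform_field(gs)
  expect_false(any(c("RV", "LV") %in% wall_summaries(fs)$wall))
  expect_error(interventricular_drt(fs), "LV and RV")
})

test_that("polar maps export cell values and adjacency gradients", {
  g <- build_mapping_grid()
  f <- uniform_field(g, rt = 400, rr = 600)
  pm <- polar_map(f)
  expect_equal(nrow(pm$cells), 56)
  expect_true(all(pm$deltas$delta_ms == 0))
  # one hot needle: +100 ms against every neighbour
  rt <- rep(400, nrow(g$electrodes))
  rt[g$electrodes$needle_id == 10] <- 500
  fh <- rt_field(g, at_ms = rep(40, nrow(g$electrodes)), rt_ms = rt,
                 rr_ms = 600)
  ph <- polar_map(fh)
  touching <- ph$deltas$needle_a == 10 | ph$deltas$needle_b == 10
  expect_true(all(abs(ph$deltas$delta_ms[touching]) == 100))
  expect_true(all(ph$deltas$delta_ms[!touching] == 0))
  # Van de Water correction at fixed RR is a global shift: cells move by
  # 0.087 x 400 = 34.8 ms, gradients unchanged
  pc <- polar_map(f, use_corrected = TRUE)
  expect_equal(pc$cells$value_ms - pm$cells$value_ms,
               rep(34.8, 56), tolerance = 1e-9)
  expect_equal(pc$deltas$delta_ms, pm$deltas$delta_ms, tolerance = 1e-9)
})
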