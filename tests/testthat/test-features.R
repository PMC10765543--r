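test_that("fiducial detection recovers generator truth on clean channels", {
  win <- beat_windows(1200, 1000)
  f <- detect_fiducials(generate_egm(40, 403), windows = win)
  expect_lt(abs(f$at_ms - 40), 1)
  expect_lt(abs(f$rt_ms - 403), 1)
  # negative T wave, steepest positive dV/dt still at rt
  f2 <- detect_fiducials(generate_egm(45, 350, t_polarity = -1), windows = win)
  expect_lt(abs(f2$rt_ms - 350), 1)
})

test_that("flat-line input yields a flagged non-result", {
  f <- detect_fiducials(rep(0.2, 2048), fs_hz = 2048,
                        windows = beat_windows(1200, 900))
  expect_false(f$ok)
  expect_true(is.na(f$at_ms) && is.na(f$rt_ms))
})

test_that("windows shorter than the smoothing kernel are a configuration error", {
  expect_error(detect_fiducials(rep(0, 5), fs_hz = 2048), "smoothing kernel")
})

test_that("detection is equivariant under sample shifts and amplitude scaling", {
  e <- generate_egm(60, 380)
  win <- beat_windows(1200, 1000)
  f0 <- detect_fiducials(e$signal, fs_hz = e$fs_hz, windows = win)
  k <- 41L  # shift by 41 samples
  dt <- 1000 / e$fs_hz
  shifted <- c(rep(e$signal[1], k), e$signal[1:(length(e$signal) - k)])
  f1 <- detect_fiducials(shifted, fs_hz = e$fs_hz, windows = win)
  expect_equal(f1$at_ms - f0$at_ms, k * dt, tolerance = 1e-9)
  expect_equal(f1$rt_ms - f0$rt_ms, k * dt, tolerance = 1e-6)
  f2 <- detect_fiducials(3.7 * e$signal, fs_hz = e$fs_hz, windows = win)
  expect_equal(f2$at_ms, f0$at_ms)
  expect_equal(f2$rt_ms, f0$rt_ms)
  # injury metric is a ratio: unchanged under scaling
  ei <- generate_egm(40, 363, quality = "INJURY", injury_fraction = 1.2)
  m1 <- channel_qc_metrics(ei$signal, fs_hz = ei$fs_hz, windows = win)
  m2 <- channel_qc_metrics(5 * ei$signal, fs_hz = ei$fs_hz, windows = win)
  expect_equal(m1$injury_metric, m2$injury_metric, tolerance = 1e-9)
})

test_that("injury rejection follows the 80% of T amplitude rule", {
  win <- beat_windows(1200, 1000)
  hot <- channel_qc_metrics(generate_egm(40, 363, quality = "INJURY",
                                         injury_fraction = 0.9),
                            windows = win)
  expect_equal(hot$qc, "REJECT_INJURY")
  cool <- channel_qc_metrics(generate_egm(40, 363, quality = "INJURY",
                                          injury_fraction = 0.5),
                             windows = win)
  expect_equal(cool$qc, "ACCEPT")
})

test_that("channel QC separates the corruption classes", {
  win <- beat_windows(1200, 1000)
  set.seed(21)
  truth <- c(rep("CLEAN", 20), rep(c("INJURY", "FLAT_T", "NOISY", "CAVITY"),
                                   each = 5))
  labels <- vapply(truth, function(q) {
    e <- generate_egm(runif(1, 30, 60), runif(1, 320, 430), quality = q,
                      injury_fraction = if (q == "INJURY")
                        runif(1, 1.0, 2.0) else 0,
                      noise_sd_mv = 0.01)
    channel_qc_metrics(e, windows = win)$qc
  }, "")
  map <- c(CLEAN = "ACCEPT", INJURY = "REJECT_INJURY",
           FLAT_T = "REJECT_FLAT_T", NOISY = "REJECT_NOISE",
           CAVITY = "REJECT_CAVITY")
  for (cls in names(map)) {
    sens <- mean(labels[truth == cls] == map[[cls]])
    spec <- mean(labels[truth != cls] != map[[cls]])
    expect_gte(sens, 0.95)
    expect_gte(spec, 0.95)
  }
})

test_that("needle-mode QC disregards a needle when half its channels fail", {
  g <- toy_grid("LV", 2, 2, wrap = FALSE)
  win <- beat_windows(1200, 1000)
  sigs <- list()
  set.seed(3)
  for (i in seq_len(nrow(g$electrodes))) {
    q <- if (g$electrodes$needle_id[i] == 1 && g$electrodes$depth[i] < 2) {
      "CAVITY"
    } else "CLEAN"
    sigs[[g$electrodes$channel[i]]] <- generate_egm(40, 380, quality = q)
  }
  qc <- channel_qc(sigs, windows = win, grid = g, mode = "needle")
  n1 <- qc[grepl("^WLVL1C1", qc$channel), ]
  expect_true(all(n1$qc != "ACCEPT"))  # whole needle disregarded
  expect_true(all(qc$qc[!grepl("^WLVL1C1", qc$channel)] == "ACCEPT"))
})

test_that("Van de Water correction of RT matches the published arithmetic", {
  expect_equal(correct_rt(453, 600), 487.8)
  expect_equal(correct_rt(573, 1200), 555.6)
  rts <- c(300, 363, 453, 573)
  expect_equal(correct_rt(rts, 1000), rts)  # zero correction at RR 1000
})
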