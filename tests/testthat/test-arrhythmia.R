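mk_beats <- function(classes, morph = NULL, t0 = 0, ibi = 600) {
  n <- length(classes)
  if (is.null(morph)) morph <- rep(1, n)
  data.frame(time_ms = t0 + ibi * (seq_len(n) - 1), beat_class = classes,
             morphology_index = morph, block_id = 1L,
             stringsAsFactors = FALSE)
}

test_that("Van de Water QTc reproduces the published table arithmetic", {
  expect_equal(round_ms(qtc_van_de_water(453, 600)), 488)
  expect_equal(round_ms(qtc_van_de_water(508, 750)), 530)
  expect_equal(round_ms(qtc_van_de_water(626, 1200)), 609)
  expect_equal(round_ms(qtc_van_de_water(598, 1000)), 598)
  qt <- seq(200, 700, by = 13)
  expect_equal(qtc_van_de_water(qt, 1000), qt)  # identity at RR 1000
})

test_that("intervals average over five consecutive beats", {
  beats <- mk_beats(rep("PACED", 5))
  beats$qt_ms <- c(451, 452, 453, 454, 455)
  iv <- measure_intervals(beats)
  expect_equal(iv$qt_ms, 453)
  expect_equal(iv$rr_ms, 600)
  expect_equal(iv$n_beats_averaged, 5)
  expect_error(measure_intervals(mk_beats(rep("PACED", 4))),
               "measurement error")
})

test_that("QT is measurable from the rendered surface lead", {
  for (case in list(c(rr = 600, qt = 453), c(rr = 750, qt = 508))) {
    beats <- mk_beats(rep("PACED", 7), ibi = case[["rr"]])
    lead <- generate_surface_lead(beats, qt_ms = case[["qt"]])
    iv <- measure_intervals(beats, lead = lead)
    expect_lt(abs(iv$qt_ms - case[["qt"]]), 2)
    expect_equal(iv$rr_ms, case[["rr"]])
  }
})

test_that("TdP requires at least five consecutive polymorphic ectopic beats", {
  # 4 consecutive ectopics: never an episode
  b4 <- mk_beats(c("PACED", rep("ECTOPIC", 4), "PACED"),
                 morph = c(1, 1, -1, 1, -1, 1))
  expect_equal(nrow(detect_tdp_episodes(b4)), 0)
  # 5 alternating ectopics, no defib: threshold case, self-terminating
  b5 <- mk_beats(c("PACED", rep("ECTOPIC", 5), "PACED"),
                 morph = c(1, 1, -1, 1, -1, 1, 1))
  ep <- detect_tdp_episodes(b5)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$n_beats, 5)
  expect_true(ep$self_terminating)
  # monomorphic run of 6: ectopy only
  b6 <- mk_beats(c("PACED", rep("ECTOPIC", 6)), morph = rep(1, 7))
  expect_equal(nrow(detect_tdp_episodes(b6)), 0)
})

test_that("defibrillation attribution marks non-self-terminating episodes", {
  b <- mk_beats(c("PACED", rep("ECTOPIC", 30), "PACED"), ibi = 400,
                morph = c(1, rep(c(1, -1), 15), 1))
  ev <- data.frame(time_ms = max(b$time_ms[b$beat_class == "ECTOPIC"]) + 2000,
                   event_type = "DEFIB", block_id = 1L)
  ep <- detect_tdp_episodes(b, ev)
  expect_equal(ep$n_defibs, 1)
  expect_false(ep$self_terminating)
  expect_gt(ep$duration_s, 10)
  # unattributable event warns and is dropped
  ev2 <- data.frame(time_ms = 1e6, event_type = "DEFIB", block_id = 1L)
  expect_warning(detect_tdp_episodes(b, ev2), "unattributed")
})

test_that("episode detection matches a brute-force run scan on random streams", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- 60
    classes <- sample(c("PACED", "ECTOPIC"), n, replace = TRUE,
                      prob = c(0.6, 0.4))
    morph <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.5, 1.5)
    b <- mk_beats(classes, morph = morph)
    got <- detect_tdp_episodes(b)
    want <- bf_episodes(b)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start_ms, vapply(want, `[[`, 0, "start"))
      expect_equal(got$n_beats, vapply(want, function(x)
        as.integer(x[["n_beats"]]), 1L))
    }
  }
})

test_that("the TdP score follows the beats / 50-75-100 rule", {
  ep <- function(n_beats, n_defibs) {
    list(n_beats = n_beats, n_defibs = n_defibs,
         self_terminating = n_defibs == 0, polymorphic = TRUE)
  }
  expect_equal(tdp_score(ep(12, 0)), 12)
  expect_equal(tdp_score(ep(5, 0)), 5)
  expect_equal(tdp_score(ep(30, 1)), 50)
  expect_equal(tdp_score(ep(30, 2)), 75)
  expect_equal(tdp_score(ep(30, 3)), 100)
  expect_equal(tdp_score(ep(30, 5)), 100)
  expect_error(tdp_score(ep(4, 0)), "contract error")
  expect_error(tdp_score(list(n_beats = 8, n_defibs = 0,
                              self_terminating = TRUE, polymorphic = FALSE)),
               "contract error")
  expect_warning(s <- tdp_score(ep(60, 0)), "capped")
  expect_equal(s, 49)
})

test_that("block summaries score the most severe episode", {
  # self-terminating 8-beat run, then a defibrillated episode
  classes <- c("PACED", rep("ECTOPIC", 8), rep("PACED", 3),
               rep("ECTOPIC", 20), "PACED")
  morph <- c(1, rep(c(1, -1), 4), rep(1, 3), rep(c(1, -1), 10), 1)
  b <- mk_beats(classes, morph = morph, ibi = 500)
  last_ect <- max(b$time_ms[b$beat_class == "ECTOPIC"])
  ev <- data.frame(time_ms = last_ect + 1500, event_type = "DEFIB",
                   block_id = 1L)
  ep <- detect_tdp_episodes(b, ev)
  expect_equal(nrow(ep), 2)
  block <- list(block_id = 1L, label = "RVA60", rate_bpm = 60,
                start_ms = 0, end_ms = max(b$time_ms) + 1000)
  bs <- summarize_block(b, ep, block)
  expect_equal(bs$tdp_score, 50)
  expect_equal(bs$n_tdp, 2)
  expect_equal(bs$n_ectopic_beats, 28)  # beats inside episodes count
  # no episodes, scattered ectopy
  b2 <- mk_beats(c("PACED", "ECTOPIC", "PACED", "ECTOPIC", "PACED",
                   "ECTOPIC", "PACED", "ECTOPIC"))
  bs2 <- summarize_block(b2, detect_tdp_episodes(b2),
                         list(block_id = 1L, label = "RVA60", rate_bpm = 60,
                              start_ms = 0, end_ms = 1e5))
  expect_equal(bs2$n_ectopic_beats, 4)
  expect_equal(bs2$n_tdp, 0)
  expect_equal(bs2$tdp_score, 0)
})

test_that("the challenge block window is anchored to the first TdP", {
  # 87 isolated ectopics in the final 2 min before TdP onset
  set.seed(12)
  paced <- data.frame(time_ms = seq(0, 300000, by = 1200),
                      beat_class = "PACED", morphology_index = 1,
                      block_id = 1L)
  onset <- 242000
  ect <- data.frame(time_ms = sort(runif(87, onset - 119000, onset - 2000)),
                    beat_class = "ECTOPIC",
                    morphology_index = 1, block_id = 1L)
  run <- data.frame(time_ms = seq(onset, onset + 8000, length.out = 12),
                    beat_class = "ECTOPIC",
                    morphology_index = rep(c(1, -1), 6), block_id = 1L)
  b <- rbind(paced[paced$time_ms < onset - 1 | paced$time_ms > onset + 8000, ],
             ect, run)
  b <- b[order(b$time_ms), ]
  ep <- detect_tdp_episodes(b)
  block <- list(block_id = 1L, label = "RVA50", rate_bpm = 50,
                start_ms = 0, end_ms = 300000)
  anchored <- rva50_window(ep, block)
  expect_equal(anchored$end_ms, onset)
  expect_equal(anchored$start_ms, onset - 120000)
  bs <- summarize_block(b, ep, anchored)
  expect_equal(bs$n_ectopic_beats, 87)
  expect_equal(bs$tdp_score, 12)  # the anchoring TdP itself is scored
  # no TdP in the challenge block: window undefined
  expect_error(rva50_window(ep[0, ], block), "window undefined")
})

test_that("ectopic counts are conserved over disjoint block windows", {
  set.seed(30)
  classes <- sample(c("PACED", "ECTOPIC"), 300, replace = TRUE)
  b <- mk_beats(classes, morph = runif(300, -1, 1), ibi = 500)
  ep <- detect_tdp_episodes(b)
  cuts <- c(0, 40000, 90000, max(b$time_ms) + 1)
  total <- 0
  for (i in 1:3) {
    bs <- summarize_block(b, ep, list(block_id = i, label = "X",
                                      rate_bpm = 60, start_ms = cuts[i],
                                      end_ms = cuts[i + 1]))
    total <- total + bs$n_ectopic_beats
  }
  expect_equal(total, sum(b$beat_class == "ECTOPIC"))
})
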