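test_that("channel label codec round-trips", {
  set.seed(11)
  for (i in 1:100) {
    wall <- sample(c("RV", "LV", "SEPTUM"), 1)
    lab <- format_channel_label(wall, sample(1:6, 1), sample(1:9, 1),
                                sample(0:3, 1))
    p <- parse_channel_label(lab)
    expect_identical(
      format_channel_label(p$wall, p$level, p$column, p$depth), lab)
  }
  expect_error(parse_channel_label("WLVL1C1D4"), "invalid")
  expect_error(parse_channel_label("XLVL1C1D0"), "invalid")
})

test_that("default grid satisfies the lattice invariants", {
  g <- build_mapping_grid()
  expect_equal(g$n_needles, 56)
  expect_equal(nrow(g$electrodes), 224)
  nd <- g$needles
  at <- function(id, col) nd[[col]][match(id, nd$needle_id)]
  # vertical pairs: same wall and column, levels differ by exactly 1
  vp <- g$vertical_pairs
  expect_true(all(at(vp[, 1], "wall") == at(vp[, 2], "wall")))
  expect_true(all(at(vp[, 1], "column") == at(vp[, 2], "column")))
  expect_true(all(abs(at(vp[, 1], "level") - at(vp[, 2], "level")) == 1))
  # horizontal pairs: same wall and level, columns adjacent (with wrap)
  hp <- g$horizontal_pairs
  expect_true(all(at(hp[, 1], "wall") == at(hp[, 2], "wall")))
  expect_true(all(at(hp[, 1], "level") == at(hp[, 2], "level")))
  dcol <- abs(at(hp[, 1], "column") - at(hp[, 2], "column"))
  ncol_w <- tapply(nd$column, nd$wall, max)[at(hp[, 1], "wall")]
  expect_true(all(dcol == 1 | dcol == ncol_w - 1))
  # every square contains exactly 2 vertical and 2 horizontal grid pairs
  pair_key <- function(m) apply(m, 1, function(r) paste(sort(r), collapse = "-"))
  vk <- pair_key(vp); hk <- pair_key(hp)
  for (i in seq_len(nrow(g$squares))) {
    q <- g$squares[i, ]
    combs <- t(utils::combn(q, 2))
    keys <- pair_key(combs)
    expect_equal(sum(keys %in% vk), 2)
    expect_equal(sum(keys %in% hk), 2)
  }
  # no pairs across walls (checked above via wall equality); septum no wrap
  sep <- nd$needle_id[nd$wall == "SEPTUM"]
  sep_hp <- hp[hp[, 1] %in% sep, , drop = FALSE]
  expect_true(all(abs(at(sep_hp[, 1], "column") -
                        at(sep_hp[, 2], "column")) == 1))
})

test_that("toy 2x2 wall enumerates pairs and squares as expected", {
  g_wrap <- toy_grid("LV", 2, 2, wrap = TRUE)
  expect_equal(g_wrap$n_needles, 4)
  expect_equal(nrow(g_wrap$horizontal_pairs), 4)  # 2 ring edges per level
  expect_equal(nrow(g_wrap$vertical_pairs), 2)
  expect_equal(nrow(enumerate_squares(g_wrap)), 1)
  g_flat <- toy_grid("LV", 2, 2, wrap = FALSE)
  expect_equal(nrow(g_flat$horizontal_pairs), 2)
  expect_equal(nrow(enumerate_squares(g_flat)), 1)
})

test_that("square enumeration handles wrap and degenerate walls", {
  expect_equal(nrow(enumerate_squares(toy_grid("LV", 2, 3, wrap = TRUE))), 3)
  expect_equal(nrow(enumerate_squares(toy_grid("LV", 2, 3, wrap = FALSE))), 2)
  expect_equal(nrow(enumerate_squares(toy_grid("LV", 1, 4))), 0)
})

test_that("geometry validation rejects bad layouts", {
  lay <- toy_layout("LV", 2, 2)
  lay$column[2] <- 1  # duplicate (wall, level, column)
  expect_error(build_mapping_grid(lay), "duplicate needle coordinates")
  lay2 <- toy_layout("LV", 2, 2)
  lay2$level[1] <- 7
  expect_error(build_mapping_grid(lay2), "level outside 1-6")
  lay3 <- toy_layout("LV", 2, 2)
  lay3$needle_id[2] <- 1L
  expect_error(build_mapping_grid(lay3), "duplicate needle_id")
})

test_that("neighbors respects orientation and boundaries", {
  g <- toy_grid("LV", 2, 3, wrap = TRUE)
  corner <- g$needles$needle_id[g$needles$level == 1 & g$needles$column == 1]
  expect_length(neighbors(g, corner, "VERTICAL"), 1)
  expect_equal(g$needles$level[match(neighbors(g, corner, "VERTICAL"),
                                     g$needles$needle_id)], 2)
  expect_length(neighbors(g, corner, "HORIZONTAL"), 2)  # ring of 3
  expect_error(neighbors(g, 999L, "VERTICAL"), "unknown needle_id")
})

test_that("geometry JSON round-trips through file", {
  lay <- default_needle_layout()
  f <- tempfile(fileext = ".json")
  write_geometry_json(lay, f)
  back <- read_geometry_json(f)
  g <- build_mapping_grid(f)
  expect_equal(g$n_needles, 56)
  expect_equal(back$needle_id, lay$needle_id)
  expect_equal(back$wall, lay$wall)
  unlink(f)
})
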