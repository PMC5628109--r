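test_that("Agatston score reproduces hand-computed worked examples", {
  # one lesion, one slice, 4 voxels at 1.35 mm pixels, slice max 250 -> w = 2
  v <- make_volume(c(2, 5, 5), spacing = c(3, 1.35, 1.35))
  v$data[1, 2:3, 2:3] <- c(250, 180, 140, 150)
  cand <- extract_candidates(v)
  expect_equal(agatston_score(cand, v), 4 * 1.8225 * 2)

  # two slices at 0.35 mm pixels: (2 vox, max 135 -> w1), (3 vox, max 450 -> w4)
  v2 <- make_volume(c(2, 5, 5), spacing = c(3, 0.35, 0.35))
  v2$data[1, 2, 2:3] <- c(135, 131)
  v2$data[2, 2, 2:3] <- c(450, 200)
  v2$data[2, 3, 2] <- 180
  cand2 <- extract_candidates(v2)
  expect_length(cand2, 1)
  expect_equal(agatston_score(cand2, v2),
               2 * 0.35^2 * 1 + 3 * 0.35^2 * 4)
  expect_equal(agatston_score(list(), v2), 0)
})

test_that("weight bands switch at 200, 300 and 400 HU", {
  for (case in list(c(199, 1), c(200, 2), c(299, 2), c(300, 3),
                    c(399, 3), c(400, 4), c(1000, 4))) {
    v <- make_volume(c(1, 4, 4), spacing = c(3, 1, 1))
    v$data[1, 1, 1:2] <- c(case[1], 130)
    expect_equal(agatston_score(extract_candidates(v), v), 2 * case[2],
                 info = paste("max HU", case[1]))
  }
})

test_that("scores are additive over disjoint lesions and order-invariant", {
  v <- make_volume(c(4, 8, 8), spacing = c(3, 1.35, 1.35))
  v$data[1, 2, 2:3] <- 250
  v$data[3, 6, 5:6] <- 450
  cand <- extract_candidates(v)
  expect_length(cand, 2)
  expect_equal(agatston_score(cand, v),
               agatston_score(cand[1], v) + agatston_score(cand[2], v))
  expect_equal(agatston_score(rev(cand), v), agatston_score(cand, v))
  expect_equal(volume_score(cand, v), 4 * prod(v$spacing))
  expect_equal(volume_score(list(), v), 0)
})

test_that("volume score is voxel count times voxel volume", {
  v <- make_volume(c(4, 6, 6), spacing = c(3, 1.35, 1.35))
  v$data[2, 2:3, 2:4] <- 200   # 6 voxels
  v$data[3, 2, 2:3] <- 200     # grows the same component by 4 more
  v$data[3, 3, 3:4] <- 200
  cand <- extract_candidates(v)
  expect_equal(volume_score(cand, v), 10 * 5.4675)
})

test_that("lesions outside the volume raise an error", {
  v <- make_volume(c(3, 4, 4))
  v$data[1, 1, 1:2] <- 200
  cand <- extract_candidates(v)
  small <- make_volume(c(1, 1, 1))
  expect_error(agatston_score(cand, small), "outside")
})

test_that("risk categories follow the five half-open Agatston intervals", {
  expect_identical(risk_category(0), 1L)
  expect_identical(risk_category(5), 2L)
  expect_identical(risk_category(10), 2L)
  expect_identical(risk_category(10.5), 3L)
  expect_identical(risk_category(100), 3L)
  expect_identical(risk_category(400), 4L)
  expect_identical(risk_category(400.01), 5L)
  expect_error(risk_category(-1), ">= 0")
  # monotone in the score
  s <- sort(runif(100, 0, 1000))
  expect_true(all(diff(risk_category(s)) >= 0))
  # the five intervals partition [0, Inf)
  tb <- risk_category_table()
  expect_equal(tb$lower[-1], tb$upper[-5])
})

test_that("rank assignment fills reference quotas from the bottom", {
  expect_identical(rank_assign(c(1, 1, 2, 3), c(0, 0, 7, 320)),
                   c(1L, 1L, 2L, 3L))
  # zeros collapse to level 1 even when they overflow the quota
  expect_identical(rank_assign(c(1, 2, 2, 3), c(0, 0, 0, 50)),
                   c(1L, 1L, 1L, 3L))
})

test_that("rank assignment is monotone and quota-exact without ties", {
  set.seed(31)
  for (rep in 1:5) {
    ref <- sample(1:5, 40, replace = TRUE)
    sc <- sample(seq(0.5, 2000, by = 0.5), 40)   # nonzero, distinct
    got <- rank_assign(ref, sc)
    expect_identical(tabulate(got, 5), tabulate(ref, 5))
    ord <- order(sc)
    expect_true(all(diff(got[ord]) >= 0))
  }
})

test_that("zero-score overflow reproduces the observed column pattern", {
  # reference quotas 13/6/12/35/62 with 24 zero scores in the test cohort:
  # all 24 land in level 1, level 2 empties, level 3 keeps its tail quota
  ref <- rep(1:5, c(13, 6, 12, 35, 62))
  set.seed(8)
  scores <- c(rep(0, 24), sort(runif(104, 1, 3000)))[sample(128)]
  got <- rank_assign(ref, scores)
  expect_identical(tabulate(got, 5), c(24L, 0L, 7L, 35L, 62L))
})

test_that("tied scores all receive the majority category of their slots", {
  # two tied scores straddling the level-1/level-2 boundary: slots are
  # {1, 2, 2} for positions 2-4 -> majority level 2
  got <- rank_assign(c(1, 1, 2, 2), c(0, 5, 5, 5))
  expect_identical(got, c(1L, 2L, 2L, 2L))
  # split 1-1 majority -> lower category wins
  got2 <- rank_assign(c(1, 2), c(3, 3))
  expect_identical(got2, c(1L, 1L))
  expect_error(rank_assign(c(1, 2), c(1, 2, 3)), "length")
})
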