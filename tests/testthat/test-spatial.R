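test_that("K estimates match hand-evaluated two-point configurations", {
  w <- rect_window(c(0, 100), c(0, 100))
  # two points 5 m apart: K jumps to |W| * 2/(n(n-1)) = 10000 at r >= 5
  k <- k_estimate(c(10, 13), c(10, 14), w, r = c(0, 4.9, 10),
                  correction = "none")
  expect_equal(k$k, c(0, 0, 10000))
  # translation weight |W|/((100-3)(100-4)) applied to both ordered pairs
  kt <- k_estimate(c(10, 13), c(10, 14), w, r = 10,
                   correction = "translation")
  expect_equal(kt$k, 10000 * 10000 / (97 * 96))
  # K(0) = 0 always
  expect_equal(k_estimate(runif(10), runif(10),
                          rect_window(c(0, 1), c(0, 1)), r = 0)$k, 0)
})

test_that("uncorrected K equals the brute-force double loop", {
  w <- rect_window(c(0, 60), c(0, 40))
  r <- seq(0, 10, length.out = 8)
  set.seed(101)
  for (case in 1:20) {
    n <- sample(3:50, 1)
    x <- runif(n, 0, 60); y <- runif(n, 0, 40)
    expect_equal(k_estimate(x, y, w, r, correction = "none")$k,
                 brute_force_k(x, y, w$area, r))
  }
})

test_that("isotropic circle fractions match geometry at canonical points", {
  w <- rect_window(c(0, 100), c(0, 100))
  frac <- cachescape:::circle_inside_fraction
  expect_equal(frac(50, 50, 10, w), 1)          # interior
  expect_equal(frac(0, 50, 10, w), 0.5)         # on an edge
  expect_equal(frac(0, 0, 10, w), 0.25)         # on a corner
  expect_equal(frac(5, 50, 10, w),
               1 - 2 * acos(5 / 10) / (2 * pi))  # one edge cut
})

test_that("translation K is invariant under translation and axis swap", {
  set.seed(5)
  x <- runif(40, 0, 80); y <- runif(40, 0, 50)
  w <- rect_window(c(0, 80), c(0, 50))
  r <- seq(0, 12, length.out = 10)
  k0 <- k_estimate(x, y, w, r)$k
  ws <- rect_window(c(200, 280), c(-30, 20))
  expect_equal(k_estimate(x + 200, y - 30, ws, r)$k, k0)
  wt <- rect_window(c(0, 50), c(0, 80))
  expect_equal(k_estimate(y, x, wt, r)$k, k0)
})

test_that("K difference is antisymmetric and near zero for duplicated sets", {
  w <- rect_window(c(0, 100), c(0, 100))
  set.seed(9)
  x <- runif(60, 0, 100); y <- runif(60, 0, 100)
  m <- rep(c(TRUE, FALSE), 30)
  r <- seq(0, 20, length.out = 16)
  d1 <- k_difference(x, y, m, w, r)
  d2 <- k_difference(x, y, !m, w, r)
  expect_equal(d1$diff, -d2$diff)
  expect_equal(d1$k_success, d2$k_failure)

  # both classes the same point set, jittered: difference ~ 0
  xs <- runif(50, 5, 95); ys <- runif(50, 5, 95)
  xx <- c(xs, xs + rnorm(50, 0, 1e-4)); yy <- c(ys, ys + rnorm(50, 0, 1e-4))
  dd <- k_difference(xx, yy, rep(c(TRUE, FALSE), each = 50), w, r)
  expect_lt(max(abs(dd$diff)) / max(dd$k_success), 1e-2)

  expect_error(k_difference(x, y, c(TRUE, rep(FALSE, 59)), w, r),
               "at least 2 points")
})

test_that("r beyond the correction validity bound is rejected by name", {
  w <- rect_window(c(0, 100), c(0, 50))
  set.seed(2)
  x <- runif(20, 0, 100); y <- runif(20, 0, 50)
  expect_error(k_estimate(x, y, w, r = c(0, 50)), "validity bound.*50")
  # uncorrected K has no such bound
  expect_silent(k_estimate(x, y, w, r = c(0, 50), correction = "none"))
})

test_that("envelopes are reproducible and monotone in level", {
  set.seed(3)
  x <- runif(80, 0, 100); y <- runif(80, 0, 100)
  m <- runif(80) < 0.5
  w <- rect_window(c(0, 100), c(0, 100))
  r <- seq(0, 25, length.out = 20)
  e1 <- random_labeling_envelope(x, y, m, w, r, n_sim = 99, seed = 42)
  e2 <- random_labeling_envelope(x, y, m, w, r, n_sim = 99, seed = 42)
  expect_identical(e1$lo, e2$lo)
  expect_identical(e1$hi, e2$hi)
  expect_identical(e1$departures, e2$departures)

  e95 <- random_labeling_envelope(x, y, m, w, r, n_sim = 199, seed = 1,
                                  level = 0.95)
  e99 <- random_labeling_envelope(x, y, m, w, r, n_sim = 199, seed = 1,
                                  level = 0.99)
  expect_true(all(e99$lo <= e95$lo))
  expect_true(all(e99$hi >= e95$hi))

  expect_error(random_labeling_envelope(x, y, m, w, r, n_sim = 10),
               "at least 39")
  expect_error(random_labeling_envelope(x, y, rep(TRUE, 80), w, r,
                                        n_sim = 99), "at least 2 points")
})

test_that("departures are the maximal runs outside the envelope", {
  dep <- cachescape:::departure_intervals
  r <- 1:10
  obs <- c(0, 5, 6, 0, 0, -4, -5, -6, 0, 7)
  lo <- rep(-2, 10); hi <- rep(2, 10)
  d <- dep(r, obs, lo, hi)
  expect_equal(d$r_min, c(2, 6, 10))
  expect_equal(d$r_max, c(3, 8, 10))
  expect_equal(d$direction, c("success-clustered", "failure-clustered",
                              "success-clustered"))
  # boundary values (== bounds) are inside
  expect_equal(nrow(dep(r, rep(2, 10), lo, hi)), 0L)
})

test_that("run_spatial_analysis analyses groups and skips degenerate ones", {
  tab <- simulate_study(seed = 55)
  sa <- suppressMessages(run_spatial_analysis(tab, "pilferage", n_sim = 49,
                                              seed = 5))
  expect_length(sa, 4L)  # two areas x two zones
  expect_s3_class(sa[[1]], "rl_envelope")
  # same seed reproduces identical envelopes
  sb <- suppressMessages(run_spatial_analysis(tab, "pilferage", n_sim = 49,
                                              seed = 5))
  expect_identical(lapply(sa, `[[`, "hi"), lapply(sb, `[[`, "hi"))

  # a group with a single germinant cannot enter the survival analysis
  tab2 <- tab
  south_tl <- tab2$study_area == "southern" & tab2$elevation_zone == "treeline"
  tab2$n_live_seedlings_y2[south_tl] <- NA_integer_
  tab2$n_germinants_y1[south_tl & tab2$located_y1] <- 0L
  idx <- which(south_tl & tab2$located_y1 & tab2$n_missing_y1 == 0L)[1]
  tab2$n_germinants_y1[idx] <- 1L
  tab2$n_live_seedlings_y2[which(south_tl)] <- NA_integer_
  tab2$n_live_seedlings_y2[idx] <- 1L
  msgs <- capture_messages(
    sa2 <- run_spatial_analysis(tab2, "survival", n_sim = 49, seed = 5))
  expect_true(any(grepl("southern/treeline.*skipped", msgs)))
  expect_true("southern/treeline" %in% attr(sa2, "skipped"))
  expect_false("southern/treeline" %in% names(sa2))
})
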