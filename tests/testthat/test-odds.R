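test_that("odds is p/(1-p) with boundary signalling", {
  expect_equal(odds(0.25), 1 / 3)
  expect_equal(odds(0), 0)
  expect_equal(odds(0.5), 1)
  expect_warning(o1 <- odds(1), "infinite")
  expect_identical(o1, Inf)
  expect_error(odds(1.2), "\\[0, 1\\]")
  expect_error(odds(-0.1), "\\[0, 1\\]")
})

test_that("odds_ratio point estimate is the cross-product ratio", {
  res <- odds_ratio(139, 78, 90, 122)
  expect_equal(round(res$or, 2), 2.42)
  expect_equal(res$or, (139 * 122) / (78 * 90))
  expect_equal(round(odds_ratio(87, 52, 23, 67)$or, 2), 4.87)
  expect_equal(odds_ratio(5, 5, 5, 5)$or, 1.0)  # the null model

  # Wald CI on the log scale, computed by hand
  se <- sqrt(1 / 139 + 1 / 78 + 1 / 90 + 1 / 122)
  expect_equal(res$ci_low, exp(log(res$or) - qnorm(0.975) * se))
  expect_equal(res$ci_high, exp(log(res$or) + qnorm(0.975) * se))
  expect_false(res$no_difference)
  expect_true(odds_ratio(5, 5, 5, 5)$no_difference)
})

test_that("odds_ratio matches exhaustive integer arithmetic on random tables", {
  set.seed(7)
  for (k in 1:200) {
    cells <- sample.int(20, 4, replace = TRUE)
    res <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
    expect_identical(res$or,
                     (cells[1] * cells[4]) / (cells[2] * cells[3]))
    expect_false(res$zero_cell_adjusted)
  }
})

test_that("reciprocity: swapping groups inverts the estimate and reflects the CI", {
  set.seed(11)
  for (k in 1:50) {
    cells <- sample.int(40, 4, replace = TRUE)
    f <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
    b <- odds_ratio(cells[3], cells[4], cells[1], cells[2])
    expect_equal(b$or, 1 / f$or)
    expect_equal(b$ci_low, 1 / f$ci_high)
    expect_equal(b$ci_high, 1 / f$ci_low)
  }
})

test_that("scaling all cells preserves the estimate and narrows the CI", {
  f <- odds_ratio(12, 7, 9, 14)
  for (k in c(2L, 5L)) {
    g <- odds_ratio(12 * k, 7 * k, 9 * k, 14 * k)
    expect_equal(g$or, f$or)
    expect_lte(f$ci_low, g$ci_low)
    expect_gte(f$ci_high, g$ci_high)
  }
})

test_that("zero cells trigger the +0.5 adjustment; empty groups error", {
  res <- odds_ratio(10, 0, 5, 5)
  expect_true(res$zero_cell_adjusted)
  expect_equal(res$or, (10.5 * 5.5) / (0.5 * 5.5))
  expect_error(odds_ratio(0, 0, 5, 5), "at least one cache")
  expect_error(odds_ratio(3, 2, -1, 4), "non-negative")
})

test_that("exact method keeps the cross-product point estimate", {
  res <- odds_ratio(21, 3, 17, 11, method = "exact")
  expect_equal(res$or, (21 * 11) / (3 * 17))
  ft <- fisher.test(matrix(c(21, 3, 17, 11), 2, byrow = TRUE))
  expect_equal(c(res$ci_low, res$ci_high), as.numeric(ft$conf.int))
})

test_that("proportion_ci reproduces Clopper-Pearson by closed form", {
  res <- proportion_ci(197, 366)
  expect_equal(round(res$p_hat, 3), 0.538)
  # CP bounds via beta quantiles, independent of binom.test
  expect_equal(res$ci_low, qbeta(0.025, 197, 366 - 197 + 1))
  expect_equal(res$ci_high, qbeta(0.975, 197 + 1, 366 - 197))
  # printed reference interval, to 1 decimal in percent: 48.6-59.0
  expect_equal(round(100 * c(res$ci_low, res$ci_high), 1), c(48.6, 59.0))

  b0 <- proportion_ci(0, 10)
  expect_equal(b0$p_hat, 0)
  expect_equal(b0$ci_low, 0)
  b1 <- proportion_ci(10, 10)
  expect_equal(b1$p_hat, 1)
  expect_equal(b1$ci_high, 1)

  w <- proportion_ci(197, 366, method = "wilson")
  pt <- prop.test(197, 366, correct = FALSE)
  expect_equal(c(w$ci_low, w$ci_high), as.numeric(pt$conf.int))
  expect_error(proportion_ci(5, 0), "n >= 1")
})

test_that("pairwise contrasts use the canonical orientation", {
  m <- mirror_study_table(seed = 3)
  sur <- build_cohort(m, "survival")
  res <- pairwise_odds_ratios(sur, "microsite",
                              within = list(study_area = "southern",
                                            elevation_zone = "treeline"))
  expect_equal(res$group1, c("rock", "rock", "tree"))
  expect_equal(res$group2, c("tree", "open", "open"))
  expect_equal(round(res$or[res$group1 == "rock" & res$group2 == "open"], 2),
               4.53)
  expect_equal(round(res$or[res$group1 == "tree" & res$group2 == "open"], 2),
               8.41)
  # counts travel with the result: rock 21/3, open 17/11
  rock_open <- res[res$group1 == "rock" & res$group2 == "open", ]
  expect_equal(unlist(rock_open[c("a", "b", "c", "d")], use.names = FALSE),
               c(21, 3, 17, 11))

  pil <- build_cohort(m, "pilferage")
  zone <- pairwise_odds_ratios(pil, "elevation_zone",
                               within = list(study_area = "northern"))
  expect_equal(zone$group1, "treeline")
  expect_equal(round(zone$or, 2), 2.23)
  expect_equal(unlist(zone[c("a", "b", "c", "d")], use.names = FALSE),
               c(112, 64, 77, 98))
})

test_that("a single-level factor yields an empty result with a warning", {
  m <- mirror_study_table(seed = 3)
  co <- build_cohort(m, "pilferage", list(study_area = "southern"))
  expect_warning(res <- pairwise_odds_ratios(co, "study_area"),
                 "fewer than two")
  expect_equal(nrow(res), 0L)
})

test_that("run_odds_analysis covers the full contrast plan", {
  m <- mirror_study_table(seed = 5)
  res <- suppressMessages(run_odds_analysis(m))
  # 4 stages x (1 area + 2 zone + 4 x 3 microsite pairs)
  expect_equal(nrow(res), 4L * 15L)
  expect_true(all(res$a + res$b >= 1 & res$c + res$d >= 1))
  # decision flag matches the interval
  expect_equal(res$no_difference, res$ci_low <= 1 & res$ci_high >= 1)
  # single-area table: area contrast absent, the rest present
  south <- validate_cache_table(
    as.data.frame(m)[m$study_area == "southern", ])
  res_s <- suppressMessages(run_odds_analysis(south,
                                              stages = "pilferage"))
  expect_false("northern" %in% c(res_s$group1, res_s$group2))
  expect_equal(nrow(res_s), 7L)  # 1 zone pair + 2 zones x 3 microsite pairs

  adj <- suppressMessages(run_odds_analysis(m, stages = "pilferage",
                                            adjust = "BH"))
  expect_true("p_adjusted" %in% names(adj))
  expect_true(all(adj$p_adjusted >= adj$p_value))
})
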