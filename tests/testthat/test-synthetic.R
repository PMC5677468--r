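test_that("cache sizes follow the truncated Poisson law", {
  expect_true(all(sample_cache_size(1000, 3, 3, 3) == 3L))  # degenerate

  set.seed(123)
  draws <- sample_cache_size(1e5, lambda = 3, lo = 1, hi = 7)
  expect_true(all(draws >= 1L & draws <= 7L))
  # oracle: enumerate the renormalised 7-point pmf directly
  pmf <- dpois(1:7, 3) / sum(dpois(1:7, 3))
  mu <- sum((1:7) * pmf)
  sdv <- sqrt(sum((1:7)^2 * pmf) - mu^2)
  expect_lt(abs(mean(draws) - mu), 3 * sdv / sqrt(1e5))

  expect_error(sample_cache_size(10, 3, 0, 7), "1 <= lo <= hi")
  expect_error(sample_cache_size(10, 1e-12, 50, 60), "vanishing mass")
})

test_that("identical config and seed give identical tables and CSV bytes", {
  t1 <- simulate_study(seed = 7)
  t2 <- simulate_study(seed = 7)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  simulate_study(seed = 8, path = f1)
  simulate_study(seed = 8, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(as.data.frame(t1),
                         as.data.frame(simulate_study(seed = 9))))
})

test_that("the default design emulates the reference study layout", {
  tab <- simulate_study(seed = 21)
  expect_equal(nrow(tab), 734L)
  expect_equal(sum(tab$study_area == "southern"), 372L)
  expect_equal(sum(tab$study_area == "northern"), 362L)
  # a stratum with zero caches is simply absent
  d <- reference_design()[c("study_area", "elevation_zone", "microsite")]
  d$n_caches <- reference_design()$n_created
  d$n_caches[1] <- 0L
  cfg <- simulation_config(design = d)
  t0 <- simulate_study(cfg, seed = 3)
  expect_equal(nrow(t0), 734L - reference_design()$n_created[1])
  # generated tables satisfy the schema (validated on the way out)
  expect_s3_class(tab, "cache_table")
  expect_true(all(tab$n_seeds_cached >= 1L & tab$n_seeds_cached <= 7L))
})

test_that("degenerate stage probabilities propagate exactly", {
  cfg <- single_stratum_config(300, p_pilf = 1)
  tab <- simulate_study(cfg, seed = 5)
  expect_true(all(tab$n_missing_y1[tab$located_y1] >= 1L))
  cfg0 <- single_stratum_config(300, p_pilf = 0)
  tab0 <- simulate_study(cfg0, seed = 5)
  expect_true(all(tab0$n_missing_y1[tab0$located_y1] == 0L))
})

test_that("missing stratum probabilities raise a named configuration error", {
  d <- data.frame(study_area = "southern", elevation_zone = "treeline",
                  microsite = "open", n_caches = 10L)
  p <- data.frame(study_area = "southern", elevation_zone = "subalpine",
                  microsite = "open", p_pilferage = 0.5,
                  p_germination = 0.5, p_survival = 0.5)
  expect_error(simulation_config(design = d, probabilities = p),
               "southern treeline open")
})

test_that("stratum success rates are calibrated at large n", {
  cfg <- single_stratum_config(10000, p_pilf = 0.603, p_germ = 0.7,
                               window = c(2000, 2000))
  tab <- simulate_study(cfg, seed = 31)
  co <- build_cohort(tab, "pilferage")
  se <- sqrt(0.603 * 0.397 / nrow(co))
  expect_lt(abs(mean(co$success) - 0.603), 3 * se)
  ger <- build_cohort(tab, "germination_y1")
  se_g <- sqrt(0.7 * 0.3 / nrow(ger))
  expect_lt(abs(mean(ger$success) - 0.7), 3 * se_g)
})

test_that("pilfered caches lose all seeds at the configured fraction", {
  cfg <- single_stratum_config(8000, p_pilf = 1, window = c(2000, 2000))
  tab <- simulate_study(cfg, seed = 13)
  multi <- tab$n_seeds_cached >= 2L  # single-seed caches can only lose all
  total <- tab$n_missing_y1[multi] == tab$n_seeds_cached[multi]
  se <- sqrt(0.749 * 0.251 / sum(multi))
  expect_lt(abs(mean(total) - 0.749), 3 * se)
})

test_that("clustered fates concentrate successes around the centers", {
  cl <- list(pilferage = list(n_centers = 2, radius = 50,
                              inside_prob = 0.9, outside_prob = 0.1))
  cfg <- single_stratum_config(500, clustering = cl)
  tab <- simulate_study(cfg, seed = 17)
  centers <- attr(tab, "cluster_centers")$pilferage
  expect_equal(nrow(centers), 2L)
  d2 <- pmin((tab$x - centers$cx[1])^2 + (tab$y - centers$cy[1])^2,
             (tab$x - centers$cx[2])^2 + (tab$y - centers$cy[2])^2)
  inside <- d2 <= 50^2
  pilf <- tab$n_missing_y1 >= 1L
  expect_gt(mean(pilf[inside]), mean(pilf[!inside]))
  expect_gt(mean(pilf[inside]), 0.7)
  expect_lt(mean(pilf[!inside]), 0.3)
})

test_that("replicate odds ratios recover the configured odds ratio", {
  # treeline vs subalpine pilferage at the southern-like area
  key <- data.frame(study_area = "southern",
                    elevation_zone = c("treeline", "subalpine"),
                    microsite = "open", stringsAsFactors = FALSE)
  cfg <- simulation_config(
    design = cbind(key, n_caches = c(189L, 177L)),
    probabilities = cbind(key, p_pilferage = c(0.603, 0.469),
                          p_germination = 0.5, p_survival = 0.5),
    p_locate = 1)
  implied <- (0.603 / 0.397) / (0.469 / 0.531)
  set.seed(41)
  ors <- replicate(200, {
    tab <- simulate_study(cfg)
    co <- build_cohort(tab, "pilferage")
    res <- pairwise_odds_ratios(co, "elevation_zone")
    res$or
  })
  expect_lt(abs(mean(ors) - implied), 3 * sd(ors) / sqrt(length(ors)))
})
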