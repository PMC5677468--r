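# Synthetic cachescape generator: stratified cache placement, truncated-
# Poisson cache sizes, and per-stratum Bernoulli stage fates, optionally with
# spatially clustered fates (two-rate model around random cluster centers).

#' Simulation configuration for a synthetic caching study
#'
#' Defines the study conditions the generator emulates: a stratified design
#' (caches per study area x elevation zone x microsite), one rectangular
#' observation window per (area, zone), truncated-Poisson cache sizes, and
#' per-stratum stage probabilities. Defaults reproduce the reference study:
#' the [reference_design()] strata (734 caches over two areas), 700 m x 700 m
#' windows (~49 ha, matching the ~50-ha study areas), cache sizes
#' Poisson(lambda = 3) truncated to 1-7 seeds, locate probability 717/734,
#' stage probabilities equal to the reference percentages, and total loss of
#' all seeds in 74.9% of pilfered caches.
#'
#' @param design Data frame with columns `study_area`, `elevation_zone`,
#'   `microsite`, `n_caches` (and optionally the `p_*` probability columns
#'   below, which override `probabilities`).
#' @param probabilities Data frame keyed by `study_area`, `elevation_zone`,
#'   `microsite` with columns `p_pilferage`, `p_germination`, `p_survival`,
#'   `p_germ_2yr` (the last optional; without it no delayed germination is
#'   drawn). Every stratum present in `design` must have probabilities.
#' @param window Numeric `c(width, height)` in meters for every (area, zone)
#'   window, or a data frame `study_area`, `elevation_zone`, `width`,
#'   `height`.
#' @param cache_size_lambda Poisson mean for seeds per cache.
#' @param cache_size_range Integer `c(lo, hi)` truncation range.
#' @param p_locate Probability a created cache is located in year 1.
#' @param p_total_loss Probability a pilfered cache loses all of its seeds
#'   (partial losses are uniform over `1:(n_seeds - 1)`).
#' @param p_relocate Probability a year-2-eligible cache is relocated.
#' @param clustering Optional named list, one entry per stage in
#'   `c("pilferage", "germination_y1", "survival", "germination_2yr")`, each
#'   `list(n_centers, radius, inside_prob, outside_prob)`. When set for a
#'   stage, that stage's success probability is `inside_prob` within `radius`
#'   meters of any cluster center (centers uniform in each (area, zone)
#'   window) and `outside_prob` elsewhere, overriding the stratum
#'   probability.
#' @return A validated object of class `cachescape_config`.
#' @export
simulation_config <- function(design = NULL,
                              probabilities = NULL,
                              window = c(700, 700),
                              cache_size_lambda = 3,
                              cache_size_range = c(1L, 7L),
                              p_locate = reference_p_locate(),
                              p_total_loss = reference_total_loss(),
                              p_relocate = 1,
                              clustering = NULL) {
  ref <- reference_design()
  if (is.null(design)) {
    design <- ref[c("study_area", "elevation_zone", "microsite")]
    design$n_caches <- ref$n_created
  }
  stopifnot(is.data.frame(design),
            all(c("study_area", "elevation_zone", "microsite",
                  "n_caches") %in% names(design)))
  if (is.null(probabilities)) {
    probabilities <- ref[c("study_area", "elevation_zone", "microsite")]
    probabilities$p_pilferage <- ref$pct_pilfered / 100
    probabilities$p_germination <- ref$pct_germinated / 100
    probabilities$p_survival <- ref$pct_survived / 100
    probabilities$p_germ_2yr <- ref$pct_germinated_2yr / 100
  }
  if (is.numeric(window)) {
    stopifnot(length(window) == 2L, all(window > 0))
    w <- unique(design[c("study_area", "elevation_zone")])
    w$width <- window[1]
    w$height <- window[2]
    window <- w
  }
  stopifnot(all(c("study_area", "elevation_zone", "width", "height")
                %in% names(window)),
            all(window$width > 0), all(window$height > 0))
  lo <- as.integer(cache_size_range[1]); hi <- as.integer(cache_size_range[2])
  if (lo < 1L || hi < lo) stop("cache_size_range must satisfy 1 <= lo <= hi",
                               call. = FALSE)
  if (cache_size_lambda <= 0) stop("cache_size_lambda must be > 0",
                                   call. = FALSE)
  pcols <- intersect(c("p_pilferage", "p_germination", "p_survival",
                       "p_germ_2yr"), names(probabilities))
  for (pc in c(pcols)) {
    p <- probabilities[[pc]]
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
      stop(pc, " must lie in [0, 1]", call. = FALSE)
  }
  for (p in c(p_locate, p_total_loss, p_relocate))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  key <- function(d) paste(d$study_area, d$elevation_zone, d$microsite)
  miss <- setdiff(key(design), key(probabilities))
  if (length(miss))
    stop("missing stage probabilities for stratum: ",
         paste(miss, collapse = "; "), call. = FALSE)
  if (!is.null(clustering)) {
    bad <- setdiff(names(clustering), stage_levels())
    if (length(bad)) stop("clustering stages unknown: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (cl in clustering) {
      stopifnot(cl$n_centers >= 1, cl$radius > 0,
                cl$inside_prob >= 0, cl$inside_prob <= 1,
                cl$outside_prob >= 0, cl$outside_prob <= 1)
    }
  }
  structure(list(design = design, probabilities = probabilities,
                 window = window, cache_size_lambda = cache_size_lambda,
                 cache_size_range = c(lo, hi), p_locate = p_locate,
                 p_total_loss = p_total_loss, p_relocate = p_relocate,
                 clustering = clustering),
            class = "cachescape_config")
}

#' @export
print.cachescape_config <- function(x, ...) {
  cat("Synthetic cachescape configuration\n")
  cat("  strata:", nrow(x$design), " caches:", sum(x$design$n_caches), "\n")
  cat("  cache size: truncated Poisson(", x$cache_size_lambda, ") on [",
      x$cache_size_range[1], ",", x$cache_size_range[2], "]\n")
  if (!is.null(x$clustering))
    cat("  clustered fates:", paste(names(x$clustering), collapse = ", "), "\n")
  invisible(x)
}

#' Sample cache sizes from a truncated Poisson distribution
#'
#' Draws seeds-per-cache counts with probability proportional to the
#' Poisson(`lambda`) mass renormalised over `lo:hi` (truncation; identical in
#' law to rejection resampling).
#'
#' @param n Number of draws.
#' @param lambda Poisson mean (> 0).
#' @param lo,hi Integer truncation bounds, `1 <= lo <= hi`.
#' @return Integer vector of length `n` with values in `lo:hi`.
#' @export
sample_cache_size <- function(n, lambda = 3, lo = 1L, hi = 7L) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo < 1L || hi < lo) stop("need 1 <= lo <= hi", call. = FALSE)
  pmf <- stats::dpois(lo:hi, lambda)
  if (sum(pmf) < .Machine$double.eps * 100)
    stop("Poisson(", lambda, ") has vanishing mass on [", lo, ",", hi, "]",
         call. = FALSE)
  if (lo == hi) return(rep(lo, n))
  sample(lo:hi, n, replace = TRUE, prob = pmf)
}

#' Place caches in their stratified windows
#'
#' For each design stratum, draws `n_caches` locations uniformly in that
#' (study area, elevation zone) window and a cache size via
#' [sample_cache_size()]. Fate columns are left unset (`NA`).
#'
#' @param config A [simulation_config()].
#' @return A data frame of cache records with fates unset.
#' @export
place_caches <- function(config) {
  stopifnot(inherits(config, "cachescape_config"))
  d <- config$design
  d <- d[d$n_caches > 0L, , drop = FALSE]
  rows <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    s <- d[i, ]
    w <- config$window[config$window$study_area == s$study_area &
                         config$window$elevation_zone == s$elevation_zone, ]
    if (nrow(w) != 1L)
      stop("no window for ", s$study_area, "/", s$elevation_zone,
           call. = FALSE)
    n <- s$n_caches
    rows[[i]] <- data.frame(
      cache_id = sprintf("%s_%s_%s_%03d", s$study_area, s$elevation_zone,
                         s$microsite, seq_len(n)),
      study_area = s$study_area,
      elevation_zone = s$elevation_zone,
      microsite = canonical_microsite(s$microsite),
      x = stats::runif(n, 0, w$width),
      y = stats::runif(n, 0, w$height),
      n_seeds_cached = sample_cache_size(n, config$cache_size_lambda,
                                         config$cache_size_range[1],
                                         config$cache_size_range[2]),
      located_y1 = NA,
      n_missing_y1 = NA_integer_,
      n_seed_coats_y1 = NA_integer_,
      n_germinants_y1 = NA_integer_,
      relocated_y2 = NA,
      n_live_seedlings_y2 = NA_integer_,
      n_new_germinants_y2 = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' @keywords internal
stage_prob_lookup <- function(config, records, column) {
  p <- config$probabilities
  key <- paste(p$study_area, p$elevation_zone, p$microsite)
  rkey <- paste(records$study_area, records$elevation_zone,
                records$microsite)
  idx <- match(rkey, key)
  if (anyNA(idx))
    stop("missing stage probabilities for stratum: ",
         paste(unique(rkey[is.na(idx)]), collapse = "; "), call. = FALSE)
  if (!column %in% names(p)) return(rep(NA_real_, nrow(records)))
  p[[column]][idx]
}

#' @keywords internal
clustered_prob <- function(records, config, stage) {
  cl <- config$clustering[[stage]]
  groups <- unique(records[c("study_area", "elevation_zone")])
  p <- rep(cl$outside_prob, nrow(records))
  centers <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    w <- config$window[config$window$study_area == groups$study_area[g] &
                         config$window$elevation_zone ==
                           groups$elevation_zone[g], ]
    cx <- stats::runif(cl$n_centers, 0, w$width)
    cy <- stats::runif(cl$n_centers, 0, w$height)
    centers[[g]] <- data.frame(study_area = groups$study_area[g],
                               elevation_zone = groups$elevation_zone[g],
                               cx = cx, cy = cy)
    in_group <- records$study_area == groups$study_area[g] &
      records$elevation_zone == groups$elevation_zone[g]
    idx <- which(in_group)
    d2min <- rep(Inf, length(idx))
    for (k in seq_len(cl$n_centers))
      d2min <- pmin(d2min, (records$x[idx] - cx[k])^2 +
                      (records$y[idx] - cy[k])^2)
    p[idx][d2min <= cl$radius^2] <- cl$inside_prob
  }
  list(p = p, centers = do.call(rbind, centers))
}

#' Assign stage fates to placed caches
#'
#' Draws the observation and fate chain for each cache: located in year 1
#' with probability `p_locate` (never-located caches get null year-1 fields);
#' pilfered with the stratum (or clustered) pilferage probability, losing all
#' seeds with probability `p_total_loss` and otherwise a uniform partial
#' count; germination in year 1 with the stratum probability among caches
#' with intact seeds; survival to year 2 among caches with first-year
#' seedlings; and delayed (year-2) germination at the rate implied by the
#' stratum's two-year probability, `(p_2yr - p_germ) / (1 - p_germ)`,
#' among eligible caches that did not germinate in year 1.
#'
#' @param records Placed cache records from [place_caches()].
#' @param config The [simulation_config()] used to place them.
#' @return A validated `cache_table`. When fate clustering is configured, the
#'   drawn cluster centers are attached as `attr(, "cluster_centers")` (a
#'   named list per stage).
#' @export
assign_outcomes <- function(records, config) {
  stopifnot(inherits(config, "cachescape_config"))
  n <- nrow(records)
  r <- records
  centers <- list()
  stage_p <- function(stage, column) {
    if (!is.null(config$clustering[[stage]])) {
      cp <- clustered_prob(r, config, stage)
      centers[[stage]] <<- cp$centers
      cp$p
    } else {
      p <- stage_prob_lookup(config, r, column)
      if (anyNA(p)) stop("probability column '", column,
                         "' missing from config$probabilities", call. = FALSE)
      p
    }
  }
  r$located_y1 <- stats::runif(n) < config$p_locate
  loc <- r$located_y1

  p_pilf <- stage_p("pilferage", "p_pilferage")
  pilfered <- loc & stats::runif(n) < p_pilf
  total <- pilfered & (stats::runif(n) < config$p_total_loss |
                         r$n_seeds_cached == 1L)
  partial <- pilfered & !total
  r$n_missing_y1 <- ifelse(loc, 0L, NA_integer_)
  r$n_missing_y1[total] <- r$n_seeds_cached[total]
  if (any(partial))
    r$n_missing_y1[partial] <- 1L + floor(stats::runif(sum(partial)) *
                                            (r$n_seeds_cached[partial] - 1L))
  intact <- r$n_seeds_cached - r$n_missing_y1
  r$n_seed_coats_y1 <- ifelse(loc, 0L, NA_integer_)

  p_germ <- stage_p("germination_y1", "p_germination")
  elig_g <- loc & intact >= 1L
  germinated <- elig_g & stats::runif(n) < p_germ
  r$n_germinants_y1 <- ifelse(loc, 0L, NA_integer_)
  if (any(germinated))
    r$n_germinants_y1[germinated] <- sample_int_vec(intact[germinated])

  # year-2 observation: caches with intact seeds or seedlings are revisited
  revisit <- loc & (intact - r$n_germinants_y1 >= 1L | r$n_germinants_y1 >= 1L)
  r$relocated_y2 <- ifelse(revisit, stats::runif(n) < config$p_relocate, NA)

  p_surv <- stage_p("survival", "p_survival")
  elig_s <- r$n_germinants_y1 >= 1L & !is.na(r$n_germinants_y1)
  observed2 <- !is.na(r$relocated_y2) & r$relocated_y2
  survived <- elig_s & observed2 & stats::runif(n) < p_surv
  r$n_live_seedlings_y2 <- ifelse(elig_s & observed2, 0L, NA_integer_)
  if (any(survived))
    r$n_live_seedlings_y2[survived] <- sample_int_vec(r$n_germinants_y1[survived])

  p_2yr <- if (!is.null(config$clustering[["germination_2yr"]]))
    stage_p("germination_2yr", "p_germ_2yr")
  else stage_prob_lookup(config, r, "p_germ_2yr")
  r$n_new_germinants_y2 <- ifelse(observed2, 0L, NA_integer_)
  if (!all(is.na(p_2yr))) {
    # conditional delayed-germination rate among year-1 non-germinators
    p_cond <- pmax(0, pmin(1, (p_2yr - p_germ) / pmax(1e-12, 1 - p_germ)))
    remaining <- intact - r$n_germinants_y1
    elig_2 <- observed2 & elig_g & r$n_germinants_y1 == 0L & remaining >= 1L
    newg <- elig_2 & stats::runif(n) < p_cond
    if (any(newg))
      r$n_new_germinants_y2[newg] <- sample_int_vec(remaining[newg])
  }
  out <- validate_cache_table(r)
  if (length(centers)) attr(out, "cluster_centers") <- centers
  out
}

#' @keywords internal
#' Uniform draw on 1..k, vectorised over k (k >= 1)
sample_int_vec <- function(k) {
  pmin(k, 1L + as.integer(floor(stats::runif(length(k)) * k)))
}

#' Simulate a complete synthetic caching study
#'
#' Composition of [place_caches()] and [assign_outcomes()]; optionally writes
#' the resulting table as CSV. Identical `config` and `seed` give identical
#' (byte-identical, if written) tables.
#'
#' @param config A [simulation_config()]; defaults emulate the reference
#'   study design.
#' @param seed Optional integer seed.
#' @param path Optional CSV output path (written via [write_cache_table()]).
#' @return A validated `cache_table`.
#' @export
simulate_study <- function(config = simulation_config(), seed = NULL,
                           path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  records <- place_caches(config)
  table <- assign_outcomes(records, config)
  if (!is.null(path)) write_cache_table(table, path)
  table
}
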