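# Ripley's K estimation on rectangular windows, the success-minus-failure
# difference of K functions for binary-marked patterns, and pointwise
# random-labeling permutation envelopes.

#' Rectangular observation window
#'
#' @param xrange,yrange Numeric length-2 ranges (meters, planar projected
#'   coordinates; geographic lat/lon is not accepted).
#' @return A list of class `rect_window` with `xrange`, `yrange`, `width`,
#'   `height`, `area`.
#' @export
rect_window <- function(xrange, yrange) {
  stopifnot(length(xrange) == 2L, length(yrange) == 2L,
            diff(xrange) > 0, diff(yrange) > 0)
  structure(list(xrange = as.numeric(xrange), yrange = as.numeric(yrange),
                 width = diff(xrange), height = diff(yrange),
                 area = diff(xrange) * diff(yrange)),
            class = "rect_window")
}

#' @keywords internal
bounding_window <- function(x, y, margin = 0) {
  rect_window(range(x) + c(-margin, margin), range(y) + c(-margin, margin))
}

#' @keywords internal
default_r_grid <- function(window, n_r = 128L) {
  seq(0, min(window$width, window$height) / 4, length.out = n_r)
}

#' @keywords internal
check_window_points <- function(x, y, window) {
  if (any(x < window$xrange[1] - 1e-9) || any(x > window$xrange[2] + 1e-9) ||
      any(y < window$yrange[1] - 1e-9) || any(y > window$yrange[2] + 1e-9))
    stop("points fall outside the observation window", call. = FALSE)
}

# Fraction of the circle of radius r centered at (x, y) lying inside the
# window: Ripley's isotropic correction weight is its reciprocal. The outside
# arc is the sum of the per-edge cut arcs 2*acos(d/r) minus, for each corner
# closer than r, the overlap max(0, pi/2 - asin(d1/r) - asin(d2/r)).
#' @keywords internal
circle_inside_fraction <- function(x, y, r, window) {
  dl <- x - window$xrange[1]; dr <- window$xrange[2] - x
  db <- y - window$yrange[1]; dt <- window$yrange[2] - y
  arc <- function(d) ifelse(d < r, 2 * acos(pmin(1, d / r)), 0)
  corner <- function(d1, d2)
    ifelse(d1^2 + d2^2 < r^2,
           pmax(0, pi / 2 - asin(pmin(1, d1 / r)) - asin(pmin(1, d2 / r))),
           0)
  out <- arc(dl) + arc(dr) + arc(db) + arc(dt) -
    corner(dl, db) - corner(dl, dt) - corner(dr, db) - corner(dr, dt)
  pmax(.Machine$double.eps, 1 - out / (2 * pi))
}

# Pairwise geometry shared by the K estimators: unordered pair distances,
# per-pair correction weights summed over both orientations, sorted by
# distance so K curves are cumulative sums indexed by findInterval().
#' @keywords internal
pair_geometry <- function(x, y, window, correction) {
  n <- length(x)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  dx <- x[i] - x[j]; dy <- y[i] - y[j]
  d <- sqrt(dx^2 + dy^2)
  wsum <- switch(correction,
    none = rep(2, length(d)),
    translation = 2 * window$area /
      ((window$width - abs(dx)) * (window$height - abs(dy))),
    isotropic = 1 / circle_inside_fraction(x[i], y[i], d, window) +
      1 / circle_inside_fraction(x[j], y[j], d, window))
  ord <- order(d)
  list(i = i[ord], j = j[ord], d = d[ord], wsum = wsum[ord],
       n = n, area = window$area)
}

#' @keywords internal
check_r_valid <- function(r, window, correction) {
  if (any(r < 0)) stop("distances r must be >= 0", call. = FALSE)
  if (correction %in% c("translation", "isotropic")) {
    bound <- min(window$width, window$height)
    if (max(r) >= bound)
      stop("r must stay below the ", correction,
           " correction's validity bound min(width, height) = ", bound,
           call. = FALSE)
  }
}

#' Ripley's K function on a rectangular window
#'
#' Estimates `K(r)` for an unmarked planar point pattern:
#' `Khat(r) = (|W| / (n (n - 1))) * sum_{i != j} w_ij 1(d_ij <= r)`,
#' with weights `w_ij = 1` (no edge correction), the translation correction
#' `w_ij = |W| / ((width - |dx_ij|) (height - |dy_ij|))`, or Ripley's
#' isotropic correction (reciprocal of the fraction of the circle of radius
#' `d_ij` around point i lying inside the window). Under complete spatial
#' randomness `K(r) = pi r^2`.
#'
#' @param x,y Point coordinates in meters.
#' @param window A [rect_window()]; defaults to the points' bounding box.
#' @param r Increasing distance grid starting reasonably near 0; defaults to
#'   128 values from 0 to one quarter of the shorter window side. For the
#'   corrected estimators `max(r)` must stay below `min(width, height)`.
#' @param correction `"translation"` (default), `"isotropic"` or `"none"`.
#' @return An object of class `k_estimate`: list with `r`, `k`, `correction`,
#'   `n`, `window`.
#' @export
k_estimate <- function(x, y, window = NULL, r = NULL,
                       correction = c("translation", "isotropic", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(x) == length(y))
  if (length(x) < 2L)
    stop("K estimation needs at least 2 points", call. = FALSE)
  if (is.null(window)) window <- bounding_window(x, y)
  check_window_points(x, y, window)
  if (is.null(r)) r <- default_r_grid(window)
  check_r_valid(r, window, correction)
  pg <- pair_geometry(x, y, window, correction)
  cum <- c(0, cumsum(pg$wsum))
  idx <- findInterval(r, pg$d)
  k <- window$area / (pg$n * (pg$n - 1)) * cum[idx + 1L]
  structure(list(r = r, k = k, correction = correction, n = pg$n,
                 window = window),
            class = "k_estimate")
}

#' @export
print.k_estimate <- function(x, ...) {
  cat("Ripley's K estimate (", x$correction, " correction), n = ", x$n,
      ", r in [", min(x$r), ", ", max(x$r), "]\n", sep = "")
  invisible(x)
}

#' @keywords internal
kdiff_from_pairs <- function(pg, marks, idx) {
  ss <- marks[pg$i] & marks[pg$j]
  ff <- !marks[pg$i] & !marks[pg$j]
  ns <- sum(marks); nf <- pg$n - ns
  cs <- c(0, cumsum(pg$wsum * ss))
  cf <- c(0, cumsum(pg$wsum * ff))
  pg$area * (cs[idx + 1L] / (ns * (ns - 1)) - cf[idx + 1L] / (nf * (nf - 1)))
}

#' Difference of K functions between marked-point classes
#'
#' `K_success(r) - K_failure(r)` estimated on the shared window and grid.
#' Positive values at a distance r indicate that successes are more clustered
#' than failures at that scale, negative values the reverse.
#'
#' @param x,y Coordinates.
#' @param marks Logical vector: `TRUE` = success, `FALSE` = failure. At least
#'   2 points of each class are required.
#' @inheritParams k_estimate
#' @return A list of class `k_difference` with `r`, `diff`, `k_success`,
#'   `k_failure`, `n_success`, `n_failure`, `correction`, `window`.
#' @export
k_difference <- function(x, y, marks, window = NULL, r = NULL,
                         correction = c("translation", "isotropic", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(x) == length(y), length(marks) == length(x),
            is.logical(marks), !anyNA(marks))
  if (sum(marks) < 2L || sum(!marks) < 2L)
    stop("each mark class needs at least 2 points", call. = FALSE)
  if (is.null(window)) window <- bounding_window(x, y)
  check_window_points(x, y, window)
  if (is.null(r)) r <- default_r_grid(window)
  check_r_valid(r, window, correction)
  ks <- k_estimate(x[marks], y[marks], window, r, correction)
  kf <- k_estimate(x[!marks], y[!marks], window, r, correction)
  structure(list(r = r, diff = ks$k - kf$k, k_success = ks$k,
                 k_failure = kf$k, n_success = sum(marks),
                 n_failure = sum(!marks), correction = correction,
                 window = window),
            class = "k_difference")
}

#' @keywords internal
departure_intervals <- function(r, observed, lo, hi) {
  state <- integer(length(r))
  state[observed > hi] <- 1L
  state[observed < lo] <- -1L
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L
  if (!any(keep))
    return(data.frame(r_min = numeric(0), r_max = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  data.frame(r_min = r[starts[keep]], r_max = r[ends[keep]],
             direction = ifelse(runs$values[keep] > 0L,
                                "success-clustered", "failure-clustered"),
             stringsAsFactors = FALSE)
}

#' Random-labeling permutation envelope for the K difference
#'
#' Tests whether one mark class is clustered relative to the other under the
#' random labeling hypothesis: the point locations are held fixed and the
#' marks are permuted `n_sim` times, preserving the observed number of
#' successes, so that the probability of success is equal for all caches.
#' The pointwise envelope takes, at each distance, the order statistics of
#' rank `floor(alpha * (n_sim + 1))` and `ceiling((1 - alpha) * (n_sim + 1))`
#' of the simulated difference curves (`alpha = (1 - level) / 2`); for
#' `n_sim = 1000` and `level = 0.95` these are the 25th and 976th of 1000.
#' Distances where the observed difference exceeds the upper bound indicate
#' clustering of successes relative to failures; below the lower bound,
#' clustering of failures.
#'
#' @inheritParams k_difference
#' @param n_sim Number of random relabelings (default 1000; at least 39 for
#'   a 95% envelope, so that the envelope ranks are defined).
#' @param level Envelope level (pointwise, default 0.95).
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `rl_envelope`: `r`, `observed` (difference
#'   curve), `lo`, `hi`, `departures` (data frame of maximal grid intervals
#'   with direction), `n_sim`, `level`, `n_success`, `n_failure`,
#'   `correction`, `seed`.
#' @export
random_labeling_envelope <- function(x, y, marks, window = NULL, r = NULL,
                                     correction = c("translation",
                                                    "isotropic", "none"),
                                     n_sim = 1000L, level = 0.95,
                                     seed = NULL) {
  correction <- match.arg(correction)
  stopifnot(length(x) == length(y), length(marks) == length(x),
            is.logical(marks), !anyNA(marks))
  if (sum(marks) < 2L || sum(!marks) < 2L)
    stop("each mark class needs at least 2 points", call. = FALSE)
  alpha <- (1 - level) / 2
  ilo <- floor(alpha * (n_sim + 1))
  ihi <- ceiling((1 - alpha) * (n_sim + 1))
  if (ilo < 1L || ihi > n_sim)
    stop("n_sim = ", n_sim, " too small for a ", level,
         " envelope; need at least ", ceiling(1 / alpha) - 1, call. = FALSE)
  if (is.null(window)) window <- bounding_window(x, y)
  check_window_points(x, y, window)
  if (is.null(r)) r <- default_r_grid(window)
  check_r_valid(r, window, correction)
  if (!is.null(seed)) set.seed(seed)
  pg <- pair_geometry(x, y, window, correction)
  idx <- findInterval(r, pg$d)
  observed <- kdiff_from_pairs(pg, marks, idx)
  n <- length(x)
  sims <- matrix(NA_real_, nrow = n_sim, ncol = length(r))
  for (s in seq_len(n_sim)) {
    perm <- logical(n)
    perm[sample.int(n, sum(marks))] <- TRUE
    sims[s, ] <- kdiff_from_pairs(pg, perm, idx)
  }
  lo <- apply(sims, 2L, function(v) sort.int(v, partial = ilo)[ilo])
  hi <- apply(sims, 2L, function(v) sort.int(v, partial = ihi)[ihi])
  structure(list(r = r, observed = observed, lo = lo, hi = hi,
                 departures = departure_intervals(r, observed, lo, hi),
                 n_sim = n_sim, level = level, n_success = sum(marks),
                 n_failure = sum(!marks), correction = correction,
                 window = window, seed = seed),
            class = "rl_envelope")
}

#' @export
print.rl_envelope <- function(x, ...) {
  cat("Random-labeling envelope for K_success - K_failure\n")
  cat("  points:", x$n_success, "successes,", x$n_failure, "failures;",
      x$n_sim, "relabelings;", paste0(round(100 * x$level), "%"),
      "pointwise envelope\n")
  if (nrow(x$departures) == 0L) {
    cat("  no departures from the envelope\n")
  } else {
    for (k in seq_len(nrow(x$departures)))
      cat(sprintf("  %s at r in [%.1f, %.1f] m\n",
                  x$departures$direction[k], x$departures$r_min[k],
                  x$departures$r_max[k]))
  }
  invisible(x)
}

#' @export
plot.rl_envelope <- function(x, main = "K-difference with random-labeling envelope",
                             ...) {
  ylim <- range(x$observed, x$lo, x$hi)
  graphics::plot(x$r, x$observed, type = "n", xlab = "r (m)",
                 ylab = expression(hat(K)[s](r) - hat(K)[f](r)),
                 ylim = ylim, main = main, ...)
  graphics::polygon(c(x$r, rev(x$r)), c(x$lo, rev(x$hi)),
                    col = "grey85", border = NA)
  graphics::lines(x$r, x$observed, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Stage-wise spatial clustering analysis of a cache-fate table
#'
#' For each study area x elevation zone combination, builds the stage cohort,
#' treats the stage outcome as the binary mark (success = pilfered /
#' germinated in year 1 / seedling survived / germinated within two years),
#' and runs [random_labeling_envelope()] on the cohort's cache coordinates.
#' Groups whose cohort has fewer than two successes or two failures are
#' reported as skipped, not fatal.
#'
#' @param records A `cache_table`.
#' @param stage Stage name (see [build_cohort()]).
#' @param grouping Columns defining the analysis groups.
#' @param margin Meters by which each group's bounding-box window is expanded
#'   on every side.
#' @param n_sim,level,correction,r Passed to [random_labeling_envelope()].
#' @param seed Optional integer; group g uses `seed + g - 1` so runs are
#'   reproducible yet groups are independent.
#' @return A list of class `spatial_analysis`: one `rl_envelope` per
#'   non-degenerate group (named `"area/zone"`), with skipped group names in
#'   `attr(, "skipped")`.
#' @export
run_spatial_analysis <- function(records, stage = "pilferage",
                                 grouping = c("study_area", "elevation_zone"),
                                 margin = 0, n_sim = 1000L, level = 0.95,
                                 correction = "translation", r = NULL,
                                 seed = NULL) {
  r_arg <- r
  groups <- unique(as.data.frame(records)[grouping])
  out <- list()
  skipped <- character(0)
  for (g in seq_len(nrow(groups))) {
    filt <- as.list(groups[g, , drop = FALSE])
    label <- paste(unlist(filt), collapse = "/")
    cohort <- withCallingHandlers(
      build_cohort(records, stage, filter = filt),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(cohort) < 4L || sum(cohort$success) < 2L ||
        sum(!cohort$success) < 2L) {
      message("group ", label, ": cohort degenerate for stage '", stage,
              "', skipped")
      skipped <- c(skipped, label)
      next
    }
    win <- bounding_window(cohort$x, cohort$y, margin = margin)
    out[[label]] <- random_labeling_envelope(
      cohort$x, cohort$y, cohort$success, window = win, r = r_arg,
      correction = correction, n_sim = n_sim, level = level,
      seed = if (is.null(seed)) NULL else seed + g - 1L)
  }
  attr(out, "skipped") <- skipped
  attr(out, "stage") <- stage
  class(out) <- "spatial_analysis"
  out
}

#' @export
print.spatial_analysis <- function(x, ...) {
  cat("Spatial clustering analysis, stage:", attr(x, "stage"), "\n")
  for (nm in names(x)) {
    dep <- x[[nm]]$departures
    cat("  ", nm, ": ",
        if (nrow(dep) == 0L) "no departures"
        else paste0(nrow(dep), " departure interval(s)"), "\n", sep = "")
  }
  if (length(attr(x, "skipped")))
    cat("  skipped:", paste(attr(x, "skipped"), collapse = ", "), "\n")
  invisible(x)
}
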