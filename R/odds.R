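# Odds, odds ratios and proportion confidence intervals for stage cohorts.

#' Odds of an event
#'
#' `odds(p)` is `p / (1 - p)` for a success proportion `p`. A proportion of
#' 0.25 gives odds 0.25/0.75 = 0.333: the probability of the event is one
#' third that of its complement.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return `p / (1 - p)`; `Inf` (with a warning) where `p == 1`.
#' @export
odds <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  if (any(p == 1)) warning("p = 1 gives infinite odds", call. = FALSE)
  p / (1 - p)
}

#' Odds ratio for a 2x2 success/failure table
#'
#' Point estimate is the cross-product ratio `(a * d) / (b * c)`, i.e. the
#' ratio of the two groups' odds. If any cell is zero, 0.5 is added to all
#' four cells (flagged via `zero_cell_adjusted`) before estimation. The
#' default confidence interval is Wald on the log-odds-ratio scale,
#' `exp(log(OR) +- z * sqrt(1/a + 1/b + 1/c + 1/d))`; `"adjusted"` adds 0.5
#' to every cell unconditionally, and `"exact"` takes the conditional exact
#' interval from [stats::fisher.test()] (the point estimate stays the
#' cross-product ratio).
#'
#' @param a,b Successes and failures in group 1.
#' @param c,d Successes and failures in group 2.
#' @param level Confidence level in (0, 1).
#' @param method One of `"wald"`, `"adjusted"`, `"exact"`.
#' @return An object of class `odds_result`: a list with `a`, `b`, `c`, `d`,
#'   `odds1`, `odds2`, `or`, `ci_low`, `ci_high`, `level`, `method`,
#'   `zero_cell_adjusted`, `no_difference` (TRUE iff the interval contains
#'   1), and a Wald `p_value`.
#' @export
odds_ratio <- function(a, b, c, d, level = 0.95,
                       method = c("wald", "adjusted", "exact")) {
  method <- match.arg(method)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (a + b < 1 || c + d < 1)
    stop("each group needs at least one cache (a+b >= 1 and c+d >= 1)",
         call. = FALSE)
  zero_adj <- any(cells == 0)
  use <- cells
  if (method == "adjusted" || (zero_adj && method != "exact"))
    use <- cells + 0.5
  or_point <- if (zero_adj || method == "adjusted")
    (use["a"] * use["d"]) / (use["b"] * use["c"])
  else (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "exact") {
    ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                             conf.level = level)
    ci <- unname(ft$conf.int)
  } else {
    se <- sqrt(sum(1 / use))
    ci <- exp(log(or_point) + c(-1, 1) * z * se)
  }
  se_w <- sqrt(sum(1 / pmax(use, 0.5)))
  p_value <- 2 * stats::pnorm(-abs(log(or_point)) / se_w)
  structure(list(a = unname(a), b = unname(b), c = unname(c), d = unname(d),
                 odds1 = unname(use["a"] / use["b"]),
                 odds2 = unname(use["c"] / use["d"]),
                 or = unname(or_point),
                 ci_low = ci[1], ci_high = ci[2], level = level,
                 method = method, zero_cell_adjusted = zero_adj,
                 no_difference = ci[1] <= 1 && 1 <= ci[2],
                 p_value = unname(p_value)),
            class = "odds_result")
}

#' @export
print.odds_result <- function(x, ...) {
  cat(sprintf("Odds ratio: %.2f (%d%% CI: %.2f, %.2f) [%s%s]\n",
              x$or, round(100 * x$level), x$ci_low, x$ci_high, x$method,
              if (x$zero_cell_adjusted) ", zero-cell +0.5" else ""))
  cat(sprintf("  counts %d/%d vs %d/%d; %s\n", x$a, x$b, x$c, x$d,
              if (x$no_difference) "CI contains 1.0: no difference concluded"
              else "CI excludes 1.0"))
  invisible(x)
}

#' Binomial proportion with confidence interval
#'
#' Default interval is the exact Clopper-Pearson interval (the method behind
#' the reference study's printed percentages); the Wilson score interval is
#' available as an option.
#'
#' @param x Number of successes.
#' @param n Number of trials (>= 1).
#' @param level Confidence level.
#' @param method `"exact"` (Clopper-Pearson) or `"wilson"`.
#' @return A list of class `proportion_result` with `x`, `n`, `p_hat`,
#'   `ci_low`, `ci_high`, `level`, `method`.
#' @export
proportion_ci <- function(x, n, level = 0.95, method = c("exact", "wilson")) {
  method <- match.arg(method)
  if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n and n >= 1",
                                    call. = FALSE)
  ci <- if (method == "exact")
    stats::binom.test(x, n, conf.level = level)$conf.int
  else
    stats::prop.test(x, n, conf.level = level, correct = FALSE)$conf.int
  structure(list(x = x, n = n, p_hat = x / n, ci_low = ci[1],
                 ci_high = ci[2], level = level, method = method),
            class = "proportion_result")
}

#' @export
print.proportion_result <- function(x, ...) {
  cat(sprintf("%.1f%% (%d%% CI: %.1f-%.1f, n = %d) [%s]\n", 100 * x$p_hat,
              round(100 * x$level), 100 * x$ci_low, 100 * x$ci_high, x$n,
              x$method))
  invisible(x)
}

#' @keywords internal
canonical_levels <- function(factor_name, values) {
  pref <- switch(factor_name,
                 microsite = c("rock", "tree", "open"),
                 elevation_zone = c("treeline", "subalpine"),
                 unique(values))
  c(intersect(pref, unique(values)),
    setdiff(unique(values), pref))
}

#' All pairwise odds-ratio contrasts for one stratum dimension
#'
#' For each unordered pair of levels of `factor` present in the cohort,
#' computes the 2x2 odds ratio with a fixed canonical orientation: microsites
#' rock/tree, rock/open, tree/open; elevation zones treeline/subalpine; study
#' areas in order of appearance. Levels with no eligible caches are skipped
#' with a warning. The 2x2 counts travel with each result for auditability.
#'
#' @param cohort A `stage_cohort` from [build_cohort()].
#' @param factor One of `"study_area"`, `"elevation_zone"`, `"microsite"`.
#' @param within Optional named list fixing other strata, e.g.
#'   `list(study_area = "southern", elevation_zone = "treeline")`.
#' @param level,method Passed to [odds_ratio()].
#' @return A data frame with one row per pair: `stage`, `factor`, `within`,
#'   `group1`, `group2`, the 2x2 cells `a`, `b`, `c`, `d`, `or`, `ci_low`,
#'   `ci_high`, `no_difference`, `zero_cell_adjusted`, `p_value`, `method`.
#' @export
pairwise_odds_ratios <- function(cohort, factor, within = NULL, level = 0.95,
                                 method = "wald") {
  stopifnot(inherits(cohort, "stage_cohort"))
  co <- as.data.frame(cohort)
  scope <- ""
  if (!is.null(within)) {
    for (nm in names(within))
      co <- co[co[[nm]] %in% within[[nm]], , drop = FALSE]
    scope <- paste(unlist(within), collapse = "/")
  }
  levs <- canonical_levels(factor, co[[factor]])
  counts <- lapply(levs, function(l) {
    s <- co$success[co[[factor]] == l]
    c(x = sum(s), n = length(s))
  })
  names(counts) <- levs
  usable <- levs[vapply(counts, function(ct) ct["n"] >= 1, logical(1))]
  if (length(usable) < length(levs))
    warning("level(s) without eligible caches skipped: ",
            paste(setdiff(levs, usable), collapse = ", "), call. = FALSE)
  if (length(usable) < 2L) {
    warning("fewer than two usable levels of '", factor,
            "': no contrasts computed", call. = FALSE)
    return(empty_or_table())
  }
  pairs <- utils::combn(usable, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    c1 <- counts[[g1]]; c2 <- counts[[g2]]
    res <- odds_ratio(c1["x"], c1["n"] - c1["x"], c2["x"], c2["n"] - c2["x"],
                      level = level, method = method)
    data.frame(stage = attr(cohort, "stage"), factor = factor, within = scope,
               group1 = g1, group2 = g2, a = res$a, b = res$b, c = res$c,
               d = res$d, or = res$or, ci_low = res$ci_low,
               ci_high = res$ci_high, no_difference = res$no_difference,
               zero_cell_adjusted = res$zero_cell_adjusted,
               p_value = res$p_value, method = res$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @keywords internal
empty_or_table <- function() {
  data.frame(stage = character(0), factor = character(0),
             within = character(0), group1 = character(0),
             group2 = character(0), a = integer(0), b = integer(0),
             c = integer(0), d = integer(0), or = numeric(0),
             ci_low = numeric(0), ci_high = numeric(0),
             no_difference = logical(0), zero_cell_adjusted = logical(0),
             p_value = numeric(0), method = character(0),
             stringsAsFactors = FALSE)
}

#' Full odds-ratio analysis of a cache-fate table
#'
#' Runs, for each requested stage cohort, the full contrast plan: the
#' study-area pair on the whole cohort, the elevation-zone pair within each
#' study area, and all microsite pairs within each study area x elevation
#' zone. Empty cohorts or single-level factors are logged and skipped; the
#' run continues.
#'
#' @param records A `cache_table`.
#' @param stages Character vector of stage names (see [build_cohort()]).
#' @param level,method Passed to [odds_ratio()].
#' @param adjust Optional multiple-testing adjustment for the Wald p-values
#'   (`"bonferroni"` or `"BH"`); adds a `p_adjusted` column. The default
#'   (`"none"`) mirrors the unadjusted pairwise analysis.
#' @return A data frame of all contrasts (see [pairwise_odds_ratios()]).
#' @export
run_odds_analysis <- function(records, stages = stage_levels(), level = 0.95,
                              method = "wald",
                              adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  out <- list()
  for (stage in stages) {
    cohort <- withCallingHandlers(
      build_cohort(records, stage),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(cohort) == 0L) {
      message("stage '", stage, "': empty cohort, skipped")
      next
    }
    grab <- function(...) {
      tryCatch(suppressWarnings(pairwise_odds_ratios(cohort, ..., level = level,
                                                     method = method)),
               error = function(e) empty_or_table())
    }
    out[[length(out) + 1L]] <- grab("study_area")
    for (area in unique(cohort$study_area)) {
      out[[length(out) + 1L]] <-
        grab("elevation_zone", within = list(study_area = area))
      for (zone in unique(cohort$elevation_zone[cohort$study_area == area]))
        out[[length(out) + 1L]] <-
          grab("microsite", within = list(study_area = area,
                                          elevation_zone = zone))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_or_table()
  if (adjust != "none" && nrow(res))
    res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  res
}
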