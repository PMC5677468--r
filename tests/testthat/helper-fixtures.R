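# Shared fixture builders: tiny in-code cache tables and point patterns.

fixture_path <- function() {
  system.file("extdata", "example_caches.csv", package = "cachescape")
}

# A minimal valid cache table built in code (n caches, all located).
make_mini_table <- function(n = 6L, seed = 42L) {
  set.seed(seed)
  data.frame(
    cache_id = sprintf("m%03d", seq_len(n)),
    study_area = rep_len(c("southern", "northern"), n),
    elevation_zone = rep_len(c("subalpine", "treeline"), n),
    microsite = rep_len(c("rock", "tree", "open"), n),
    x = runif(n, 0, 100), y = runif(n, 0, 100),
    n_seeds_cached = 3L,
    located_y1 = TRUE,
    n_missing_y1 = rep_len(c(0L, 1L, 3L), n),
    n_seed_coats_y1 = 0L,
    n_germinants_y1 = rep_len(c(1L, 1L, 0L), n),
    relocated_y2 = TRUE,
    n_live_seedlings_y2 = rep_len(c(1L, 0L, 0L), n),
    n_new_germinants_y2 = 0L,
    stringsAsFactors = FALSE
  )
}

# One-stratum simulation config, handy for calibration tests.
single_stratum_config <- function(n_caches, p_pilf = 0.5, p_germ = 0.5,
                                  p_surv = 0.5, window = c(300, 300),
                                  clustering = NULL, p_locate = 1) {
  key <- data.frame(study_area = "southern", elevation_zone = "treeline",
                    microsite = "open", stringsAsFactors = FALSE)
  design <- cbind(key, n_caches = n_caches)
  probs <- cbind(key, p_pilferage = p_pilf, p_germination = p_germ,
                 p_survival = p_surv)
  simulation_config(design = design, probabilities = probs, window = window,
                    p_locate = p_locate, clustering = clustering)
}

# Brute-force Ripley's K with no edge correction: the independent oracle.
brute_force_k <- function(x, y, area, r) {
  n <- length(x)
  vapply(r, function(rr) {
    tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= rr)
        tot <- tot + 1
    }
    area * tot / (n * (n - 1))
  }, numeric(1))
}
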