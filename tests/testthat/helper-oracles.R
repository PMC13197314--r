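# Shared helpers: independent oracles and small generated fixtures.

# Global-optimum K-means WCSS by exhaustive enumeration of all k^n label
# assignments (feasible for n <= 8, k <= 3). Independent of stats::kmeans.
brute_force_wcss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 10, k^n <= 1e6)
  labels <- rep(1L, n)
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  for (g in seq_len(nrow(grid))) {
    lab <- grid[g, ]
    w <- 0
    for (cl in unique(lab)) {
      pts <- x[lab == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      w <- w + sum(sweep(pts, 2, ctr)^2)
    }
    if (w < best) best <- w
  }
  best
}

# A zero-noise participant profile (deterministic trial synthesis).
noise_free_profile <- function(archetype, kappa = 0.9) {
  participant_profile(paste0("NF_", archetype), archetype, kappa = kappa,
                      planning_noise_sd = 0, execution_noise_sd_frac = 0)
}

# Memoised small default-noise cohort shared across test files.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(c(2L, 2L, 2L)), seed = 101L)
    }
    cache
  }
})
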