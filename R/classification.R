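# Per-participant correlation signatures and K-means strategy
# classification in Fisher-Z space.

#' Fisher Z transform of a Pearson correlation
#'
#' `Z = 0.5 * [ln(1 + r) - ln(1 - r)]`, the variance-stabilizing transform
#' under which correlations become approximately normal and comparable in
#' Euclidean distance; requires `|r| < 1`.
#'
#' @param r Correlation(s) in (-1, 1).
#' @return Fisher-Z value(s).
#' @examples
#' fisher_z(0.5)
#' @export
fisher_z <- function(r) {
  stopifnot(is.numeric(r))
  if (any(abs(r) >= 1)) stop("fisher_z is defined for |r| < 1")
  0.5 * (log(1 + r) - log(1 - r))
}

#' @rdname fisher_z
#' @param z Fisher-Z value(s).
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Two-tailed critical Pearson correlation
#'
#' The smallest `|r|` significant at level `alpha` for `n` paired
#' observations, from the t transform of the correlation coefficient:
#' `r_crit = t_c / sqrt(t_c^2 + n - 2)` with `t_c` the `1 - alpha/2`
#' quantile of the t distribution on `n - 2` degrees of freedom. For the
#' study's 120 trials per participant this is 0.18 (2 dp), the criterion
#' separating significant from non-significant duration-speed couplings.
#'
#' @param n Number of observations (>= 3).
#' @param alpha Two-sided significance level.
#' @return The critical correlation.
#' @examples
#' critical_r(120, 0.05)
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n < 3) stop("critical_r requires n >= 3")
  stopifnot(alpha > 0, alpha < 1)
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + n - 2)
}

#' Per-participant correlation triplet
#'
#' Pearson correlations between the three performance variables over one
#' participant's trials: `r(D, IS)`, `r(D, A)`, `r(A, IS)`, each with the
#' two-sided p-value from the t transform and a 95% confidence interval via
#' the Fisher-Z back-transform.
#'
#' @param trials Data.frame with columns `A_mm`, `D_s`, `IS_mps` (one row
#'   per trial; >= 3 rows).
#' @param conf_level Confidence level for the intervals.
#' @return One-row data.frame with columns `n`, then for each pair `<pair>`,
#'   `<pair>_p`, `<pair>_lo`, `<pair>_hi` where pair is `r_D_IS`, `r_D_A`,
#'   `r_A_IS`.
#' @export
correlation_triplet <- function(trials, conf_level = 0.95) {
  stopifnot(all(c("A_mm", "D_s", "IS_mps") %in% names(trials)))
  n <- nrow(trials)
  if (n < 3) stop("correlation_triplet requires at least 3 trials")
  pairs <- list(r_D_IS = c("D_s", "IS_mps"),
                r_D_A = c("D_s", "A_mm"),
                r_A_IS = c("A_mm", "IS_mps"))
  out <- list(n = n)
  for (nm in names(pairs)) {
    x <- trials[[pairs[[nm]][1]]]
    y <- trials[[pairs[[nm]][2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("undefined correlation: zero variance in ", paste(pairs[[nm]],
                                                             collapse = " or "))
    }
    r <- stats::cor(x, y)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    zc <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(atanh(r) + c(-1, 1) * zc / sqrt(n - 3))
    out[[nm]] <- r
    out[[paste0(nm, "_p")]] <- p
    out[[paste0(nm, "_lo")]] <- ci[1]
    out[[paste0(nm, "_hi")]] <- ci[2]
  }
  as.data.frame(out)
}

#' Correlation triplets for every participant of a trial table
#'
#' @param trials Trial table with a `participant_id` column.
#' @return Data.frame with one row per participant (ordered as first
#'   encountered), `participant_id` first.
#' @export
cohort_correlations <- function(trials) {
  stopifnot("participant_id" %in% names(trials))
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    tri <- correlation_triplet(trials[trials$participant_id == id, ])
    cbind(data.frame(participant_id = id, stringsAsFactors = FALSE), tri)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a participant's regulation mode from r(D, IS)
#'
#' `r(D, IS) < -r_crit` is a negative duration-speed coupling (faster
#' strikes are shorter), `|r(D, IS)| <= r_crit` is duration invariance, and
#' `r(D, IS) > r_crit` is a positive coupling (faster strikes are longer).
#'
#' @param r_d_is Correlation(s) between strike duration and impact speed.
#' @param r_crit Positive significance criterion (e.g.
#'   `critical_r(120, 0.05)`).
#' @return Factor with levels `negative_coupling`, `invariant`,
#'   `positive_coupling`.
#' @examples
#' assign_mode(c(-0.60, 0.05, 0.44), critical_r(120))
#' @export
assign_mode <- function(r_d_is, r_crit) {
  stopifnot(r_crit > 0)
  factor(ifelse(r_d_is < -r_crit, "negative_coupling",
                ifelse(r_d_is > r_crit, "positive_coupling", "invariant")),
         levels = c("negative_coupling", "invariant", "positive_coupling"))
}

#' K-means clustering of Fisher-Z correlation triplets
#'
#' Hartigan-Wong K-means on the unstandardized Z-space points, best of
#' `n_restarts` random initializations (minimal total within-cluster sum of
#' squares), deterministic for a given seed. The caller's RNG state is left
#' untouched.
#'
#' @param z Numeric matrix, one row per participant, columns
#'   `(z_D_IS, z_D_A, z_A_IS)` (any column count >= 1 is accepted).
#' @param k Number of clusters (`1 <= k < nrow(z)` for a meaningful fit).
#' @param n_restarts Random restarts (default 100).
#' @param seed Integer seed for the restart draws.
#' @return Object of class `cluster_solution`: list with `k`, `assignments`
#'   (integer vector, named by rownames of `z`), `centroids` (k x p),
#'   `wcss_per_cluster`, `total_wcss`, `bss`, `tss`, `bss_over_tss`,
#'   `sizes`, and `labels` (strategy names, only when `k == 3`).
#' @export
kmeans_cluster <- function(z, k, n_restarts = 100L, seed = 1L) {
  z <- as.matrix(z)
  if (k > nrow(z)) stop("k must not exceed the number of points")
  stopifnot(k >= 1, n_restarts >= 1)
  if (k == nrow(z)) {
    # singleton clusters: every point is its own centroid
    ctr <- z
    tss <- sum(sweep(z, 2, colMeans(z))^2)
    km <- list(cluster = seq_len(nrow(z)), centers = ctr,
               withinss = rep(0, k), tot.withinss = 0, betweenss = tss,
               totss = tss, size = rep(1L, k))
  } else {
    km <- with_seed(seed, suppressWarnings(
      stats::kmeans(z, centers = k, nstart = n_restarts, iter.max = 100L,
                    algorithm = "Hartigan-Wong")
    ))
  }
  sol <- structure(list(
    k = k,
    assignments = stats::setNames(km$cluster, rownames(z)),
    centroids = km$centers,
    wcss_per_cluster = km$withinss,
    total_wcss = km$tot.withinss,
    bss = km$betweenss,
    tss = km$totss,
    bss_over_tss = km$betweenss / km$totss,
    sizes = km$size,
    labels = NULL
  ), class = "cluster_solution")
  if (k == 3 && ncol(z) >= 1) sol$labels <- label_clusters(sol)
  sol
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution: k = %d, sizes %s, BSS/TSS = %.3f>\n",
              x$k, paste(x$sizes, collapse = "/"), x$bss_over_tss))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(sprintf("%d=%s", seq_along(x$labels), x$labels),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Label a 3-cluster solution with strategy names
#'
#' The cluster whose centroid has the most negative duration-speed Fisher Z
#' (first column) is the Inverse Duration-Amplitude strategy, the most
#' positive is the Late-Impulse strategy, and the remaining cluster is the
#' Temporal Invariance strategy.
#'
#' @param solution A `cluster_solution` with `k = 3`.
#' @return Character vector of length 3: strategy label per cluster index.
#' @export
label_clusters <- function(solution) {
  if (solution$k != 3) {
    warning("strategy labelling requires k = 3; skipping")
    return(NULL)
  }
  z_dis <- solution$centroids[, 1]
  labels <- rep("temporal_invariance", 3)
  labels[which.min(z_dis)] <- "inverse_duration_amplitude"
  labels[which.max(z_dis)] <- "late_impulse"
  labels
}

#' Elbow profile of explained variance across cluster counts
#'
#' Percentage of total variance explained (100 * BSS/TSS) for `k = 1 ..
#' k_max`, and the marginal gain over `k - 1` — the quantities read off an
#' elbow plot when choosing the cluster count.
#'
#' @inheritParams kmeans_cluster
#' @param k_max Largest cluster count (must be < nrow(z)).
#' @return Data.frame with columns `k`, `pct_explained`, `gain`.
#' @export
elbow_profile <- function(z, k_max, n_restarts = 100L, seed = 1L) {
  z <- as.matrix(z)
  if (k_max >= nrow(z) + 1) stop("k_max must be at most the number of points")
  pct <- vapply(seq_len(k_max), function(k) {
    100 * kmeans_cluster(z, k, n_restarts, seed)$bss_over_tss
  }, numeric(1))
  data.frame(k = seq_len(k_max), pct_explained = pct,
             gain = c(NA_real_, diff(pct)))
}

#' Calinski-Harabasz index of a cluster solution
#'
#' Pseudo-F comparing between-cluster to within-cluster dispersion:
#' `[BSS / (k - 1)] / [WCSS / (n - k)]`, with degrees of freedom
#' `(k - 1, n - k)`.
#'
#' @param solution A `cluster_solution`.
#' @return The index value, with attribute `df = c(k - 1, n - k)`.
#' @export
calinski_harabasz <- function(solution) {
  k <- solution$k
  n <- length(solution$assignments)
  if (k <= 1 || k >= n) stop("Calinski-Harabasz requires 1 < k < n")
  if (solution$total_wcss == 0) stop("undefined: zero within-cluster variance")
  f <- (solution$bss / (k - 1)) / (solution$total_wcss / (n - k))
  attr(f, "df") <- c(k - 1, n - k)
  f
}

#' Full strategy classification of a cohort
#'
#' Convenience wrapper: correlation triplets per participant, Fisher-Z
#' transform, regulation-mode assignment at the `critical_r` criterion, and
#' a k = 3 K-means solution with strategy labels.
#'
#' @param trials Trial table with `participant_id`, `A_mm`, `D_s`, `IS_mps`.
#' @param n_restarts,seed Passed to [kmeans_cluster()].
#' @param alpha Significance level for the mode criterion.
#' @return List with `correlations` (per-participant triplets plus `mode`,
#'   `cluster`, `strategy` columns), `solution` (the `cluster_solution`),
#'   `r_crit`.
#' @export
classify_cohort <- function(trials, n_restarts = 100L, seed = 1L,
                            alpha = 0.05) {
  cors <- cohort_correlations(trials)
  r_crit <- critical_r(cors$n[1], alpha)
  z <- cbind(z_D_IS = fisher_z(cors$r_D_IS),
             z_D_A = fisher_z(cors$r_D_A),
             z_A_IS = fisher_z(cors$r_A_IS))
  rownames(z) <- cors$participant_id
  sol <- kmeans_cluster(z, 3, n_restarts, seed)
  cors$mode <- assign_mode(cors$r_D_IS, r_crit)
  cors$cluster <- unname(sol$assignments)
  cors$strategy <- sol$labels[cors$cluster]
  list(correlations = cors, solution = sol, r_crit = r_crit, z = z)
}
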