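# Slope scaling analysis: per-participant regressions of the performance
# variables on optimal cube speed (the task-demand axis), pooled Z-scoring
# of the slopes, between-cluster ANOVA with effect sizes, and the
# strategy-by-coordination contingency test.

#' Per-participant regression slopes on task demand
#'
#' Ordinary least squares of strike amplitude (mm), strike duration (s),
#' impact speed (m/s) and spatial error (%) on optimal cube speed (m/s),
#' over all of one participant's trials (demand enters as a continuous
#' regressor, one point per trial).
#'
#' @param trials One participant's trial table (columns `optimal_speed_mps`,
#'   `A_mm`, `D_s`, `IS_mps`, `spatial_error_pct`).
#' @return One-row data.frame: `raw_slope_A`, `raw_slope_D`, `raw_slope_IS`,
#'   `raw_slope_err` and the matching intercepts.
#' @export
fit_slopes <- function(trials) {
  x <- trials$optimal_speed_mps
  if (length(unique(x)) < 2) {
    stop("degenerate demand: need >= 2 distinct optimal-speed values")
  }
  vars <- c(raw_slope_A = "A_mm", raw_slope_D = "D_s",
            raw_slope_IS = "IS_mps", raw_slope_err = "spatial_error_pct")
  out <- list()
  for (nm in names(vars)) {
    fit <- stats::lm.fit(cbind(1, x), trials[[vars[[nm]]]])
    out[[nm]] <- fit$coefficients[2]
    out[[sub("raw_slope", "intercept", nm)]] <- fit$coefficients[1]
  }
  as.data.frame(out)
}

#' Slope table for a whole cohort
#'
#' @param trials Trial table with `participant_id` (and optionally
#'   `archetype` / cluster metadata, carried through).
#' @return Data.frame, one row per participant, with any per-participant
#'   constant metadata columns preserved.
#' @export
cohort_slopes <- function(trials) {
  ids <- unique(trials$participant_id)
  meta_cols <- intersect(c("archetype", "coordination_group"), names(trials))
  rows <- lapply(ids, function(id) {
    sub <- trials[trials$participant_id == id, ]
    cbind(data.frame(participant_id = id, stringsAsFactors = FALSE),
          sub[1, meta_cols, drop = FALSE], fit_slopes(sub))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Z-score slope columns across participants
#'
#' Standardizes each raw slope column over the whole analyzed cohort
#' (pooled, sample-SD convention), putting the disparate units of
#' millimetres, seconds and m/s on one scale so the relative scaling
#' magnitudes can be compared between clusters.
#'
#' @param slopes Slope table from [cohort_slopes()].
#' @param columns Raw slope columns to standardize.
#' @return `slopes` with added `z_slope_*` columns.
#' @export
zscore_slopes <- function(slopes,
                          columns = c("raw_slope_A", "raw_slope_D",
                                      "raw_slope_IS")) {
  if (nrow(slopes) < 2) stop("Z-scoring requires >= 2 participants")
  for (cl in columns) {
    s <- stats::sd(slopes[[cl]])
    if (s == 0) stop("zero standard deviation in ", cl)
    slopes[[sub("raw_slope", "z_slope", cl)]] <-
      (slopes[[cl]] - mean(slopes[[cl]])) / s
  }
  slopes
}

# 95% CI for partial eta^2 by inverting the noncentral-F distribution.
partial_eta_sq_ci <- function(f_obs, df1, df2, conf_level = 0.95) {
  alpha <- 1 - conf_level
  ncp_limit <- function(p) {
    if (stats::pf(f_obs, df1, df2, ncp = 0) < p) return(0)
    upper <- 10
    while (stats::pf(f_obs, df1, df2, ncp = upper) > p) upper <- upper * 2
    stats::uniroot(function(nc) stats::pf(f_obs, df1, df2, ncp = nc) - p,
                   c(0, upper), tol = 1e-8)$root
  }
  ncp <- c(ncp_limit(1 - alpha / 2), ncp_limit(alpha / 2))
  ncp / (ncp + df1 + df2 + 1)
}

# 95% CI for Cohen's d by inverting the noncentral-t distribution.
cohens_d_ci <- function(d, n1, n2, conf_level = 0.95) {
  alpha <- 1 - conf_level
  scale <- sqrt(n1 * n2 / (n1 + n2))
  t_obs <- d * scale
  df <- n1 + n2 - 2
  lim <- function(p) {
    lo <- t_obs - 20 - 20 * abs(t_obs)
    hi <- t_obs + 20 + 20 * abs(t_obs)
    # pt() warns about reduced precision deep in the noncentral tails;
    # ~1e-8 accuracy is ample for a CI bound
    suppressWarnings(
      stats::uniroot(function(nc) stats::pt(t_obs, df, ncp = nc) - p,
                     c(lo, hi), tol = 1e-8)$root)
  }
  c(lim(1 - alpha / 2), lim(alpha / 2)) / scale
}

#' One-way between-subjects ANOVA with effect sizes
#'
#' Classical one-way ANOVA of `values` on `groups`, reporting partial
#' eta^2 (`SSB / (SSB + SSW)`) with a 95% CI from noncentral-F inversion,
#' per-group means with t-based 95% CIs, Tukey HSD adjusted p-values for
#' all pairs, and pairwise Cohen's d (pooled SD of the two groups) with
#' noncentral-t CIs.
#'
#' @param values Numeric response (e.g. per-participant slopes).
#' @param groups Grouping factor (e.g. cluster labels).
#' @param conf_level Confidence level.
#' @return Object of class `anova_result`: list with `F`, `df_between`,
#'   `df_within`, `p`, `partial_eta_sq`, `partial_eta_sq_ci`, `group_means`
#'   (data.frame group/n/mean/lo/hi), `tukey` (data.frame with pair,
#'   difference, Tukey-adjusted p), `cohens_d` (data.frame with pair, d,
#'   lo, hi), and the sums of squares `ssb`, `ssw`, `sst`.
#' @export
oneway_anova <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop("need >= 2 groups with >= 2 observations each")
  }
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  ssb <- an$`Sum Sq`[1]
  ssw <- an$`Sum Sq`[2]
  f_obs <- an$`F value`[1]
  df1 <- an$Df[1]
  df2 <- an$Df[2]

  gm <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    se <- stats::sd(v) / sqrt(length(v))
    tc <- stats::qt(1 - (1 - conf_level) / 2, df = length(v) - 1)
    data.frame(group = g, n = length(v), mean = mean(v),
               lo = mean(v) - tc * se, hi = mean(v) + tc * se,
               stringsAsFactors = FALSE)
  }))

  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)

  lev <- levels(groups)
  dl <- list()
  for (i in seq_along(lev)[-length(lev)]) {
    for (j in (i + 1):length(lev)) {
      v1 <- values[groups == lev[i]]
      v2 <- values[groups == lev[j]]
      sp <- sqrt(((length(v1) - 1) * stats::var(v1) +
                    (length(v2) - 1) * stats::var(v2)) /
                   (length(v1) + length(v2) - 2))
      d <- (mean(v1) - mean(v2)) / sp
      ci <- cohens_d_ci(d, length(v1), length(v2), conf_level)
      dl[[length(dl) + 1L]] <- data.frame(
        pair = paste(lev[i], lev[j], sep = "-"), d = d,
        lo = ci[1], hi = ci[2], stringsAsFactors = FALSE)
    }
  }

  structure(list(
    F = f_obs, df_between = df1, df_within = df2,
    p = an$`Pr(>F)`[1],
    partial_eta_sq = ssb / (ssb + ssw),
    partial_eta_sq_ci = partial_eta_sq_ci(f_obs, df1, df2, conf_level),
    group_means = gm, tukey = tukey, cohens_d = do.call(rbind, dl),
    ssb = ssb, ssw = ssw, sst = ssb + ssw
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f [%.3f, %.3f]\n",
              x$df_between, x$df_within, x$F, x$p, x$partial_eta_sq,
              x$partial_eta_sq_ci[1], x$partial_eta_sq_ci[2]))
  invisible(x)
}

#' Chi-square test of independence with Cramer's V
#'
#' Pearson chi-square (no continuity correction) on an r x c contingency
#' table, with `Cramer's V = sqrt(chi^2 / (N * min(r - 1, c - 1)))`.
#'
#' @param counts Matrix of non-negative integer counts with positive
#'   margins.
#' @return List with `chi_sq`, `df`, `p`, `cramers_v`, `observed`,
#'   `expected`.
#' @examples
#' contingency_stats(table2_counts())
#' @export
contingency_stats <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  n <- sum(counts)
  v <- sqrt(unname(ct$statistic) / (n * (min(dim(counts)) - 1)))
  list(chi_sq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, cramers_v = v,
       observed = counts, expected = ct$expected)
}
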