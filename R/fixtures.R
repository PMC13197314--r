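# In-study reference tables shipped with the package.

#' Published per-participant correlation table
#'
#' The 33 retained participants' pairwise Pearson correlations between
#' strike duration, strike amplitude and impact speed, each computed over
#' 120 trials and printed to 2 decimals; rows are ordered by ascending
#' `r_D_IS`. Significance flags are not stored: they are recomputable from
#' [critical_r()] (n = 120).
#'
#' @return Data.frame with columns `participant_id`, `r_D_IS`, `r_D_A`,
#'   `r_A_IS`.
#' @examples
#' head(table1_correlations())
#' @export
table1_correlations <- function() {
  path <- system.file("extdata", "table1_correlations.csv",
                      package = "strikekin", mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c(participant_id = "character"))
  stopifnot(nrow(df) == 33)
  df
}

#' Fisher-Z matrix of the published correlation table
#'
#' @return 33 x 3 numeric matrix (`z_D_IS`, `z_D_A`, `z_A_IS`), rownames =
#'   participant ids; the input to the strategy clustering.
#' @export
table1_fisher_z <- function() {
  df <- table1_correlations()
  z <- cbind(z_D_IS = fisher_z(df$r_D_IS),
             z_D_A = fisher_z(df$r_D_A),
             z_A_IS = fisher_z(df$r_A_IS))
  rownames(z) <- df$participant_id
  z
}

#' Published strategy-by-coordination contingency counts
#'
#' Participant counts cross-classifying the three spatio-temporal strategy
#' clusters with the two upper-limb coordination groups (wrist vs forearm)
#' identified for the same striking task.
#'
#' @return 2 x 3 integer matrix, rows `wrist`/`forearm`, columns the three
#'   strategies.
#' @export
table2_counts <- function() {
  path <- system.file("extdata", "table2_coordination_counts.csv",
                      package = "strikekin", mustWork = TRUE)
  df <- utils::read.csv(path)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$coordination_group
  storage.mode(m) <- "integer"
  m
}
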