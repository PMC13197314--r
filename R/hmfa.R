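# Hierarchical Multiple Factor Analysis.
#
# Mixed blocks (continuous kinematic profiles, one categorical cluster
# block) are each processed with the factorial method appropriate to their
# type (PCA-standardization for continuous blocks, MCA indicator coding for
# categorical ones), balanced by dividing every block by the square root of
# its own first eigenvalue so no block can dominate the compromise, then --
# re-applying the same 1/sqrt(lambda1) standardization at each level of the
# hierarchy bottom-up -- merged into a single global PCA.  No rotation is
# ever applied: the contribution accounting depends on the unrotated
# eigenstructure.
#
# Eigenvalue convention: for a processed block X (columns centered), the
# eigenvalues are those of crossprod(X) / (n - 1); for a standardized
# continuous block this is the correlation-matrix PCA spectrum.

block_lambda1 <- function(mat) {
  ev <- eigen(crossprod(mat) / (nrow(mat) - 1), symmetric = TRUE,
              only.values = TRUE)$values
  max(ev)
}

#' Prepare one HMFA block
#'
#' Continuous blocks are column-centered and unit-scaled, then divided by
#' the square root of the first eigenvalue of their correlation-matrix PCA.
#' Categorical blocks are expanded to a complete disjunctive (indicator)
#' table with MCA-standard column processing — category `j` with relative
#' frequency `p_j` becomes `(indicator - p_j) / sqrt(p_j)` — and divided by
#' the square root of that analysis' first eigenvalue. Either way the
#' prepared block's own first eigenvalue is exactly 1.
#'
#' @param x Numeric matrix/data.frame (continuous) or factor/character
#'   vector (categorical).
#' @param name Block name.
#' @param kind `"continuous"` or `"categorical"` (inferred from `x` when
#'   missing).
#' @return List of class `hmfa_block`: `name`, `kind`, `weighted` (the
#'   processed n x p matrix), `lambda1`, `columns`.
#' @export
prepare_block <- function(x, name, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (is.factor(x) || is.character(x)) "categorical" else "continuous"
  }
  kind <- match.arg(kind, c("continuous", "categorical"))
  if (kind == "continuous") {
    x <- as.matrix(x)
    if (anyNA(x)) stop("block '", name, "' contains missing values")
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant column in block '", name, "': ",
           paste(colnames(x)[sds == 0], collapse = ", "))
    }
    xs <- scale(x)
    attr(xs, "scaled:center") <- attr(xs, "scaled:scale") <- NULL
  } else {
    f <- factor(x)
    if (anyNA(f)) stop("block '", name, "' contains missing values")
    if (nlevels(f) < 2) stop("categorical block '", name,
                             "' needs >= 2 categories")
    ind <- stats::model.matrix(~ f - 1)
    colnames(ind) <- levels(f)
    p <- colMeans(ind)
    xs <- sweep(sweep(ind, 2, p, "-"), 2, sqrt(p), "/")
  }
  l1 <- block_lambda1(xs)
  structure(list(name = name, kind = kind, weighted = xs / sqrt(l1),
                 lambda1 = l1, columns = colnames(xs)),
            class = "hmfa_block")
}

#' Fit a hierarchical multiple factor analysis
#'
#' Concatenates the prepared blocks group by group: within each top-level
#' group the member blocks' weighted tables are joined and the group table
#' is itself divided by the square root of its first eigenvalue (a group
#' with a single block is unchanged, since a prepared block's first
#' eigenvalue is already 1). The groups are then merged and a single global
#' PCA (SVD) yields dimensions, individual coordinates and the contribution
#' decomposition at every level: per column (variable or category), per
#' leaf block, and per top-level group.
#'
#' @param blocks Named list of [prepare_block()] results sharing the same
#'   individuals in the same order.
#' @param hierarchy Named list of character vectors assigning block names to
#'   top-level groups; default: each categorical block is its own group and
#'   all continuous blocks form one `"Kinematics"` group.
#' @param n_dims Number of dimensions to report: by default up to 95%
#'   cumulative inertia, and always at least 4 (when available).
#' @return Object of class `hmfa_result`: `eigenvalues`, `percent_variance`,
#'   `coordinates` (individuals x dims), `column_contrib` (% per column x
#'   dim, with `column_block` / `column_kind` maps), `block_contrib`,
#'   `group_contrib` (% per dim, each summing to 100), `lambda1` per block,
#'   `hierarchy`.
#' @export
hmfa_fit <- function(blocks, hierarchy = NULL, n_dims = NULL) {
  stopifnot(length(blocks) >= 1,
            all(vapply(blocks, inherits, logical(1), "hmfa_block")))
  names(blocks) <- vapply(blocks, `[[`, character(1), "name")
  ns <- vapply(blocks, function(b) nrow(b$weighted), integer(1))
  if (length(unique(ns)) != 1) {
    stop("all blocks must share the same individuals in the same order")
  }
  n <- ns[1]

  if (is.null(hierarchy)) {
    kinds0 <- vapply(blocks, `[[`, character(1), "kind")
    cat_names <- names(blocks)[kinds0 == "categorical"]
    hierarchy <- stats::setNames(as.list(cat_names), cat_names)
    if (any(kinds0 == "continuous")) {
      hierarchy$Kinematics <- names(blocks)[kinds0 == "continuous"]
    }
  }
  if (!setequal(unlist(hierarchy), names(blocks))) {
    stop("hierarchy must reference every block exactly once")
  }

  col_block <- character(0)
  parts <- list()
  for (g in names(hierarchy)) {
    members <- hierarchy[[g]]
    gm <- do.call(cbind, lapply(blocks[members], `[[`, "weighted"))
    l1g <- block_lambda1(gm)
    gm <- gm / sqrt(l1g)
    parts[[g]] <- gm
    col_block <- c(col_block,
                   rep(members, vapply(blocks[members], function(b)
                     ncol(b$weighted), integer(1))))
  }
  G <- do.call(cbind, parts)
  colnames(G) <- make.unique(
    unlist(lapply(names(hierarchy), function(g)
      unlist(lapply(blocks[hierarchy[[g]]], `[[`, "columns")))), sep = "_")

  sv <- svd(G)
  eig <- sv$d^2 / (n - 1)
  keep <- eig > max(eig) * 1e-10
  eig <- eig[keep]
  pct <- 100 * eig / sum(eig)
  if (is.null(n_dims)) {
    n_dims <- max(min(4L, length(eig)),
                  which(cumsum(pct) >= 95)[1])
  }
  n_dims <- min(n_dims, length(eig))
  dims <- seq_len(n_dims)

  coords <- sv$u[, dims, drop = FALSE] %*% diag(sv$d[dims], n_dims)
  rownames(coords) <- rownames(blocks[[1]]$weighted)
  colnames(coords) <- paste0("Dim", dims)

  v2 <- sv$v[, dims, drop = FALSE]^2 * 100
  rownames(v2) <- colnames(G)
  colnames(v2) <- paste0("Dim", dims)

  block_of <- col_block
  kinds <- vapply(blocks, `[[`, character(1), "kind")
  block_contrib <- rowsum(v2, block_of, reorder = FALSE)
  group_of <- rep(names(hierarchy),
                  vapply(hierarchy, function(m) sum(vapply(
                    blocks[m], function(b) ncol(b$weighted), integer(1))),
                    integer(1)))
  group_contrib <- rowsum(v2, group_of, reorder = FALSE)

  structure(list(
    eigenvalues = eig, percent_variance = pct[dims],
    coordinates = coords,
    column_contrib = v2,
    column_block = stats::setNames(block_of, colnames(G)),
    column_kind = stats::setNames(kinds[block_of], colnames(G)),
    block_contrib = block_contrib,
    group_contrib = group_contrib,
    lambda1 = vapply(blocks, `[[`, numeric(1), "lambda1"),
    block_kind = kinds,
    hierarchy = hierarchy
  ), class = "hmfa_result")
}

#' @export
print.hmfa_result <- function(x, ...) {
  cat(sprintf("<hmfa_result: %d individuals, %d dims reported (%.1f%% of inertia)>\n",
              nrow(x$coordinates), ncol(x$coordinates),
              sum(x$percent_variance)))
  cat("  eigenvalues:",
      paste(sprintf("%.3f", x$eigenvalues[seq_len(ncol(x$coordinates))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Categorical vs quantitative contribution shares of one dimension
#'
#' Sums the leaf-block contributions of a fitted HMFA by block kind; the two
#' shares sum to 100%.
#'
#' @param result An `hmfa_result`.
#' @param dimension Dimension index (within the reported range).
#' @return Named numeric vector `c(categorical = , quantitative = )` in %.
#' @export
contribution_split <- function(result, dimension) {
  stopifnot(inherits(result, "hmfa_result"))
  if (dimension < 1 || dimension > ncol(result$coordinates)) {
    stop("dimension out of the computed range")
  }
  contrib <- result$block_contrib[, dimension]
  kind <- result$block_kind[rownames(result$block_contrib)]
  c(categorical = sum(contrib[kind == "categorical"]),
    quantitative = sum(contrib[kind == "continuous"]))
}

#' Participant-level HMFA of a classified cohort
#'
#' Builds the participant-by-condition mean table (12 demand levels per
#' kinematic variable), assembles the four blocks -- the cluster assignment
#' as a categorical block and the A / D / IS condition profiles as three
#' continuous blocks grouped under one kinematics node -- and fits the HMFA.
#'
#' @param trials Extracted or ground-truth trial table (`participant_id`,
#'   `demand_rank`, `A_mm`, `D_s`, `IS_mps`).
#' @param cluster Factor of cluster/strategy assignments, one per
#'   participant in the order of `unique(trials$participant_id)`.
#' @param ... Passed to [hmfa_fit()].
#' @return An `hmfa_result`.
#' @export
hmfa_cohort <- function(trials, cluster, ...) {
  ids <- unique(trials$participant_id)
  stopifnot(length(cluster) == length(ids))
  ranks <- sort(unique(trials$demand_rank))
  wide <- function(var) {
    m <- t(vapply(ids, function(id) {
      sub <- trials[trials$participant_id == id, ]
      vapply(ranks, function(r)
        mean(sub[[var]][sub$demand_rank == r]), numeric(1))
    }, numeric(length(ranks))))
    colnames(m) <- sprintf("%s_cond%02d", sub("_.*", "", var), ranks)
    rownames(m) <- ids
    m
  }
  blocks <- list(
    prepare_block(factor(cluster), "Cluster"),
    prepare_block(wide("A_mm"), "A"),
    prepare_block(wide("D_s"), "D"),
    prepare_block(wide("IS_mps"), "IS")
  )
  hmfa_fit(blocks,
           hierarchy = list(Cluster = "Cluster",
                            Kinematics = c("A", "D", "IS")), ...)
}
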