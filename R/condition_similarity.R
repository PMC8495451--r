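#' K-nearest neighbors by Euclidean distance
#'
#' Self is excluded; ties are broken by cell index (deterministic, duplicate
#' points allowed).
#'
#' @param embedding Cells x dims numeric matrix.
#' @param k Number of neighbors (`0 < k < n`).
#' @return List of integer neighbor index vectors, one per cell.
#' @export
knn_neighbors <- function(embedding, k) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k < 1L || k >= n) stop("'k' must satisfy 1 <= k < n_cells",
                             call. = FALSE)
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  unname(apply(d, 1L, function(r) order(r, seq_along(r))[seq_len(k)],
               simplify = FALSE))
}

#' Shared-neighbor similarity between conditions
#'
#' The similarity between two conditions is the average fraction of a cell's
#' k nearest neighbors (in the pooled graph over all cells in the dataset)
#' that carry the other condition's label, symmetrized by averaging the two
#' directions; the diagonal holds the within-condition neighbor fraction.
#' This neighbor-composition reading handles unequal condition sizes; a
#' neighborhood-set `"jaccard"` alternative is provided.
#'
#' @param neighbors Neighbor list from [knn_neighbors()] (pooled over all
#'   conditions), or an embedding matrix in which case `k` must be given.
#' @param condition_labels Condition label per cell.
#' @param metric `"composition"` (default) or `"jaccard"` (Jaccard index of
#'   the unions of the two conditions' neighborhoods).
#' @param k Neighbors, used only when `neighbors` is an embedding.
#' @return A symmetric condition x condition matrix in \[0, 1\] (class
#'   `condition_similarity`), with attributes `k` and `n_cells`. The
#'   pre-symmetrization row-stochastic matrix is in
#'   `attr(, "unsymmetrized")`.
#' @export
condition_similarity <- function(neighbors, condition_labels,
                                 metric = c("composition", "jaccard"),
                                 k = NULL) {
  metric <- match.arg(metric)
  if (is.matrix(neighbors) || is.data.frame(neighbors)) {
    if (is.null(k)) stop("'k' is required when passing an embedding",
                         call. = FALSE)
    neighbors <- knn_neighbors(neighbors, k)
  }
  lab <- as.character(condition_labels)
  stopifnot(length(lab) == length(neighbors))
  if (is.factor(condition_labels)) {
    unused <- setdiff(levels(condition_labels), lab)
    if (length(unused))
      warning("dropping condition(s) with 0 cells: ",
              paste(unused, collapse = ", "))
  }
  conds <- unique(lab)
  n_per <- table(lab)[conds]
  S <- matrix(0, length(conds), length(conds),
              dimnames = list(conds, conds))
  if (metric == "composition") {
    U <- S
    for (a in conds) {
      cells <- which(lab == a)
      fr <- sapply(conds, function(b) {
        mean(vapply(neighbors[cells],
                    function(nb) mean(lab[nb] == b), numeric(1)))
      })
      U[a, ] <- fr
    }
    S <- (U + t(U)) / 2
    diag(S) <- diag(U)
    attr_u <- U
  } else {
    for (ai in seq_along(conds)) for (bi in seq_len(ai)) {
      na <- unique(unlist(neighbors[lab == conds[ai]], use.names = FALSE))
      nb <- unique(unlist(neighbors[lab == conds[bi]], use.names = FALSE))
      S[ai, bi] <- S[bi, ai] <- length(intersect(na, nb)) /
        length(union(na, nb))
    }
    attr_u <- S
  }
  structure(S, class = c("condition_similarity", "matrix"),
            unsymmetrized = attr_u, k = length(neighbors[[1L]]),
            n_cells = as.integer(n_per), metric = metric)
}

#' Hierarchically cluster conditions on a similarity matrix
#'
#' Average-linkage agglomeration on the distance `1 - S`; merge heights are
#' non-decreasing.
#'
#' @param S Symmetric condition similarity matrix (>= 2 conditions).
#' @return An `hclust` object.
#' @export
cluster_conditions <- function(S) {
  S <- unclass(S)
  attributes(S)[setdiff(names(attributes(S)), c("dim", "dimnames"))] <- NULL
  if (nrow(S) < 2L) stop("at least 2 conditions are required", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8)
    stop("similarity matrix must be symmetric", call. = FALSE)
  D <- 1 - S
  diag(D) <- 0
  stats::hclust(stats::as.dist(D), method = "average")
}
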