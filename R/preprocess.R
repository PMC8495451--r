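#' Cell filter configuration
#'
#' Defaults follow the organoid analysis settings: cells are kept when the
#' number of detected genes lies in \[2000, 5000\] and the mitochondrial read
#' fraction in \[0.075, 0.2\] (both closed intervals; the mitochondrial range
#' is a fraction, matching the printed decimals).
#'
#' @param min_genes,max_genes Detected-gene range (closed).
#' @param min_mito_frac,max_mito_frac Mitochondrial count fraction range
#'   (closed).
#' @return A `cell_filter_config` list.
#' @export
cell_filter_config <- function(min_genes = 2000, max_genes = 5000,
                               min_mito_frac = 0.075, max_mito_frac = 0.2) {
  if (min_genes >= max_genes || min_mito_frac >= max_mito_frac)
    stop("filter ranges must satisfy min < max", call. = FALSE)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_mito_frac = min_mito_frac, max_mito_frac = max_mito_frac),
            class = "cell_filter_config")
}

#' Filter cells by detected genes and mitochondrial fraction
#'
#' Both predicates are evaluated on the `total` layer. The gene set is left
#' unchanged; filtering is idempotent.
#'
#' @param x A [layered_counts()] object.
#' @param mito_genes Character vector of mitochondrial gene identifiers
#'   (subset of the gene list; may be empty, in which case the mitochondrial
#'   fraction is 0 for every cell).
#' @param cfg A [cell_filter_config()].
#' @return The filtered [layered_counts()] object.
#' @export
filter_cells <- function(x, mito_genes = character(),
                         cfg = cell_filter_config()) {
  stopifnot(inherits(x, "layered_counts"), inherits(cfg, "cell_filter_config"))
  if (length(setdiff(mito_genes, x$genes)))
    stop("'mito_genes' must be a subset of the gene list", call. = FALSE)
  tot <- x$layers$total
  n_detected <- Matrix::colSums(tot > 0)
  depth <- Matrix::colSums(tot)
  mito <- if (length(mito_genes))
    Matrix::colSums(tot[mito_genes, , drop = FALSE]) else rep(0, ncol(tot))
  frac <- ifelse(depth > 0, mito / depth, 0)
  keep <- n_detected >= cfg$min_genes & n_detected <= cfg$max_genes &
    frac >= cfg$min_mito_frac & frac <= cfg$max_mito_frac
  if (!any(keep)) warning("cell filter removed all cells")
  layered_counts(x$layers$nascent[, keep, drop = FALSE],
                 x$layers$old[, keep, drop = FALSE])
}

#' Depth-normalize and log1p-transform a count matrix
#'
#' Each cell (column) is scaled to `target_sum` total counts (default: the
#' median column sum), then transformed with `log1p`.
#'
#' @param m Gene x cell matrix (sparse or dense), or a [layered_counts()]
#'   object whose `total` layer is used.
#' @param target_sum Target per-cell sum; `NULL` uses the median column sum.
#' @return A sparse real matrix of normalized log expression.
#' @export
normalize_log <- function(m, target_sum = NULL) {
  if (inherits(m, "layered_counts")) m <- m$layers$total
  m <- methods::as(m, "CsparseMatrix")
  cs <- Matrix::colSums(m)
  if (any(cs == 0))
    stop("zero-sum column(s): ",
         paste(head(colnames(m)[cs == 0], 5L), collapse = ", "), call. = FALSE)
  if (is.null(target_sum)) target_sum <- stats::median(cs)
  sf <- target_sum / cs
  out <- m %*% Matrix::Diagonal(x = sf)
  dimnames(out) <- dimnames(m)
  out@x <- log1p(out@x)
  out
}

#' Select highly variable genes by normalized dispersion
#'
#' Seurat-flavour dispersion: per gene, mean and dispersion (variance / mean)
#' of `expm1(normalized)` values; dispersions are z-scored within 20
#' equal-count mean bins and genes ranked by the normalized dispersion,
#' ties broken by gene identifier.
#'
#' @param norm Normalized log matrix from [normalize_log()].
#' @param n Number of genes to return (default 2000, the study's HVG count).
#' @param n_bins Number of mean bins for dispersion normalization.
#' @return Character vector of the top `n` gene identifiers, ranked.
#' @export
select_hvg <- function(norm, n = 2000L, n_bins = 20L) {
  if (n <= 0) stop("'n' must be positive", call. = FALSE)
  n <- min(as.integer(n), nrow(norm))
  x <- expm1(as.matrix(norm))
  mu <- rowMeans(x)
  v <- apply(x, 1L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(br) < 2L) factor(rep("all", length(mu)))
  else cut(mu, breaks = br, include.lowest = TRUE)
  z <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, rownames(norm))
  rownames(norm)[ord][seq_len(n)]
}

#' Score a gene set against expression-matched controls
#'
#' Module score in the style of Seurat's `AddModuleScore`: the per-cell mean
#' expression of the set genes minus the mean over control genes drawn, per
#' set gene, from the same average-expression bin.
#'
#' @param norm Normalized log matrix (genes x cells).
#' @param gene_set Character vector; at least one gene must be present.
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_ctrl Controls drawn per set gene (default 100, with replacement
#'   if the bin is smaller).
#' @param seed Integer seed making the control draw deterministic.
#' @return Named numeric vector of per-cell scores (class `signature_score`
#'   with the control genes in `attr(, "controls")`).
#' @export
score_gene_set <- function(norm, gene_set, n_bins = 25L, n_ctrl = 100L,
                           seed = 0L) {
  present <- intersect(gene_set, rownames(norm))
  if (!length(present))
    stop("no gene of the set is present in the matrix", call. = FALSE)
  mu <- Matrix::rowMeans(norm)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(br) < 2L) rep(1L, length(mu))
  else as.integer(cut(mu, breaks = br, include.lowest = TRUE))
  names(bin) <- rownames(norm)
  ctrl <- with_local_seed(seed, {
    unlist(lapply(sort(present), function(g) {
      pool <- rownames(norm)[bin == bin[g]]
      sample(pool, min(n_ctrl, length(pool)), replace = n_ctrl > length(pool))
    }), use.names = FALSE)
  })
  score <- Matrix::colMeans(norm[present, , drop = FALSE]) -
    Matrix::colMeans(norm[ctrl, , drop = FALSE])
  structure(stats::setNames(as.numeric(score), colnames(norm)),
            controls = ctrl, class = "signature_score")
}

#' Regress the cell-cycle covariate out of every gene
#'
#' The covariate is the difference between the S-phase and G2/M module
#' scores; each gene is replaced by the residuals of its least-squares fit on
#' the covariate plus the gene's mean, so per-gene means are preserved.
#'
#' @param norm Normalized log matrix (genes x cells).
#' @param s_genes,g2m_genes Cell-cycle gene sets (scoreable via
#'   [score_gene_set()]).
#' @param seed Seed forwarded to the two scoring calls.
#' @return Matrix of the same shape with the covariate regressed out. A
#'   zero-variance covariate returns the input unchanged with a warning.
#' @export
regress_out_cell_cycle <- function(norm, s_genes, g2m_genes, seed = 0L) {
  s <- score_gene_set(norm, s_genes, seed = seed)
  g2m <- score_gene_set(norm, g2m_genes, seed = seed + 1L)
  x <- as.numeric(s) - as.numeric(g2m)
  if (stats::var(x) == 0) {
    warning("cell-cycle covariate has zero variance; matrix unchanged")
    return(norm)
  }
  m <- as.matrix(norm)
  xc <- x - mean(x)
  slope <- (m %*% xc) / sum(xc^2)
  m - slope %*% matrix(xc, nrow = 1L)
}

#' KNN-smoothed first-order moments per condition
#'
#' Within each condition: PCA (centered, unscaled) of the normalized total
#' layer, a symmetric k-nearest-neighbor graph in PC space (Euclidean), and
#' per-layer smoothing by the unweighted mean over each cell and its
#' neighbors. Conditions are processed independently so no smoothing leaks
#' across condition boundaries (30 components and 30 neighbors by default,
#' the study's settings).
#'
#' @param x A [layered_counts()] object.
#' @param condition_labels Factor/character per cell; `NULL` treats the whole
#'   dataset as one condition.
#' @param n_pcs Number of principal components (capped by the data rank).
#' @param k Neighbors per cell; `k = 0` returns the raw layers.
#' @param layers Which layers to smooth.
#' @return List per condition, each with `moments` (named list of gene x cell
#'   matrices), `neighbors` (list of neighbor index vectors) and `cells`.
#' @export
compute_moments <- function(x, condition_labels = NULL, n_pcs = 30L, k = 30L,
                            layers = c("nascent", "old")) {
  stopifnot(inherits(x, "layered_counts"))
  cl <- if (is.null(condition_labels))
    rep("all", length(x$cells)) else as.character(condition_labels)
  stopifnot(length(cl) == length(x$cells))
  out <- list()
  for (cond in unique(cl)) {
    idx <- which(cl == cond)
    if (k > 0 && length(idx) <= k)
      stop(sprintf("condition '%s' has %d cells but k = %d neighbors requested",
                   cond, length(idx), k), call. = FALSE)
    nb <- vector("list", length(idx))
    if (k > 0) {
      norm <- normalize_log(x$layers$total[, idx, drop = FALSE])
      np <- min(n_pcs, length(idx) - 1L, nrow(norm))
      pc <- stats::prcomp(as.matrix(Matrix::t(norm)), center = TRUE,
                          scale. = FALSE, rank. = np)$x
      d2 <- as.matrix(stats::dist(pc))
      diag(d2) <- Inf
      nn <- apply(d2, 1L, function(r) order(r, seq_along(r))[seq_len(k)],
                  simplify = FALSE)
      # symmetrize: union of directed KNN edges
      adj <- matrix(FALSE, length(idx), length(idx))
      for (i in seq_along(nn)) adj[i, nn[[i]]] <- TRUE
      adj <- adj | t(adj)
      nb <- apply(adj, 1L, which, simplify = FALSE)
    }
    mom <- lapply(layers, function(ly) {
      m <- as.matrix(x$layers[[ly]][, idx, drop = FALSE])
      if (k == 0) return(m)
      sm <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
      for (i in seq_len(ncol(m))) {
        cols <- c(i, nb[[i]])
        sm[, i] <- rowMeans(m[, cols, drop = FALSE])
      }
      sm
    })
    names(mom) <- layers
    out[[cond]] <- list(moments = mom, neighbors = nb, cells = x$cells[idx])
  }
  out
}
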