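#' Genomically smoothed, reference-centered expression profiles
#'
#' A deliberately simplified substrate for the clone-wise SCNA score (not a
#' full inferCNV re-implementation): genes are ordered along the genome,
#' centered per gene by the mean over reference cells, smoothed by a centered
#' moving average of `window` genes within each chromosome (truncated at the
#' chromosome ends, never crossing boundaries), and clipped.
#'
#' @param expr Gene x cell expression matrix (log scale).
#' @param coords Gene coordinate table (`gene_id`, `chrom`, `start`; 0-based).
#'   Chromosome order follows first appearance unless `natural_sort = TRUE`.
#' @param reference_cells Barcodes (or column indices) of reference (normal)
#'   cells used for centering; at least one required.
#' @param window Odd moving-average window in genes (default 101).
#' @param clip Symmetric clipping bound applied after smoothing (default 3).
#' @param natural_sort Order chromosomes naturally instead of by first
#'   appearance.
#' @return An object of class `smoothed_profiles`: list with `profiles`
#'   (gene x cell matrix in genomic order), `coords` (ordered), `window`,
#'   `reference_cells`, and `dropped` (genes without coordinates).
#' @export
smooth_genomic_expression <- function(expr, coords, reference_cells,
                                      window = 101L, clip = 3,
                                      natural_sort = FALSE) {
  if (window %% 2L == 0L) stop("'window' must be odd", call. = FALSE)
  co <- data.table::as.data.table(coords)
  if (is.numeric(reference_cells))
    reference_cells <- colnames(expr)[reference_cells]
  if (!length(reference_cells) ||
      length(setdiff(reference_cells, colnames(expr))))
    stop("at least one valid reference cell is required", call. = FALSE)
  dropped <- setdiff(rownames(expr), co$gene_id)
  co <- co[gene_id %in% rownames(expr)]
  chrom_order <- if (natural_sort)
    unique(co$chrom)[order(as.numeric(gsub("\\D", "", unique(co$chrom))),
                           unique(co$chrom))]
  else unique(co$chrom)
  co[, chrom := factor(chrom, levels = chrom_order)]
  data.table::setorder(co, chrom, start)
  m <- as.matrix(expr)[co$gene_id, , drop = FALSE]

  ref_mean <- rowMeans(m[, reference_cells, drop = FALSE])
  m <- m - ref_mean

  half <- (window - 1L) %/% 2L
  sm <- m
  for (ch in chrom_order) {
    i <- which(co$chrom == ch)
    n <- length(i)
    # banded averaging operator: exact locality (a perturbed gene can only
    # affect smoothed values within half a window on its own chromosome)
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    len <- hi - lo + 1L
    W <- Matrix::sparseMatrix(
      i = rep(seq_len(n), len),
      j = unlist(lapply(seq_len(n), function(r) lo[r]:hi[r])),
      x = rep(1 / len, len), dims = c(n, n))
    sm[i, ] <- as.matrix(W %*% m[i, , drop = FALSE])
  }
  sm[sm > clip] <- clip
  sm[sm < -clip] <- -clip
  structure(list(profiles = sm, coords = co[], window = as.integer(window),
                 reference_cells = reference_cells, dropped = dropped),
            class = "smoothed_profiles")
}

#' @export
print.smoothed_profiles <- function(x, ...) {
  cat(sprintf("smoothed_profiles: %d genes x %d cells (window %d, %d reference cells)\n",
              nrow(x$profiles), ncol(x$profiles), x$window,
              length(x$reference_cells)))
  invisible(x)
}

#' Cut cells into clones by hierarchical clustering of genomic profiles
#'
#' Ward-linkage hierarchical clustering (Euclidean on cell profiles), cut
#' into exactly `k` groups; the study cut copy-number dendrograms at k = 2.
#'
#' @param profiles A [smooth_genomic_expression()] result or a gene x cell
#'   matrix.
#' @param k Number of clones (default 2; must not exceed the cell count).
#' @return List with `assignment` (named integer clone per cell), `tree`
#'   (the `hclust` object) and `degenerate` (all cells identical).
#' @export
cluster_clones <- function(profiles, k = 2L) {
  m <- if (inherits(profiles, "smoothed_profiles")) profiles$profiles
  else as.matrix(profiles)
  n <- ncol(m)
  if (n < 2L) stop("at least 2 cells are required", call. = FALSE)
  if (k > n) stop("'k' must not exceed the number of cells", call. = FALSE)
  d <- stats::dist(t(m))
  degenerate <- max(d) == 0
  if (degenerate) warning("all cell profiles identical; clone cut is degenerate")
  tree <- stats::hclust(d, method = "ward.D2")
  assignment <- stats::cutree(tree, k = k)
  names(assignment) <- colnames(m)
  list(assignment = assignment, tree = tree, degenerate = degenerate)
}

#' Clone-wise SCNA score
#'
#' For each clone, the mean over its cells of the per-cell standard deviation
#' across genomic positions, divided by the same per-cell SD averaged over
#' all normal-sample cells pooled. A clone drawn from the reference
#' distribution scores 1 in expectation; segmental gains or losses add
#' between-position variance and push the score above 1.
#'
#' @param profiles Smoothed profile matrix (gene x cell) or a
#'   [smooth_genomic_expression()] result covering the clone cells.
#' @param clone_assignment Named clone label per profile cell.
#' @param normal_profiles Gene x cell matrix of all normal-sample cells
#'   pooled (non-empty).
#' @return `data.table` with `clone`, `n_cells`, `score`.
#' @export
scna_score <- function(profiles, clone_assignment, normal_profiles) {
  m <- if (inherits(profiles, "smoothed_profiles")) profiles$profiles
  else as.matrix(profiles)
  normal_profiles <- as.matrix(normal_profiles)
  if (!ncol(normal_profiles)) stop("normal profiles are empty", call. = FALSE)
  denom <- mean(apply(normal_profiles, 2L, stats::sd))
  if (denom == 0)
    stop("zero variance in normal profiles; SCNA score undefined",
         call. = FALSE)
  cell_sd <- apply(m, 2L, stats::sd)
  lab <- as.character(clone_assignment)
  res <- lapply(unique(lab), function(cl) {
    i <- which(lab == cl)
    if (!length(i)) {
      warning(sprintf("clone '%s' has no cells; skipped", cl))
      return(NULL)
    }
    data.table::data.table(clone = cl, n_cells = length(i),
                           score = mean(cell_sd[i]) / denom)
  })
  data.table::rbindlist(res)[]
}

#' Call clones copy-number aberrant
#'
#' A clone is aberrant iff its SCNA score is strictly greater than the
#' highest score observed for normal samples.
#'
#' @param scores Numeric clone scores (optionally named).
#' @param normal_scores Scores of the normal samples (>= 1 value).
#' @return Named logical vector.
#' @export
call_aberrant <- function(scores, normal_scores) {
  if (!length(normal_scores)) stop("at least one normal score is required",
                                   call. = FALSE)
  stats::setNames(as.numeric(scores) > max(as.numeric(normal_scores)),
                  names(scores))
}

#' Hypergeometric enrichment of deregulated genes in a CNA region
#'
#' Upper-tail hypergeometric probability of the observed overlap between the
#' deregulated gene set and the genes of a genomic region, Bonferroni
#' multiplied by `n_tests` and capped at 1 (the study tested chromosome
#' arms).
#'
#' @param deregulated_genes,region_genes Gene sets (subsets of `universe`).
#' @param universe Background gene identifiers (non-empty).
#' @param n_tests Number of tests for the Bonferroni factor (default 1).
#' @return List with `overlap`, `p_raw`, `p_adjusted`.
#' @export
cna_region_enrichment <- function(deregulated_genes, region_genes, universe,
                                  n_tests = 1L) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  deregulated_genes <- unique(deregulated_genes)
  region_genes <- unique(region_genes)
  if (length(setdiff(deregulated_genes, universe)) ||
      length(setdiff(region_genes, universe)))
    stop("gene sets must be subsets of the universe", call. = FALSE)
  k <- length(intersect(deregulated_genes, region_genes))
  p <- stats::phyper(k - 1L, length(region_genes),
                     length(universe) - length(region_genes),
                     length(deregulated_genes), lower.tail = FALSE)
  list(overlap = k, p_raw = p, p_adjusted = min(1, p * n_tests))
}
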