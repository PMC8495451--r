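#' Configuration for the clonal copy-number expression simulator
#'
#' Generates genomically ordered (log-scale, reference-centered) expression for
#' normal cells and one or more clones carrying segmental gains or losses,
#' the substrate for genomic smoothing and clone-wise SCNA scoring.
#'
#' @param n_genes Total number of genes, split evenly across chromosomes.
#' @param n_chromosomes Number of chromosomes (>= 2).
#' @param n_normal_cells Number of reference (normal) cells.
#' @param clones List of clones; each clone is a list with `n_cells` and
#'   `segments`, a `data.frame` with columns `chrom` (e.g. `"chr1"`),
#'   `start`, `end` (1-based inclusive gene indices within that chromosome)
#'   and `shift` (log2 expression shift added on the segment). A shift of 0
#'   makes the clone indistinguishable from normal in expectation. Segments of
#'   one clone must not overlap.
#' @param noise_sd Within-cell gaussian noise standard deviation.
#' @param seed Integer RNG seed.
#' @return A `clone_sim_config` list.
#' @export
clone_sim_config <- function(n_genes = 600L, n_chromosomes = 3L,
                             n_normal_cells = 100L,
                             clones = list(list(
                               n_cells = 60L,
                               segments = data.frame(chrom = "chr1", start = 1L,
                                                     end = 120L, shift = 0.8))),
                             noise_sd = 0.15, seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(n_chromosomes, "n_chromosomes", min = 2L)
  assert_count(n_normal_cells, "n_normal_cells")
  assert_pos(noise_sd, "noise_sd")
  per_chrom <- n_genes %/% n_chromosomes
  for (ci in seq_along(clones)) {
    cl <- clones[[ci]]
    clones[[ci]]$n_cells <- assert_count(cl$n_cells,
                                         sprintf("clones[[%d]]$n_cells", ci))
    seg <- cl$segments
    if (nrow(seg)) {
      if (any(seg$start < 1L) || any(seg$end < seg$start))
        stop("segment gene indices must satisfy 1 <= start <= end",
             call. = FALSE)
      if (any(seg$end > per_chrom))
        stop(sprintf("segment exceeds the %d genes available per chromosome",
                     per_chrom), call. = FALSE)
      for (ch in unique(seg$chrom)) {
        s <- seg[seg$chrom == ch, , drop = FALSE]
        s <- s[order(s$start), , drop = FALSE]
        if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
          stop(sprintf("overlapping segments on %s in clone %d", ch, ci),
               call. = FALSE)
      }
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_normal_cells = as.integer(n_normal_cells),
                 clones = clones, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "clone_sim_config")
}

#' Simulate genomically ordered clone expression with a normal reference
#'
#' Normal cells are zero-mean noise around a flat baseline; clone cells carry
#' the configured segment shifts before noise.
#'
#' @param cfg A [clone_sim_config()].
#' @return A list of class `clone_sim` with `expr` (gene x cell matrix),
#'   `coords` (gene coordinate `data.table`: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`), `labels` (per-cell clone label, `"normal"` for
#'   reference cells) and `normal` (logical flag per cell).
#' @export
simulate_clone_expression <- function(cfg) {
  stopifnot(inherits(cfg, "clone_sim_config"))
  with_local_seed(cfg$seed, {
    per_chrom <- cfg$n_genes %/% cfg$n_chromosomes
    G <- per_chrom * cfg$n_chromosomes
    chrom <- rep(sprintf("chr%d", seq_len(cfg$n_chromosomes)), each = per_chrom)
    idx_in_chrom <- rep(seq_len(per_chrom), cfg$n_chromosomes)
    gene_id <- sprintf("G%04d", seq_len(G))
    coords <- data.table::data.table(
      gene_id = gene_id, chrom = chrom,
      start = (idx_in_chrom - 1L) * 1000L, end = (idx_in_chrom - 1L) * 1000L + 500L,
      strand = "+")

    n_clone_cells <- vapply(cfg$clones, function(cl) cl$n_cells, integer(1))
    C <- cfg$n_normal_cells + sum(n_clone_cells)
    labels <- c(rep("normal", cfg$n_normal_cells),
                rep(sprintf("clone%d", seq_along(cfg$clones)), n_clone_cells))
    barcode <- sprintf("BC%04d", seq_len(C))

    mu <- matrix(0, G, C, dimnames = list(gene_id, barcode))
    offset <- cfg$n_normal_cells
    for (ci in seq_along(cfg$clones)) {
      cl <- cfg$clones[[ci]]
      cells <- offset + seq_len(cl$n_cells)
      seg <- cl$segments
      for (r in seq_len(nrow(seg)))
        mu[chrom == seg$chrom[r] &
             idx_in_chrom >= seg$start[r] & idx_in_chrom <= seg$end[r],
           cells] <- seg$shift[r]
      offset <- offset + cl$n_cells
    }
    expr <- mu + matrix(rnorm(G * C, sd = cfg$noise_sd), G, C)
    dimnames(expr) <- list(gene_id, barcode)
    structure(list(expr = expr, coords = coords,
                   labels = stats::setNames(labels, barcode),
                   normal = stats::setNames(labels == "normal", barcode),
                   config = cfg), class = "clone_sim")
  })
}

#' Simulate a multi-condition dataset in a low-dimensional embedding
#'
#' Condition `c` is an isotropic unit-variance gaussian centered at
#' `separation * e_c` (the c-th standard basis vector), so `separation = 0`
#' makes all conditions exchangeable while large separations fully isolate
#' them.
#'
#' @param n_conditions Number of conditions (>= 2).
#' @param n_cells_per_condition Cells per condition (recycled).
#' @param separation Non-negative center distance from the origin.
#' @param dim Embedding dimensionality (>= 1; must be >= `n_conditions` when
#'   `separation > 0`).
#' @param seed Integer RNG seed.
#' @return List with `embedding` (cells x dim matrix) and `labels`
#'   (condition factor per cell).
#' @export
simulate_condition_dataset <- function(n_conditions = 2L,
                                       n_cells_per_condition = 200L,
                                       separation = 0, dim = 2L, seed = 1L) {
  assert_count(n_conditions, "n_conditions", min = 2L)
  assert_count(dim, "dim")
  if (separation < 0) stop("'separation' must be >= 0", call. = FALSE)
  if (separation > 0 && dim < n_conditions)
    stop("'dim' must be >= 'n_conditions' when separation > 0", call. = FALSE)
  n <- rep_len(as.integer(n_cells_per_condition), n_conditions)
  with_local_seed(seed, {
    total <- sum(n)
    lab <- rep(sprintf("cond%d", seq_len(n_conditions)), n)
    centers <- matrix(0, n_conditions, dim)
    if (separation > 0)
      centers[cbind(seq_len(n_conditions), seq_len(n_conditions))] <- separation
    emb <- centers[rep(seq_len(n_conditions), n), , drop = FALSE] +
      matrix(rnorm(total * dim), total, dim)
    rownames(emb) <- sprintf("BC%04d", seq_len(total))
    list(embedding = emb, labels = stats::setNames(factor(lab), rownames(emb)))
  })
}
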