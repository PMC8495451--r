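#' Configuration for the scSLAM-seq read simulator
#'
#' Describes a 10x-style experiment in which a fraction of mRNA molecules is
#' metabolically labeled during a 4sU window (the study design used 200 uM
#' 4-thio-uridine for 2 h); labeled molecules carry T-to-C conversions at a
#' per-uridine rate, and all reads additionally acquire sequencing errors.
#'
#' Every gene carries `K = round(mean_T_per_read / read_coverage)` uridine
#' (reference T) positions in a gene-local 0-based coordinate frame; each read
#' covers a contiguous window of `round(read_coverage * K)` of them, so reads
#' of one molecule overlap only partially and discordant evidence can arise
#' when `error_rate > 0`. With `read_coverage = 1` every read covers all of a
#' molecule's T positions, which makes closed-form sensitivity calculations
#' exact.
#'
#' @param n_genes,n_cells Number of genes / cell barcodes (>= 1).
#' @param mean_molecules_per_cell Poisson mean of captured molecules per cell.
#' @param mean_reads_per_molecule Mean reads per molecule (>= 1; the per-
#'   molecule read count is `1 + Poisson(mean - 1)`).
#' @param labeled_fraction Probability `f` that a molecule is nascent
#'   (4sU-labeled). Default 0.25, a realistic new/total RNA ratio for a 2 h
#'   labeling window given typical mRNA half-lives.
#' @param conversion_rate Per-T conversion probability `p_c` on labeled
#'   molecules. Default 0.02 (typical iodoacetamide SLAM chemistry).
#' @param error_rate Per covered base sequencing error probability `p_e`
#'   (default 1e-3). Errors at T positions produce C with probability 1/3.
#' @param mean_T_per_read Expected number of covered T positions per read.
#' @param snp_density Per-base probability of a common SNP within a gene.
#'   SNPs at T positions are heterozygous T>C in half the molecules, creating
#'   false conversions that SNP masking must remove.
#' @param read_coverage Fraction of a molecule's T positions covered by each
#'   read (in (0, 1], default 0.8).
#' @param seed Integer RNG seed; identical seed and config give bit-identical
#'   output.
#' @return A `read_sim_config` list.
#' @export
read_sim_config <- function(n_genes = 50L, n_cells = 20L,
                            mean_molecules_per_cell = 100,
                            mean_reads_per_molecule = 2,
                            labeled_fraction = 0.25,
                            conversion_rate = 0.02,
                            error_rate = 1e-3,
                            mean_T_per_read = 20,
                            snp_density = 1e-3,
                            read_coverage = 0.8,
                            seed = 1L) {
  assert_count(n_genes, "n_genes"); assert_count(n_cells, "n_cells")
  assert_pos(mean_molecules_per_cell, "mean_molecules_per_cell")
  if (mean_reads_per_molecule < 1)
    stop("'mean_reads_per_molecule' must be >= 1", call. = FALSE)
  assert_prob(labeled_fraction, "labeled_fraction")
  assert_prob(conversion_rate, "conversion_rate")
  assert_prob(error_rate, "error_rate")
  assert_pos(mean_T_per_read, "mean_T_per_read")
  assert_prob(snp_density, "snp_density")
  if (read_coverage <= 0 || read_coverage > 1)
    stop("'read_coverage' must be in (0, 1]", call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    mean_molecules_per_cell = mean_molecules_per_cell,
    mean_reads_per_molecule = mean_reads_per_molecule,
    labeled_fraction = labeled_fraction,
    conversion_rate = conversion_rate,
    error_rate = error_rate,
    mean_T_per_read = mean_T_per_read,
    snp_density = snp_density,
    read_coverage = read_coverage,
    seed = as.integer(seed)), class = "read_sim_config")
}

#' Simulate barcoded, UMI-tagged scSLAM-seq read observations
#'
#' Generates a read-observation table together with the molecule-level ground
#' truth, the gene coordinate table, and the list of simulated common SNPs.
#' Positions are gene-local 0-based offsets; [write_vcf_min()],
#' [write_bed()] and [write_sam_dialect()] translate to global 1-based
#' coordinates at the I/O boundary.
#'
#' @param cfg A [read_sim_config()].
#' @return A list of class `slam_sim` with elements
#'   \describe{
#'     \item{reads}{`data.table` with `barcode`, `umi`, `gene_id` and
#'       list-columns `covered` (all covered reference-T positions),
#'       `converted` (observed T-to-C) and `other` (non-T-to-C mismatches).}
#'     \item{truth}{per-molecule `data.table`: `barcode`, `umi`, `gene_id`,
#'       `labeled`, `n_conversions` (true conversions on the molecule),
#'       `n_T` (T positions on the molecule).}
#'     \item{snps}{simulated SNPs: `gene_id`, `pos` (gene-local), `chrom`,
#'       `pos_global` (0-based), `ref`, `alt`, `at_T`.}
#'     \item{genes}{gene coordinates: `gene_id`, `chrom`, `start`, `end`
#'       (0-based half-open), `strand`.}
#'   }
#' @export
simulate_reads <- function(cfg) {
  stopifnot(inherits(cfg, "read_sim_config"))
  with_local_seed(cfg$seed, {
    G <- cfg$n_genes; C <- cfg$n_cells
    K <- max(1L, as.integer(round(cfg$mean_T_per_read / cfg$read_coverage)))
    L <- max(4L * K, 20L)

    gene_id <- sprintf("G%04d", seq_len(G))
    chrom <- ifelse(seq_len(G) %% 2L == 1L, "chr1", "chr2")
    start <- integer(G)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      start[i] <- cumsum(c(0L, rep(L + 100L, length(i) - 1L)))
    }
    genes <- data.table::data.table(
      gene_id = gene_id, chrom = chrom, start = start, end = start + L,
      strand = rep_len(c("+", "-"), G))

    # reference T positions per gene, gene-local 0-based
    tpos <- matrix(0L, G, K)
    for (g in seq_len(G)) tpos[g, ] <- sort(sample.int(L, K) - 1L)

    # common SNPs within genes
    snp_list <- vector("list", G)
    for (g in seq_len(G)) {
      p <- which(runif(L) < cfg$snp_density) - 1L
      if (length(p)) snp_list[[g]] <- data.table::data.table(
        gene_id = gene_id[g], pos = p, at_T = p %in% tpos[g, ])
    }
    snps <- data.table::rbindlist(snp_list)
    if (nrow(snps)) {
      gi <- match(snps$gene_id, gene_id)
      plus <- genes$strand[gi] == "+"
      snps[, `:=`(chrom = genes$chrom[gi],
                  pos_global = ifelse(plus, genes$start[gi] + pos,
                                      genes$end[gi] - 1L - pos),
                  ref = ifelse(at_T, ifelse(plus, "T", "A"),
                               ifelse(plus, "G", "C")),
                  alt = ifelse(at_T, ifelse(plus, "C", "G"),
                               ifelse(plus, "A", "T")))]
    } else {
      snps <- data.table::data.table(gene_id = character(), pos = integer(),
                                     at_T = logical(), chrom = character(),
                                     pos_global = integer(), ref = character(),
                                     alt = character())
    }
    # gene x T-index SNP indicator (heterozygous T>C sites)
    snpT <- matrix(FALSE, G, K)
    if (nrow(snps)) {
      st <- snps[at_T == TRUE]
      if (nrow(st)) {
        gi <- match(st$gene_id, gene_id)
        for (r in seq_len(nrow(st)))
          snpT[gi[r], match(st$pos[r], tpos[gi[r], ])] <- TRUE
      }
    }

    # molecules
    n_mol <- rpois(C, cfg$mean_molecules_per_cell)
    M <- sum(n_mol)
    if (M == 0L) stop("simulation produced zero molecules; increase ",
                      "'mean_molecules_per_cell'", call. = FALSE)
    barcode_id <- sprintf("BC%04d", seq_len(C))
    mol <- data.table::data.table(
      mol_id = seq_len(M),
      barcode = rep(barcode_id, n_mol),
      umi = sprintf("U%05d", unlist(lapply(n_mol, seq_len), use.names = FALSE)),
      gene_idx = sample.int(G, M, replace = TRUE))
    mol[, labeled := runif(M) < cfg$labeled_fraction]

    # molecule-level true conversions and heterozygous SNP alt alleles
    conv <- matrix(runif(M * K) < cfg$conversion_rate, M, K) & mol$labeled
    alt <- snpT[mol$gene_idx, , drop = FALSE] & (matrix(runif(M * K), M, K) < 0.5)
    baseC <- conv | alt

    truth <- data.table::data.table(
      barcode = mol$barcode, umi = mol$umi, gene_id = gene_id[mol$gene_idx],
      labeled = mol$labeled, n_conversions = as.integer(rowSums(conv)),
      n_T = K)

    # reads: contiguous windows of w T positions
    w <- max(1L, as.integer(round(cfg$read_coverage * K)))
    n_reads <- 1L + rpois(M, cfg$mean_reads_per_molecule - 1)
    R <- sum(n_reads)
    rd <- data.table::data.table(
      read_id = seq_len(R),
      mol_id = rep(mol$mol_id, n_reads),
      start_idx = sample.int(K - w + 1L, R, replace = TRUE) - 1L)

    # read x covered-T long form
    rp_read <- rep(rd$read_id, each = w)
    rp_mol <- rep(rd$mol_id, each = w)
    rp_idx <- rep(rd$start_idx, each = w) + rep(seq_len(w) - 1L, times = R)
    n_rp <- length(rp_idx)
    gidx <- mol$gene_idx[rp_mol]
    local_pos <- tpos[cbind(gidx, rp_idx + 1L)]
    bC <- baseC[cbind(rp_mol, rp_idx + 1L)]
    err <- runif(n_rp) < cfg$error_rate
    sub <- sample.int(3L, n_rp, replace = TRUE)  # uniform substitution choice
    obs_C <- (!err & bC) | (err & !bC & sub == 1L)
    obs_O <- err & sub > 1L

    rp <- data.table::data.table(read_id = rp_read, lp = local_pos,
                                 oC = obs_C, oO = obs_O)
    reads <- rp[, .(covered = list(sort(lp)),
                    converted = list(sort(lp[oC])),
                    other = list(sort(lp[oO]))), by = read_id]
    reads[, `:=`(barcode = mol$barcode[rd$mol_id[read_id]],
                 umi = mol$umi[rd$mol_id[read_id]],
                 gene_id = gene_id[mol$gene_idx[rd$mol_id[read_id]]])]
    data.table::setcolorder(reads, c("barcode", "umi", "gene_id",
                                     "covered", "converted", "other", "read_id"))
    data.table::setorder(reads, barcode, umi, gene_id, read_id)
    reads[, read_id := NULL]

    structure(list(reads = reads[], truth = truth[], snps = snps[],
                   genes = genes[], config = cfg),
              class = "slam_sim")
  })
}

#' @export
print.slam_sim <- function(x, ...) {
  cat(sprintf(
    "scSLAM-seq simulation: %d reads, %d molecules, %d genes, %d cells, %d SNPs\n",
    nrow(x$reads), nrow(x$truth), nrow(x$genes),
    length(unique(x$truth$barcode)), nrow(x$snps)))
  invisible(x)
}
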