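sim_cohort <- function(shift = 0.8, seg_frac = 0.2, sd = 0.15, seed = 1,
                       n_genes = 600, n_normal = 120, n_clone = 60) {
  per_chrom <- n_genes %/% 3
  seg_len <- round(seg_frac * per_chrom * 3)  # fraction of the whole genome
  seg_len <- min(seg_len, per_chrom)
  simulate_clone_expression(clone_sim_config(
    n_genes = n_genes, n_chromosomes = 3, n_normal_cells = n_normal,
    clones = list(
      list(n_cells = n_clone,
           segments = data.frame(chrom = "chr1", start = 1L, end = 1L,
                                 shift = 0)),
      list(n_cells = n_clone,
           segments = data.frame(chrom = "chr2", start = 1L,
                                 end = seg_len, shift = shift))),
    noise_sd = sd, seed = seed))
}

test_that("genomic smoothing centers, truncates at chromosome ends and clips", {
  co <- sim_cohort(seed = 2)
  ref <- co$labels == "normal"
  # expression identical to the reference mean -> all zeros
  flat <- matrix(5, 60, 10,
                 dimnames = list(co$coords$gene_id[1:60], sprintf("c%d", 1:10)))
  sp0 <- smooth_genomic_expression(flat, co$coords[1:60], sprintf("c%d", 1:3),
                                   window = 11)
  expect_true(all(sp0$profiles == 0))

  # window = 1 is the identity on centered values
  sp1 <- smooth_genomic_expression(co$expr, co$coords, names(which(ref)),
                                   window = 1)
  centered <- co$expr - rowMeans(co$expr[, ref])
  expect_equal(sp1$profiles, centered[rownames(sp1$profiles), ],
               tolerance = 1e-12)

  # matches the brute-force truncated moving average (plateau at the planted
  # step, ramps at segment edges)
  sp <- smooth_genomic_expression(co$expr, co$coords, names(which(ref)),
                                  window = 101)
  ora <- brute_genomic_smooth(centered[rownames(sp$profiles), ],
                              sp$coords$chrom, 101)
  ora[ora > 3] <- 3; ora[ora < -3] <- -3
  expect_equal(sp$profiles, ora, tolerance = 1e-12)
  clone2 <- co$labels == "clone2"
  mid_seg <- which(sp$coords$chrom == "chr2")[60]
  expect_equal(mean(sp$profiles[mid_seg, clone2]), 0.8, tolerance = 0.1)

  expect_error(smooth_genomic_expression(co$expr, co$coords,
                                         names(which(ref)), window = 10),
               "odd")
})

test_that("smoothing locality: a change affects only the window neighborhood", {
  co <- sim_cohort(seed = 3, n_genes = 300, n_normal = 20, n_clone = 5)
  ref <- names(co$labels)[co$labels == "normal"]
  w <- 21
  a <- smooth_genomic_expression(co$expr, co$coords, ref, window = w)
  expr2 <- co$expr
  target <- rownames(a$profiles)[10]  # 10th gene on chr1
  expr2[target, ncol(expr2)] <- expr2[target, ncol(expr2)] + 1
  b <- smooth_genomic_expression(expr2, co$coords, ref, window = w)
  changed <- which(rowSums(a$profiles != b$profiles) > 0)
  idx <- which(rownames(a$profiles) == target)
  expect_true(all(abs(changed - idx) <= (w - 1) / 2))
  expect_true(all(a$coords$chrom[changed] == a$coords$chrom[idx]))
})

test_that("cluster_clones recovers planted clones and handles edge cases", {
  co <- sim_cohort(shift = 1, seg_frac = 0.2, sd = 0.1, seed = 4)
  ref <- names(co$labels)[co$labels == "normal"]
  tumor <- names(co$labels)[co$labels != "normal"]
  sp <- smooth_genomic_expression(co$expr, co$coords, ref, window = 101)
  cut <- cluster_clones(sp$profiles[, tumor], k = 2)
  agreement <- max(mean((cut$assignment == 1) ==
                          (co$labels[tumor] == "clone1")),
                   mean((cut$assignment == 2) ==
                          (co$labels[tumor] == "clone1")))
  expect_gte(agreement, 0.99)

  one <- cluster_clones(sp$profiles[, tumor], k = 1)
  expect_true(all(one$assignment == 1))
  expect_error(cluster_clones(sp$profiles[, tumor], k = 1e6), "exceed")
  expect_warning(cluster_clones(matrix(1, 5, 4), k = 2), "degenerate")
})

test_that("scna_score is calibrated on reference-like clones and detects shifts", {
  co <- sim_cohort(shift = 0.8, seg_frac = 0.2, sd = 0.15, seed = 5,
                   n_normal = 200)
  ref <- names(co$labels)[co$labels == "normal"]
  sp <- smooth_genomic_expression(co$expr, co$coords, ref, window = 101)
  normal_prof <- sp$profiles[, ref]
  # clone1 has no shift: score ~ 1 within 3 SE over its cells
  cl <- names(co$labels)[co$labels != "normal"]
  sc <- scna_score(sp$profiles[, cl], co$labels[cl], normal_prof)
  s1 <- sc[clone == "clone1"]
  cell_sds <- apply(sp$profiles[, names(co$labels)[co$labels == "clone1"]],
                    2, sd)
  se <- sd(cell_sds) / sqrt(length(cell_sds)) / mean(apply(normal_prof, 2, sd))
  expect_lt(abs(s1$score - 1), 3 * se)
  expect_gt(sc[clone == "clone2"]$score, s1$score)
  expect_gt(sc[clone == "clone2"]$score, 1)

  # scale invariance
  sc2 <- scna_score(sp$profiles[, cl] * 7, co$labels[cl], normal_prof * 7)
  expect_equal(sc2$score, sc$score, tolerance = 1e-12)

  expect_error(scna_score(matrix(0, 5, 3), rep("a", 3), matrix(0, 5, 2)),
               "zero variance")
})

test_that("call_aberrant uses a strict threshold", {
  expect_identical(unname(call_aberrant(c(1.0, 1.2), c(0.9, 1.0))),
                   c(FALSE, TRUE))
  expect_true(call_aberrant(1.0 + 1e-9, c(0.9, 1.0)))
  expect_error(call_aberrant(1, numeric(0)), "normal")
})

test_that("hypergeometric region enrichment matches exact tails and caps", {
  uni <- sprintf("u%03d", 1:100)
  reg <- uni[1:10]
  full <- cna_region_enrichment(uni[1:10], reg, uni)
  expect_equal(full$p_raw, 1 / choose(100, 10), tolerance = 1e-9)
  expect_equal(full$overlap, 10)

  # overlap at its independence expectation is unremarkable
  some <- cna_region_enrichment(uni[c(1, 11:19)], reg, uni)
  expect_gt(some$p_raw, 0.5)

  capped <- cna_region_enrichment(uni[c(1:2, 11:18)], reg, uni, n_tests = 39)
  expect_lte(capped$p_adjusted, 1)
  p <- cna_region_enrichment(uni[c(1, 11:19)], reg, uni, n_tests = 39)
  expect_equal(p$p_adjusted, min(1, p$p_raw * 39))
  expect_error(cna_region_enrichment("x", "x", character(0)), "universe")
  expect_error(cna_region_enrichment("notin", reg, uni), "subsets")
})
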