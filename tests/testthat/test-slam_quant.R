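mk_read <- function(barcode = "BC1", umi = "U1", gene = "G1",
                    covered = integer(0), converted = integer(0),
                    other = integer(0)) {
  data.table::data.table(barcode = barcode, umi = umi, gene_id = gene,
                         covered = list(as.integer(covered)),
                         converted = list(as.integer(converted)),
                         other = list(as.integer(other)))
}

test_that("snp_mask parsing uses 1-based VCF coordinates and set semantics", {
  expect_length(parse_snp_mask(character(0)), 0)
  m <- parse_snp_mask(c("##fileformat=VCFv4.2",
                        "chr1\t101\t.\tT\tC\t.\t.\t."))
  expect_length(m, 1)
  expect_identical(m$entries$pos, 100L)
  m3 <- parse_snp_mask(c("chr1\t10\t.\tT\tC\t.\t.\t.",
                         "chr1\t20\t.\tT\tC\t.\t.\t.",
                         "chr1\t10\t.\tT\tC\t.\t.\t."))
  expect_length(m3, 2)
  expect_error(read_vcf_min(c("chr1\t5\t.\tT\tC\t.\t.\t.", "chr1\tbroken")),
               "line 2")
})

test_that("read_conversion_profile masks and validates", {
  r <- mk_read(covered = 0:9, converted = c(2L, 5L))
  p <- read_conversion_profile(r, NULL)
  expect_equal(p$n_T, 10)
  expect_equal(p$converted, c(2L, 5L))

  m <- snp_mask(c("G1", "G1"), c(2L, 5L))
  p2 <- read_conversion_profile(r, m)
  expect_equal(p2$n_T, 8)
  expect_length(p2$converted, 0)

  empty <- mk_read()
  p3 <- read_conversion_profile(empty, NULL)
  expect_equal(p3$n_T, 0)

  bad <- mk_read(covered = 0:4, converted = 9L)
  expect_error(read_conversion_profile(bad, NULL), "data error")
})

test_that("collapse_molecule implements concordance, discordance and defaults", {
  two_conc <- rbind(mk_read(covered = 95:105, converted = 100L),
                    mk_read(covered = 98:110, converted = 100L))
  call <- collapse_molecule(two_conc)
  expect_equal(call$label, "nascent")
  expect_equal(call$n_conv, 1)
  expect_equal(call$n_discordant, 0)

  disc <- rbind(mk_read(covered = 95:105, converted = 100L),
                mk_read(covered = 98:110))
  call <- collapse_molecule(disc)
  expect_equal(call$label, "old")
  expect_equal(call$n_discordant, 1)

  old <- collapse_molecule(mk_read(covered = 1:10))
  expect_equal(old$label, "old")
  expect_false(old$no_T)

  no_t <- collapse_molecule(mk_read())
  expect_equal(no_t$label, "old")
  expect_true(no_t$no_T)

  expect_error(collapse_molecule(mk_read()[0]), "empty")
  # duplicate identical records are deduplicated
  dup <- rbind(mk_read(covered = 1:5, converted = 3L),
               mk_read(covered = 1:5, converted = 3L))
  expect_equal(collapse_molecule(dup)$n_reads, 1)
})

test_that("classify_molecules matches the brute-force oracle exactly", {
  sim <- simulate_reads(read_sim_config(n_genes = 15, n_cells = 30,
                                        mean_molecules_per_cell = 60,
                                        mean_reads_per_molecule = 2.5,
                                        error_rate = 0.01, snp_density = 0.005,
                                        seed = 77))
  mask <- snp_mask(sim$snps$gene_id, sim$snps$pos)
  got <- classify_molecules(sim$reads, mask)$calls
  want <- brute_classify(as.data.frame(sim$reads), mask$entries)
  expect_equal(nrow(got), nrow(want))
  expect_identical(got$label, want$label)
  expect_identical(got$n_T, want$n_T)
  expect_identical(got$n_conv, want$n_conv)
})

test_that("zero-rate purity, conservation and masking monotonicity hold", {
  sim <- simulate_reads(read_sim_config(n_genes = 10, n_cells = 20,
                                        conversion_rate = 0, error_rate = 0,
                                        snp_density = 0, seed = 3))
  calls <- classify_molecules(sim$reads)$calls
  expect_equal(sum(calls$label == "nascent"), 0)

  sim2 <- simulate_reads(read_sim_config(n_genes = 10, n_cells = 20,
                                         error_rate = 0.01,
                                         snp_density = 0.01, seed = 4))
  res <- classify_molecules(sim2$reads)
  expect_equal(nrow(res$calls),
               length(unique(paste(sim2$reads$barcode, sim2$reads$umi,
                                   sim2$reads$gene_id))))
  # enlarging the mask never increases the nascent count
  small <- snp_mask(sim2$snps$gene_id[1], sim2$snps$pos[1])
  big <- snp_mask(sim2$snps$gene_id, sim2$snps$pos)
  n_small <- sum(classify_molecules(sim2$reads, small)$calls$label == "nascent")
  n_big <- sum(classify_molecules(sim2$reads, big)$calls$label == "nascent")
  n_none <- sum(res$calls$label == "nascent")
  expect_lte(n_small, n_none)
  expect_lte(n_big, n_small)
})

test_that("gene-ambiguous UMIs are discarded and reported", {
  amb <- rbind(mk_read(gene = "G1", covered = 1:5, converted = 2L),
               mk_read(gene = "G2", covered = 1:5),
               mk_read(barcode = "BC2", gene = "G1", covered = 1:5))
  res <- classify_molecules(amb)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$barcode, "BC2")
  expect_equal(nrow(res$discarded), 1)
  expect_equal(res$discarded$n_genes, 2L)
})

test_that("build_layered_matrix tallies calls and matches simulated truth", {
  empty <- build_layered_matrix(
    classify_molecules(mk_read()[0])$calls, c("BC1"), c("G1"))
  expect_equal(sum(empty$layers$total), 0)

  calls <- data.table::data.table(
    barcode = rep("BC1", 5), umi = sprintf("U%d", 1:5),
    gene_id = rep("G1", 5), label = c(rep("nascent", 3), rep("old", 2)))
  m <- build_layered_matrix(calls, "BC1", "G1")
  expect_equal(as.numeric(m$layers$nascent[1, 1]), 3)
  expect_equal(as.numeric(m$layers$old[1, 1]), 2)
  expect_equal(as.numeric(m$layers$total[1, 1]), 5)

  expect_error(build_layered_matrix(calls, "BCX", "G1", on_unknown = "error"),
               "unknown")

  # with p_e = 0, no SNPs and full read coverage (so every molecule-level
  # conversion is observed) the matrix marginals equal the truth tally
  sim <- simulate_reads(read_sim_config(n_genes = 12, n_cells = 25,
                                        mean_molecules_per_cell = 80,
                                        error_rate = 0, snp_density = 0,
                                        read_coverage = 1, seed = 21))
  calls <- classify_molecules(sim$reads)$calls
  lcm <- build_layered_matrix(calls, sort(unique(sim$truth$barcode)),
                              sort(unique(sim$truth$gene_id)))
  truth_nascent <- sim$truth$labeled & sim$truth$n_conversions > 0
  expect_equal(sum(lcm$layers$nascent), sum(truth_nascent))
  expect_equal(sum(lcm$layers$total), nrow(sim$truth))
  tt <- table(sim$truth$gene_id[truth_nascent])
  expect_equal(as.numeric(Matrix::rowSums(lcm$layers$nascent)[names(tt)]),
               as.numeric(tt))
})
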