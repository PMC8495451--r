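test_that("read simulator honours zero-rate and certainty cases", {
  z <- simulate_reads(read_sim_config(n_genes = 10, n_cells = 10,
                                      mean_molecules_per_cell = 30,
                                      conversion_rate = 0, error_rate = 0,
                                      snp_density = 0, seed = 7))
  expect_true(all(lengths(z$reads$converted) == 0))
  expect_true(all(z$truth$n_conversions == 0))

  c1 <- simulate_reads(read_sim_config(n_genes = 5, n_cells = 10,
                                       mean_molecules_per_cell = 30,
                                       labeled_fraction = 1,
                                       conversion_rate = 1, error_rate = 0,
                                       snp_density = 0,
                                       mean_T_per_read = 5, seed = 7))
  expect_true(all(c1$truth$labeled))
  expect_true(all(c1$truth$n_conversions >= 1))
})

test_that("fraction of molecules with a conversion matches the Bernoulli complement", {
  # f * (1 - (1-p_c)^m) with m = 50 usable T per molecule (full read coverage)
  cfg <- read_sim_config(n_genes = 20, n_cells = 100,
                         mean_molecules_per_cell = 100,
                         mean_reads_per_molecule = 1,
                         labeled_fraction = 0.3, conversion_rate = 0.05,
                         error_rate = 0, snp_density = 0,
                         mean_T_per_read = 50, read_coverage = 1, seed = 11)
  sim <- simulate_reads(cfg)
  n <- nrow(sim$truth)
  expect_gt(n, 5000)
  expected <- 0.3 * (1 - 0.95^50)
  observed <- mean(sim$truth$n_conversions >= 1)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("simulators are deterministic and conserve truth records", {
  cfg <- read_sim_config(n_genes = 8, n_cells = 12, seed = 42)
  a <- simulate_reads(cfg); b <- simulate_reads(cfg)
  expect_identical(a, b)
  keys_reads <- unique(paste(a$reads$barcode, a$reads$umi, a$reads$gene_id))
  expect_equal(nrow(a$truth), length(keys_reads))

  kc <- kinetic_sim_config(n_genes = 20, n_cells = 50, seed = 5)
  expect_identical(simulate_kinetic_population(kc),
                   simulate_kinetic_population(kc))
  cc <- clone_sim_config(seed = 5)
  expect_identical(simulate_clone_expression(cc),
                   simulate_clone_expression(cc))
})

test_that("read simulator rejects invalid probabilities", {
  expect_error(read_sim_config(labeled_fraction = 1.2), "probability")
  expect_error(read_sim_config(conversion_rate = -0.1), "probability")
  expect_error(read_sim_config(error_rate = 2), "probability")
  expect_error(kinetic_sim_config(alpha_range = c(-1, 2)), "positive")
})

test_that("kinetic simulator follows the ODE fixed point and Poisson error bounds", {
  # gene pinned at alpha=2, beta=1, gamma=0.5; long induction phase so most
  # cells sit at the (alpha/beta, alpha/gamma) = (2, 4) fixed point
  cfg <- kinetic_sim_config(n_genes = 1, n_cells = 500,
                            alpha_range = c(2, 2), beta_range = c(1, 1),
                            gamma_range = c(0.5, 0.5),
                            t_switch_range = c(0.9, 0.9), t_max = 200,
                            one_sided_fraction = 0, seed = 3)
  sim <- simulate_kinetic_population(cfg)
  steady <- sim$truth_time > 40 & sim$truth_time < 180
  expect_gt(sum(steady), 300)
  expect_equal(unname(sim$expectation$nascent[1, steady]),
               rep(2, sum(steady)), tolerance = 1e-6)
  expect_equal(unname(sim$expectation$old[1, steady]),
               rep(4, sum(steady)), tolerance = 1e-6)
  n <- sum(steady)
  obs <- mean(as.matrix(sim$counts$layers$nascent)[1, steady])
  expect_lt(abs(obs - 2), 3 * sqrt(2 / n))
  # layered invariant
  expect_equal(as.matrix(sim$counts$layers$total),
               as.matrix(sim$counts$layers$nascent) +
                 as.matrix(sim$counts$layers$old))
})

test_that("clone simulator plants the configured shifts", {
  seg <- data.frame(chrom = "chr1", start = 1L, end = 200L, shift = 1)
  cfg <- clone_sim_config(n_genes = 600, n_chromosomes = 3,
                          n_normal_cells = 150,
                          clones = list(list(n_cells = 150, segments = seg)),
                          noise_sd = 0.1, seed = 9)
  sim <- simulate_clone_expression(cfg)
  shifted <- sim$coords$chrom == "chr1" &
    seq_len(nrow(sim$coords)) %in% 1:200
  d <- mean(sim$expr[shifted, !sim$normal]) - mean(sim$expr[shifted, sim$normal])
  expect_lt(abs(d - 1), 3 * 0.1 * sqrt(2 / (200 * 150)))

  null <- simulate_clone_expression(clone_sim_config(
    n_genes = 300, n_chromosomes = 3, n_normal_cells = 100,
    clones = list(list(n_cells = 100,
                       segments = data.frame(chrom = "chr1", start = 1L,
                                             end = 50L, shift = 0))),
    noise_sd = 0.1, seed = 10))
  d0 <- mean(null$expr[, !null$normal]) - mean(null$expr[, null$normal])
  expect_lt(abs(d0), 3 * 0.1 * sqrt(2 / (300 * 100)))

  expect_error(clone_sim_config(clones = list(list(
    n_cells = 10, segments = data.frame(chrom = "chr1",
                                        start = c(1L, 50L),
                                        end = c(60L, 90L),
                                        shift = c(1, 1))))), "overlapping")
})

test_that("condition simulator separation geometry behaves", {
  far <- simulate_condition_dataset(2, 100, separation = 100, dim = 2,
                                    seed = 1)
  nb <- knn_neighbors(far$embedding, k = 10)
  same <- vapply(seq_along(nb), function(i)
    all(far$labels[nb[[i]]] == far$labels[i]), logical(1))
  expect_true(all(same))

  ex <- simulate_condition_dataset(2, 1000, separation = 0, dim = 2,
                                   seed = 2)
  nb <- knn_neighbors(ex$embedding, k = 30)
  other <- mean(vapply(seq_along(nb), function(i)
    mean(ex$labels[nb[[i]]] != ex$labels[i]), numeric(1)))
  se <- sqrt(0.25 / (2000 * 30 / 5))  # conservative SE for dependent draws
  expect_lt(abs(other - 0.5), 3 * se)

  expect_error(simulate_condition_dataset(2, 10, dim = 0), "dim")
  expect_error(simulate_condition_dataset(3, 10, separation = 1, dim = 2),
               "dim")
})
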