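mk_counts <- function(m) {
  dimnames(m) <- list(sprintf("G%03d", seq_len(nrow(m))),
                      sprintf("BC%03d", seq_len(ncol(m))))
  layered_counts(methods::as(m, "CsparseMatrix"),
                 methods::as(matrix(0, nrow(m), ncol(m),
                                    dimnames = dimnames(m)),
                             "CsparseMatrix"))
}

test_that("filter_cells applies both closed-interval predicates and is idempotent", {
  set.seed(1)
  n_genes <- 30; n_cells <- 20
  m <- matrix(rpois(n_genes * n_cells, 2) + 1, n_genes, n_cells)
  # engineer: detected genes = n_genes everywhere; vary mito fraction so that
  # exactly 7 of 20 cells pass a mito window (and gene range passes for all)
  mito_frac <- seq(0.01, 0.96, length.out = n_cells)
  mito_rows <- 1:3
  x <- mk_counts(m)
  tot <- as.matrix(x$layers$nascent)
  for (j in seq_len(n_cells)) {
    s <- sum(tot[-mito_rows, j])
    tot[mito_rows, j] <- round(s * mito_frac[j] / (1 - mito_frac[j]) / 3) + 1
  }
  x <- mk_counts(tot)
  cfg <- cell_filter_config(min_genes = 1, max_genes = 1e6,
                            min_mito_frac = 0.075, max_mito_frac = 0.4)
  frac <- Matrix::colSums(x$layers$total[mito_rows, ]) /
    Matrix::colSums(x$layers$total)
  want <- sum(frac >= 0.075 & frac <= 0.4)
  filt <- filter_cells(x, mito_genes = x$genes[mito_rows], cfg)
  expect_equal(length(filt$cells), want)
  expect_identical(filt$genes, x$genes)
  # idempotence
  again <- filter_cells(filt, mito_genes = x$genes[mito_rows], cfg)
  expect_identical(again$cells, filt$cells)

  # gene-count predicate boundaries: 1999 detected genes removed at min 2000
  big <- mk_counts(rbind(matrix(1, 1999, 2), matrix(c(0, 1), 1, 2)))
  got <- filter_cells(big, cfg = cell_filter_config(
    2000, 5000, 0, 1))
  expect_identical(got$cells, "BC002")
})

test_that("normalize_log matches the closed form and target sums", {
  m <- matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "c1"))
  out <- normalize_log(m, target_sum = 2)
  expect_equal(as.numeric(out), log1p(c(1, 1)), tolerance = 1e-12)

  set.seed(2)
  r <- matrix(rpois(50 * 20, 5) + 1, 50, 20,
              dimnames = list(sprintf("g%d", 1:50), sprintf("c%d", 1:20)))
  out <- normalize_log(r, target_sum = 100)
  expect_equal(unname(Matrix::colSums(expm1(as.matrix(out)))),
               rep(100, 20), tolerance = 1e-9)
  r[, 3] <- 0
  expect_error(normalize_log(r), "c3")
})

test_that("select_hvg ranks planted high-dispersion genes first", {
  # single extreme gene among constants is ranked first
  flat <- matrix(5, 50, 30, dimnames = list(sprintf("f%02d", 1:50),
                                            sprintf("c%d", 1:30)))
  flat["f25", ] <- rep(c(0, 30), 15)
  expect_equal(select_hvg(normalize_log(flat + 1), n = 1), "f25")

  set.seed(3)
  n <- 510
  # background genes span a range of means; three bimodal genes planted far
  # apart so each dominates its own mean bin
  lam <- rep(seq(1, 12, length.out = 51), each = 10)
  m <- matrix(rpois(n * 60, lam), n, 60,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("c%d", 1:60)))
  hot_idx <- c(120, 300, 480)
  hot <- sprintf("g%03d", hot_idx)
  for (i in hot_idx)  # bimodal with matched mean: huge dispersion
    m[i, ] <- rbinom(60, 1, 0.2) * lam[i] * 5
  norm <- normalize_log(m + 1, target_sum = 500)
  top <- select_hvg(norm, n = 3, n_bins = 5)
  expect_setequal(top, hot)
  expect_identical(select_hvg(norm, n = n),
                   select_hvg(norm, n = n))  # deterministic, full set allowed
  expect_error(select_hvg(norm, n = 0), "positive")

  # ranking equals an independent brute-force recomputation
  x <- expm1(as.matrix(norm))
  mu <- rowMeans(x)
  disp <- apply(x, 1, var) / ifelse(mu > 0, mu, 1)
  br <- unique(quantile(mu, seq(0, 1, length.out = 6)))
  bin <- cut(mu, br, include.lowest = TRUE)
  z <- disp
  for (b in levels(bin)) {
    i <- bin == b
    z[i] <- (disp[i] - mean(disp[i])) / sd(disp[i])
  }
  want <- rownames(m)[order(-z, rownames(m))][1:50]
  expect_identical(select_hvg(norm, n = 50, n_bins = 5), want)
})

test_that("score_gene_set is control-balanced, deterministic and sensitive", {
  set.seed(4)
  m <- matrix(rnorm(200 * 80), 200, 80,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:80)))
  const <- matrix(1, 50, 10, dimnames = list(sprintf("g%d", 1:50),
                                             sprintf("c%d", 1:10)))
  expect_equal(as.numeric(score_gene_set(const, c("g1", "g2"), seed = 1)),
               rep(0, 10))

  s1 <- score_gene_set(m, c("g001", "g002"), seed = 9)
  s2 <- score_gene_set(m, c("g001", "g002"), seed = 9)
  expect_identical(s1, s2)
  expect_error(score_gene_set(m, "absent"), "no gene")

  # planted signature: +1 shift of set genes in half the cells; background
  # gene means span a range so expression-matched controls come from the
  # background, not from other signature genes
  set.seed(12)
  mu_g <- runif(400, -2, 2)
  m2 <- matrix(rnorm(400 * 80), 400, 80,
               dimnames = list(sprintf("h%03d", 1:400),
                               sprintf("c%02d", 1:80))) + mu_g
  sig <- sprintf("h%03d", seq(10, 390, by = 40))
  m2[sig, 1:40] <- m2[sig, 1:40] + 1
  sc <- score_gene_set(m2, sig, seed = 5)
  d <- mean(sc[1:40]) - mean(sc[41:80])
  se <- sqrt(var(sc[1:40]) / 40 + var(sc[41:80]) / 40)
  expect_lt(abs(d - 1), 3 * se + 0.1)  # 0.1 allows residual control bias
})

test_that("regress_out_cell_cycle removes the covariate and keeps means", {
  set.seed(5)
  n_cells <- 100
  m <- matrix(rnorm(60 * n_cells), 60, n_cells,
              dimnames = list(sprintf("g%02d", 1:60),
                              sprintf("c%03d", 1:n_cells)))
  m <- m - rowMeans(m)  # equal gene means keep control draws stable
  s_genes <- sprintf("g%02d", 1:5); g2m_genes <- sprintf("g%02d", 6:10)
  x <- as.numeric(score_gene_set(m, s_genes, seed = 0)) -
    as.numeric(score_gene_set(m, g2m_genes, seed = 1))
  # plant a gene proportional to the covariate (mean kept at 0)
  g60 <- 2 * x + rnorm(n_cells, sd = 0.01)
  m["g60", ] <- g60 - mean(g60)
  out <- regress_out_cell_cycle(m, s_genes, g2m_genes, seed = 0)
  expect_lt(var(out["g60", ]) / var(m["g60", ]), 1e-3)
  expect_equal(rowMeans(out), rowMeans(m), tolerance = 1e-9)
  # per-gene residual + mean equals the least-squares oracle
  x_in <- as.numeric(score_gene_set(m, s_genes, seed = 0)) -
    as.numeric(score_gene_set(m, g2m_genes, seed = 1))
  for (g in c("g20", "g60"))
    expect_equal(unname(out[g, ]),
                 unname(stats::residuals(stats::lm(m[g, ] ~ x_in)) +
                          mean(m[g, ])), tolerance = 1e-9)
  # a gene uncorrelated with the covariate barely changes
  expect_gt(cor(out["g20", ], m["g20", ]), 0.99)
})

test_that("moments smooth within conditions only and are convex", {
  set.seed(6)
  m <- matrix(rpois(40 * 80, 4), 40, 80,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:80)))
  x <- layered_counts(methods::as(m, "CsparseMatrix"),
                      methods::as(m, "CsparseMatrix"))
  # k = 0: identity
  id <- compute_moments(x, n_pcs = 5, k = 0)
  expect_equal(id[[1]]$moments$nascent, as.matrix(x$layers$nascent))

  # two conditions with disjoint planted values: no leakage
  cond <- rep(c("A", "B"), each = 40)
  x2 <- x
  x2$layers$nascent[1, ] <- c(rep(0, 40), rep(100, 40))
  mom <- compute_moments(x2, cond, n_pcs = 5, k = 10)
  expect_true(all(mom$A$moments$nascent[1, ] == 0))
  expect_true(all(mom$B$moments$nascent[1, ] == 100))

  # convexity within condition
  sm <- mom$A$moments$old
  raw <- as.matrix(x2$layers$old[, cond == "A"])
  expect_true(all(sm >= matrix(apply(raw, 1, min), nrow(sm), ncol(sm)) - 1e-12))
  expect_true(all(sm <= matrix(apply(raw, 1, max), nrow(sm), ncol(sm)) + 1e-12))

  expect_error(compute_moments(x, rep(c("A", "B"), c(5, 75)), k = 10),
               "condition 'A'")
})
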