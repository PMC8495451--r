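# Independent oracles, deliberately written with plain base-R set algebra /
# numerics and kept free of the package's production code paths.

# Brute-force molecule classifier: per-molecule loop, direct set operations.
brute_classify <- function(reads, mask_df = NULL) {
  key <- paste(reads$barcode, reads$umi, reads$gene_id, sep = "\r")
  # drop duplicated identical read records
  sig <- paste(key,
               vapply(reads$covered, paste, character(1), collapse = ","),
               vapply(reads$converted, paste, character(1), collapse = ","),
               vapply(reads$other, paste, character(1), collapse = ","))
  keep <- !duplicated(sig)
  reads <- reads[keep, ]
  key <- key[keep]
  # drop gene-ambiguous (barcode, umi)
  bu <- paste(reads$barcode, reads$umi, sep = "\r")
  genes_per_bu <- tapply(reads$gene_id, bu, function(g) length(unique(g)))
  ambiguous <- names(genes_per_bu)[genes_per_bu > 1]
  ok <- !(bu %in% ambiguous)
  reads <- reads[ok, ]
  key <- key[ok]

  out <- lapply(split(seq_len(nrow(reads)), key), function(idx) {
    gene <- reads$gene_id[idx[1]]
    masked <- if (is.null(mask_df)) integer(0) else
      mask_df$pos[mask_df$key == gene]
    conv_any <- integer(0); reft_any <- integer(0); cov_any <- integer(0)
    for (i in idx) {
      cv <- reads$covered[[i]]; cn <- reads$converted[[i]]
      ot <- reads$other[[i]]
      conv_any <- union(conv_any, cn)
      reft_any <- union(reft_any, setdiff(cv, union(cn, ot)))
      cov_any <- union(cov_any, cv)
    }
    disc <- intersect(conv_any, reft_any)
    usable <- setdiff(cov_any, union(masked, disc))
    conv <- setdiff(conv_any, union(masked, disc))
    data.frame(barcode = reads$barcode[idx[1]], umi = reads$umi[idx[1]],
               gene_id = gene, n_T = length(usable), n_conv = length(conv),
               label = if (length(conv) >= 1) "nascent" else "old",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$barcode, res$umi, res$gene_id), ]
}

# Generic RK4 integrator for the two-layer ODE with switching at tsw.
# Each evaluation time is integrated independently from the origin, split at
# the switch discontinuity, so accuracy is O(h^4) at every requested time.
rk4_kinetics <- function(alpha, beta, gamma, tsw, t_eval, n_steps = 2000L) {
  rk4_segment <- function(y, t0, t1, a) {
    if (t1 <= t0) return(y)
    f <- function(y) c(a - beta * y[1], beta * y[1] - gamma * y[2])
    h <- (t1 - t0) / n_steps
    for (step in seq_len(n_steps)) {
      k1 <- f(y); k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  res <- vapply(t_eval, function(te) {
    y <- rk4_segment(c(0, 0), 0, min(te, tsw), alpha)
    if (te > tsw) y <- rk4_segment(y, tsw, te, 0)
    y
  }, numeric(2))
  list(t = t_eval, u = res[1, ], s = res[2, ])
}

# Exhaustive KNN (double loop over pairs).
brute_knn <- function(emb, k) {
  n <- nrow(emb)
  lapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(emb) - emb[i, ])^2))
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  })
}

# Brute-force condition similarity (composition reading): double loop.
brute_similarity <- function(emb, labels, k) {
  nb <- brute_knn(emb, k)
  labels <- as.character(labels)
  conds <- unique(labels)
  U <- matrix(0, length(conds), length(conds),
              dimnames = list(conds, conds))
  for (a in conds) {
    for (b in conds) {
      fr <- c()
      for (i in which(labels == a))
        fr <- c(fr, mean(labels[nb[[i]]] == b))
      U[a, b] <- mean(fr)
    }
  }
  S <- (U + t(U)) / 2
  diag(S) <- diag(U)
  S
}

# Brute-force truncated moving average within chromosome blocks.
brute_genomic_smooth <- function(centered, chrom, window) {
  half <- (window - 1) %/% 2
  out <- centered
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    for (jj in seq_along(idx)) {
      lo <- max(1, jj - half); hi <- min(length(idx), jj + half)
      out[idx[jj], ] <- colMeans(centered[idx[lo:hi], , drop = FALSE])
    }
  }
  out
}
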