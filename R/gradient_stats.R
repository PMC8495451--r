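#' Assign cells to bins along a signature gradient
#'
#' Cells are ordered by decreasing score (ties broken by barcode) and
#' partitioned into `n_bins` bins: `"quantile"` (default) gives near-equal
#' cell counts (sizes differ by at most one, larger bins first), `"width"`
#' splits the score range into equal-width intervals. Bin 1 is the start of
#' the gradient (highest activity); the study used 40 bins.
#'
#' @param scores Named numeric vector of per-cell signature scores.
#' @param n_bins Number of bins (<= number of cells).
#' @param scheme `"quantile"` or `"width"`.
#' @return `data.table` with `barcode`, `score`, `rank`, `bin` (class
#'   `bin_assignment`); constant scores collapse to a single effective bin
#'   and set `attr(, "constant") = TRUE` with a warning.
#' @export
assign_bins <- function(scores, n_bins = 40L, scheme = c("quantile", "width")) {
  scheme <- match.arg(scheme)
  n <- length(scores)
  if (n_bins > n) stop("'n_bins' must not exceed the number of cells",
                       call. = FALSE)
  bc <- names(scores) %||% sprintf("cell%05d", seq_len(n))
  ord <- order(-scores, bc)
  constant <- max(scores) == min(scores)
  if (scheme == "quantile") {
    sizes <- rep(n %/% n_bins, n_bins)
    r <- n %% n_bins
    if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
    bin_of_rank <- rep(seq_len(n_bins), sizes)
  } else {
    s <- scores[ord]
    if (constant) bin_of_rank <- rep(1L, n)
    else {
      br <- seq(max(s), min(s), length.out = n_bins + 1L)
      bin_of_rank <- pmin(pmax(findInterval(-s, -br, rightmost.closed = TRUE),
                               1L), n_bins)
    }
  }
  out <- data.table::data.table(barcode = bc[ord],
                                score = as.numeric(scores[ord]),
                                rank = seq_len(n), bin = bin_of_rank)
  if (constant) {
    warning("constant scores: single effective bin")
    if (scheme == "width") out[, bin := 1L]
  }
  structure(out[], class = c("bin_assignment", class(out)), n_bins = n_bins,
            constant = constant)
}

#' Bin-by-state distribution table
#'
#' @param bins A [assign_bins()] result.
#' @param state_labels Named state per cell (every binned cell must have
#'   one).
#' @return A `bin_table`: list with `counts` and row-normalized `fractions`
#'   (bins x states matrices) and `n_bins`.
#' @export
state_distribution <- function(bins, state_labels) {
  stopifnot(inherits(bins, "bin_assignment"))
  st <- state_labels[bins$barcode]
  if (anyNA(st)) stop("every cell must have a state label", call. = FALSE)
  n_bins <- attr(bins, "n_bins")
  counts <- table(factor(bins$bin, levels = seq_len(n_bins)),
                  as.character(st))
  counts <- matrix(counts, nrow = n_bins,
                   dimnames = list(seq_len(n_bins), colnames(counts)))
  rs <- rowSums(counts)
  fractions <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, fractions = fractions, n_bins = n_bins),
            class = "bin_table")
}

#' Pearson correlation of a state's fraction along the gradient
#'
#' Pearson's r between bin index (1..n_bins) and the state's per-bin
#' fraction, with a two-sided p-value from `t = r sqrt(n-2) / sqrt(1-r^2)`.
#'
#' @param bin_table A [state_distribution()] result.
#' @param state State (column) name.
#' @return List with `r`, `t`, `p`, `n_bins`; zero-variance fractions give an
#'   `NA` correlation with `flag` set to `"zero_variance"`.
#' @export
gradient_correlation <- function(bin_table, state) {
  stopifnot(inherits(bin_table, "bin_table"))
  y <- bin_table$fractions[, state]
  x <- seq_along(y)
  if (length(y) < 3L) stop("need >= 3 bins", call. = FALSE)
  if (stats::sd(y) == 0)
    return(list(r = NA_real_, t = NA_real_, p = NA_real_,
                n_bins = length(y), flag = "zero_variance"))
  r <- stats::cor(x, y)
  n <- length(y)
  tt <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, t = tt, p = p, n_bins = n, flag = NA_character_)
}

#' Chi-squared enrichment of states at the start of the gradient
#'
#' Per state, a 2x2 Pearson chi-squared test (no continuity correction) of
#' state membership against location in the head of the gradient (the first
#' `head_fraction` of bins, default the top quarter), with Benjamini-
#' Hochberg adjustment across states.
#'
#' @param bin_table A [state_distribution()] result.
#' @param head_fraction Fraction of bins forming the gradient head (in
#'   (0, 1)).
#' @return `data.table` with `state`, `chi2`, `p`, `p_adj`, `head_count`,
#'   `head_expected`, `skipped` (test skipped when an expected cell count is
#'   0).
#' @export
state_enrichment_test <- function(bin_table, head_fraction = 0.25) {
  stopifnot(inherits(bin_table, "bin_table"))
  if (head_fraction <= 0 || head_fraction >= 1)
    stop("'head_fraction' must be in (0, 1)", call. = FALSE)
  n_head <- max(1L, round(head_fraction * bin_table$n_bins))
  counts <- bin_table$counts
  head_tot <- sum(counts[seq_len(n_head), , drop = FALSE])
  total <- sum(counts)
  res <- lapply(colnames(counts), function(st) {
    a <- sum(counts[seq_len(n_head), st])           # state, head
    b <- sum(counts[, st]) - a                      # state, rest
    c_ <- head_tot - a                              # other, head
    d <- total - a - b - c_                         # other, rest
    n <- a + b + c_ + d
    exp_a <- (a + b) * (a + c_) / n
    margins <- c(a + b, c_ + d, a + c_, b + d)
    if (any(margins == 0))
      return(data.table::data.table(state = st, chi2 = NA_real_,
                                    p = NA_real_, head_count = a,
                                    head_expected = exp_a, skipped = TRUE))
    chi2 <- n * (a * d - b * c_)^2 / prod(margins)
    data.table::data.table(state = st, chi2 = chi2,
                           p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                           head_count = a, head_expected = exp_a,
                           skipped = FALSE)
  })
  out <- data.table::rbindlist(res)
  out[, p_adj := stats::p.adjust(p, method = "BH")]
  data.table::setcolorder(out, c("state", "chi2", "p", "p_adj"))
  out[]
}

#' Kruskal-Wallis and post hoc Wilcoxon tests of signatures across clusters
#'
#' Per signature: a Kruskal-Wallis test across clusters with BH (FDR)
#' adjustment over signatures; when the adjusted p is below `alpha`, each
#' cluster is tested one-vs-rest with a Wilcoxon rank-sum test, BH-adjusted
#' across clusters, and star-coded (0.05 / 0.01 / 0.001). Singleton clusters
#' are excluded with a warning.
#'
#' @param scores Matrix or data.frame of per-cell signature scores (cells x
#'   signatures), or a single named vector.
#' @param cluster_labels Cluster label per cell.
#' @param alpha FDR threshold gating the post hoc tests (default 0.05).
#' @return List with `global` (`data.table`: `signature`, `H`, `p`, `p_adj`)
#'   and `posthoc` (`data.table`: `signature`, `cluster`, `W`, `p`, `p_adj`,
#'   `stars`).
#' @export
cluster_signature_tests <- function(scores, cluster_labels, alpha = 0.05) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L,
                                             dimnames = list(names(scores),
                                                             "signature"))
  scores <- as.matrix(scores)
  lab <- as.character(cluster_labels)
  stopifnot(length(lab) == nrow(scores))
  sizes <- table(lab)
  single <- names(sizes)[sizes < 2L]
  if (length(single)) {
    warning("excluding singleton cluster(s): ",
            paste(single, collapse = ", "))
    keep <- !(lab %in% single)
    scores <- scores[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  if (length(unique(lab)) < 2L)
    stop("need >= 2 clusters with >= 2 cells each", call. = FALSE)
  glob <- data.table::rbindlist(lapply(colnames(scores), function(sg) {
    kw <- stats::kruskal.test(scores[, sg], factor(lab))
    data.table::data.table(signature = sg,
                           H = unname(kw$statistic), p = kw$p.value)
  }))
  glob[, p_adj := stats::p.adjust(p, method = "BH")]
  ph <- list()
  stars <- function(p) ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", "")))
  for (sg in glob[p_adj < alpha, signature]) {
    res <- data.table::rbindlist(lapply(sort(unique(lab)), function(cl) {
      w <- stats::wilcox.test(scores[lab == cl, sg], scores[lab != cl, sg],
                              exact = FALSE)
      data.table::data.table(signature = sg, cluster = cl,
                             W = unname(w$statistic), p = w$p.value)
    }))
    res[, p_adj := stats::p.adjust(p, method = "BH")]
    res[, stars := stars(p_adj)]
    ph[[sg]] <- res
  }
  posthoc <- if (length(ph)) data.table::rbindlist(ph) else
    data.table::data.table(signature = character(), cluster = character(),
                           W = numeric(), p = numeric(), p_adj = numeric(),
                           stars = character())
  list(global = glob[], posthoc = posthoc[])
}
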