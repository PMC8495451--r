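# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' seeded operations never perturb the global random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1], got %s",
                 name, format(x)), call. = FALSE)
  invisible(x)
}

#' @noRd
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

#' @noRd
assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(as.numeric(x))
}

#' Weighted median (lower weighted median, deterministic)
#' @noRd
weighted_median <- function(x, w) {
  keep <- is.finite(x) & is.finite(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Dense-or-sparse row variance helper
#' @noRd
row_vars <- function(m) {
  mu <- Matrix::rowMeans(m)
  Matrix::rowMeans(m * m) - mu^2
}

#' Comma-join integer vectors for TSV serialization ('' for empty)
#' @noRd
join_pos <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ","), character(1))
}

#' Inverse of join_pos
#' @noRd
split_pos <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    if (!length(v)) integer(0) else as.integer(v)
  })
}
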