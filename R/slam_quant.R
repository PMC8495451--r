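#' SNP position mask
#'
#' A set of `(key, position)` pairs excluded from conversion counting, where
#' `key` is a chromosome or gene identifier and positions are 0-based. The
#' study masked positions with common SNPs (dbSNP build 151) before counting
#' T-to-C conversions; any minimal VCF works here.
#'
#' @param key Character vector of chromosome or gene identifiers (may be
#'   empty).
#' @param pos Integer vector of 0-based positions, same length as `key`.
#' @return An object of class `snp_mask`. Duplicated entries are collapsed
#'   (set semantics); `length()` returns the number of distinct entries.
#' @export
snp_mask <- function(key = character(), pos = integer()) {
  stopifnot(length(key) == length(pos))
  dt <- data.table::data.table(k = as.character(key), pos = as.integer(pos))
  data.table::setnames(dt, "k", "key")  # 'key' is a formal arg of data.table()
  dt <- unique(dt)
  data.table::setorder(dt, key, pos)
  structure(list(entries = dt, tokens = paste(dt$key, dt$pos)),
            class = "snp_mask")
}

#' @export
length.snp_mask <- function(x) nrow(x$entries)

#' @export
print.snp_mask <- function(x, ...) {
  cat(sprintf("SNP mask with %d positions over %d keys\n",
              length(x), length(unique(x$entries$key))))
  invisible(x)
}

mask_positions <- function(mask, key) {
  if (is.null(mask) || length(mask) == 0L) return(integer(0))
  mask$entries[key, pos, on = "key", nomatch = NULL]
}

#' Parse a minimal VCF into a SNP mask
#'
#' Positions are converted from the 1-based VCF convention to the internal
#' 0-based frame. When a gene coordinate table is supplied, records falling
#' inside genes are additionally keyed by `gene_id` with strand-aware
#' gene-local positions, so masks can be applied to gene-local read
#' observations.
#'
#' @param vcf Path to a minimal VCF file, or a character vector of VCF lines.
#' @param coords Optional gene coordinate `data.table` (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`; 0-based half-open).
#' @return A [snp_mask()].
#' @export
parse_snp_mask <- function(vcf, coords = NULL) {
  rec <- read_vcf_min(vcf)
  key <- rec$chrom; pos <- rec$pos
  if (!is.null(coords) && nrow(rec)) {
    co <- data.table::as.data.table(coords)
    for (r in seq_len(nrow(rec))) {
      hit <- co[chrom == rec$chrom[r] & start <= rec$pos[r] & rec$pos[r] < end]
      if (nrow(hit)) {
        local <- ifelse(hit$strand == "-", hit$end - 1L - rec$pos[r],
                        rec$pos[r] - hit$start)
        key <- c(key, hit$gene_id); pos <- c(pos, local)
      }
    }
  }
  snp_mask(key, pos)
}

#' Conversion profile of a single read
#'
#' Counts usable T positions and retained conversions after SNP masking.
#' Non-T-to-C mismatches are carried along but never counted as conversions.
#'
#' @param read A list or one-row data frame with `gene_id` and integer
#'   position vectors `covered` (all covered reference-T positions),
#'   `converted` and `other`.
#' @param mask A [snp_mask()] or `NULL`.
#' @return List with `n_T` (usable T count), `converted` (retained converted
#'   positions) and `discarded` (masked positions on this read).
#' @export
read_conversion_profile <- function(read, mask = NULL) {
  cov <- read$covered; if (is.list(cov)) cov <- cov[[1L]]
  conv <- read$converted; if (is.list(conv)) conv <- conv[[1L]]
  cov <- as.integer(cov); conv <- as.integer(conv)
  if (length(setdiff(conv, cov)))
    stop("data error: converted position(s) ",
         paste(setdiff(conv, cov), collapse = ","),
         " not among covered positions", call. = FALSE)
  masked <- mask_positions(mask, as.character(read$gene_id))
  usable <- setdiff(cov, masked)
  list(n_T = length(usable),
       converted = sort(intersect(conv, usable)),
       discarded = sort(intersect(cov, masked)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse the reads of one molecule into a nascent/old call
#'
#' Reads sharing one `(barcode, UMI, gene)` key are deduplicated and their
#' evidence unioned. A position observed as converted in at least one read
#' and as reference T in at least one other read is discordant and excluded
#' from both the usable and the converted count, mirroring the study's
#' molecule-level exclusion rule. A molecule is `nascent` iff it retains at
#' least one conversion, and `old` otherwise; molecules without usable T
#' positions are labeled old and flagged `no_T`.
#'
#' @param reads A `data.table`/`data.frame` of reads sharing one key, with
#'   columns `barcode`, `umi`, `gene_id` and position list-columns `covered`,
#'   `converted`, `other`.
#' @param mask A [snp_mask()] or `NULL`.
#' @return A molecule call: list with `barcode`, `umi`, `gene_id`, `n_T`,
#'   `n_conv`, `n_discordant`, `label`, `no_T`, `n_reads`.
#' @export
collapse_molecule <- function(reads, mask = NULL) {
  reads <- data.table::as.data.table(reads)
  if (!nrow(reads)) stop("usage error: empty read list", call. = FALSE)
  k <- unique(reads[, .(barcode, umi, gene_id)])
  if (nrow(k) != 1L)
    stop("all reads must share one (barcode, umi, gene_id) key", call. = FALSE)
  sig <- paste(join_pos(reads$covered), join_pos(reads$converted),
               join_pos(reads$other), sep = "|")
  reads <- reads[!duplicated(sig)]
  for (r in seq_len(nrow(reads)))
    read_conversion_profile(reads[r], NULL)  # validates converted <= covered

  conv_any <- unique(unlist(reads$converted, use.names = FALSE))
  reft_any <- unique(unlist(
    Map(function(cv, cn, ot) setdiff(cv, c(cn, ot)),
        reads$covered, reads$converted, reads$other), use.names = FALSE))
  discordant <- intersect(conv_any, reft_any)
  masked <- mask_positions(mask, k$gene_id)
  cov_all <- unique(unlist(reads$covered, use.names = FALSE))
  usable <- setdiff(cov_all, union(masked, discordant))
  conv <- setdiff(conv_any, union(masked, discordant))
  list(barcode = k$barcode, umi = k$umi, gene_id = k$gene_id,
       n_T = length(usable), n_conv = length(conv),
       n_discordant = length(discordant),
       label = if (length(conv)) "nascent" else "old",
       no_T = length(usable) == 0L, n_reads = nrow(reads))
}

#' Classify all molecules of a read table as nascent or old
#'
#' Vectorized molecule collapsing over a full read-observation table:
#' duplicate identical read records are removed, `(barcode, UMI)` pairs whose
#' reads map to more than one gene are discarded as ambiguous (tallied in the
#' discard report), positions with discordant nucleotides across the reads of
#' one molecule are excluded, SNP-masked positions are removed, and each
#' molecule is labeled `nascent` iff it retains at least one T-to-C
#' conversion.
#'
#' @param reads Read table (`data.table` with `barcode`, `umi`, `gene_id` and
#'   position list-columns `covered`, `converted`, `other`), as produced by
#'   [simulate_reads()] or [read_read_table()].
#' @param mask A [snp_mask()] or `NULL`.
#' @return List with `calls` (per-molecule audit `data.table`: key columns,
#'   `n_T`, `n_conv`, `n_discordant`, `label`, `no_T`, `n_reads`) and
#'   `discarded` (report `data.table` of ambiguous keys with read counts).
#' @export
classify_molecules <- function(reads, mask = NULL) {
  dt <- data.table::as.data.table(reads)
  need <- c("barcode", "umi", "gene_id", "covered", "converted", "other")
  if (!all(need %in% names(dt)))
    stop("read table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(dt))
    return(list(calls = data.table::data.table(
      barcode = character(), umi = character(), gene_id = character(),
      n_T = integer(), n_conv = integer(), n_discordant = integer(),
      label = character(), no_T = logical(), n_reads = integer()),
      discarded = data.table::data.table(barcode = character(),
                                         umi = character(),
                                         n_genes = integer(),
                                         n_reads = integer())))

  # deduplicate identical read records
  sig <- paste(dt$barcode, dt$umi, dt$gene_id, join_pos(dt$covered),
               join_pos(dt$converted), join_pos(dt$other), sep = "|")
  dt <- dt[!duplicated(sig)]

  # discard gene-ambiguous (barcode, umi) keys
  amb <- dt[, .(n_genes = data.table::uniqueN(gene_id), n_reads = .N),
            by = .(barcode, umi)][n_genes > 1L]
  if (nrow(amb)) dt <- dt[!amb, on = c("barcode", "umi")]

  dt[, key_id := .GRP, by = .(barcode, umi, gene_id)]
  keys <- dt[, .(barcode = barcode[1L], umi = umi[1L], gene_id = gene_id[1L],
                 n_reads = .N), by = key_id]

  nc <- lengths(dt$covered)
  long <- data.table::data.table(
    key_id = rep(dt$key_id, nc),
    gene_id = rep(dt$gene_id, nc),
    read_row = rep(seq_len(nrow(dt)), nc),
    pos = unlist(dt$covered, use.names = FALSE))
  conv_tok <- unlist(Map(function(i, p) if (length(p)) paste(i, p),
                         seq_len(nrow(dt)), dt$converted), use.names = FALSE)
  oth_tok <- unlist(Map(function(i, p) if (length(p)) paste(i, p),
                        seq_len(nrow(dt)), dt$other), use.names = FALSE)
  tok <- paste(long$read_row, long$pos)
  long[, is_conv := tok %in% conv_tok]
  long[, is_oth := tok %in% oth_tok]
  bad <- setdiff(conv_tok, tok)
  if (length(bad))
    stop("data error: converted position not among covered positions",
         call. = FALSE)

  pos_stat <- long[, .(any_conv = any(is_conv),
                       any_reft = any(!is_conv & !is_oth)),
                   by = .(key_id, gene_id, pos)]
  pos_stat[, discordant := any_conv & any_reft]
  if (!is.null(mask) && length(mask)) {
    pos_stat[, masked := paste(gene_id, pos) %chin% mask$tokens]
  } else pos_stat[, masked := FALSE]

  stat <- pos_stat[, .(
    n_T = sum(!masked & !discordant),
    n_conv = sum(any_conv & !masked & !discordant),
    n_discordant = sum(discordant)), by = key_id]
  calls <- keys[stat, on = "key_id"]
  calls[, `:=`(label = ifelse(n_conv >= 1L, "nascent", "old"),
               no_T = n_T == 0L, key_id = NULL)]
  data.table::setcolorder(calls, c("barcode", "umi", "gene_id", "n_T",
                                   "n_conv", "n_discordant", "label", "no_T",
                                   "n_reads"))
  data.table::setorder(calls, barcode, umi, gene_id)
  list(calls = calls[],
       discarded = if (nrow(amb)) amb[] else
         data.table::data.table(barcode = character(), umi = character(),
                                n_genes = integer(), n_reads = integer()))
}

#' Layered gene-by-cell count matrix
#'
#' The interchange container between quantification and kinetics: sparse
#' gene x cell integer matrices named `nascent`, `old` and `total`, with
#' `nascent + old == total` elementwise.
#'
#' @param nascent,old Gene x cell sparse (or dense) non-negative integer
#'   matrices with identical dimnames.
#' @param total Optional; computed as `nascent + old` when missing and
#'   validated otherwise.
#' @return An object of class `layered_counts` with elements `genes`, `cells`
#'   and `layers` (named list).
#' @export
layered_counts <- function(nascent, old, total = NULL) {
  nascent <- methods::as(nascent, "CsparseMatrix")
  old <- methods::as(old, "CsparseMatrix")
  if (!identical(dim(nascent), dim(old)) ||
      !identical(dimnames(nascent), dimnames(old)))
    stop("'nascent' and 'old' must have identical dims and dimnames",
         call. = FALSE)
  if (any(nascent@x < 0) || any(old@x < 0))
    stop("layer entries must be non-negative", call. = FALSE)
  tot <- nascent + old
  if (!is.null(total)) {
    total <- methods::as(total, "CsparseMatrix")
    if (max(abs(total - tot)) > 0)
      stop("'total' must equal nascent + old elementwise", call. = FALSE)
  }
  structure(list(genes = rownames(nascent), cells = colnames(nascent),
                 layers = list(nascent = nascent, old = old, total = tot)),
            class = "layered_counts")
}

#' @export
print.layered_counts <- function(x, ...) {
  cat(sprintf("layered_counts: %d genes x %d cells; %s nascent / %s old molecules\n",
              length(x$genes), length(x$cells),
              format(sum(x$layers$nascent)), format(sum(x$layers$old))))
  invisible(x)
}

#' @export
dim.layered_counts <- function(x) c(length(x$genes), length(x$cells))

#' Aggregate molecule calls into a layered count matrix
#'
#' @param calls Molecule-call `data.table` (see [classify_molecules()]).
#' @param cells,genes Ordered barcode and gene identifier vectors defining the
#'   matrix axes.
#' @param on_unknown `"drop"` (default) drops calls referencing unknown
#'   barcodes or genes and tallies them in the discard report; `"error"`
#'   fails.
#' @return A [layered_counts()] object; the discard report is attached as
#'   `attr(x, "discarded")` (a list with counts).
#' @export
build_layered_matrix <- function(calls, cells, genes,
                                 on_unknown = c("drop", "error")) {
  on_unknown <- match.arg(on_unknown)
  calls <- data.table::as.data.table(calls)
  gi <- match(calls$gene_id, genes)
  ci <- match(calls$barcode, cells)
  unknown <- is.na(gi) | is.na(ci)
  if (any(unknown) && on_unknown == "error")
    stop(sprintf("%d molecule call(s) reference unknown barcode or gene",
                 sum(unknown)), call. = FALSE)
  keep <- !unknown
  mk <- function(sel) {
    i <- gi[keep & sel]; j <- ci[keep & sel]
    Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                         dims = c(length(genes), length(cells)),
                         dimnames = list(genes, cells))
  }
  out <- layered_counts(mk(calls$label == "nascent"), mk(calls$label == "old"))
  attr(out, "discarded") <- list(unknown_key = sum(unknown))
  out
}
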