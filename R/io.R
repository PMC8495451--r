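# Readers and writers for the plain-text interchange formats.
#
# Internal convention: all genomic coordinates are 0-based half-open; VCF
# (1-based) and SAM (1-based) are converted at this boundary, BED passes
# through. TSV outputs use '.' decimals, tab separators, Unix newlines and
# always carry a header, so outputs are byte-stable across reruns.

fwrite_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, eol = "\n",
                     na = "NA")
}

#' Write a read-observation table as TSV
#'
#' Position list-columns are comma-joined (`covered_T_positions`,
#' `converted_positions`, `other_mismatch_positions`).
#'
#' @param reads Read table with list-columns `covered`, `converted`, `other`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_read_table <- function(reads, path) {
  dt <- data.table::data.table(
    barcode = reads$barcode, umi = reads$umi, gene_id = reads$gene_id,
    covered_T_positions = join_pos(reads$covered),
    converted_positions = join_pos(reads$converted),
    other_mismatch_positions = join_pos(reads$other))
  fwrite_tsv(dt, path)
  invisible(path)
}

#' Read a read-observation TSV
#'
#' @param path TSV written by [write_read_table()].
#' @return `data.table` with position list-columns `covered`, `converted`,
#'   `other`.
#' @export
read_read_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("barcode", "umi", "gene_id", "covered_T_positions",
                  "converted_positions", "other_mismatch_positions")))
  data.table::data.table(
    barcode = dt$barcode, umi = dt$umi, gene_id = dt$gene_id,
    covered = split_pos(dt$covered_T_positions),
    converted = split_pos(dt$converted_positions),
    other = split_pos(dt$other_mismatch_positions))
}

#' Read a minimal VCF
#'
#' Header lines beginning with `#` are ignored; each record needs at least
#' the 8 standard columns. Positions are converted to the internal 0-based
#' frame. Malformed lines raise an error naming the line number.
#'
#' @param vcf File path or character vector of VCF lines.
#' @return `data.table` with `chrom`, `pos` (0-based), `id`, `ref`, `alt`.
#' @export
read_vcf_min <- function(vcf) {
  lines <- if (length(vcf) == 1L && file.exists(vcf)) readLines(vcf) else vcf
  is_rec <- !startsWith(lines, "#") & nzchar(lines)
  recs <- lines[is_rec]
  lineno <- which(is_rec)
  if (!length(recs))
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  id = character(), ref = character(),
                                  alt = character()))
  parts <- strsplit(recs, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8L)
  if (length(bad))
    stop(sprintf("malformed VCF line %d: expected >= 8 tab-separated fields",
                 lineno[bad[1L]]), call. = FALSE)
  pos1 <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(pos1))
    stop(sprintf("malformed VCF line %d: POS is not an integer",
                 lineno[which(is.na(pos1))[1L]]), call. = FALSE)
  data.table::data.table(
    chrom = vapply(parts, `[[`, character(1), 1L), pos = pos1 - 1L,
    id = vapply(parts, `[[`, character(1), 3L),
    ref = vapply(parts, `[[`, character(1), 4L),
    alt = vapply(parts, `[[`, character(1), 5L))
}

#' Write a minimal VCF
#'
#' @param snps `data.table` with `chrom`, `pos_global` (0-based; or `pos`)
#'   and optionally `ref`, `alt`, `id`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf_min <- function(snps, path) {
  snps <- data.table::as.data.table(snps)
  pos0 <- if ("pos_global" %in% names(snps)) snps$pos_global else snps$pos
  dt <- data.table::data.table(
    chrom = snps$chrom, pos = as.integer(pos0) + 1L,
    id = if ("id" %in% names(snps)) snps$id else ".",
    ref = if ("ref" %in% names(snps)) snps$ref else "N",
    alt = if ("alt" %in% names(snps)) snps$alt else "N")
  data.table::setorder(dt, chrom, pos)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       dt$chrom, dt$pos, dt$id, dt$ref, dt$alt)), con)
  invisible(path)
}

#' Read a BED gene-coordinate table
#'
#' @param path BED file with columns chrom, start, end, name and optionally
#'   score and strand.
#' @return `data.table` with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 4L) stop("BED needs >= 4 columns", call. = FALSE)
  data.table::data.table(
    gene_id = as.character(dt[[4L]]), chrom = as.character(dt[[1L]]),
    start = as.integer(dt[[2L]]), end = as.integer(dt[[3L]]),
    strand = if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "+")
}

#' Write a BED gene-coordinate table
#'
#' @param coords `data.table` with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(coords, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%s\t.\t%s", coords$chrom,
                     as.integer(coords$start), as.integer(coords$end),
                     coords$gene_id, coords$strand), con)
  invisible(path)
}

# -- MatrixMarket coordinate I/O ---------------------------------------------

write_mtx <- function(m, path) {
  m <- methods::as(m, "TsparseMatrix")
  integer_valued <- all(m@x == round(m@x))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("%%%%MatrixMarket matrix coordinate %s general",
                       if (integer_valued) "integer" else "real"),
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  o <- order(m@j, m@i)
  val <- if (integer_valued) format(as.integer(m@x[o]), scientific = FALSE)
  else format(m@x[o], digits = 15)
  writeLines(sprintf("%d %d %s", m@i[o] + 1L, m@j[o] + 1L, trimws(val)), con)
  invisible(path)
}

read_mtx <- function(path) {
  lines <- readLines(path, n = 1L)
  if (!grepl("^%%MatrixMarket matrix coordinate (integer|real) general",
             lines))
    stop("unsupported MatrixMarket header in ", path, call. = FALSE)
  body <- data.table::fread(path, skip = 1L, header = FALSE,
                            colClasses = "numeric",
                            col.names = c("i", "j", "x")[1:3])
  dims <- as.integer(body[1L, 1:2, with = FALSE])
  nnz <- as.integer(body[[3L]][1L])
  ent <- body[-1L]
  if (nrow(ent) != nnz)
    stop(sprintf("MTX %s declares %d entries but has %d", path, nnz,
                 nrow(ent)), call. = FALSE)
  bad <- which(ent$i < 1 | ent$i > dims[1] | ent$j < 1 | ent$j > dims[2])
  if (length(bad))
    stop(sprintf("MTX %s: entry %d has out-of-range index (%d, %d) for %d x %d matrix",
                 path, bad[1L], as.integer(ent$i[bad[1L]]),
                 as.integer(ent$j[bad[1L]]), dims[1], dims[2]),
         call. = FALSE)
  Matrix::sparseMatrix(i = as.integer(ent$i), j = as.integer(ent$j),
                       x = ent$x, dims = dims)
}

#' Write a layered count matrix as a MatrixMarket directory
#'
#' Writes `nascent.mtx`, `old.mtx`, `total.mtx`, `barcodes.tsv` and
#' `features.tsv`.
#'
#' @param x A [layered_counts()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_layered_matrix <- function(x, dir) {
  stopifnot(inherits(x, "layered_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ly in names(x$layers))
    write_mtx(x$layers[[ly]], file.path(dir, paste0(ly, ".mtx")))
  con <- file(file.path(dir, "barcodes.tsv"), "wb")
  writeLines(x$cells, con); close(con)
  con <- file(file.path(dir, "features.tsv"), "wb")
  writeLines(x$genes, con); close(con)
  invisible(dir)
}

#' Read a layered count matrix from a MatrixMarket directory
#'
#' @param dir Directory with `nascent.mtx`, `old.mtx` (optionally
#'   `total.mtx`), `barcodes.tsv` and `features.tsv`.
#' @return A [layered_counts()] object.
#' @export
read_layered_matrix <- function(dir) {
  need <- c("nascent.mtx", "old.mtx", "barcodes.tsv", "features.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("missing layer files in ", dir, ": ", paste(miss, collapse = ", "),
         "; expected layers nascent, old (optionally total)", call. = FALSE)
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- readLines(file.path(dir, "features.tsv"))
  rd <- function(f) {
    m <- read_mtx(file.path(dir, f))
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop(sprintf("%s is %d x %d but sidecars declare %d genes x %d cells",
                   f, nrow(m), ncol(m), length(genes), length(cells)),
           call. = FALSE)
    dimnames(m) <- list(genes, cells)
    m
  }
  tot <- if (file.exists(file.path(dir, "total.mtx"))) rd("total.mtx")
  layered_counts(rd("nascent.mtx"), rd("old.mtx"), total = tot)
}

# -- SAM text dialect ---------------------------------------------------------

# global (1-based) <-> gene-local 0-based transcript coordinates
to_global1 <- function(local, g) {
  if (g$strand == "-") g$end - local else g$start + local + 1L
}
to_local0 <- function(global1, g) {
  if (g$strand == "-") g$end - global1 else global1 - 1L - g$start
}

#' Write read observations as a SAM text dialect
#'
#' One record per read: mapped position is the smallest covered global
#' coordinate, CIGAR the covered reference span (`M`), SEQ/QUAL are `*`.
#' Tags: `CB:Z` barcode, `UB:Z` UMI, `GX:Z` gene, `TP:Z` covered
#' sense-strand T positions (1-based reference-forward, comma-joined) and
#' `XC:Z` mismatches as `pos:ref>alt`. For minus-strand genes the T-to-C
#' event appears as A>G on the reference-forward strand.
#'
#' @param reads Read table (list-columns `covered`, `converted`, `other`).
#' @param genes Gene coordinate table (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam_dialect <- function(reads, genes, path) {
  genes <- data.table::as.data.table(genes)
  gl <- split(genes, by = "gene_id")
  chroms <- genes[, .(len = max(end) + 1000L), by = chrom]
  out <- character(nrow(reads))
  for (r in seq_len(nrow(reads))) {
    g <- gl[[reads$gene_id[r]]]
    cov <- sort(to_global1(reads$covered[[r]], g))
    conv <- sort(to_global1(reads$converted[[r]], g))
    oth <- sort(to_global1(reads$other[[r]], g))
    plus <- g$strand == "+"
    pos <- if (length(cov)) min(cov) else g$start + 1L
    span <- if (length(cov)) max(cov) - pos + 1L else 1L
    mism <- c(
      if (length(conv)) sprintf("%d:%s>%s", conv, if (plus) "T" else "A",
                                if (plus) "C" else "G"),
      if (length(oth)) sprintf("%d:%s>%s", oth, if (plus) "T" else "A",
                               if (plus) "G" else "C"))
    tags <- c(sprintf("CB:Z:%s", reads$barcode[r]),
              sprintf("UB:Z:%s", reads$umi[r]),
              sprintf("GX:Z:%s", reads$gene_id[r]),
              sprintf("TP:Z:%s", paste(cov, collapse = ",")),
              sprintf("XC:Z:%s",
                      if (length(mism)) paste(mism, collapse = ",") else "."))
    out[r] <- paste(c(sprintf("read%06d", r), if (plus) "0" else "16",
                      g$chrom, pos, "255", sprintf("%dM", span), "*", "0",
                      "0", "*", "*", tags), collapse = "\t")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chroms$chrom, chroms$len),
               out), con)
  invisible(path)
}

parse_sam_tag <- function(fields, tag) {
  hit <- fields[startsWith(fields, paste0(tag, ":"))]
  if (!length(hit)) return(NA_character_)
  sub("^..:.:", "", hit[1L])
}

# mismatches (1-based global pos, ref, alt) from MD:Z + CIGAR + SEQ
md_mismatches <- function(pos1, cigar, md, seq) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  lens <- as.integer(sub("[A-Z=]", "", ops))
  type <- sub("\\d+", "", ops)
  # map aligned (M/=/X) read offsets to reference positions
  ref <- pos1; rdo <- 1L
  ref_of_read <- integer(0); read_idx <- integer(0)
  for (i in seq_along(ops)) {
    if (type[i] %in% c("M", "=", "X")) {
      ref_of_read <- c(ref_of_read, ref + seq_len(lens[i]) - 1L)
      read_idx <- c(read_idx, rdo + seq_len(lens[i]) - 1L)
      ref <- ref + lens[i]; rdo <- rdo + lens[i]
    } else if (type[i] %in% c("D", "N")) ref <- ref + lens[i]
    else if (type[i] %in% c("I", "S")) rdo <- rdo + lens[i]
  }
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1L]]
  ai <- 0L  # index into aligned bases
  res <- list()
  for (tk in toks) {
    if (grepl("^\\d+$", tk)) ai <- ai + as.integer(tk)
    else if (startsWith(tk, "^")) next  # deletion: ref consumed, not aligned
    else {
      ai <- ai + 1L
      res[[length(res) + 1L]] <- data.table::data.table(
        pos = ref_of_read[ai], ref = tk,
        alt = if (!is.null(seq) && seq != "*")
          substr(seq, read_idx[ai], read_idx[ai]) else "N")
    }
  }
  if (length(res)) data.table::rbindlist(res) else
    data.table::data.table(pos = integer(), ref = character(),
                           alt = character())
}

#' Read the SAM text dialect into a read-observation table
#'
#' Records need `CB:Z` and `UB:Z` tags, mismatch information (`XC:Z` as
#' `pos:ref>alt` comma-joined, or `MD:Z` + CIGAR + SEQ) and a `TP:Z` tag
#' listing covered sense-strand T positions (the dialect carries these
#' because no reference FASTA is consumed). Unmapped, secondary and
#' supplementary records are skipped with counts, as are records lacking
#' required tags; more than `max_skip_frac` skipped records is an error.
#' Conversions are evaluated on the transcribed strand: for minus-strand
#' genes the reference-forward A>G mismatch is the T-to-C event.
#'
#' @param path SAM file.
#' @param gene_coords Gene coordinate table (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`); used to resolve records without a `GX:Z` tag by
#'   overlap and to transform to gene-local coordinates.
#' @param max_skip_frac Hard-error threshold on the skipped-record fraction.
#' @return Read table `data.table` (as [read_read_table()]) with the skip
#'   report in `attr(, "skipped")`.
#' @export
read_sam_dialect <- function(path, gene_coords, max_skip_frac = 0.1) {
  genes <- data.table::as.data.table(gene_coords)
  gl <- split(genes, by = "gene_id")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  skipped <- c(flag = 0L, missing_tag = 0L, no_gene = 0L)
  rows <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 0x4L) > 0L || bitwAnd(flag, 0x100L) > 0L ||
        bitwAnd(flag, 0x800L) > 0L) {
      skipped["flag"] <- skipped["flag"] + 1L
      next
    }
    tags <- f[12:length(f)]
    cb <- parse_sam_tag(tags, "CB"); ub <- parse_sam_tag(tags, "UB")
    tp <- parse_sam_tag(tags, "TP")
    xc <- parse_sam_tag(tags, "XC"); md <- parse_sam_tag(tags, "MD")
    if (is.na(cb) || is.na(ub) || is.na(tp) || (is.na(xc) && is.na(md))) {
      skipped["missing_tag"] <- skipped["missing_tag"] + 1L
      next
    }
    pos1 <- as.integer(f[4L])
    gx <- parse_sam_tag(tags, "GX")
    g <- if (!is.na(gx)) gl[[gx]] else {
      hit <- genes[chrom == f[3L] & start < pos1 & pos1 <= end]
      if (nrow(hit)) gl[[hit$gene_id[1L]]] else NULL
    }
    if (is.null(g)) {
      skipped["no_gene"] <- skipped["no_gene"] + 1L
      next
    }
    cov_g <- as.integer(strsplit(tp, ",", fixed = TRUE)[[1L]])
    if (!is.na(xc) && xc == ".") xc <- ""
    mism <- if (!is.na(xc)) {
      if (nzchar(xc)) {
        parts <- strsplit(strsplit(xc, ",", fixed = TRUE)[[1L]], "[:>]")
        data.table::data.table(
          pos = as.integer(vapply(parts, `[[`, character(1), 1L)),
          ref = vapply(parts, `[[`, character(1), 2L),
          alt = vapply(parts, `[[`, character(1), 3L))
      } else data.table::data.table(pos = integer(), ref = character(),
                                    alt = character())
    } else md_mismatches(pos1, f[6L], md, f[10L])
    plus <- g$strand == "+"
    is_conv <- if (plus) mism$ref == "T" & mism$alt == "C"
    else mism$ref == "A" & mism$alt == "G"
    conv_g <- mism$pos[is_conv]
    oth_g <- intersect(mism$pos[!is_conv], cov_g)
    rows[[li]] <- data.table::data.table(
      barcode = cb, umi = ub, gene_id = g$gene_id,
      covered = list(sort(to_local0(cov_g, g))),
      converted = list(sort(to_local0(conv_g, g))),
      other = list(sort(to_local0(oth_g, g))))
  }
  n_skip <- sum(skipped)
  if (length(lines) && n_skip / length(lines) > max_skip_frac)
    stop(sprintf("%d of %d SAM records skipped (> %.0f%%)", n_skip,
                 length(lines), 100 * max_skip_frac), call. = FALSE)
  out <- data.table::rbindlist(rows)
  if (!nrow(out))
    out <- data.table::data.table(barcode = character(), umi = character(),
                                  gene_id = character(), covered = list(),
                                  converted = list(), other = list())
  data.table::setattr(out, "skipped", skipped)
  out[]
}
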