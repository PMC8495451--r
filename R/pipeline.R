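# Stage-keyed pipeline configuration, run log, and the subcommand CLI.

default_config <- function() {
  list(
    seed = 1L,
    out = "slamtraj_out",
    simulate = list(
      reads = list(n_genes = 40L, n_cells = 30L, mean_molecules_per_cell = 80,
                   mean_reads_per_molecule = 2, labeled_fraction = 0.25,
                   conversion_rate = 0.02, error_rate = 1e-3,
                   mean_T_per_read = 20, snp_density = 1e-3,
                   read_coverage = 0.8),
      kinetics = list(n_genes = 60L, n_cells = 200L, noise = "poisson",
                      one_sided_fraction = 0.2, t_max = 10),
      clones = list(n_genes = 300L, n_chromosomes = 3L, n_normal_cells = 60L,
                    clone_cells = 40L, shift = 0.8, segment_frac = 0.2,
                    noise_sd = 0.15),
      conditions = list(n_conditions = 3L, n_cells_per_condition = 150L,
                        separation = 2, dim = 3L)
    ),
    filter = list(min_genes = 1, max_genes = 1e9, mito_range = c(0, 1)),
    hvg = list(n = 2000L),
    moments = list(n_pcs = 30L, k = 30L),
    kinetics = list(min_shared = 20L, lambda = NULL, theta = 0.5,
                    n_root_cells = 20L),
    scna = list(window = 101L, k = 2L, clip = 3),
    similarity = list(k = 30L, metric = "composition"),
    gradient = list(n_bins = 40L, head_fraction = 0.25, scheme = "quantile")
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown config key: ", full, call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key ", full, " must be a section", call. = FALSE)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    } else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected before any stage runs; the resolved
#' configuration (defaults applied) is written next to every pipeline output.
#'
#' @param config Named list of overrides, or a path to a JSON config file.
#' @return The resolved configuration (class `pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (inherits(config, "pipeline_config")) return(config)
  cfg <- merge_config(default_config(), config)
  structure(cfg, class = "pipeline_config")
}

new_run_log <- function() {
  env <- new.env()
  env$events <- list()
  env
}

log_event <- function(log, stage, event, ...) {
  if (is.null(log)) return(invisible(NULL))
  info <- list(...)
  log$events[[length(log$events) + 1L]] <- sprintf(
    "%s\t%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, event,
    paste(names(info), vapply(info, function(x) paste(format(x), collapse = ","),
                              character(1)), sep = "=", collapse = ";"))
  invisible(NULL)
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes simulate, quantify, preprocess, velocity, scna, similarity and
#' gradient stages as configured, writing every stage's TSV/MTX outputs, the
#' resolved config and a run log into the output directory. Later stages
#' read earlier stages' files from disk, so stages can also be (re)run
#' individually. A fixed `seed` makes the result artifacts byte-identical
#' across reruns (the run log carries wall-clock timestamps and is excluded
#' from that contract).
#'
#' @param config A [pipeline_config()], override list, or JSON path.
#' @param stages Stages to run (default: all, in order).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "quantify", "preprocess",
                                    "velocity", "scna", "similarity",
                                    "gradient")) {
  cfg <- pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out <- cfg$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(cfg), file.path(out, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  log <- new_run_log()
  runner <- list(simulate = stage_simulate, quantify = stage_quantify,
                 preprocess = stage_preprocess, velocity = stage_velocity,
                 scna = stage_scna, similarity = stage_similarity,
                 gradient = stage_gradient)
  for (st in stages) {
    ok <- tryCatch({ runner[[st]](cfg, out, log); TRUE },
                   error = function(e) {
                     log_event(log, st, "error", message = conditionMessage(e))
                     writeLines(unlist(log$events), file.path(out, "run_log.txt"))
                     stop(sprintf("stage '%s' failed: %s", st,
                                  conditionMessage(e)), call. = FALSE)
                   })
  }
  writeLines(unlist(log$events), file.path(out, "run_log.txt"))
  invisible(out)
}

stage_simulate <- function(cfg, out, log) {
  d <- file.path(out, "sim")
  dir.create(d, showWarnings = FALSE)
  sc <- cfg$simulate
  rs <- do.call(read_sim_config, c(sc$reads, list(seed = cfg$seed)))
  sim <- simulate_reads(rs)
  write_read_table(sim$reads, file.path(d, "reads.tsv"))
  write_vcf_min(sim$snps, file.path(d, "snps.vcf"))
  write_bed(sim$genes, file.path(d, "genes.bed"))
  fwrite_tsv(sim$truth, file.path(d, "molecule_truth.tsv"))
  log_event(log, "simulate", "reads", n_reads = nrow(sim$reads),
            n_molecules = nrow(sim$truth), seed = cfg$seed)

  ks <- do.call(kinetic_sim_config, c(sc$kinetics, list(seed = cfg$seed + 1L)))
  kin <- simulate_kinetic_population(ks)
  write_layered_matrix(kin$counts, file.path(d, "kinetic_counts"))
  fwrite_tsv(data.table::data.table(barcode = names(kin$truth_time),
                                    t_true = kin$truth_time),
             file.path(d, "kinetic_truth_time.tsv"))
  fwrite_tsv(kin$truth_params, file.path(d, "kinetic_truth_params.tsv"))
  log_event(log, "simulate", "kinetics", n_genes = ks$n_genes,
            n_cells = ks$n_cells)

  cc <- sc$clones
  per_chrom <- cc$n_genes %/% cc$n_chromosomes
  seg_len <- max(1L, as.integer(round(cc$segment_frac * per_chrom)))
  cs <- clone_sim_config(
    n_genes = cc$n_genes, n_chromosomes = cc$n_chromosomes,
    n_normal_cells = cc$n_normal_cells,
    clones = list(
      list(n_cells = cc$clone_cells,
           segments = data.frame(chrom = "chr1", start = 1L, end = seg_len,
                                 shift = 0)),
      list(n_cells = cc$clone_cells,
           segments = data.frame(chrom = "chr1", start = 1L, end = seg_len,
                                 shift = cc$shift))),
    noise_sd = cc$noise_sd, seed = cfg$seed + 2L)
  cl <- simulate_clone_expression(cs)
  fwrite_tsv(data.table::as.data.table(cl$expr, keep.rownames = "gene_id"),
             file.path(d, "clone_expr.tsv"))
  write_bed(cl$coords, file.path(d, "clone_genes.bed"))
  fwrite_tsv(data.table::data.table(barcode = names(cl$labels),
                                    clone = cl$labels, normal = cl$normal),
             file.path(d, "clone_labels.tsv"))
  log_event(log, "simulate", "clones", n_cells = length(cl$labels))

  cd <- sc$conditions
  cond <- simulate_condition_dataset(cd$n_conditions, cd$n_cells_per_condition,
                                     cd$separation, cd$dim,
                                     seed = cfg$seed + 3L)
  emb <- data.table::as.data.table(cond$embedding, keep.rownames = "barcode")
  emb[, condition := as.character(cond$labels)]
  fwrite_tsv(emb, file.path(d, "condition_embedding.tsv"))
  log_event(log, "simulate", "conditions", n_cells = nrow(emb))
  invisible(d)
}

stage_quantify <- function(cfg, out, log) {
  d <- file.path(out, "quant")
  dir.create(d, showWarnings = FALSE)
  sim_d <- file.path(out, "sim")
  reads <- read_read_table(file.path(sim_d, "reads.tsv"))
  genes <- read_bed(file.path(sim_d, "genes.bed"))
  mask <- parse_snp_mask(file.path(sim_d, "snps.vcf"), coords = genes)
  cls <- classify_molecules(reads, mask)
  cells <- sort(unique(reads$barcode))
  lcm <- build_layered_matrix(cls$calls, cells, genes$gene_id)
  write_layered_matrix(lcm, file.path(d, "layers"))
  fwrite_tsv(cls$calls, file.path(d, "molecule_audit.tsv"))
  fwrite_tsv(cls$discarded, file.path(d, "discard_report.tsv"))
  log_event(log, "quantify", "classified", n_molecules = nrow(cls$calls),
            n_nascent = sum(cls$calls$label == "nascent"),
            n_ambiguous = nrow(cls$discarded), mask_size = length(mask))
  invisible(d)
}

stage_preprocess <- function(cfg, out, log) {
  d <- file.path(out, "preprocess")
  dir.create(d, showWarnings = FALSE)
  lcm <- read_layered_matrix(file.path(out, "sim", "kinetic_counts"))
  fc <- cell_filter_config(cfg$filter$min_genes, cfg$filter$max_genes,
                           cfg$filter$mito_range[1], cfg$filter$mito_range[2])
  filt <- filter_cells(lcm, cfg = fc)
  log_event(log, "preprocess", "filter", n_in = length(lcm$cells),
            n_out = length(filt$cells))
  norm <- normalize_log(filt)
  hvg <- select_hvg(norm, n = min(cfg$hvg$n, nrow(norm)))
  writeLines(hvg, file.path(d, "hvg.txt"))
  mom <- compute_moments(filt, n_pcs = cfg$moments$n_pcs, k = cfg$moments$k)
  md <- file.path(d, "moments")
  dir.create(md, showWarnings = FALSE)
  for (ly in names(mom[[1L]]$moments))
    write_mtx(methods::as(mom[[1L]]$moments[[ly]], "CsparseMatrix"),
              file.path(md, paste0(ly, ".mtx")))
  con <- file(file.path(md, "barcodes.tsv"), "wb")
  writeLines(mom[[1L]]$cells, con); close(con)
  con <- file(file.path(md, "features.tsv"), "wb")
  writeLines(filt$genes, con); close(con)
  log_event(log, "preprocess", "moments", k = cfg$moments$k,
            n_pcs = cfg$moments$n_pcs)
  invisible(d)
}

stage_velocity <- function(cfg, out, log) {
  d <- file.path(out, "velocity")
  dir.create(d, showWarnings = FALSE)
  md <- file.path(out, "preprocess", "moments")
  cells <- readLines(file.path(md, "barcodes.tsv"))
  genes <- readLines(file.path(md, "features.tsv"))
  u <- as.matrix(read_mtx(file.path(md, "nascent.mtx")))
  s <- as.matrix(read_mtx(file.path(md, "old.mtx")))
  dimnames(u) <- dimnames(s) <- list(genes, cells)
  # root prior: cells with the highest nascent fraction (transcriptionally
  # youngest) act as the asserted origin
  nf <- colSums(u) / pmax(colSums(u) + colSums(s), 1e-12)
  root <- root_prior(cells[order(-nf)][seq_len(min(cfg$kinetics$n_root_cells,
                                                   length(cells)))],
                     lambda = cfg$kinetics$lambda, theta = cfg$kinetics$theta)
  fits <- fit_kinetics(u, s, cells, min_shared = cfg$kinetics$min_shared,
                       root = root)
  tau <- compute_latent_time(fits)
  fwrite_tsv(fits$genes, file.path(d, "gene_kinetics.tsv"))
  fwrite_tsv(data.table::data.table(
    barcode = cells, latent_time = as.numeric(tau),
    n_informative_genes = nrow(fits$genes)), file.path(d, "latent_time.tsv"))
  vel <- do.call(rbind, lapply(fits$genes$gene_id, function(g)
    compute_velocity(fits$fits[[g]], u[g, ], s[g, ])))
  dimnames(vel) <- list(fits$genes$gene_id, cells)
  write_mtx(methods::as(vel, "CsparseMatrix"), file.path(d, "velocity.mtx"))
  nb <- knn_neighbors(t(s[fits$genes$gene_id, , drop = FALSE]),
                      k = min(10L, length(cells) - 1L))
  vg <- velocity_graph(vel, s[fits$genes$gene_id, , drop = FALSE], nb)
  fwrite_tsv(vg, file.path(d, "velocity_graph.tsv"))
  log_event(log, "velocity", "fitted", n_genes = nrow(fits$genes),
            n_one_sided = sum(fits$genes$one_sided))
  invisible(d)
}

stage_scna <- function(cfg, out, log) {
  d <- file.path(out, "scna")
  dir.create(d, showWarnings = FALSE)
  sim_d <- file.path(out, "sim")
  expr_dt <- data.table::fread(file.path(sim_d, "clone_expr.tsv"))
  expr <- as.matrix(expr_dt[, -1L]); rownames(expr) <- expr_dt$gene_id
  coords <- read_bed(file.path(sim_d, "clone_genes.bed"))
  lab <- data.table::fread(file.path(sim_d, "clone_labels.tsv"))
  normal_cells <- lab$barcode[lab$normal]
  tumor_cells <- lab$barcode[!lab$normal]
  sp <- smooth_genomic_expression(expr, coords, normal_cells,
                                  window = cfg$scna$window,
                                  clip = cfg$scna$clip)
  cut <- cluster_clones(sp$profiles[, tumor_cells, drop = FALSE],
                        k = cfg$scna$k)
  scores <- scna_score(sp$profiles[, tumor_cells, drop = FALSE],
                       cut$assignment, sp$profiles[, normal_cells,
                                                   drop = FALSE])
  # each normal half acts as one observed normal sample for the call
  half <- split(normal_cells,
                rep(1:2, length.out = length(normal_cells)))
  normal_scores <- vapply(half, function(cc)
    scna_score(sp$profiles[, cc, drop = FALSE],
               rep("n", length(cc)),
               sp$profiles[, normal_cells, drop = FALSE])$score, numeric(1))
  scores[, aberrant := call_aberrant(score, normal_scores)]
  fwrite_tsv(data.table::data.table(barcode = tumor_cells,
                                    clone = cut$assignment[tumor_cells]),
             file.path(d, "clones.tsv"))
  fwrite_tsv(scores, file.path(d, "clone_scores.tsv"))
  log_event(log, "scna", "scored", n_clones = nrow(scores),
            n_aberrant = sum(scores$aberrant))
  invisible(d)
}

stage_similarity <- function(cfg, out, log) {
  d <- file.path(out, "similarity")
  dir.create(d, showWarnings = FALSE)
  emb <- data.table::fread(file.path(out, "sim", "condition_embedding.tsv"))
  coords <- as.matrix(emb[, setdiff(names(emb), c("barcode", "condition")),
                          with = FALSE])
  S <- condition_similarity(coords, emb$condition,
                            metric = cfg$similarity$metric,
                            k = cfg$similarity$k)
  fwrite_tsv(data.table::as.data.table(unclass(S)[,], keep.rownames = "condition"),
             file.path(d, "similarity.tsv"))
  hc <- cluster_conditions(S)
  fwrite_tsv(data.table::data.table(merge1 = hc$merge[, 1L],
                                    merge2 = hc$merge[, 2L],
                                    height = hc$height),
             file.path(d, "linkage.tsv"))
  log_event(log, "similarity", "computed", k = cfg$similarity$k)
  invisible(d)
}

stage_gradient <- function(cfg, out, log) {
  d <- file.path(out, "gradient")
  dir.create(d, showWarnings = FALSE)
  emb <- data.table::fread(file.path(out, "sim", "condition_embedding.tsv"))
  # the first embedding axis is the demo gradient; conditions are the states
  scores <- stats::setNames(emb$V1, emb$barcode)
  states <- stats::setNames(emb$condition, emb$barcode)
  bins <- assign_bins(scores, n_bins = cfg$gradient$n_bins,
                      scheme = cfg$gradient$scheme)
  bt <- state_distribution(bins, states)
  fwrite_tsv(data.table::as.data.table(bt$fractions, keep.rownames = "bin"),
             file.path(d, "bin_fractions.tsv"))
  stat <- data.table::rbindlist(lapply(colnames(bt$fractions), function(st) {
    gc <- gradient_correlation(bt, st)
    data.table::data.table(state = st, r = gc$r, t = gc$t, p = gc$p)
  }))
  enr <- state_enrichment_test(bt, head_fraction = cfg$gradient$head_fraction)
  fwrite_tsv(stat[enr, on = "state"], file.path(d, "gradient_stats.tsv"))
  log_event(log, "gradient", "computed", n_bins = cfg$gradient$n_bins)
  invisible(d)
}

#' Command-line interface
#'
#' Subcommands `simulate`, `quantify`, `preprocess`, `velocity`, `scna`,
#' `similarity`, `gradient` and `run` (end-to-end), with flags `--config
#' <json>`, `--seed <int>`, `--out <dir>`, `--threads <n>` and `--log-level
#' <level>`.
#'
#' @param args Character vector of arguments (defaults to the command line).
#' @return The output directory, invisibly.
#' @export
slamtraj_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: slamtraj <simulate|quantify|preprocess|velocity|scna|",
         "similarity|gradient|run> [--config FILE] [--seed N] [--out DIR]",
         call. = FALSE)
  sub <- args[1L]
  args <- args[-1L]
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--[a-z-]+=", a)) {
      opt[[sub("^--", "", sub("=.*", "", a))]] <- sub("^[^=]*=", "", a)
      i <- i + 1L
    } else if (startsWith(a, "--")) {
      if (i == length(args)) stop("missing value for ", a, call. = FALSE)
      opt[[sub("^--", "", a)]] <- args[i + 1L]
      i <- i + 2L
    } else stop("unexpected argument: ", a, call. = FALSE)
  }
  cfg <- if (!is.null(opt$config)) pipeline_config(opt$config)
  else pipeline_config()
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$out <- opt$out
  stages <- if (sub == "run") c("simulate", "quantify", "preprocess",
                                "velocity", "scna", "similarity", "gradient")
  else sub
  run_pipeline(cfg, stages = stages)
}
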