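#' Assemble and validate a pipeline run configuration
#'
#' Input paths plus the per-stage configurations, normally read from a
#' JSON config file (see [read_run_config()]). All stage defaults follow
#' the workflow's stated thresholds (meta alpha 0.05, heatmap FDR 1e-4,
#' miRNA p < 0.001 / q < 0.01 / FC > 2, top 5 miRNAs).
#'
#' @param expression Named character vector/list of expression TSV paths,
#'   one per mRNA study (>= 3 for the QC stage).
#' @param annotation Named character vector/list of annotation TSV paths
#'   parallel to `expression`.
#' @param mirna_expression,mirna_annotation Paths for the miRNA study.
#' @param genesets Path to a GMT file.
#' @param ppi Path to the scored PPI edge TSV.
#' @param targets Named vector/list of exactly three target TSV paths.
#' @param outdir Output directory.
#' @param seed Integer seed recorded in the run report and used for every
#'   stochastic stage.
#' @param meta_de,qc,mirna A [meta_de_config()], [qc_config()] and
#'   [mirna_filter_config()].
#' @param score_min,n_hubs Network options.
#' @param quantile_normalize Apply within-study quantile normalization
#'   before DE testing.
#' @param verbose Log one line per stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(expression, annotation,
                       mirna_expression, mirna_annotation,
                       genesets, ppi, targets,
                       outdir = "transmeta_out", seed = 1L,
                       meta_de = meta_de_config(), qc = qc_config(),
                       mirna = mirna_filter_config(),
                       score_min = 0.4, n_hubs = 6L,
                       quantile_normalize = FALSE,
                       verbose = TRUE) {
  cfg <- list(expression = as.list(expression),
              annotation = as.list(annotation),
              mirna_expression = mirna_expression,
              mirna_annotation = mirna_annotation,
              genesets = genesets, ppi = ppi, targets = as.list(targets),
              outdir = outdir, seed = as.integer(seed),
              meta_de = meta_de, qc = qc, mirna = mirna,
              score_min = score_min, n_hubs = as.integer(n_hubs),
              quantile_normalize = isTRUE(quantile_normalize),
              verbose = isTRUE(verbose))
  validate_run_config_(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config_ <- function(cfg) {
  if (length(cfg$expression) < 3L) {
    stop("validation: need >= 3 mRNA studies for quality control")
  }
  if (length(cfg$expression) != length(cfg$annotation)) {
    stop("validation: expression and annotation lists differ in length")
  }
  if (length(cfg$targets) != 3L) {
    stop("validation: exactly three target source files are required")
  }
  paths <- c(unlist(cfg$expression), unlist(cfg$annotation),
             cfg$mirna_expression, cfg$mirna_annotation,
             cfg$genesets, cfg$ppi, unlist(cfg$targets))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("validation: missing input file(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors [run_config()]'s arguments; stage-config objects
#' (`meta_de`, `qc`, `mirna`) are given as objects whose fields override
#' the defaults. Relative input paths are resolved against the config
#' file's directory. (YAML is not supported: no YAML parser is available
#' in the target environment.)
#'
#' @param path JSON config path.
#' @param seed,outdir Optional overrides.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path, seed = NULL, outdir = NULL) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    vapply(as.character(p), function(x) {
      if (startsWith(x, "/")) x else file.path(base, x)
    }, character(1))
  }
  mk <- function(fun, over) do.call(fun, as.list(over))
  run_config(
    expression = rel(js$expression), annotation = rel(js$annotation),
    mirna_expression = rel(js$mirna_expression),
    mirna_annotation = rel(js$mirna_annotation),
    genesets = rel(js$genesets), ppi = rel(js$ppi),
    targets = rel(js$targets),
    outdir = if (!is.null(outdir)) outdir else
      if (!is.null(js$outdir)) js$outdir else "transmeta_out",
    seed = if (!is.null(seed)) seed else if (!is.null(js$seed)) js$seed else 1L,
    meta_de = mk(meta_de_config, js$meta_de),
    qc = mk(qc_config, js$qc),
    mirna = mk(mirna_filter_config, js$mirna),
    score_min = if (!is.null(js$score_min)) js$score_min else 0.4,
    n_hubs = if (!is.null(js$n_hubs)) js$n_hubs else 6L,
    quantile_normalize = isTRUE(js$quantile_normalize),
    verbose = !isFALSE(js$verbose)
  )
}

log_stage_ <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[transmeta] %s", sprintf(fmt, ...)))
}

#' Run the full integrated analysis
#'
#' Stages, in order: load inputs; study QC with exclusion; optional
#' quantile normalization; per-study penalized-t DE; overlap-DE list;
#' Fisher + maxP meta-analysis with meta-DE and heatmap flags; gene-set
#' enrichment of the meta-DE genes; miRNA DE with variance filter and
#' top-k selection; three-source 3'-UTR targetome consensus and candidate
#' genes; mixed network with hub report. Every stage's tables are written
#' under `outdir` together with a JSON run report of per-stage counts.
#'
#' @param config A [run_config()].
#' @return The run report, invisibly (list; also written as
#'   `run_report.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config_(config)
  t0 <- Sys.time()
  v <- config$verbose
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  config$qc$seed <- config$seed

  # --- load -----------------------------------------------------------
  studies <- lapply(seq_along(config$expression), function(i) {
    read_expression(config$expression[[i]], config$annotation[[i]])
  })
  collection <- study_collection(studies)
  mirna_study <- read_expression(config$mirna_expression,
                                 config$mirna_annotation)
  gs <- read_genesets(config$genesets,
                      universe = collection$common_genes)
  ppi <- read_ppi(config$ppi)
  targets <- read_targets(config$targets)
  log_stage_(v, "loaded %d studies (%d common genes), %d miRNAs",
             collection$K, length(collection$common_genes),
             nrow(mirna_study$mat))

  tables <- list()

  # --- QC -------------------------------------------------------------
  qc_report <- compute_qc_indices(collection, gs, config$qc)
  tables$qc_report <- qc_report
  collection <- apply_exclusions(collection, qc_report)
  log_stage_(v, "QC: %d/%d studies retained", collection$K,
             nrow(qc_report))

  if (config$quantile_normalize) {
    collection <- quantile_normalize(collection)
    log_stage_(v, "quantile-normalized %d studies", collection$K)
  }

  # --- per-study DE + meta --------------------------------------------
  de_results <- lapply(collection$studies, penalized_t,
                       config = config$meta_de)
  for (r in de_results) {
    tables[[paste0("de_", attr(r, "study_id"))]] <- r
  }
  overlap <- overlap_de_genes(de_results, config$meta_de)
  meta <- meta_de_genes(combine_de_results(de_results, config$meta_de),
                        config$meta_de)
  tables$meta_de <- meta
  meta_genes <- meta$gene_id[meta$is_meta_de]
  log_stage_(v, "meta-DE: %d overlap genes, %d meta-DE genes, %d heatmap genes",
             length(overlap), length(meta_genes), sum(meta$is_heatmap))
  tables$overlap_genes <- data.frame(gene_id = overlap,
                                     stringsAsFactors = FALSE)

  # --- enrichment -----------------------------------------------------
  enr <- NULL
  if (length(meta_genes)) {
    enr <- enrich(meta_genes, gs)
    tables$enrichment <- enr
    log_stage_(v, "enrichment: %d/%d sets significant at raw p < 0.05",
               sum(enr$significant), nrow(enr))
  } else {
    log_stage_(v, "enrichment skipped: no meta-DE genes")
  }

  # --- miRNA ----------------------------------------------------------
  mirna_res <- test_mirnas(mirna_study, config$mirna)
  tables$mirna_de <- mirna_res
  top_mirnas <- top_k_mirnas(mirna_res, config$mirna)
  log_stage_(v, "miRNA DE: %d retained, %d DE, top %d selected",
             sum(mirna_res$passed_filter), sum(mirna_res$is_de),
             length(top_mirnas))

  # --- targetome ------------------------------------------------------
  candidates <- pairing <- NULL
  if (length(top_mirnas)) {
    tmap <- build_target_map(targets, top_mirnas)
    candidates <- candidate_genes(tmap, top_mirnas, meta_genes)
    pairing <- pairing_table(candidates)
    tables$candidate_genes <- candidates
    tables$mirna_gene_pairs <- pairing
    log_stage_(v, "targetome: %d candidate genes, %d miRNA-gene pairs",
               nrow(candidates), nrow(pairing))
  } else {
    log_stage_(v, "targetome skipped: no DE miRNAs")
  }

  # --- network --------------------------------------------------------
  net <- build_network(ppi, pairing, meta_genes,
                       score_min = config$score_min)
  hub_report <- NULL
  if (igraph::vcount(net) > config$n_hubs) {
    hub_report <- network_hubs(net, config$n_hubs)
    net <- hub_report$network
    tables$hubs <- data.frame(hub = hub_report$hubs,
                              stringsAsFactors = FALSE)
    log_stage_(v, "network: %d nodes, %d edges; components %d -> %d after removing %d hubs",
               igraph::vcount(net), igraph::ecount(net),
               hub_report$components_before, hub_report$components_after,
               config$n_hubs)
  } else {
    log_stage_(v, "network too small for %d hubs; hub stage skipped",
               config$n_hubs)
  }

  files <- write_results(tables, net, config$outdir)
  report <- list(
    seed = config$seed,
    studies_input = nrow(qc_report),
    studies_retained = collection$K,
    excluded_studies = qc_report$study_id[qc_report$excluded],
    n_common_genes = length(collection$common_genes),
    n_overlap_de_genes = length(overlap),
    n_meta_de_genes = length(meta_genes),
    n_heatmap_genes = sum(meta$is_heatmap),
    n_significant_sets = if (is.null(enr)) 0L else sum(enr$significant),
    n_de_mirnas = sum(mirna_res$is_de),
    top_mirnas = top_mirnas,
    n_candidate_genes = if (is.null(candidates)) 0L else nrow(candidates),
    hubs = if (is.null(hub_report)) character(0) else hub_report$hubs,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = files
  )
  jsonlite::write_json(report, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage_(v, "done in %.1f s", report$elapsed_sec)
  invisible(report)
}
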