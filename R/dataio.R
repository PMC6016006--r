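# On-disk formats (all tab-delimited, UTF-8):
#   expression:  first column `gene_id`, remaining columns one per sample
#   annotation:  columns sample_id, group (case|control), study_id
#   GMT:         name <tab> description <tab> member genes...
#   PPI:         gene_a, gene_b, combined_score in [0,1]
#   targets:     mirna_id, gene_id, region (3UTR|CDS|5UTR), optional score

REGION_LEVELS <- c("3UTR", "CDS", "5UTR")

read_tsv_ <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read an expression study from TSV files
#'
#' Gene ids are opaque case-sensitive strings. Duplicate gene rows are
#' collapsed by the configured rule: `"max_mean"` keeps the row with the
#' highest mean expression (a stand-in for probe summarization),
#' `"mean"` averages duplicate rows.
#'
#' @param matrix_path Expression TSV (first column `gene_id`).
#' @param annotation_path Annotation TSV covering every matrix column.
#' @param study_id Study to extract; defaults to the single study id found
#'   in the annotation rows for these samples.
#' @param collapse Duplicate-gene collapse rule.
#' @param linear If `TRUE` the matrix holds linear-scale values and is
#'   log2(x+1)-transformed on load. Default assumes log2 input.
#' @return An [expression_study()].
#' @export
read_expression <- function(matrix_path, annotation_path, study_id = NULL,
                            collapse = c("max_mean", "mean"),
                            linear = FALSE) {
  collapse <- match.arg(collapse)
  df <- read_tsv_(matrix_path)
  if (names(df)[1] != "gene_id") stop("first column must be `gene_id`")
  ann <- read_tsv_(annotation_path)
  need <- c("sample_id", "group", "study_id")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample id in annotation")
  samples <- names(df)[-1]
  missing <- setdiff(samples, ann$sample_id)
  if (length(missing)) {
    stop("annotation missing sample(s): ", paste(missing, collapse = ", "))
  }
  ann <- ann[match(samples, ann$sample_id), , drop = FALSE]
  bad <- setdiff(unique(ann$group), c("case", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (is.null(study_id)) {
    sid <- unique(ann$study_id)
    if (length(sid) != 1L) {
      stop("samples span several study ids; pass `study_id` explicitly")
    }
    study_id <- sid
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$gene_id
  if (linear) mat <- log2(mat + 1)
  if (anyDuplicated(df$gene_id)) {
    mat <- collapse_duplicates_(mat, df$gene_id, collapse)
  }
  expression_study(study_id, mat, ann$group)
}

collapse_duplicates_ <- function(mat, ids, rule) {
  keep <- switch(rule,
    max_mean = {
      m <- rowMeans(mat)
      ord <- order(ids, -m)
      idx <- ord[!duplicated(ids[ord])]
      out <- mat[idx, , drop = FALSE]
      rownames(out) <- ids[idx]
      out
    },
    mean = {
      out <- rowsum(mat, ids, reorder = FALSE) /
        as.vector(table(factor(ids, levels = unique(ids))))
      out
    })
  # preserve first-appearance order of the unique ids
  keep[unique(ids)[unique(ids) %in% rownames(keep)], , drop = FALSE]
}

#' Write an expression study to TSV files
#'
#' Values are serialized at full double precision so that a write/read
#' round trip is lossless.
#'
#' @param study An [expression_study()].
#' @param matrix_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(study, matrix_path, annotation_path) {
  mat <- study$mat
  df <- data.frame(gene_id = rownames(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- sprintf("%.17g", mat[, j])
  write_tsv_(df, matrix_path)
  ann <- data.frame(sample_id = colnames(mat), group = study$group,
                    study_id = study$study_id, stringsAsFactors = FALSE)
  write_tsv_(ann, annotation_path)
  invisible(c(matrix_path, annotation_path))
}

#' Read a gene-set collection from a GMT file
#'
#' @param gmt_path Path to a standard GMT file (name, description,
#'   members...).
#' @param universe Optional universe; defaults to the union of all members.
#' @return A [gene_set_collection()].
#' @export
read_genesets <- function(gmt_path, universe = NULL) {
  lines <- readLines(gmt_path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, character(1), 1L)
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(lengths(sets) == 0L)) {
    stop("GMT line with empty member list: ", nm[which(lengths(sets) == 0L)[1]])
  }
  names(sets) <- nm
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe, desc)
}

#' Write a gene-set collection to GMT
#' @param gs A [gene_set_collection()].
#' @param gmt_path Output path.
#' @return Invisibly, the path.
#' @export
write_genesets <- function(gs, gmt_path) {
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, gs$descriptions[[nm]], gs$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  invisible(gmt_path)
}

normalize_region_ <- function(x) {
  r <- toupper(gsub("[' ′-]", "", x))
  r[r == "3PUTR"] <- "3UTR"
  r[r == "5PUTR"] <- "5UTR"
  bad <- setdiff(unique(r), REGION_LEVELS)
  if (length(bad)) stop("unknown region token(s): ", paste(bad, collapse = ", "))
  r
}

#' Read miRNA target-prediction tables from exactly three sources
#'
#' @param paths_by_source Named character vector or list of length 3 giving
#'   one TSV path per prediction source. Each file needs columns
#'   `mirna_id`, `gene_id`, `region` and optionally `score`. Region tokens
#'   are normalized case-insensitively to `3UTR`/`CDS`/`5UTR`.
#' @return A data.frame of target records with columns `source`,
#'   `mirna_id`, `gene_id`, `region`, `score`.
#' @export
read_targets <- function(paths_by_source) {
  if (length(paths_by_source) != 3L) {
    stop("exactly three target sources are required, got ",
         length(paths_by_source))
  }
  if (is.null(names(paths_by_source)) || any(!nzchar(names(paths_by_source)))) {
    stop("`paths_by_source` must be named by source")
  }
  recs <- lapply(names(paths_by_source), function(src) {
    df <- read_tsv_(paths_by_source[[src]])
    need <- c("mirna_id", "gene_id", "region")
    if (!all(need %in% names(df))) {
      stop("target file for ", src, " must have columns: ",
           paste(need, collapse = ", "))
    }
    data.frame(source = src,
               mirna_id = as.character(df$mirna_id),
               gene_id = as.character(df$gene_id),
               region = normalize_region_(df$region),
               score = if ("score" %in% names(df)) as.numeric(df$score) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write target records as one TSV per source
#' @param records Target record data.frame (see [read_targets()]).
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, named vector of paths by source.
#' @export
write_targets <- function(records, dir, prefix = "targets") {
  paths <- character(0)
  for (src in unique(records$source)) {
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, src))
    write_tsv_(records[records$source == src,
                       c("mirna_id", "gene_id", "region", "score")], p)
    paths[src] <- p
  }
  invisible(paths)
}

#' Read a scored gene-gene interaction edge list
#'
#' Edges are undirected: endpoints are stored in canonical (lexicographic)
#' order and duplicate edges are collapsed keeping the highest score.
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `combined_score`.
#' @return data.frame with canonicalized, de-duplicated edges.
#' @export
read_ppi <- function(path) {
  df <- read_tsv_(path)
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% names(df))) {
    stop("PPI file must have columns: ", paste(need, collapse = ", "))
  }
  a <- as.character(df$gene_a); b <- as.character(df$gene_b)
  s <- as.numeric(df$combined_score)
  if (any(a == b)) stop("self-loop in PPI edge list")
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("combined_score outside [0,1]")
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- data.frame(gene_a = lo, gene_b = hi, combined_score = s,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, -out$combined_score), ]
  out <- out[!duplicated(out[c("gene_a", "gene_b")]), ]
  rownames(out) <- NULL
  out
}

format_numeric_cols_ <- function(df) {
  out <- df
  full <- list()
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      full[[paste0(nm, "_full")]] <- sprintf("%.17g", df[[nm]])
      out[[nm]] <- signif(df[[nm]], 6)
    }
  }
  for (nm in names(full)) out[[nm]] <- full[[nm]]
  out
}

#' Write result tables and a network to a directory
#'
#' Numeric columns are rounded to 6 significant digits for readability,
#' with a `<column>_full` companion at full precision for exact
#' reproducibility checks.
#'
#' @param tables Named list of data.frames; each becomes `<name>.tsv`.
#' @param network Optional igraph network (see [build_network()]) exported
#'   as GraphML and SIF.
#' @param dir Output directory (created if needed).
#' @return Character vector manifest of the files written.
#' @export
write_results <- function(tables, network = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv_(format_numeric_cols_(as.data.frame(tables[[nm]])), p)
    files <- c(files, p)
  }
  if (!is.null(network)) {
    files <- c(files, export_network(network, dir))
  }
  files
}
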