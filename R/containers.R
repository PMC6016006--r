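#' Construct an expression study
#'
#' An `expression_study` is the unit of meta-analysis: one study's log2
#' expression matrix (genes in rows, samples in columns) together with the
#' case/control assignment of each sample.
#'
#' @param study_id Single string identifying the study.
#' @param mat Numeric matrix, genes x samples, with unique rownames
#'   (gene ids) and unique colnames (sample ids). Values are assumed to be
#'   on the log2 scale.
#' @param group Character vector, one of `"case"`/`"control"` per sample,
#'   in column order. At least two samples per group are required.
#' @param platform_id Optional platform annotation string.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(study_id, mat, group, platform_id = NULL) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("`mat` must be a numeric matrix")
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop("matrix must have unique rownames (gene ids)")
  }
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat))) {
    stop("matrix must have unique colnames (sample ids)")
  }
  group <- as.character(group)
  if (length(group) != ncol(mat)) {
    stop("`group` must have one label per sample column")
  }
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  if (sum(group == "case") < 2L || sum(group == "control") < 2L) {
    stop("need at least 2 samples per group")
  }
  structure(
    list(study_id = study_id, mat = mat, group = group,
         platform_id = platform_id),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d genes x %d samples (%d case / %d control)\n",
              x$study_id, nrow(x$mat), ncol(x$mat),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$mat)

#' Bundle several expression studies for meta-analysis
#'
#' @param studies List of [expression_study()] objects with distinct
#'   study ids. At least two studies are required.
#' @return An object of class `study_collection` with elements `studies`
#'   (named list), `common_genes` (gene ids present in every study) and
#'   `K` (number of studies).
#' @export
study_collection <- function(studies) {
  if (!is.list(studies) || length(studies) < 2L) {
    stop("need a list of at least 2 studies")
  }
  ok <- vapply(studies, inherits, logical(1), "expression_study")
  if (!all(ok)) stop("all elements must be expression_study objects")
  ids <- vapply(studies, function(s) s$study_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate study ids")
  names(studies) <- ids
  common <- Reduce(intersect, lapply(studies, function(s) rownames(s$mat)))
  if (!length(common)) stop("studies share no genes")
  structure(
    list(studies = studies, common_genes = common, K = length(studies)),
    class = "study_collection"
  )
}

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf("<study_collection> %d studies, %d common genes\n",
              x$K, length(x$common_genes)))
  for (s in x$studies) print(s)
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene ids). Names must be
#'   unique; members are de-duplicated.
#' @param universe Character vector of all gene ids against which sets are
#'   interpreted. Members outside the universe are retained but flagged at
#'   enrichment time.
#' @param descriptions Optional character vector parallel to `sets`.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (!length(sets)) stop("empty gene-set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names")
  }
  if (!length(universe)) stop("empty universe")
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) stop("gene set with empty member list")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(
    list(sets = sets, universe = unique(as.character(universe)),
         descriptions = stats::setNames(descriptions, names(sets))),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over %d universe genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}
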