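#' Hypergeometric over-representation analysis
#'
#' For each gene set, the probability of observing at least the attained
#' overlap between the query list and the set, drawing `n` genes without
#' replacement from a universe of `N` of which `Kset` are set members:
#' p = P(X >= x), X ~ hypergeometric(N, Kset, n). The significance flag
#' uses raw p < `alpha` (the conventional ORA reading); BH-adjusted
#' p-values are reported alongside.
#'
#' @param gene_list Character vector of query gene ids. Genes outside the
#'   universe are dropped with a warning.
#' @param genesets A [gene_set_collection()].
#' @param alpha Raw-p significance cut-off (default 0.05).
#' @return data.frame (class `enrichment_result`) ordered by ascending p:
#'   `set_name`, `N`, `set_size`, `list_size`, `overlap`, `p`, `adj_p`,
#'   `significant`, `overlap_genes` (semicolon-joined).
#' @export
enrich <- function(gene_list, genesets, alpha = 0.05) {
  stopifnot(inherits(genesets, "gene_set_collection"))
  universe <- genesets$universe
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(as.character(gene_list))
  if (!length(gene_list)) stop("empty gene list")
  off <- setdiff(gene_list, universe)
  if (length(off)) {
    warning(length(off), " gene(s) outside the universe dropped")
    gene_list <- intersect(gene_list, universe)
    if (!length(gene_list)) stop("no query genes inside the universe")
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(genesets$sets), function(nm) {
    members <- intersect(genesets$sets[[nm]], universe)
    Kset <- length(members)
    ov <- intersect(gene_list, members)
    x <- length(ov)
    p <- stats::phyper(x - 1, Kset, N - Kset, n, lower.tail = FALSE)
    data.frame(set_name = nm, N = N, set_size = Kset, list_size = n,
               overlap = x, p = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$set_name),
             c("set_name", "N", "set_size", "list_size", "overlap",
               "p", "adj_p", "significant", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment p-value profiles for several gene lists
#'
#' One [enrich()] call per list against a shared universe; the result is a
#' sets x lists matrix of raw hypergeometric p-values (feeds the
#' pathway-level study-quality indices).
#'
#' @param gene_lists Named list of character vectors.
#' @param genesets A [gene_set_collection()].
#' @return Numeric matrix, one row per set (collection order), one column
#'   per list.
#' @export
enrichment_profile <- function(gene_lists, genesets) {
  stopifnot(is.list(gene_lists), length(gene_lists) >= 1)
  set_names <- names(genesets$sets)
  cols <- lapply(gene_lists, function(gl) {
    e <- enrich(gl, genesets)
    e$p[match(set_names, e$set_name)]
  })
  out <- do.call(cbind, cols)
  rownames(out) <- set_names
  colnames(out) <- names(gene_lists)
  out
}
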