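#' Assemble the mixed gene-gene / miRNA-gene interaction network
#'
#' Keeps gene-gene (PPI) edges whose confidence score reaches `score_min`
#' and whose two endpoints both belong to `genes_of_interest`, adds every
#' miRNA-gene pair as a `mirna_target` edge, and retains requested genes
#' even when isolated. Self-loops and duplicate edges are collapsed.
#'
#' @param ppi data.frame of scored edges (`gene_a`, `gene_b`,
#'   `combined_score`; see [read_ppi()]). May be empty.
#' @param pairs data.frame of miRNA-gene pairs (`mirna_id`, `gene_id`;
#'   see [pairing_table()]). May be empty.
#' @param genes_of_interest Genes eligible as PPI endpoints and retained
#'   as (possibly isolated) nodes.
#' @param score_min Minimum combined score in [0,1]; default 0.4, the
#'   conventional medium-confidence threshold for scored PPI resources.
#' @return An undirected igraph with vertex attributes `node_type`
#'   (gene|mirna) and `degree`, and edge attribute `edge_type`
#'   (ppi|mirna_target).
#' @export
build_network <- function(ppi, pairs, genes_of_interest,
                          score_min = 0.4) {
  stopifnot(score_min >= 0, score_min <= 1)
  genes_of_interest <- unique(as.character(genes_of_interest))
  ed <- NULL
  if (!is.null(ppi) && nrow(ppi)) {
    keep <- ppi$combined_score >= score_min &
      ppi$gene_a %in% genes_of_interest &
      ppi$gene_b %in% genes_of_interest &
      ppi$gene_a != ppi$gene_b
    if (any(keep)) {
      ed <- data.frame(from = pmin(ppi$gene_a[keep], ppi$gene_b[keep]),
                       to = pmax(ppi$gene_a[keep], ppi$gene_b[keep]),
                       edge_type = "ppi", stringsAsFactors = FALSE)
    }
  }
  mirnas <- character(0)
  if (!is.null(pairs) && nrow(pairs)) {
    mirnas <- unique(pairs$mirna_id)
    ed <- rbind(ed, data.frame(from = pairs$mirna_id, to = pairs$gene_id,
                               edge_type = "mirna_target",
                               stringsAsFactors = FALSE))
  }
  if (!is.null(ed)) ed <- ed[!duplicated(ed[c("from", "to")]), , drop = FALSE]
  node_genes <- sort(unique(c(genes_of_interest,
                              if (!is.null(ed)) setdiff(unlist(ed[c("from", "to")]), mirnas))))
  nodes <- data.frame(name = c(node_genes, sort(mirnas)),
                      node_type = c(rep("gene", length(node_genes)),
                                    rep("mirna", length(mirnas))),
                      stringsAsFactors = FALSE)
  if (is.null(ed)) {
    warning("network has no edges")
    ed <- data.frame(from = character(0), to = character(0),
                     edge_type = character(0), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Extract hub nodes and quantify fragmentation on their removal
#'
#' Hubs are the top `h` nodes by degree (ties broken lexicographically by
#' id). The report contrasts the connected-component structure before and
#' after deleting the hubs: a hub-centred network fragments.
#'
#' @param network An igraph from [build_network()].
#' @param h Number of hubs (1 <= h < node count).
#' @return List of class `hub_report`: `hubs`, `components_before`,
#'   `components_after`, `largest_before`, `largest_after`. The network
#'   gains a logical vertex attribute `is_hub` (returned as `network`).
#' @export
network_hubs <- function(network, h = 6L) {
  n <- igraph::vcount(network)
  if (h < 1 || h >= n) stop("h must satisfy 1 <= h < number of nodes")
  deg <- igraph::degree(network)
  nm <- igraph::V(network)$name
  ord <- order(-deg, nm)
  hubs <- nm[ord[seq_len(h)]]
  igraph::V(network)$is_hub <- nm %in% hubs
  before <- igraph::components(network)
  reduced <- igraph::delete_vertices(network, hubs)
  after <- igraph::components(reduced)
  structure(list(hubs = hubs,
                 components_before = as.integer(before$no),
                 components_after = as.integer(after$no),
                 largest_before = if (before$no) as.integer(max(before$csize)) else 0L,
                 largest_after = if (after$no) as.integer(max(after$csize)) else 0L,
                 network = network),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat("<hub_report>\n  hubs:", paste(x$hubs, collapse = ", "), "\n")
  cat(sprintf("  components %d -> %d, largest %d -> %d after removal\n",
              x$components_before, x$components_after,
              x$largest_before, x$largest_after))
  invisible(x)
}

#' Export a network as GraphML and SIF
#'
#' GraphML preserves the vertex attributes `node_type`, `degree` and
#' `is_hub` (when present); the SIF file carries one line per edge with
#' the edge type (`ppi` or `mirna_target`) as the relation.
#'
#' @param network An igraph from [build_network()].
#' @param dir Output directory.
#' @param basename File stem (default `"network"`).
#' @return Character vector of the two paths written.
#' @export
export_network <- function(network, dir, basename = "network") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gml <- file.path(dir, paste0(basename, ".graphml"))
  sif <- file.path(dir, paste0(basename, ".sif"))
  igraph::write_graph(network, gml, format = "graphml")
  el <- igraph::as_data_frame(network, what = "edges")
  lines <- if (nrow(el)) {
    paste(el$from, el$edge_type, el$to, sep = "\t")
  } else character(0)
  writeLines(lines, sif)
  c(gml, sif)
}
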