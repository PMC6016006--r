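# Gene-symbol aliases applied when harmonizing target records against a
# meta-DE gene list. Identifiers are otherwise opaque and case-sensitive.
GENE_ALIASES <- c(VAVP = "VAPA")

resolve_aliases_ <- function(x) {
  hit <- x %in% names(GENE_ALIASES)
  x[hit] <- GENE_ALIASES[x[hit]]
  x
}

#' Per-miRNA three-source target intersection (3'-UTR only)
#'
#' For each requested miRNA, collects its predicted target genes per
#' source, restricted to records with a 3'-UTR site, and intersects the
#' three source sets into a consensus. Records from regions other than
#' 3UTR never contribute; records lacking a usable region were already
#' rejected or normalized at read time.
#'
#' @param records Target record data.frame (see [read_targets()]),
#'   spanning exactly three sources.
#' @param mirnas Character vector of miRNA ids to build maps for.
#' @param assume_3utr Treat records with NA region as 3UTR instead of
#'   dropping them with a warning.
#' @return List of class `target_map`: per miRNA a list with `sources`
#'   (named list of per-source 3'-UTR gene sets), `consensus`, and
#'   `provenance` (per consensus gene, the number of supporting sources,
#'   always 3).
#' @export
build_target_map <- function(records, mirnas, assume_3utr = FALSE) {
  srcs <- sort(unique(records$source))
  if (length(srcs) != 3L) {
    stop("records must span exactly three sources, found ", length(srcs))
  }
  gene <- resolve_aliases_(records$gene_id)
  region <- records$region
  if (anyNA(region)) {
    if (assume_3utr) {
      region[is.na(region)] <- "3UTR"
    } else {
      warning(sum(is.na(region)), " record(s) without region dropped")
    }
  }
  keep <- !is.na(region) & region == "3UTR"
  rec <- data.frame(source = records$source[keep],
                    mirna_id = records$mirna_id[keep],
                    gene_id = gene[keep], stringsAsFactors = FALSE)
  maps <- lapply(mirnas, function(m) {
    sub <- rec[rec$mirna_id == m, , drop = FALSE]
    if (!nrow(sub)) {
      warning("miRNA ", m, " absent from all sources: empty consensus")
    }
    sets <- lapply(srcs, function(s) sort(unique(sub$gene_id[sub$source == s])))
    names(sets) <- srcs
    consensus <- sort(Reduce(intersect, sets))
    list(sources = sets, consensus = consensus,
         provenance = stats::setNames(rep(3L, length(consensus)), consensus))
  })
  names(maps) <- mirnas
  structure(maps, class = "target_map")
}

#' Candidate genes: consensus targets that are also meta-DE
#'
#' Takes the union of the per-miRNA consensus sets over the given miRNAs
#' and intersects it with the meta-DE gene list, attaching to each
#' candidate the list of miRNAs whose consensus supports it.
#'
#' @param map A [build_target_map()] result.
#' @param mirnas Ordered miRNA ids (subset of the map's names).
#' @param meta_genes Character vector of meta-DE gene ids.
#' @return data.frame (class `candidate_gene_set`) with columns `gene_id`,
#'   `supporting_mirnas` (semicolon-joined), `n_support`; rows sorted by
#'   gene id.
#' @export
candidate_genes <- function(map, mirnas = names(map), meta_genes) {
  stopifnot(inherits(map, "target_map"))
  missing <- setdiff(mirnas, names(map))
  if (length(missing)) stop("miRNA(s) not in map: ", paste(missing, collapse = ", "))
  meta_genes <- resolve_aliases_(as.character(meta_genes))
  support <- list()
  for (m in mirnas) {
    for (g in map[[m]]$consensus) {
      support[[g]] <- c(support[[g]], m)
    }
  }
  genes <- sort(intersect(names(support), meta_genes))
  out <- data.frame(
    gene_id = genes,
    supporting_mirnas = vapply(genes, function(g)
      paste(sort(unique(support[[g]])), collapse = ";"), character(1)),
    n_support = vapply(genes, function(g)
      length(unique(support[[g]])), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("candidate_gene_set", "data.frame")
  out
}

#' Explicit miRNA-gene pairing table for network assembly
#'
#' @param candidates A [candidate_genes()] result.
#' @return data.frame with columns `mirna_id`, `gene_id`, ordered by
#'   miRNA then gene lexicographically.
#' @export
pairing_table <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_gene_set"))
  if (!nrow(candidates)) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
    data.frame(mirna_id = strsplit(candidates$supporting_mirnas[i], ";")[[1]],
               gene_id = candidates$gene_id[i], stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$mirna_id, rows$gene_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
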