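#' Configuration for study-level quality control
#'
#' @param n_qc_genes Number of most-variable common genes the indices are
#'   computed on (default 500; must not exceed the common-gene count).
#' @param n_perm Permutation count B for the permutation-based indices
#'   (default 500, minimum 100).
#' @param seed Base RNG seed. One shared set of permutation draws serves
#'   every study (common random numbers), so the report does not depend
#'   on the order in which studies are listed and identical studies
#'   receive identical indices.
#' @param correlation_kind Correlation used for the concordance indices:
#'   `"spearman"` (default) or `"pearson"`.
#' @param top_m Gene-list length for the accuracy/consistency indices
#'   (default 100).
#' @param exclusion_threshold A study is flagged for exclusion when its
#'   standardized mean index rank falls below this many SDs relative to
#'   the across-study mean (default -1.0).
#' @return List of class `qc_config`.
#' @export
qc_config <- function(n_qc_genes = 500L, n_perm = 500L, seed = 1L,
                      correlation_kind = c("spearman", "pearson"),
                      top_m = 100L, exclusion_threshold = -1.0) {
  correlation_kind <- match.arg(correlation_kind)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  stopifnot(n_qc_genes >= 10, top_m >= 1)
  structure(list(n_qc_genes = as.integer(n_qc_genes),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 correlation_kind = correlation_kind,
                 top_m = as.integer(top_m),
                 exclusion_threshold = exclusion_threshold),
            class = "qc_config")
}

# Deterministic 31-bit seed from a string, mixed with a base seed, so
# per-study permutation streams are independent of study ordering.
seed_from_string_ <- function(s, base) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer((h + as.numeric(base) * 7919) %% 2147483647)
}

uppertri_ <- function(mat) mat[upper.tri(mat)]

# Center to zero mean and scale to unit L2 norm so crossprod() of two
# such vectors is their Pearson correlation.
normalize_ <- function(x) {
  x <- x - mean(x)
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) x else x / nrm
}

#' Six quality-control indices per study
#'
#' On the `n_qc_genes` most variable common genes, each index measures
#' one facet of a study's agreement with the rest of the collection, and
#' is reported as -log10 of a one-sided p-value (larger = better quality):
#'
#' * IQC (internal): mean correlation between the study's gene-gene
#'   co-expression pattern and that of every other study; permutation
#'   null by shuffling the study's gene labels.
#' * EQC (external): correlation between the study's co-expression and
#'   the binary co-membership pattern of the gene-set collection; same
#'   permutation null.
#' * AQCg (accuracy, genes): hypergeometric p of the overlap between the
#'   study's `top_m` genes (by penalized-t p) and the `top_m` genes of
#'   the leave-this-study-out Fisher meta-analysis.
#' * CQCg (consistency, genes): permutation p of the rank correlation
#'   between the study's gene p-values and the leave-one-out meta
#'   p-values.
#' * AQCp / CQCp: the same two constructions computed on per-gene-set
#'   enrichment p-values instead of gene p-values.
#'
#' Indices are ranked across studies (larger index = larger rank), the
#' mean rank per study is standardized, and studies falling below
#' `exclusion_threshold` SDs are flagged. When `genesets` is missing or
#' empty, EQC/AQCp/CQCp are reported as NA with a warning and the
#' aggregation uses the available indices.
#'
#' @param collection A [study_collection()] with K >= 3 studies (the
#'   leave-one-out constructions need at least two remaining studies).
#' @param genesets Optional [gene_set_collection()].
#' @param config A [qc_config()].
#' @return data.frame (class `qc_report`): `study_id`, the six index
#'   columns, `mean_rank`, `z_rank`, `pc1`, `pc2`, `excluded`.
#' @export
compute_qc_indices <- function(collection, genesets = NULL,
                               config = qc_config()) {
  stopifnot(inherits(collection, "study_collection"))
  K <- collection$K
  if (K < 3L) stop("quality control needs at least 3 studies")
  common <- collection$common_genes
  if (config$n_qc_genes > length(common)) {
    stop("n_qc_genes exceeds the number of common genes")
  }
  if (config$top_m >= config$n_qc_genes) {
    stop("top_m must be smaller than n_qc_genes")
  }
  B <- config$n_perm
  ids <- names(collection$studies)
  have_gs <- !is.null(genesets) && length(genesets$sets) > 0
  if (!have_gs) {
    warning("no gene sets supplied: EQC, AQCp and CQCp reported as NA")
  }

  # restrict to the most variable common genes (variance summed over studies)
  vtot <- Reduce(`+`, lapply(collection$studies, function(s) {
    apply(s$mat[common, , drop = FALSE], 1, stats::var)
  }))
  qc_genes <- common[order(-vtot, common)][seq_len(config$n_qc_genes)]
  n <- length(qc_genes)

  # per-study penalized-t p-values on the QC genes
  de_cfg <- meta_de_config()
  P <- sapply(collection$studies, function(s) {
    sub <- expression_study(s$study_id, s$mat[qc_genes, , drop = FALSE],
                            s$group)
    r <- penalized_t(sub, de_cfg)
    r$p[match(qc_genes, r$gene_id)]
  })
  rownames(P) <- qc_genes

  # leave-one-out Fisher meta p-values
  P_loo <- sapply(seq_len(K), function(s) {
    fisher_combine(P[, -s, drop = FALSE])$p
  })

  # co-expression upper triangles, rank-transformed for spearman
  spearman <- config$correlation_kind == "spearman"
  U <- sapply(collection$studies, function(s) {
    u <- uppertri_(stats::cor(t(s$mat[qc_genes, , drop = FALSE])))
    if (spearman) rank(u) else u
  })
  UN <- apply(U, 2, normalize_)

  # gene-set co-membership upper triangle
  en <- NULL
  set_members <- NULL
  if (have_gs) {
    set_members <- lapply(genesets$sets, function(m) intersect(m, qc_genes))
    A <- vapply(set_members, function(m) qc_genes %in% m,
                logical(n))
    co <- tcrossprod(A * 1) > 0
    ev <- uppertri_(co) * 1
    en <- normalize_(if (spearman) rank(ev) else ev)
  }

  w <- which(upper.tri(diag(n)))
  ii <- as.integer(((w - 1) %% n) + 1)
  jj <- as.integer(((w - 1) %/% n) + 1)
  # column-major upper-triangle offsets: entry (a,b), a<b, sits at a + T3[b]
  T3 <- as.integer((seq_len(n) - 1) * (seq_len(n) - 2) / 2)

  top_genes <- function(p) qc_genes[order(p, qc_genes)][seq_len(config$top_m)]
  log_hyper_overlap <- function(set1, set2, m, Ntot) {
    x <- length(intersect(set1, set2))
    p <- stats::phyper(x - 1, m, Ntot - m, m, lower.tail = FALSE)
    -log10(max(p, 1e-300))
  }
  spear <- function(x, y) stats::cor(rank(x), rank(y))

  # per-set enrichment p profile of a gene list over the QC universe
  enrich_pvec <- function(gl) {
    vapply(set_members, function(m) {
      x <- length(intersect(gl, m))
      stats::phyper(x - 1, length(m), n - length(m), length(gl),
                    lower.tail = FALSE)
    }, numeric(1))
  }

  IQC <- EQC <- AQCg <- AQCp <- CQCg <- CQCp <- rep(NA_real_, K)

  # --- IQC / EQC: one shared set of gene-label permutations ------------
  # The concordance statistic for study s is the mean correlation of its
  # (unit-normalized) co-expression triangle with the other studies';
  # with Stot = rowSums(UN) that is (UN[,s].Stot - 1) / (K - 1). A
  # gene-label permutation permutes the upper triangle in place and leaves
  # its mean/norm unchanged, so the permuted normalized vector is a pure
  # reindex of UN[,s]. One permutation map per draw serves every study.
  Stot <- rowSums(UN)
  obs_iqc <- (crossprod(UN, Stot)[, 1] - 1) / (K - 1)
  obs_eqc <- if (have_gs) crossprod(UN, en)[, 1] else rep(NA_real_, K)
  comp <- cbind(UN, Stot, if (have_gs) en)
  set.seed(seed_from_string_("coexpression", config$seed))
  cnt_iqc <- cnt_eqc <- numeric(K)
  for (b in seq_len(B)) {
    pm <- sample.int(n)
    a <- pm[ii]; bb <- pm[jj]
    idx <- pmin(a, bb) + T3[pmax(a, bb)]
    M <- crossprod(UN[idx, , drop = FALSE], comp)
    null_iqc <- (M[, K + 1] - M[cbind(seq_len(K), seq_len(K))]) / (K - 1)
    cnt_iqc <- cnt_iqc + (null_iqc >= obs_iqc)
    if (have_gs) cnt_eqc <- cnt_eqc + (M[, K + 2] >= obs_eqc)
  }
  IQC <- -log10((cnt_iqc + 1) / (B + 1))
  if (have_gs) EQC <- -log10((cnt_eqc + 1) / (B + 1))

  # --- AQC / CQC -------------------------------------------------------
  # The CQC permutation draws are shared across studies (common random
  # numbers): identical studies then receive identical indices, and the
  # report cannot depend on the order studies are supplied in.
  set.seed(seed_from_string_("consistency", config$seed))
  sh_gene <- lapply(seq_len(B), function(b) sample.int(n))
  n_sets_all <- if (have_gs) length(set_members) else 0L
  sh_set <- if (have_gs) lapply(seq_len(B), function(b) sample.int(n_sets_all))
  for (s in seq_len(K)) {
    obs_cqcg <- spear(P[, s], P_loo[, s])
    tops <- top_genes(P[, s])
    topl <- top_genes(P_loo[, s])
    AQCg[s] <- log_hyper_overlap(tops, topl, config$top_m, n)
    if (have_gs) {
      Es <- enrich_pvec(tops)
      El <- enrich_pvec(topl)
      n_sets <- length(Es)
      m_sets <- max(1L, min(config$top_m, floor(n_sets / 2)))
      top_sets <- function(e) names(set_members)[order(e, names(set_members))][seq_len(m_sets)]
      AQCp[s] <- log_hyper_overlap(top_sets(Es), top_sets(El), m_sets, n_sets)
      obs_cqcp <- spear(Es, El)
      rank_el <- rank(El)
      rank_es <- rank(Es)
    }
    cnt_cqcg <- cnt_cqcp <- 0L
    rank_ps <- rank(P[, s])
    rank_pl <- rank(P_loo[, s])
    for (b in seq_len(B)) {
      cnt_cqcg <- cnt_cqcg +
        (stats::cor(rank_ps[sh_gene[[b]]], rank_pl) >= obs_cqcg)
      if (have_gs) {
        cnt_cqcp <- cnt_cqcp +
          (stats::cor(rank_es[sh_set[[b]]], rank_el) >= obs_cqcp)
      }
    }
    CQCg[s] <- -log10((cnt_cqcg + 1) / (B + 1))
    if (have_gs) CQCp[s] <- -log10((cnt_cqcp + 1) / (B + 1))
  }

  idx_mat <- cbind(IQC = IQC, EQC = EQC, AQCg = AQCg, AQCp = AQCp,
                   CQCg = CQCg, CQCp = CQCp)
  rownames(idx_mat) <- ids
  avail <- colSums(is.na(idx_mat)) == 0
  ranks <- apply(idx_mat[, avail, drop = FALSE], 2, rank)
  mean_rank <- rowMeans(ranks)
  sdr <- stats::sd(mean_rank)
  z_rank <- if (is.na(sdr) || sdr == 0) rep(0, K) else
    (mean_rank - mean(mean_rank)) / sdr
  excluded <- z_rank < config$exclusion_threshold

  pca <- qc_pca(idx_mat[, avail, drop = FALSE])
  out <- data.frame(study_id = ids, idx_mat, mean_rank = mean_rank,
                    z_rank = z_rank,
                    pc1 = pca$coordinates[, 1],
                    pc2 = if (ncol(pca$coordinates) >= 2)
                            pca$coordinates[, 2] else 0,
                    excluded = excluded,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "qc_genes") <- qc_genes
  attr(out, "explained_variance") <- pca$explained
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Principal components of the study x index matrix
#'
#' Columns are centered and unit-scaled (constant columns are left
#' centered only); component signs are canonicalized so the loading with
#' the largest magnitude is positive, making the output invariant to the
#' order of the input rows.
#'
#' @param x A `qc_report` or a numeric studies x indices matrix.
#' @return List with `coordinates` (studies x components scores) and
#'   `explained` (variance fractions summing to 1).
#' @export
qc_pca <- function(x) {
  if (inherits(x, "qc_report")) {
    cols <- intersect(c("IQC", "EQC", "AQCg", "AQCp", "CQCg", "CQCp"),
                      names(x))
    m <- as.matrix(x[cols])
    m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
    rownames(m) <- x$study_id
  } else {
    m <- as.matrix(x)
  }
  ctr <- scale(m, center = TRUE, scale = FALSE)
  sds <- apply(ctr, 2, stats::sd)
  sds[is.na(sds) | sds == 0] <- 1
  ctr <- sweep(ctr, 2, sds, "/")
  sv <- svd(ctr)
  # canonical sign: dominant loading positive
  for (j in seq_along(sv$d)) {
    v <- sv$v[, j]
    k <- which.max(abs(v))
    if (v[k] < 0) { sv$v[, j] <- -v; sv$u[, j] <- -sv$u[, j] }
  }
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_along(sv$d))
  expl <- sv$d^2 / sum(sv$d^2)
  list(coordinates = scores, explained = expl)
}

#' Drop excluded studies from a collection
#'
#' @param collection A [study_collection()].
#' @param report A [compute_qc_indices()] report for the same studies.
#' @return The collection without the flagged studies; refuses to drop
#'   below two remaining studies.
#' @export
apply_exclusions <- function(collection, report) {
  stopifnot(inherits(collection, "study_collection"),
            inherits(report, "qc_report"))
  drop <- report$study_id[report$excluded]
  if (!length(drop)) return(collection)
  keep <- setdiff(names(collection$studies), drop)
  if (length(keep) < 2L) {
    stop("exclusion would leave fewer than 2 studies")
  }
  study_collection(collection$studies[keep])
}
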