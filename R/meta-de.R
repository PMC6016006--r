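#' Configuration for per-study and meta differential expression
#'
#' @param s0_rule How the fudge parameter s0 is chosen: `"median_se"`
#'   (default; the median of the gene-wise standard errors, SAM-style),
#'   `"fixed"` (use `s0`), or `"none"` (classical pooled t).
#' @param s0 Fixed fudge value (log2 units) when `s0_rule = "fixed"`.
#' @param p_method `"t_reference"` (default) evaluates two-sided p-values
#'   against the t distribution with n1+n2-2 df; `"permutation"` uses
#'   group-label permutation with `n_perm` draws.
#' @param n_perm,seed Permutation count (>= 100) and RNG seed for
#'   `p_method = "permutation"`.
#' @param combine Which combined statistic gates the meta-DE call:
#'   `"both"` (default; Fisher AND maxP must pass), `"fisher"`, `"maxp"`.
#'   Both statistics are always computed and reported.
#' @param meta_alpha BH-adjusted meta p-value threshold for meta-DE calls.
#' @param heatmap_fdr Stricter BH Fisher threshold selecting genes for the
#'   heatmap submatrix.
#' @param per_study_alpha BH-adjusted per-study threshold for the
#'   overlap-DE gene list.
#' @param direction_rule Cross-study effect-sign consistency required for a
#'   meta-DE call: `"all_same_sign"` (default), `"majority"`, `"off"`.
#' @param p_floor Smallest p-value allowed into Fisher's log; inputs of 0
#'   are clamped here with a warning.
#' @return A list of class `meta_de_config`.
#' @export
meta_de_config <- function(s0_rule = c("median_se", "fixed", "none"),
                           s0 = 0,
                           p_method = c("t_reference", "permutation"),
                           n_perm = 1000L, seed = 1L,
                           combine = c("both", "fisher", "maxp"),
                           meta_alpha = 0.05,
                           heatmap_fdr = 1e-4,
                           per_study_alpha = 0.05,
                           direction_rule = c("all_same_sign", "majority", "off"),
                           p_floor = 1e-300) {
  s0_rule <- match.arg(s0_rule)
  p_method <- match.arg(p_method)
  combine <- match.arg(combine)
  direction_rule <- match.arg(direction_rule)
  stopifnot(meta_alpha > 0, meta_alpha < 1,
            heatmap_fdr > 0, heatmap_fdr < 1,
            per_study_alpha > 0, per_study_alpha < 1,
            s0 >= 0)
  if (p_method == "permutation" && n_perm < 100L) {
    stop("n_perm must be >= 100 for permutation p-values")
  }
  structure(list(s0_rule = s0_rule, s0 = s0, p_method = p_method,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 combine = combine, meta_alpha = meta_alpha,
                 heatmap_fdr = heatmap_fdr,
                 per_study_alpha = per_study_alpha,
                 direction_rule = direction_rule, p_floor = p_floor),
            class = "meta_de_config")
}

#' Penalized two-sample t test per gene
#'
#' For each gene, the case-minus-control log2 difference d is divided by
#' the pooled standard error plus a fudge parameter s0:
#' t = d / (se + s0), se = s_p * sqrt(1/n1 + 1/n2), where s_p^2 is the
#' pooled within-group variance. The fudge stabilizes genes whose variance
#' estimate is accidentally tiny. With s0 = 0 this reduces exactly to the
#' classical pooled two-sample t.
#'
#' @param study An [expression_study()].
#' @param config A [meta_de_config()].
#' @return data.frame (class `study_de_result`) with columns `gene_id`,
#'   `logFC`, `se`, `t`, `p`, `adj_p`, `zero_se`; attributes `study_id`
#'   and `s0`.
#' @export
penalized_t <- function(study, config = meta_de_config()) {
  mat <- study$mat
  case <- study$group == "case"
  n1 <- sum(case); n2 <- sum(!case)
  m1 <- rowMeans(mat[, case, drop = FALSE])
  m2 <- rowMeans(mat[, !case, drop = FALSE])
  d <- m1 - m2
  v1 <- apply(mat[, case, drop = FALSE], 1, stats::var)
  v2 <- apply(mat[, !case, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  s0 <- switch(config$s0_rule,
               median_se = stats::median(se),
               fixed = config$s0,
               none = 0)
  zero_se <- se + s0 == 0
  tt <- ifelse(zero_se, 0, d / (se + s0))
  df <- n1 + n2 - 2
  if (config$p_method == "t_reference") {
    p <- 2 * stats::pt(-abs(tt), df = df)
  } else {
    p <- perm_p_(mat, case, s0, tt, config$n_perm, config$seed)
  }
  if (any(zero_se & d != 0)) {
    warning("gene(s) with zero pooled variance and s0 = 0; p reported as limit 0")
    tt[zero_se & d != 0] <- sign(d[zero_se & d != 0]) * Inf
    p[zero_se & d != 0] <- 0
  }
  p[zero_se & d == 0] <- 1
  out <- data.frame(gene_id = rownames(mat), logFC = d, se = se, t = tt,
                    p = p, adj_p = bh_adjust(p), zero_se = zero_se,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "study_id") <- study$study_id
  attr(out, "s0") <- s0
  class(out) <- c("study_de_result", "data.frame")
  out
}

perm_p_ <- function(mat, case, s0, t_obs, n_perm, seed) {
  set.seed(seed)
  n <- ncol(mat); n1 <- sum(case); n2 <- n - n1
  count <- rep(0L, nrow(mat))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    pc <- logical(n); pc[idx] <- TRUE
    m1 <- rowMeans(mat[, pc, drop = FALSE])
    m2 <- rowMeans(mat[, !pc, drop = FALSE])
    v1 <- apply(mat[, pc, drop = FALSE], 1, stats::var)
    v2 <- apply(mat[, !pc, drop = FALSE], 1, stats::var)
    se <- sqrt((((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)) * (1 / n1 + 1 / n2))
    tb <- ifelse(se + s0 == 0, 0, (m1 - m2) / (se + s0))
    count <- count + (abs(tb) >= abs(t_obs))
  }
  (count + 1) / (n_perm + 1)
}

#' Fisher's p-value combination across studies
#'
#' S_g = -2 * sum_k log p_gk is chi-square with 2K degrees of freedom
#' under independent uniform nulls; the meta p-value is its upper tail.
#'
#' @param p_matrix Numeric matrix, genes x studies, of per-study p-values
#'   in (0, 1]. Zeros are clamped to `p_floor` with a warning.
#' @param p_floor Clamp for zero p-values.
#' @return data.frame with columns `S` and `p`.
#' @export
fisher_combine <- function(p_matrix, p_floor = 1e-300) {
  p_matrix <- as.matrix(p_matrix)
  check_p_matrix_(p_matrix)
  if (any(p_matrix == 0)) {
    warning("p-value(s) of 0 clamped to ", p_floor)
    p_matrix[p_matrix == 0] <- p_floor
  }
  K <- ncol(p_matrix)
  S <- -2 * rowSums(log(p_matrix))
  data.frame(S = S, p = stats::pchisq(S, df = 2 * K, lower.tail = FALSE),
             row.names = rownames(p_matrix))
}

#' maxP p-value combination across studies
#'
#' The statistic is the maximum of the K per-study p-values; under
#' independent uniform nulls P(max <= x) = x^K, so the meta p-value is
#' (max p)^K. maxP demands evidence in every study, damping the influence
#' of a single large study.
#'
#' @inheritParams fisher_combine
#' @return data.frame with columns `maxp` and `p`.
#' @export
maxp_combine <- function(p_matrix) {
  p_matrix <- as.matrix(p_matrix)
  check_p_matrix_(p_matrix)
  K <- ncol(p_matrix)
  mp <- apply(p_matrix, 1, max)
  data.frame(maxp = mp, p = mp^K, row.names = rownames(p_matrix))
}

check_p_matrix_ <- function(p_matrix) {
  if (ncol(p_matrix) < 2L) stop("need p-values from at least 2 studies")
  if (anyNA(p_matrix)) stop("missing p-values; drop incomplete genes first")
  if (any(p_matrix < 0 | p_matrix > 1)) stop("p-values outside [0,1]")
  invisible(TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' adj p_(i) = min over j >= i of min(1, m * p_(j) / j) on the sorted
#' vector, mapped back to input order.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Genes significant in every study
#'
#' The "overlap DE" list: genes whose BH-adjusted per-study p-value falls
#' below `per_study_alpha` in every one of the studies.
#'
#' @param results List of [penalized_t()] results.
#' @param config A [meta_de_config()].
#' @return Character vector of gene ids (sorted).
#' @export
overlap_de_genes <- function(results, config = meta_de_config()) {
  sets <- lapply(results, function(r) r$gene_id[r$adj_p < config$per_study_alpha])
  sort(Reduce(intersect, sets))
}

#' Assemble per-study results into a meta-analysis table
#'
#' Genes present in every study result are carried (complete-case rule:
#' Fisher's null degrees of freedom must not vary silently). Both Fisher
#' and maxP statistics are computed, each BH-adjusted across genes, plus
#' an effect-sign consistency flag per `direction_rule`.
#'
#' @param results List of [penalized_t()] results (>= 2 studies).
#' @param config A [meta_de_config()].
#' @return data.frame (class `meta_de_result`): `gene_id`, one `p_<study>`
#'   and `d_<study>` column per study, `fisher_S`, `fisher_p`, `maxp`,
#'   `maxp_p`, `fisher_fdr`, `maxp_fdr`, `direction_consistent`.
#' @export
combine_de_results <- function(results, config = meta_de_config()) {
  if (length(results) < 2L) stop("meta-analysis needs >= 2 studies")
  ids <- vapply(results, function(r) attr(r, "study_id"), character(1))
  genes <- sort(Reduce(intersect, lapply(results, `[[`, "gene_id")))
  if (!length(genes)) stop("no genes common to all study results")
  P <- sapply(results, function(r) r$p[match(genes, r$gene_id)])
  D <- sapply(results, function(r) r$logFC[match(genes, r$gene_id)])
  colnames(P) <- ids; colnames(D) <- ids
  fi <- fisher_combine(P, p_floor = config$p_floor)
  mx <- maxp_combine(P)
  dircon <- switch(config$direction_rule,
    all_same_sign = rowSums(D > 0) == ncol(D) | rowSums(D < 0) == ncol(D),
    majority = pmax(rowSums(D > 0), rowSums(D < 0)) > ncol(D) / 2,
    off = rep(TRUE, length(genes)))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (s in ids) out[[paste0("p_", s)]] <- P[, s]
  for (s in ids) out[[paste0("d_", s)]] <- D[, s]
  out$fisher_S <- fi$S
  out$fisher_p <- fi$p
  out$maxp <- mx$maxp
  out$maxp_p <- mx$p
  out$fisher_fdr <- bh_adjust(fi$p)
  out$maxp_fdr <- bh_adjust(mx$p)
  out$direction_consistent <- dircon
  attr(out, "study_ids") <- ids
  class(out) <- c("meta_de_result", "data.frame")
  out
}

#' Flag meta-DE and heatmap genes
#'
#' A gene is meta-DE when its BH-adjusted combined p-value(s) pass
#' `meta_alpha` under the configured `combine` rule AND the effect signs
#' satisfy the direction rule. The heatmap subset applies the stricter
#' `heatmap_fdr` to the BH Fisher p-value.
#'
#' @param meta A [combine_de_results()] table.
#' @param config A [meta_de_config()].
#' @return The table with logical columns `is_meta_de` and `is_heatmap`
#'   added.
#' @export
meta_de_genes <- function(meta, config = meta_de_config()) {
  pass <- switch(config$combine,
    fisher = meta$fisher_fdr < config$meta_alpha,
    maxp   = meta$maxp_fdr < config$meta_alpha,
    both   = meta$fisher_fdr < config$meta_alpha &
             meta$maxp_fdr < config$meta_alpha)
  dirok <- if (config$direction_rule == "off") TRUE else meta$direction_consistent
  meta$is_meta_de <- pass & dirok
  meta$is_heatmap <- meta$fisher_fdr < config$heatmap_fdr & pass & dirok
  meta
}

#' Quantile-normalize expression columns within each study
#'
#' Every sample column is mapped onto the mean-of-order-statistics
#' reference profile of its study; rank ties receive the average of the
#' corresponding reference values.
#'
#' @param x An [expression_study()] or [study_collection()].
#' @return Object of the same class with normalized matrices.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "study_collection")) {
    x$studies <- lapply(x$studies, quantile_normalize)
    return(x)
  }
  stopifnot(inherits(x, "expression_study"))
  x$mat <- quantile_normalize_matrix_(x$mat)
  x
}

quantile_normalize_matrix_ <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}
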