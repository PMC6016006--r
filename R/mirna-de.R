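#' Configuration for miRNA differential expression
#'
#' @param sd_ratio_threshold Variance filter: miRNAs are kept when their
#'   standard deviation is at least this fraction of the largest SD in the
#'   matrix (sigma_i / sigma_max >= tau). Default 0.1.
#' @param p_threshold Raw p cut-off (default 0.001).
#' @param q_threshold BH-adjusted p cut-off (default 0.01).
#' @param fc_threshold Linear fold-change cut-off (default 2; a miRNA must
#'   exceed it, FC > 2).
#' @param top_k How many top DE miRNAs feed the targetome stage.
#' @return List of class `mirna_filter_config`.
#' @export
mirna_filter_config <- function(sd_ratio_threshold = 0.1,
                                p_threshold = 0.001,
                                q_threshold = 0.01,
                                fc_threshold = 2.0,
                                top_k = 5L) {
  stopifnot(sd_ratio_threshold >= 0, sd_ratio_threshold < 1,
            p_threshold > 0, p_threshold < 1,
            q_threshold > 0, q_threshold < 1,
            fc_threshold > 1, top_k >= 0)
  structure(list(sd_ratio_threshold = sd_ratio_threshold,
                 p_threshold = p_threshold, q_threshold = q_threshold,
                 fc_threshold = fc_threshold, top_k = as.integer(top_k)),
            class = "mirna_filter_config")
}

#' Row-standardize an expression study (mean 0, SD 1)
#'
#' Centers and scales each row. Zero-variance rows are centered only and
#' flagged in the `constant_rows` attribute. The transform matches the
#' visualization preprocessing of the emulated workflow; testing and the
#' variance filter run on the pre-standardization values (a per-row
#' standardized matrix would force every sigma to 1 and distort a
#' two-sample t).
#'
#' @param study An [expression_study()].
#' @return The study with a standardized matrix; attribute
#'   `constant_rows` names the zero-variance rows.
#' @export
standardize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  mat <- study$mat
  mu <- rowMeans(mat)
  sd <- apply(mat, 1, stats::sd)
  const <- sd == 0
  sc <- ifelse(const, 1, sd)
  study$mat <- (mat - mu) / sc
  attr(study, "constant_rows") <- rownames(mat)[const]
  study
}

#' sigma/sigma_max variance filter
#'
#' Retains rows whose standard deviation reaches at least
#' `sd_ratio_threshold` times the maximum row SD. Must be applied to the
#' pre-standardization matrix.
#'
#' @param study An [expression_study()].
#' @param config A [mirna_filter_config()].
#' @return Character vector of retained row ids.
#' @export
variance_filter <- function(study, config = mirna_filter_config()) {
  sd <- apply(study$mat, 1, stats::sd)
  smax <- max(sd)
  if (smax == 0) stop("all rows constant: sigma_max = 0")
  rownames(study$mat)[sd / smax >= config$sd_ratio_threshold]
}

#' Two-group miRNA differential-expression test
#'
#' Applies the sigma/sigma_max filter, then a two-sided pooled-variance
#' two-sample t per retained miRNA on the log2 values, BH q-values over
#' the retained set, and the triple threshold p < `p_threshold`,
#' q < `q_threshold`, FC > `fc_threshold`. The fold change is reported as
#' magnitude 2^|log2 difference| with a separate direction sign.
#'
#' @param study An [expression_study()] of log2 miRNA values.
#' @param config A [mirna_filter_config()].
#' @return data.frame (class `mirna_de_result`): `mirna_id`, `sigma`,
#'   `sigma_ratio`, `passed_filter`, `log2fc` (case - control),
#'   `direction` (-1/0/1), `fold_change`, `t`, `p`, `q`, `is_de`, `rank`.
#'   Unretained miRNAs carry NA statistics.
#' @export
test_mirnas <- function(study, config = mirna_filter_config()) {
  mat <- study$mat
  sd <- apply(mat, 1, stats::sd)
  smax <- max(sd)
  if (smax == 0) stop("all rows constant: sigma_max = 0")
  retained <- sd / smax >= config$sd_ratio_threshold
  case <- study$group == "case"
  n1 <- sum(case); n2 <- sum(!case)
  out <- data.frame(mirna_id = rownames(mat), sigma = sd,
                    sigma_ratio = sd / smax, passed_filter = retained,
                    log2fc = NA_real_, direction = NA_real_,
                    fold_change = NA_real_, t = NA_real_, p = NA_real_,
                    q = NA_real_, is_de = FALSE, rank = NA_integer_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(retained)) {
    sub <- mat[retained, , drop = FALSE]
    m1 <- rowMeans(sub[, case, drop = FALSE])
    m2 <- rowMeans(sub[, !case, drop = FALSE])
    d <- m1 - m2
    v1 <- apply(sub[, case, drop = FALSE], 1, stats::var)
    v2 <- apply(sub[, !case, drop = FALSE], 1, stats::var)
    se <- sqrt((((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)) *
                 (1 / n1 + 1 / n2))
    tt <- ifelse(se == 0, ifelse(d == 0, 0, sign(d) * Inf), d / se)
    p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
    q <- bh_adjust(p)
    fc <- 2^abs(d)
    out$log2fc[retained] <- d
    out$direction[retained] <- sign(d)
    out$fold_change[retained] <- fc
    out$t[retained] <- tt
    out$p[retained] <- p
    out$q[retained] <- q
    out$is_de[retained] <- p < config$p_threshold &
      q < config$q_threshold & fc > config$fc_threshold
    ord <- order(p, -fc, rownames(sub))
    out$rank[retained][ord] <- seq_along(ord)
  }
  class(out) <- c("mirna_de_result", "data.frame")
  out
}

#' Select the top-k DE miRNAs
#'
#' Orders the DE calls by ascending p, breaking ties by descending fold
#' change then lexicographic id, and returns the first `top_k`. Also
#' accepts any data.frame carrying `mirna_id`, `p` and `fold_change`
#' columns (e.g. the published table from [published_mirna_table()]); rows
#' without an `is_de` column are all treated as DE.
#'
#' @param result A [test_mirnas()] result or compatible data.frame.
#' @param config A [mirna_filter_config()] (supplies `top_k`).
#' @return Character vector of miRNA ids, at most `top_k` long.
#' @export
top_k_mirnas <- function(result, config = mirna_filter_config()) {
  need <- c("mirna_id", "p", "fold_change")
  stopifnot(all(need %in% names(result)))
  de <- if ("is_de" %in% names(result)) result$is_de & !is.na(result$p)
        else !is.na(result$p)
  sub <- result[de, , drop = FALSE]
  sub <- sub[order(sub$p, -sub$fold_change, sub$mirna_id), , drop = FALSE]
  utils::head(sub$mirna_id, config$top_k)
}
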