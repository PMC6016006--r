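# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the specific stats:: calls the package uses) so that
# agreement is a two-route check, not a tautology.

# BH step-up by the literal double loop over the sorted vector.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, min(1, m * ps[j] / j))
    adj[i] <- best
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Fisher chi-square upper tail via the closed-form series for even df:
# P(X2_{2K} > S) = exp(-S/2) * sum_{i=0}^{K-1} (S/2)^i / i!
oracle_fisher_p <- function(pvec) {
  S <- -2 * sum(log(pvec))
  K <- length(pvec)
  i <- 0:(K - 1)
  exp(-S / 2) * sum((S / 2)^i / factorial(i))
}

# maxP null p-value via the order-statistic Beta distribution.
oracle_maxp_p <- function(pvec) {
  stats::pbeta(max(pvec), length(pvec), 1)
}

# Hypergeometric upper tail by explicit combinatorial summation.
oracle_hyper_p <- function(x, K, N, n) {
  xs <- x:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Quantile normalization by per-column loops: replace each value by the
# average of the reference order statistics its (average) rank spans.
oracle_quantile_norm <- function(mat) {
  sorted <- apply(mat, 2, sort)
  ref <- rowMeans(sorted)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    for (i in seq_len(nrow(mat))) {
      out[i, j] <- mean(ref[c(floor(r[i]), ceiling(r[i]))])
    }
  }
  out
}

# Triple set intersection by scanning every gene of the first set.
oracle_triple_intersect <- function(a, b, c) {
  out <- character(0)
  for (g in unique(a)) {
    hit_b <- FALSE; hit_c <- FALSE
    for (x in b) if (x == g) { hit_b <- TRUE; break }
    for (x in c) if (x == g) { hit_c <- TRUE; break }
    if (hit_b && hit_c) out <- c(out, g)
  }
  sort(out)
}

# Connected components by breadth-first search over an edge data.frame.
oracle_components <- function(nodes, edges_from, edges_to) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edges_from)) {
    adj[[edges_from[i]]] <- c(adj[[edges_from[i]]], edges_to[i])
    adj[[edges_to[i]]] <- c(adj[[edges_to[i]]], edges_from[i])
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  sizes <- integer(0)
  for (start in nodes) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    sizes <- c(sizes, size)
  }
  list(no = length(sizes), sizes = sort(sizes, decreasing = TRUE))
}

# Small helpers to build toy objects in tests -------------------------------

toy_study <- function(id = "s1", mat = NULL, n1 = 3, n2 = 3, genes = 4,
                      seed = 1) {
  if (is.null(mat)) {
    set.seed(seed)
    mat <- matrix(rnorm(genes * (n1 + n2), 7, 1), genes, n1 + n2)
    rownames(mat) <- sprintf("g%02d", seq_len(genes))
    colnames(mat) <- sprintf("%s_smp%d", id, seq_len(n1 + n2))
  }
  expression_study(id, mat, c(rep("case", n1), rep("control", n2)))
}

write_toy_expression_files <- function(study, dir) {
  mp <- file.path(dir, paste0(study$study_id, "_expr.tsv"))
  ap <- file.path(dir, paste0(study$study_id, "_ann.tsv"))
  write_expression(study, mp, ap)
  list(matrix = mp, annotation = ap)
}

small_bundle_params <- function(seed = 1, ...) {
  sim_params(genes = 600L, n_case = 6L, n_control = 6L,
             n_mirna = 80L, mirna_de_count = 5L,
             decoys_per_source = 20L, n_genesets = 15L,
             geneset_size_range = c(10L, 40L), signal_set_size = 25L,
             n_ppi_edges = 800L, seed = seed, ...)
}

small_qc_config <- function(seed = 1, ...) {
  qc_config(n_qc_genes = 150L, n_perm = 100L, seed = seed, top_m = 40L, ...)
}
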