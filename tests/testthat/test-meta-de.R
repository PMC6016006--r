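test_that("penalized t matches hand-derived values", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                dimnames = list("g1", paste0("s", 1:6)))
  st <- expression_study("toy", mat, c(rep("case", 3), rep("control", 3)))
  r0 <- penalized_t(st, meta_de_config(s0_rule = "none"))
  expect_equal(r0$logFC, -3)
  expect_equal(r0$se, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r0$t, -3 / sqrt(2 / 3), tolerance = 1e-4)   # -3.6742
  r5 <- penalized_t(st, meta_de_config(s0_rule = "fixed", s0 = 0.5))
  expect_equal(r5$t, -3 / (sqrt(2 / 3) + 0.5), tolerance = 1e-4)  # -2.2788

  # identical groups: d = 0, t = 0, p = 1
  mat2 <- matrix(rep(c(1, 2, 3), 2), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  st2 <- expression_study("toy", mat2, c(rep("case", 3), rep("control", 3)))
  r <- penalized_t(st2, meta_de_config(s0_rule = "none"))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
})

test_that("s0 = 0 reduces to the classical pooled t on arbitrary inputs", {
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1); G <- 20
    mat <- matrix(rnorm(G * (n1 + n2), 5, 2), G)
    rownames(mat) <- sprintf("g%02d", 1:G)
    colnames(mat) <- sprintf("s%02d", seq_len(n1 + n2))
    grp <- c(rep("case", n1), rep("control", n2))
    st <- expression_study("x", mat, grp)
    r <- penalized_t(st, meta_de_config(s0_rule = "none"))
    for (g in c(1, G %/% 2, G)) {
      tt <- t.test(mat[g, grp == "case"], mat[g, grp == "control"],
                   var.equal = TRUE)
      expect_equal(r$t[g], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(r$p[g], tt$p.value, tolerance = 1e-12)
    }
  }
})

test_that("permutation p-values agree with the t reference in rank", {
  st <- toy_study("p", genes = 30, n1 = 6, n2 = 6, seed = 2)
  rt <- penalized_t(st, meta_de_config(s0_rule = "none"))
  rp <- penalized_t(st, meta_de_config(s0_rule = "none",
                                       p_method = "permutation",
                                       n_perm = 200, seed = 4))
  expect_gte(min(rp$p), 1 / 201)          # permutation floor
  expect_gt(cor(rank(rt$p), rank(rp$p)), 0.9)
})

test_that("fisher_combine matches high-precision logs and handles bounds", {
  r <- fisher_combine(matrix(c(0.01, 0.05), 1))
  expect_equal(r$S, -2 * (log(0.01) + log(0.05)), tolerance = 1e-12)
  expect_equal(round(r$S, 4), 15.2018)

  r1 <- fisher_combine(matrix(c(1, 1, 1), 1))
  expect_equal(r1$S, 0)
  expect_equal(r1$p, 1)

  expect_warning(rz <- fisher_combine(matrix(c(0, 0.5), 1)), "clamped")
  expect_true(is.finite(rz$S))
  expect_error(fisher_combine(matrix(0.5, 2, 1)), "at least 2")
  expect_error(fisher_combine(matrix(c(0.5, NA), 1)), "missing")
})

test_that("maxp_combine: closed form and boundaries", {
  r <- maxp_combine(matrix(c(0.2, 0.3), 1))
  expect_equal(r$maxp, 0.3)
  expect_equal(r$p, 0.09)
  expect_equal(maxp_combine(matrix(c(1.0, 0.5), 1))$p, 1.0)
})

test_that("bh_adjust matches the brute-force double loop", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)       # single p unchanged
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                # adjusted >= raw elementwise
  }
})

test_that("overlap_de_genes is an all-studies intersection", {
  mk <- function(id, sig, all_genes) {
    r <- data.frame(gene_id = all_genes, logFC = -1, se = 1, t = -1,
                    p = ifelse(all_genes %in% sig, 1e-6, 0.9),
                    adj_p = ifelse(all_genes %in% sig, 1e-5, 0.95),
                    zero_se = FALSE)
    attr(r, "study_id") <- id
    class(r) <- c("study_de_result", "data.frame")
    r
  }
  genes <- sprintf("g%d", 1:6)
  res <- list(mk("a", c("g1", "g2", "g3"), genes),
              mk("b", c("g2", "g3", "g4"), genes),
              mk("c", c("g2", "g3"), genes))
  expect_identical(overlap_de_genes(res), c("g2", "g3"))
  # significant in K-1 studies only: g1, g4 excluded by construction
  res2 <- c(res, list(mk("d", character(0), genes)))
  expect_identical(overlap_de_genes(res2), character(0))
})

test_that("direction rule and flagging behave as specified", {
  mk <- function(id, p, d, genes) {
    r <- data.frame(gene_id = genes, logFC = d, se = 1, t = d, p = p,
                    adj_p = bh_adjust(p), zero_se = FALSE)
    attr(r, "study_id") <- id
    class(r) <- c("study_de_result", "data.frame")
    r
  }
  genes <- c("up_down", "down_down")
  res <- list(mk("a", c(1e-8, 1e-8), c(+1, -1), genes),
              mk("b", c(1e-8, 1e-8), c(-1, -1), genes))
  meta <- meta_de_genes(combine_de_results(res))
  expect_false(meta$is_meta_de[meta$gene_id == "up_down"])
  expect_true(meta$is_meta_de[meta$gene_id == "down_down"])
  m2 <- meta_de_genes(combine_de_results(res,
          meta_de_config(direction_rule = "off")),
          meta_de_config(direction_rule = "off"))
  expect_true(all(m2$is_meta_de))
  # heatmap subset is always inside the meta-DE set
  expect_true(all(meta$gene_id[meta$is_heatmap] %in%
                    meta$gene_id[meta$is_meta_de]))
})

test_that("quantile normalization: fixed points, equal means, oracle", {
  same <- matrix(rep(c(1, 3, 5, 9), 3), 4)
  rownames(same) <- paste0("g", 1:4); colnames(same) <- paste0("s", 1:3)
  expect_error(expression_study("q", same, c("case", "case", "control")),
               "at least 2")
  st <- toy_study("q", genes = 5, n1 = 2, n2 = 2, seed = 3)
  qn <- quantile_normalize(st)
  cm <- colMeans(qn$mat)
  expect_lt(max(cm) - min(cm), 1e-9)

  # identical columns are unchanged
  st$mat[] <- rep(st$mat[, 1], 4)
  expect_equal(quantile_normalize(st)$mat, st$mat)

  # 5x4 toy with ties vs brute-force oracle
  set.seed(8)
  m <- matrix(sample(1:8, 20, replace = TRUE) + 0, 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  st2 <- expression_study("q2", m, c("case", "case", "control", "control"))
  expect_equal(quantile_normalize(st2)$mat, oracle_quantile_norm(m),
               tolerance = 1e-12)
})

test_that("meta-DE true-positive count is monotone in effect size and n", {
  tp_at <- function(range, n, seed) {
    p <- sim_params(genes = 600, n_case = n, n_control = n,
                    effect_size_range = range, seed = seed)
    sim <- simulate_studies(p)
    meta <- meta_de_genes(combine_de_results(
      lapply(sim$collection$studies, penalized_t)))
    length(intersect(meta$gene_id[meta$is_meta_de], sim$truth$de_genes))
  }
  for (sd in 1:3) {
    tps <- c(tp_at(c(0.2, 0.4), 8, sd), tp_at(c(0.6, 0.8), 8, sd),
             tp_at(c(1.0, 1.2), 8, sd))
    expect_true(all(diff(tps) >= 0))
  }
  mean_tp <- function(n) mean(vapply(1:3, function(sd)
    tp_at(c(0.8, 1.2), n, sd), numeric(1)))
  tps_n <- c(mean_tp(4), mean_tp(8), mean_tp(16))
  expect_true(all(diff(tps_n) >= 0))
})
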