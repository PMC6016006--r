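test_that("sim_params validates its contract", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(de_fraction = 1e-5), "no DE gene")
  expect_error(sim_params(source_retention = c(1, 1, 0)), "\\(0, 1\\]")
  expect_error(sim_params(mirna_de_count = 500, n_mirna = 100), "exceeds")
  expect_error(sim_params(effect_size_range = c(2, 1)))
})

test_that("simulate_studies: zero-DE case, determinism, shapes", {
  p <- sim_params(n_studies = 3, genes = 200, de_fraction = 0, seed = 7)
  sim <- simulate_studies(p)
  expect_length(sim$truth$de_genes, 0)
  expect_identical(sim$collection$K, 3L)
  expect_identical(dim(sim$collection$studies[[1]]$mat), c(200L, 16L))

  sim2 <- simulate_studies(p)
  expect_identical(sim$collection$studies[[2]]$mat,
                   sim2$collection$studies[[2]]$mat)
})

test_that("planted mean case-control difference matches -E[delta]", {
  # Monte-Carlo over 20 seeds at the default world: the planted effects
  # are uniform on [0.8, 1.2] and downregulated, so the mean difference
  # over planted genes should be -1.0
  diffs <- vapply(1:20, function(sd) {
    sim <- simulate_studies(sim_params(seed = sd))
    de <- sim$truth$de_genes
    mean(vapply(sim$collection$studies, function(s) {
      case <- s$group == "case"
      mean(rowMeans(s$mat[de, case]) - rowMeans(s$mat[de, !case]))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(diffs) - (-1.0)), 0.05)
})

test_that("corrupting one study leaves the others bit-identical", {
  pa <- sim_params(n_studies = 4, genes = 300, seed = 3)
  pb <- sim_params(n_studies = 4, genes = 300, seed = 3, corrupt_study = 2)
  a <- simulate_studies(pa)
  b <- simulate_studies(pb)
  expect_identical(a$collection$studies[[1]]$mat, b$collection$studies[[1]]$mat)
  expect_identical(a$collection$studies[[4]]$mat, b$collection$studies[[4]]$mat)
  expect_false(isTRUE(all.equal(a$collection$studies[[2]]$mat,
                                b$collection$studies[[2]]$mat)))
  expect_identical(b$truth$corrupted_study, "study2")
})

test_that("miRNA study: shapes, zero case, planted log2 difference", {
  p <- sim_params(mirna_de_count = 0)
  m <- simulate_mirna_study(p)
  expect_length(m$truth$de_mirnas, 0)
  expect_identical(ncol(m$study$mat), 32L)  # 19 + 13 samples

  # planted FC = 4 means a group log2 difference of -2 (downregulation)
  diffs <- vapply(1:20, function(sd) {
    m <- simulate_mirna_study(sim_params(seed = sd))
    de <- m$truth$de_mirnas
    case <- m$study$group == "case"
    mean(rowMeans(m$study$mat[de, case]) - rowMeans(m$study$mat[de, !case]))
  }, numeric(1))
  expect_lt(abs(mean(diffs) - (-2.0)), 0.05)
})

test_that("target sources: identity, binomial retention, zero rejected", {
  p0 <- sim_params(source_retention = c(a = 1, b = 1, c = 1),
                   decoys_per_source = 0, seed = 11)
  m <- simulate_mirna_study(p0)
  recs <- simulate_target_sources(p0, m$truth)
  tm <- build_target_map(recs, m$truth$de_mirnas)
  got <- do.call(rbind, lapply(names(tm), function(mir) {
    if (length(tm[[mir]]$consensus))
      data.frame(mirna_id = mir, gene_id = tm[[mir]]$consensus)
  }))
  truth <- m$truth$true_targets
  expect_equal(got[order(got$mirna_id, got$gene_id), ],
               truth[order(truth$mirna_id, truth$gene_id), ],
               ignore_attr = TRUE)

  # retention (1, 1, 0.5): expected three-way intersection = half the truth
  sizes <- vapply(1:50, function(sd) {
    p <- sim_params(source_retention = c(a = 1, b = 1, c = 0.5),
                    decoys_per_source = 0, seed = sd)
    m <- simulate_mirna_study(p)
    recs <- simulate_target_sources(p, m$truth)
    tm <- build_target_map(recs, m$truth$de_mirnas)
    sum(lengths(lapply(tm, `[[`, "consensus")))
  }, numeric(1))
  n_true <- nrow(m$truth$true_targets)
  expect_lt(abs(mean(sizes) - 0.5 * n_true), 0.05 * n_true)

  bad <- p0; bad$source_retention <- c(1, 1, 0)
  expect_error(simulate_target_sources(bad, m$truth), "> 0")
})

test_that("gene sets: signal enrichment by construction, size guard", {
  p <- sim_params(seed = 5)
  sim <- simulate_studies(p)
  gs <- simulate_genesets(p, sim$truth)
  sig <- gs$sets$signal_set
  n_de_in_sig <- length(intersect(sig, sim$truth$de_genes))
  expect_gte(n_de_in_sig / length(sig), 0.5)

  # random sets overlap the DE genes at the hypergeometric rate
  rnd <- gs$sets[grep("^random_", names(gs$sets))]
  obs <- sum(vapply(rnd, function(s)
    length(intersect(s, sim$truth$de_genes)), integer(1)))
  expected <- sum(lengths(rnd)) * length(sim$truth$de_genes) / p$genes
  expect_lt(abs(obs - expected), 4 * sqrt(expected))

  p_small <- sim_params(genes = 30, de_fraction = 0.1, signal_set_size = 5L,
                        geneset_size_range = c(40L, 50L))
  sim_small <- simulate_studies(p_small)
  expect_error(simulate_genesets(p_small, sim_small$truth),
               "exceeds universe")
})

test_that("fixture bundle writes every input plus manifest, deterministically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p <- small_bundle_params(seed = 9)
  m1 <- write_fixture_bundle(p, dir1)
  m2 <- write_fixture_bundle(p, dir2)
  expect_identical(m1$truth, m2$truth)
  for (f in c("genesets.gmt", "ppi.tsv", "expr_study1.tsv", "expr_mirna.tsv",
              "targets_mirdb.tsv", "published_mirna_de.tsv",
              "manifest.json")) {
    expect_true(file.exists(file.path(dir1, f)))
    if (f != "manifest.json") {   # manifest embeds absolute paths
      expect_identical(readLines(file.path(dir1, f)),
                       readLines(file.path(dir2, f)))
    }
  }
})
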