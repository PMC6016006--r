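three_source_records <- function(per_source) {
  do.call(rbind, lapply(names(per_source), function(src) {
    df <- per_source[[src]]
    data.frame(source = src, mirna_id = df$mirna_id, gene_id = df$gene_id,
               region = if ("region" %in% names(df)) df$region else "3UTR",
               score = NA_real_, stringsAsFactors = FALSE)
  }))
}

test_that("consensus is the 3'-UTR-restricted triple intersection", {
  recs <- three_source_records(list(
    A = data.frame(mirna_id = "m1", gene_id = c("g1", "g2")),
    B = data.frame(mirna_id = "m1", gene_id = c("g2", "g3")),
    C = data.frame(mirna_id = "m1", gene_id = "g2")))
  tm <- build_target_map(recs, "m1")
  expect_identical(tm$m1$consensus, "g2")

  # a CDS record in all three sources never contributes
  recs2 <- rbind(recs, three_source_records(list(
    A = data.frame(mirna_id = "m1", gene_id = "g4", region = "CDS"),
    B = data.frame(mirna_id = "m1", gene_id = "g4", region = "CDS"),
    C = data.frame(mirna_id = "m1", gene_id = "g4", region = "CDS"))))
  expect_identical(build_target_map(recs2, "m1")$m1$consensus, "g2")

  # duplicates change nothing; extra records in one source cannot grow
  # the consensus beyond the other two sources' intersection
  recs3 <- rbind(recs, recs[1, ])
  expect_identical(build_target_map(recs3, "m1")$m1$consensus, "g2")
  recs4 <- rbind(recs, three_source_records(list(
    A = data.frame(mirna_id = "m1", gene_id = "g9"))))
  tm4 <- build_target_map(recs4, "m1")
  expect_identical(tm4$m1$consensus, "g2")
  expect_true(all(tm4$m1$consensus %in%
                    intersect(tm4$m1$sources$B, tm4$m1$sources$C)))

  expect_error(build_target_map(recs[recs$source != "C", ], "m1"),
               "exactly three")
  expect_warning(build_target_map(recs, c("m1", "absent")), "absent")
})

test_that("random sources match the brute-force triple intersection", {
  set.seed(21)
  for (i in 1:30) {
    genes <- sprintf("g%02d", 1:25)
    sets <- lapply(1:3, function(j) sample(genes, sample(5:20, 1)))
    recs <- three_source_records(list(
      A = data.frame(mirna_id = "mx", gene_id = sets[[1]]),
      B = data.frame(mirna_id = "mx", gene_id = sets[[2]]),
      C = data.frame(mirna_id = "mx", gene_id = sets[[3]])))
    tm <- build_target_map(recs, "mx")
    expect_identical(tm$mx$consensus,
                     oracle_triple_intersect(sets[[1]], sets[[2]], sets[[3]]))
  }
})

test_that("published fixture recovers the 11 candidate genes and 10 pairs", {
  recs <- published_target_fixture(include_kif3a = TRUE)
  top5 <- c("miR-199b-3p", "miR-126-5p", "miR-29a-3p", "miR-19b-3p",
            "miR-301a-3p")
  tm <- suppressWarnings(build_target_map(recs, top5))
  cand <- candidate_genes(tm, top5, published_meta_genes())
  expect_setequal(cand$gene_id, published_candidate_genes())

  # the printed pairing proper (no KIF3A attribution): ten edges
  recs10 <- published_target_fixture(include_kif3a = FALSE)
  tm10 <- suppressWarnings(build_target_map(recs10, top5))
  cand10 <- candidate_genes(tm10, top5, published_meta_genes())
  pairs <- pairing_table(cand10)
  expect_identical(nrow(pairs), 10L)
  expect_identical(sum(pairs$mirna_id == "miR-126-5p"), 4L)
  expect_identical(sum(pairs$mirna_id == "miR-29a-3p"), 3L)
  expect_identical(sum(pairs$mirna_id == "miR-19b-3p"), 3L)

  # VAVP alias maps to VAPA in the meta gene list
  meta_alias <- c(setdiff(published_meta_genes(), "VAPA"), "VAVP")
  cand_alias <- candidate_genes(tm, top5, meta_alias)
  expect_true("VAPA" %in% cand_alias$gene_id)

  # empty meta list: empty overlap; ordering stable under input shuffling
  expect_identical(nrow(candidate_genes(tm, top5, character(0))), 0L)
  set.seed(3)
  recs_shuf <- recs[sample(nrow(recs)), ]
  tm_s <- suppressWarnings(build_target_map(recs_shuf, top5))
  expect_identical(pairing_table(candidate_genes(tm_s, top5,
                                                 published_meta_genes())),
                   pairing_table(cand))
})

test_that("consensus recovery matches the product of retention rates", {
  sizes <- vapply(1:50, function(sd) {
    p <- sim_params(source_retention = c(a = 0.9, b = 0.8, c = 0.7),
                    decoys_per_source = 0, seed = sd)
    m <- simulate_mirna_study(p)
    recs <- simulate_target_sources(p, m$truth)
    tm <- suppressWarnings(build_target_map(recs, m$truth$de_mirnas))
    sum(lengths(lapply(tm, `[[`, "consensus")))
  }, numeric(1))
  n_true <- 10 * 20
  expected <- 0.9 * 0.8 * 0.7 * n_true
  se <- sqrt(n_true * 0.504 * (1 - 0.504) / 50)
  expect_lt(abs(mean(sizes) - expected), 4 * se + 1)
})

test_that("synthetic truth: full retention recovers planted target genes", {
  p <- sim_params(source_retention = c(a = 1, b = 1, c = 1),
                  decoys_per_source = 0, targets_from = "de_genes",
                  targets_per_mirna = 5, seed = 17)
  sim <- simulate_studies(p)
  m <- simulate_mirna_study(p, sim$truth)
  recs <- simulate_target_sources(p, m$truth)
  tm <- build_target_map(recs, m$truth$de_mirnas)
  cand <- candidate_genes(tm, m$truth$de_mirnas, sim$truth$de_genes)
  expect_setequal(cand$gene_id, unique(m$truth$true_targets$gene_id))
})
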