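test_that("expression round trip is lossless and validated", {
  dir <- withr::local_tempdir()
  st <- toy_study("s1", genes = 5)
  paths <- write_toy_expression_files(st, dir)
  back <- read_expression(paths$matrix, paths$annotation)
  expect_identical(back$study_id, "s1")
  expect_identical(dim(back$mat), dim(st$mat))
  expect_identical(back$mat, st$mat)
  expect_identical(back$group, st$group)

  # annotation missing a sample is rejected
  ann <- read.table(paths$annotation, header = TRUE, sep = "\t")
  write.table(ann[-1, ], paths$annotation, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_expression(paths$matrix, paths$annotation),
               "missing sample")
})

test_that("toy 3x4 matrix reads with the expected shape", {
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.tsv"); ap <- file.path(dir, "a.tsv")
  writeLines(c("gene_id\ta\tb\tc\td",
               "g1\t1\t2\t3\t4", "g2\t5\t6\t7\t8", "g3\t1\t1\t2\t2"), mp)
  writeLines(c("sample_id\tgroup\tstudy_id",
               "a\tcase\tS", "b\tcase\tS", "c\tcontrol\tS", "d\tcontrol\tS"),
             ap)
  st <- read_expression(mp, ap)
  expect_identical(dim(st$mat), c(3L, 4L))
})

test_that("duplicate gene rows collapse by the configured rule", {
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.tsv"); ap <- file.path(dir, "a.tsv")
  writeLines(c("gene_id\ta\tb\tc\td",
               "g1\t5\t5\t5\t5", "g1\t7\t7\t7\t7", "g2\t1\t1\t1\t1"), mp)
  writeLines(c("sample_id\tgroup\tstudy_id",
               "a\tcase\tS", "b\tcase\tS", "c\tcontrol\tS", "d\tcontrol\tS"),
             ap)
  st <- read_expression(mp, ap)
  expect_equal(unname(st$mat["g1", 1]), 7)   # max-mean keeps the 7.0 row
  st2 <- read_expression(mp, ap, collapse = "mean")
  expect_equal(unname(st2$mat["g1", 1]), 6)
})

test_that("group labels and sample ids are validated", {
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.tsv"); ap <- file.path(dir, "a.tsv")
  writeLines(c("gene_id\ta\tb\tc\td",
               "g1\t1\t2\t3\t4", "g2\t2\t3\t4\t5"), mp)
  writeLines(c("sample_id\tgroup\tstudy_id",
               "a\ttreated\tS", "b\tcase\tS", "c\tcontrol\tS",
               "d\tcontrol\tS"), ap)
  expect_error(read_expression(mp, ap), "unknown group label")
  writeLines(c("sample_id\tgroup\tstudy_id",
               "a\tcase\tS", "a\tcase\tS", "c\tcontrol\tS",
               "d\tcontrol\tS"), ap)
  expect_error(read_expression(mp, ap), "duplicate sample id")
})

test_that("GMT parsing: one set per line, dedup, empty set rejected", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "x.gmt")
  writeLines(c("setA\tdescA\tg1\tg2\tg2\tg3", "setB\t\tg2\tg4"), gmt)
  gs <- read_genesets(gmt)
  expect_length(gs$sets, 2)
  expect_identical(gs$sets$setA, c("g1", "g2", "g3"))  # member de-duplicated
  writeLines(c("setA\tdescA\tg1", "empty\tdesc"), gmt)
  expect_error(read_genesets(gmt), "empty member list")
  # round trip
  writeLines(c("setA\tdescA\tg1\tg2", "setB\tdescB\tg3"), gmt)
  gs <- read_genesets(gmt)
  gmt2 <- file.path(dir, "y.gmt")
  write_genesets(gs, gmt2)
  expect_identical(read_genesets(gmt2)$sets, gs$sets)
})

test_that("target tables need exactly three sources with a closed region vocabulary", {
  dir <- withr::local_tempdir()
  recs <- published_target_fixture(include_kif3a = FALSE)
  paths <- write_targets(recs, dir)
  back <- read_targets(paths)
  hit <- back$mirna_id == "miR-126-5p" & back$gene_id == "NDUFS1" &
    back$region == "3UTR"
  expect_identical(sum(hit), 3L)  # reported by all three sources

  expect_error(read_targets(paths[1:2]), "exactly three")

  # case-insensitive region normalization, unknown token rejected
  tp <- file.path(dir, "t1.tsv")
  writeLines(c("mirna_id\tgene_id\tregion", "m1\tg1\t3utr"), tp)
  one <- read_targets(c(a = tp, b = paths[[1]], c = paths[[2]]))
  expect_identical(one$region[one$source == "a"], "3UTR")
  writeLines(c("mirna_id\tgene_id\tregion", "m1\tg1\tintron"), tp)
  expect_error(read_targets(c(a = tp, b = paths[[1]], c = paths[[2]])),
               "unknown region token")
})

test_that("PPI edges are canonicalized, deduplicated and validated", {
  dir <- withr::local_tempdir()
  pp <- file.path(dir, "ppi.tsv")
  writeLines(c("gene_a\tgene_b\tcombined_score",
               "B\tA\t0.5", "A\tB\t0.9", "C\tD\t0.2"), pp)
  ppi <- read_ppi(pp)
  expect_identical(nrow(ppi), 2L)
  expect_identical(ppi$gene_a[1], "A")       # canonical ordering
  expect_equal(ppi$combined_score[1], 0.9)   # duplicate keeps max score
  writeLines(c("gene_a\tgene_b\tcombined_score", "A\tA\t0.5"), pp)
  expect_error(read_ppi(pp), "self-loop")
  writeLines(c("gene_a\tgene_b\tcombined_score", "A\tB\t1.5"), pp)
  expect_error(read_ppi(pp), "outside")
})

test_that("write_results rounds to 6 significant digits with full companions", {
  dir <- withr::local_tempdir()
  tab <- data.frame(gene_id = "g1", p = 0.123456789)
  files <- write_results(list(out = tab), NULL, dir)
  back <- read.table(files[1], header = TRUE, sep = "\t",
                     colClasses = "character")
  expect_identical(back$p, "0.123457")
  expect_equal(as.numeric(back$p_full), 0.123456789)
})
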