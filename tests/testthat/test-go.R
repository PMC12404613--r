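test_that("process selection respects the minimum-representation cutoff", {
  ann <- toy_annotation(c(60, 55, 10))
  genes <- unique(ann$gene)
  expect_equal(length(select_processes(ann, genes, min_count = 50)), 2)
  expect_equal(length(select_processes(ann, genes, min_count = 1)), 3)
  # only genes present in the dataset count
  expect_equal(length(select_processes(ann, genes[1:30], min_count = 50)), 0)
  expect_warning(out <- select_processes(ann[0, ], genes), "empty")
  expect_equal(length(out), 0)
})

test_that("disjoint-pair enumeration discards shared-gene pairs", {
  ann <- tibble::tibble(
    gene = c("g1", "g2", "g2", "g3", "g4"),
    process = c("A", "A", "B", "B", "C")
  )
  genes <- unique(ann$gene)
  pairs <- enumerate_disjoint_pairs(c("A", "B", "C"), ann, genes)
  # A and B share g2 -> discarded; A-C and B-C are disjoint
  expect_equal(nrow(pairs), 2)
  expect_equal(attr(pairs, "n_shared_discarded"), 1L)
  # 5 mutually disjoint processes -> all C(5,2) pairs
  ann5 <- toy_annotation(rep(3, 5))
  p5 <- enumerate_disjoint_pairs(unique(ann5$process), ann5,
                                 unique(ann5$gene))
  expect_equal(nrow(p5), choose(5, 2))
})

test_that("pair profiles restrict to cross-process records, symmetrically", {
  cfg <- synth_config(n_genes = 400, n_pairs = 8000, law = "product",
                      noise_sd = 0.05, n_processes = 4,
                      genes_per_process = 60, overlap_fraction = 0,
                      seed = 11)
  ann <- generate_annotations(cfg)
  recs <- preprocess_sga(generate_fitness_table(cfg))
  rt <- residual_table(recs, laws = "product")
  pab <- pair_residual_profile(rt, ann, "P001", "P002")
  pba <- pair_residual_profile(rt, ann, "P002", "P001")
  expect_equal(pab$median, pba$median)
  expect_equal(pab$n, pba$n)
  expect_true(sum(pab$n) > 0)
  # product-law data under the product law: occupied bin medians near zero
  occ <- pab[pab$n >= 20, ]
  expect_true(all(abs(occ$median) < 3 * 0.05 / sqrt(occ$n) + 0.01))
  # a pair with no qualifying records returns all-empty bins
  ann2 <- dplyr::bind_rows(ann,
                           tibble::tibble(gene = c("ZZ1", "ZZ2"),
                                          process = c("PX", "PY")))
  empty <- pair_residual_profile(rt, ann2, "PX", "PY")
  expect_equal(sum(empty$n), 0)
  expect_equal(nrow(empty), 10)
})

test_that("profiles under the wrong law deviate with the ordering sign", {
  cfg <- synth_config(n_genes = 400, n_pairs = 12000, law = "product",
                      noise_sd = 0.05, n_processes = 3,
                      genes_per_process = 80, seed = 21)
  ann <- generate_annotations(cfg)
  recs <- preprocess_sga(generate_fitness_table(cfg))
  rt_min <- residual_table(recs, laws = "minimum")
  prof <- pair_residual_profile(rt_min, ann, "P001", "P002")
  occ <- prof[prof$n >= 30, ]
  # minimum predicts too high on product-law truth: negative medians,
  # increasingly so for more severe mutations
  expect_true(all(occ$median < 0.01))
  expect_lt(occ$median[which.min(occ$bin_mid)],
            occ$median[which.max(occ$bin_mid)] + 1e-9)
})

test_that("intra-process pairs show heavier residual tails when noisier", {
  cfg <- synth_config(n_genes = 500, n_pairs = 15000, law = "product",
                      noise_sd = 0.05, sigma_intra = 0.2,
                      n_processes = 4, genes_per_process = 100,
                      overlap_fraction = 0, seed = 13)
  ann <- generate_annotations(cfg)
  recs <- generate_fitness_table(cfg, annotation = ann)
  rt <- residual_table(preprocess_sga(recs), laws = "product")
  tails <- intra_vs_inter_tails(rt, ann, threshold = 0.1)
  expect_setequal(tails$class, c("intra", "inter"))
  intra <- tails[tails$class == "intra", ]
  inter <- tails[tails$class == "inter", ]
  expect_gt(intra$frac_above, inter$frac_above)
  expect_gt(intra$frac_below, inter$frac_below)
})

test_that("tail fractions handle degenerate inputs per the contract", {
  ann <- toy_annotation(c(2, 2), genes = c("GA", "GX", "GB", "GY"))
  rt <- tibble::tibble(
    query_gene = c("GA", "GA", "QQ"), array_gene = c("GX", "GB", "GX"),
    law = "product", residual = c(0, 0.5, 9), max_single = 0.9
  )
  tails <- intra_vs_inter_tails(rt, ann, threshold = 0.1)
  # GA & GX share P001 -> intra; record with unannotated QQ is excluded
  expect_equal(attr(tails, "n_unannotated"), 1)
  intra <- tails[tails$class == "intra", ]
  expect_equal(intra$frac_above, 0)   # all-zero residuals: no tails
  inter <- tails[tails$class == "inter", ]
  expect_equal(inter$frac_above, 1)  # the +0.5 record, GA-GB inter
  expect_error(intra_vs_inter_tails(rt, ann, threshold = -1))
})

test_that("annotation readers parse TSV and GAF dialects", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "ann.tsv")
  writeLines(c("g1\tP1", "g2\tP1", "g1\tP2", "g1\tP2"), tsv)
  ann <- read_annotation(tsv)
  expect_equal(nrow(ann), 3)  # duplicate collapsed
  gaf <- file.path(dir, "ann.gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    paste("DB", "ID1", "GENE1", "", "GO:0001", "ref", "IDA", "", "P",
          "", "", "", "", "", "", "", "", sep = "\t"),
    paste("DB", "ID2", "GENE2", "", "GO:0002", "ref", "IEA", "", "C",
          "", "", "", "", "", "", "", "", sep = "\t")
  ), gaf)
  g <- read_gaf(gaf)
  expect_equal(g$gene, "GENE1")  # aspect C dropped
  expect_equal(g$process, "GO:0001")
  g2 <- read_gaf(gaf, evidence = "IEA")
  expect_equal(nrow(g2), 0)
})

test_that("overlap controls in generated annotations drive pair exclusion", {
  cfg0 <- synth_config(n_genes = 500, n_pairs = 100, n_processes = 5,
                       genes_per_process = 60, overlap_fraction = 0,
                       seed = 1)
  ann0 <- generate_annotations(cfg0)
  pairs0 <- enumerate_disjoint_pairs(unique(ann0$process), ann0,
                                     unique(ann0$gene))
  expect_equal(nrow(pairs0), choose(5, 2))
  cfg1 <- synth_config(n_genes = 500, n_pairs = 100, n_processes = 2,
                       genes_per_process = 60, overlap_fraction = 1,
                       seed = 1)
  ann1 <- generate_annotations(cfg1)
  pairs1 <- enumerate_disjoint_pairs(unique(ann1$process), ann1,
                                     unique(ann1$gene))
  expect_equal(nrow(pairs1), 0)
  expect_equal(attr(pairs1, "n_shared_discarded"), 1L)
  # all processes of 60 genes clear a min_count of 50
  expect_equal(length(select_processes(ann0, unique(ann0$gene), 50)), 5)
})
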