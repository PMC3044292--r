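small_cfg <- function(...) {
  panel_config(n_samples = 20, class_sizes = c(a = 10, b = 10),
               n_genes = 15, n_metabolites_known = 5,
               n_metabolites_unknown = 5, n_true_pairs = 2,
               n_outlier_pairs = 2, n_background_mutations = 4,
               n_background_cnv = 2,
               heterogeneous_classes = character(), ...)
}

test_that("identical seeds give bit-identical panels", {
  cfg <- function(seed) panel_config(n_genes = 500,
                                     n_metabolites_known = 20,
                                     n_metabolites_unknown = 20,
                                     n_true_pairs = 10, n_outlier_pairs = 5,
                                     seed = seed)
  a <- generate_panel(cfg(1))
  b <- generate_panel(cfg(1))
  expect_identical(a$panel$genes, b$panel$genes)
  expect_identical(a$panel$metabolites, b$panel$metabolites)
  expect_identical(a$truth, b$truth)
  c <- generate_panel(cfg(2))
  expect_false(identical(a$panel$genes, c$panel$genes))
})

test_that("missingness honours the configured rate and spares spiked cells", {
  gp0 <- generate_panel(small_cfg(missing_rate = 0, seed = 3))
  expect_false(anyNA(gp0$panel$metabolites))
  gp <- generate_panel(small_cfg(missing_rate = 0.4, seed = 3))
  rate <- mean(is.na(gp$panel$metabolites))
  expect_gt(rate, 0.25)
  expect_lt(rate, 0.55)
  op <- gp$truth$outlier_pairs
  for (i in seq_len(nrow(op))) {
    expect_false(is.na(gp$panel$metabolites[op$metabolite_id[i],
                                            op$sample_id[i]]))
  }
  expect_false(anyNA(gp$panel$genes))
})

test_that("panel structure follows the id and class conventions", {
  gp <- generate_panel(small_cfg(seed = 9))
  mets <- rownames(gp$panel$metabolites)
  expect_identical(sum(grepl("^C\\d{5}$", mets)), 5L)
  expect_identical(sum(grepl("^X-\\d+$", mets)), 5L)
  expect_identical(table(gp$panel$samples$class)[["a"]], 10L)
  # every planted outlier pair has exactly one knowledge row on the same
  # gene and spiked cell line
  op <- gp$truth$outlier_pairs
  for (i in seq_len(nrow(op))) {
    n_mut <- sum(gp$truth$mutation_table$gene_id == op$gene_id[i] &
                   gp$truth$mutation_table$cell_line == op$sample_id[i])
    n_cnv <- sum(gp$truth$cnv_table$gene_id == op$gene_id[i] &
                   gp$truth$cnv_table$cell_line == op$sample_id[i])
    expect_identical(n_mut + n_cnv, 1L)
  }
  # planted true and outlier pairs are disjoint
  expect_length(intersect(
    paste(gp$truth$true_pairs$gene_id, gp$truth$true_pairs$metabolite_id),
    paste(op$gene_id, op$metabolite_id)), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(panel_config(n_samples = 10, class_sizes = c(a = 4, b = 4)),
               "class_sizes")
  expect_error(panel_config(missing_rate = 1), "missing_rate")
  expect_error(panel_config(n_samples = 6, class_sizes = c(a = 3, b = 3),
                            n_genes = 3, n_metabolites_known = 2,
                            n_metabolites_unknown = 2, n_true_pairs = 3,
                            n_outlier_pairs = 2),
               "planted pairs")
  expect_error(panel_config(true_pair_slope_range = c(2, 1)), "slope_range")
})

test_that("realized coupling strength matches the analytic attenuation", {
  # met = s * gene + noise with gene-noise SD 0.5, met-noise SD 1, s = 1.5:
  # expected PCC = s * 0.5 / sqrt(s^2 * 0.25 + 1) = 0.6
  rs <- c()
  for (s in 1:100) {
    gp <- generate_panel(panel_config(
      n_samples = 40, class_sizes = c(a = 20, b = 20), n_genes = 10,
      n_metabolites_known = 3, n_metabolites_unknown = 3,
      informative_gene_fraction = 0, informative_metabolite_fraction = 0,
      gene_noise_sd = 0.5, metabolite_noise_sd = 1, missing_rate = 0,
      n_true_pairs = 3, true_pair_slope_range = c(1.5, 1.5),
      n_outlier_pairs = 0, heterogeneous_classes = character(),
      n_background_mutations = 0, n_background_cnv = 0, seed = s))
    tp <- gp$truth$true_pairs
    for (i in 1:3) {
      rs <- c(rs, cor(gp$panel$genes[tp$gene_id[i], ],
                      gp$panel$metabolites[tp$metabolite_id[i], ]))
    }
  }
  expected <- 1.5 * 0.5 / sqrt(1.5^2 * 0.25 + 1)
  expect_equal(mean(rs), expected, tolerance = 0.05)
})

test_that("outlier pairs are background-uncorrelated", {
  # dropping the spiked sample, the remaining background of a planted
  # outlier pair is plain noise: |PCC| < 0.3 in at least 95% of seeds
  ok <- 0
  for (s in 1:100) {
    gp <- generate_panel(panel_config(
      n_samples = 80, class_sizes = c(a = 40, b = 40), n_genes = 10,
      n_metabolites_known = 3, n_metabolites_unknown = 3,
      informative_gene_fraction = 0, informative_metabolite_fraction = 0,
      missing_rate = 0, n_true_pairs = 0, n_outlier_pairs = 1,
      heterogeneous_classes = character(), n_background_mutations = 0,
      n_background_cnv = 0, seed = s))
    op <- gp$truth$outlier_pairs
    keep <- colnames(gp$panel$genes) != op$sample_id[1]
    r <- cor(gp$panel$genes[op$gene_id[1], keep],
             gp$panel$metabolites[op$metabolite_id[1], keep])
    ok <- ok + (abs(r) < 0.3)
  }
  expect_gte(ok, 95)
})

test_that("write_panel round-trips losslessly and tolerates empty truth", {
  gp <- generate_panel(small_cfg(missing_rate = 0.3, seed = 6))
  dir <- withr::local_tempdir()
  write_panel(gp$panel, gp$truth, dir)
  back <- read_panel(dir)
  expect_identical(back$panel$genes, gp$panel$genes)
  expect_identical(back$panel$metabolites, gp$panel$metabolites)
  expect_identical(back$panel$samples, gp$panel$samples)
  expect_identical(back$panel$annotation, gp$panel$annotation)
  expect_identical(back$truth$true_pairs, gp$truth$true_pairs)
  expect_identical(back$truth$outlier_pairs, gp$truth$outlier_pairs)
  expect_identical(back$truth$mutation_table, gp$truth$mutation_table)
  expect_identical(back$truth$cnv_table, gp$truth$cnv_table)

  # empty truth tables write as header-only files that still parse
  dir2 <- withr::local_tempdir()
  write_panel(gp$panel, NULL, dir2)
  back2 <- read_panel(dir2)
  expect_identical(nrow(back2$truth$true_pairs), 0L)
  expect_identical(nrow(back2$truth$mutation_table), 0L)

  # documented column counts: matrices are 1 + n_samples columns
  hdr <- strsplit(readLines(file.path(dir, "genes.tsv"), n = 1), "\t")[[1]]
  expect_length(hdr, 1 + ncol(gp$panel$genes))
})
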