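rec_row <- function(pcc = NA, pqc = NA, n_outliers = NA, pcc_rm = NA,
                    pqc_rm = NA, n_complete = 25L, category = NA_character_,
                    gene_id = "G1", metabolite_id = "M1") {
  data.frame(gene_id = gene_id, metabolite_id = metabolite_id,
             n_complete = n_complete, pcc = pcc, pqc = pqc,
             n_outliers = as.integer(n_outliers), pcc_rm = pcc_rm,
             pqc_rm = pqc_rm, category = category,
             stringsAsFactors = FALSE)
}

test_that("threshold validation enforces the rule geometry", {
  th <- decision_thresholds()
  expect_identical(th$pcc_outlier_min, 0.6)
  expect_identical(th$max_outliers, 3L)
  expect_error(decision_thresholds(pcc_outlier_min = 1.2), "\\[0, 1\\]")
  expect_error(decision_thresholds(pqc_outlier_max = 0.6,
                                   pqc_assoc_min = 0.5), "below")
  expect_error(decision_thresholds(max_outliers = 0), "max_outliers")
})

test_that("classification reproduces the benchmark outlier and association calls", {
  # an amplified-gene style pair: PCC 0.90, PQC 0.008, one outlier, low
  # post-removal PCC
  out <- classify_pairs(rec_row(pcc = 0.90, pqc = 0.008, n_outliers = 1,
                                pcc_rm = 0.05, pqc_rm = 0.02))
  expect_identical(out$category, "outlier_driven")
  # a steady-state enzyme-substrate style pair: PQC 0.69, PCC 0.36
  as_ <- classify_pairs(rec_row(pcc = 0.36, pqc = 0.69))
  expect_identical(as_$category, "robust_association")
  expect_identical(classify_pairs(rec_row(pcc = 0, pqc = 0,
                                          n_outliers = 0))$category, "none")
})

test_that("rule boundaries are strict and undefined operands never satisfy a rule", {
  # boundary values fall through the outlier rule
  expect_identical(classify_pairs(rec_row(pcc = 0.6, pqc = 0.1,
                                          n_outliers = 1,
                                          pcc_rm = 0))$category, "none")
  expect_identical(classify_pairs(rec_row(pcc = 0.9, pqc = 0.3,
                                          n_outliers = 1,
                                          pcc_rm = 0))$category, "none")
  expect_identical(classify_pairs(rec_row(pcc = 0.9, pqc = 0.1,
                                          n_outliers = 3,
                                          pcc_rm = 0))$category, "none")
  # undefined outlier statistics: premise holds but no call is made
  und <- classify_pairs(rec_row(pcc = 0.9, pqc = 0.1))
  expect_identical(und$category, "none")
  expect_identical(attr(und, "undefined_operands"), 1L)
  # insufficient_n passes through untouched
  ins <- classify_pairs(rec_row(pcc = 0.9, pqc = 0.1,
                                category = "insufficient_n"))
  expect_identical(ins$category, "insufficient_n")
})

test_that("every pair receives exactly one category", {
  set.seed(31)
  n <- 500
  recs <- rec_row(gene_id = sprintf("G%03d", seq_len(n)))
  recs$pcc <- ifelse(runif(n) < 0.1, NA, runif(n, -1, 1))
  recs$pqc <- ifelse(runif(n) < 0.1, NA, runif(n, -1, 1))
  recs$n_outliers <- ifelse(runif(n) < 0.5, NA,
                            as.integer(sample(0:5, n, replace = TRUE)))
  recs$pcc_rm <- ifelse(is.na(recs$n_outliers), NA, runif(n, -1, 1))
  recs$category[sample(n, 20)] <- "insufficient_n"
  out <- classify_pairs(recs)
  expect_true(all(out$category %in% c("outlier_driven", "robust_association",
                                      "none", "insufficient_n")))
  expect_false(anyNA(out$category))
})

test_that("raising the outlier PCC threshold never increases outlier calls", {
  set.seed(13)
  n <- 400
  recs <- rec_row(gene_id = sprintf("G%03d", seq_len(n)))
  recs$pcc <- runif(n, 0, 1)
  recs$pqc <- runif(n, -0.5, 0.5)
  recs$n_outliers <- as.integer(sample(0:4, n, replace = TRUE))
  recs$pcc_rm <- runif(n, -0.5, 0.5)
  counts <- sapply(c(0.3, 0.5, 0.6, 0.7, 0.9), function(cut) {
    sum(classify_pairs(recs, decision_thresholds(pcc_outlier_min = cut))$
          category == "outlier_driven")
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("ranking is a stable descending sort with id tie-breaks", {
  recs <- rbind(rec_row(pcc = 0.5, gene_id = "G2", metabolite_id = "M1"),
                rec_row(pcc = 0.9, gene_id = "G3", metabolite_id = "M2"),
                rec_row(pcc = 0.5, gene_id = "G1", metabolite_id = "M9"),
                rec_row(pcc = NA, gene_id = "G0", metabolite_id = "M0"))
  out <- rank_candidates(recs, by = "pcc")
  expect_identical(out$gene_id, c("G3", "G1", "G2", "G0"))
  expect_identical(rank_candidates(recs["2", ], by = "pcc")$gene_id, "G3")
  expect_identical(nrow(rank_candidates(recs, gene_subset = character())), 0L)
  sub <- rank_candidates(recs, gene_subset = c("G1", "G2"), by = "pcc")
  expect_identical(sub$gene_id, c("G1", "G2"))
})

test_that("screen_report counts categories and scores against planted truth", {
  recs <- rbind(
    rec_row(gene_id = "G1", metabolite_id = "M1", category = "outlier_driven"),
    rec_row(gene_id = "G2", metabolite_id = "M2", category = "outlier_driven"),
    rec_row(gene_id = "G3", metabolite_id = "M3",
            category = "robust_association"),
    rec_row(gene_id = "G4", metabolite_id = "M4", category = "none"))
  rep0 <- screen_report(recs)
  expect_identical(as.integer(rep0$counts[["outlier_driven"]]), 2L)
  expect_null(rep0$outlier_precision)
  truth <- list(
    true_pairs = data.frame(gene_id = c("G3", "G9"),
                            metabolite_id = c("M3", "M9"), slope = c(1, 1)),
    outlier_pairs = data.frame(gene_id = "G1", metabolite_id = "M1",
                               sample_id = "S1"))
  rep1 <- screen_report(recs, truth)
  expect_equal(rep1$outlier_precision, 0.5)
  expect_equal(rep1$outlier_recall, 1)
  expect_equal(rep1$assoc_precision, 1)
  expect_equal(rep1$assoc_recall, 0.5)
})

test_that("planted events dominate the outlier-driven ranking on a mutated-gene subset", {
  gp <- generate_panel(validation_panel_config("outlier_screen", seed = 2))
  rec <- screen_pairs(gp$panel)
  res <- add_outlier_stats(gp$panel, rec, seed = 2)
  rec2 <- classify_pairs(res$records)
  mut_genes <- unique(gp$truth$mutation_table$gene_id)
  ranked <- rank_candidates(rec2[rec2$category == "outlier_driven", ,
                                 drop = FALSE],
                            gene_subset = mut_genes, by = "pcc")
  truth_key <- paste(gp$truth$outlier_pairs$gene_id,
                     gp$truth$outlier_pairs$metabolite_id)
  expect_gt(nrow(ranked), 0)
  expect_true(all(paste(ranked$gene_id, ranked$metabolite_id) %in% truth_key))
})
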