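ann_row <- function(gene, cmp, pw, rid = "R00001") {
  data.frame(gene_id = gene, compound_id = cmp, reaction_id = rid,
             pathway = pw, stringsAsFactors = FALSE)
}

screened <- function(genes, mets, pqc = NULL) {
  rec <- expand.grid(metabolite_id = mets, gene_id = genes,
                     stringsAsFactors = FALSE)[, 2:1]
  rec$n_complete <- 20L
  rec$pcc <- 0.1
  rec$pqc <- if (is.null(pqc)) 0.1 else pqc
  rec$n_outliers <- NA_integer_
  rec$pcc_rm <- NA_real_
  rec$pqc_rm <- NA_real_
  rec$category <- "none"
  rec
}

test_that("overlay groups by pathway, orders by gene count and masks linked cells", {
  rec <- screened(c("G1", "G2", "G3", "G4", "G5", "G6", "G7", "G8"),
                  c("C1", "C2", "C3"))
  ann <- rbind(ann_row(c("G1", "G2", "G3", "G4", "G5"), "C1", "pwBig"),
               ann_row(c("G6", "G7", "G8"), c("C2", "C3", "C2"), "pwSmall"))
  ov <- overlay_matrix(rec, ann)
  # pathway with 5 genes precedes the one with 3
  expect_identical(ov$pathways, c("pwBig", "pwSmall"))
  expect_identical(ov$rows$pathway, rep(c("pwBig", "pwSmall"), c(5, 3)))
  expect_identical(dim(ov$pqc), c(8L, 3L))
  expect_identical(dim(ov$mask), dim(ov$pqc))
  # masked cells are exactly the annotated gene-compound links: G1..G5
  # against C1, plus G6-C2, G7-C3 and G8-C2
  expect_identical(sum(ov$mask), 8L)
  # matrix cells carry the screened pqc
  expect_true(all(ov$pqc == 0.1))
})

test_that("mask cardinality equals the annotation entries surviving the screen", {
  set.seed(8)
  genes <- sprintf("G%02d", 1:12)
  mets <- sprintf("C%02d", 1:8)
  rec <- screened(genes[1:9], mets[1:6])
  ann <- data.frame(gene_id = sample(genes, 50, replace = TRUE),
                    compound_id = sample(mets, 50, replace = TRUE),
                    reaction_id = sprintf("R%05d", 1:50),
                    pathway = sample(c("p1", "p2", "p3"), 50, replace = TRUE),
                    stringsAsFactors = FALSE)
  ov <- overlay_matrix(rec, ann)
  # oracle: set intersection of annotation links with screened id pairs,
  # counted once per pathway block the gene and compound both occupy
  surv <- ann[ann$gene_id %in% rec$gene_id &
                ann$compound_id %in% rec$metabolite_id, ]
  links <- unique(paste(surv$gene_id, surv$compound_id))
  cells <- outer(paste(ov$rows$gene_id), paste(ov$cols$compound_id), paste)
  expect_identical(sum(ov$mask), sum(cells %in% links))
  # a link occupies at most one cell per (row-pathway, col-pathway) block
  expect_lte(sum(ov$mask), length(links) * length(ov$pathways)^2)
  # every masked cell is a real annotation link
  expect_true(all(cells[ov$mask] %in% links))
})

test_that("overlay with disjoint vocabularies warns and returns empty", {
  rec <- screened("G1", "C1")
  expect_warning(ov <- overlay_matrix(rec, ann_row("GX", "CX", "p")),
                 "no annotation")
  expect_identical(dim(ov$pqc), c(0L, 0L))
})

test_that("crossref matches flagged cell lines to mutation and CNV rows", {
  rec <- screened(c("G1", "G2", "G3"), c("M1", "M2", "M3"))
  rec$category <- "none"
  pick <- function(g, m) rec$gene_id == g & rec$metabolite_id == m
  rec$category[pick("G1", "M1")] <- "outlier_driven"
  rec$pcc[pick("G1", "M1")] <- 0.8
  rec$category[pick("G2", "M2")] <- "outlier_driven"
  rec$pcc[pick("G2", "M2")] <- 0.9
  rec$category[pick("G3", "M3")] <- "outlier_driven"
  rec$pcc[pick("G3", "M3")] <- 0.7
  flags <- data.frame(
    gene_id = c("G1", "G2", "G3"), metabolite_id = c("M1", "M2", "M3"),
    sample_id = c("CL1", "CL2", "CL3"), robust_distance = 9,
    cutoff = 2.7, flagged = 1L, stringsAsFactors = FALSE)
  mut <- data.frame(gene_id = c("G1", "G9"), cell_line = c("CL1", "CL1"),
                    stringsAsFactors = FALSE)
  cnv <- data.frame(gene_id = "G2", cell_line = "CL2", copy_number = 14.22,
                    stringsAsFactors = FALSE)
  m <- crossref_structural(rec, mut, cnv, flags)
  # exactly the two planted matches, ordered by descending PCC
  expect_identical(nrow(m), 2L)
  expect_identical(m$gene_id, c("G2", "G1"))
  expect_identical(m$evidence, c("cnv", "mutation"))
  expect_identical(m$copy_number, c(14.22, NA))
  # gene match without a flagged-cell-line match yields nothing
  mut2 <- data.frame(gene_id = "G3", cell_line = "CL1")
  expect_identical(nrow(crossref_structural(rec, mut2, cnv[0, ], flags)), 0L)
  expect_identical(nrow(crossref_structural(rec, mut[0, ], cnv[0, ], flags)),
                   0L)
})

test_that("permuting the mutation cell lines destroys the cross-reference", {
  hits <- perm_hits <- 0
  for (s in 1:10) {
    gp <- generate_panel(validation_panel_config("outlier_screen", seed = s))
    rec <- screen_pairs(gp$panel)
    res <- add_outlier_stats(gp$panel, rec, seed = s)
    rec2 <- classify_pairs(res$records)
    mut <- gp$truth$mutation_table
    hits <- hits + nrow(crossref_structural(rec2, mut, gp$truth$cnv_table,
                                            res$flags))
    set.seed(s)
    mut$cell_line <- sample(mut$cell_line)
    perm_hits <- perm_hits +
      nrow(crossref_structural(rec2, mut, gp$truth$cnv_table[0, ],
                               res$flags))
  }
  expect_gt(hits, perm_hits)
})

test_that("annotation coverage counts direct, high and unannotated-high pairs", {
  rec <- screened(c("G1", "G2", "G3"), c("C1", "C2"),
                  pqc = c(0.9, 0.1, NA, 0.6, 0.2, 0.8))
  ann <- rbind(ann_row("G1", "C1", "p"), ann_row("G2", "C1", "p"),
               ann_row("G9", "C1", "p"))
  cov <- annotation_coverage(rec, ann, pqc_high = 0.5)
  expect_identical(cov$n_direct_total, 2L)      # G1-C1, G2-C1 in screen
  expect_identical(cov$n_direct_defined, 1L)    # G2-C1 pqc is NA
  expect_identical(cov$n_direct_high, 1L)       # G1-C1 at 0.9
  expect_identical(cov$n_high_unannotated, 2L)  # G2-C2, G3-C2
  expect_identical(annotation_coverage(rec, ann, pqc_high = 1.01)$n_direct_high,
                   0L)
  far <- annotation_coverage(rec, ann_row("GX", "CX", "p"))
  expect_identical(unlist(far, use.names = FALSE), c(0L, 0L, 0L, 3L))
})
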