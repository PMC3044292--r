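# Annotation overlay and structural cross-referencing.

#' Read gene-compound-pathway annotation
#'
#' @param path TSV file with columns `gene_id`, `compound_id`,
#'   `reaction_id`, `pathway`.
#' @return A validated annotation data frame.
#' @export
read_annotation <- function(path) {
  validate_annotation(read_tsv_empty_ok(path, c("gene_id", "compound_id",
                                                "reaction_id", "pathway")))
}

#' Read a mutation table
#'
#' @param path TSV file with columns `gene_id`, `cell_line`.
#' @return A validated data frame.
#' @export
read_mutations <- function(path) {
  validate_knowledge(read_tsv_empty_ok(path, c("gene_id", "cell_line")),
                     "mutation")
}

#' Read a copy-number table
#'
#' @param path TSV file with columns `gene_id`, `cell_line`,
#'   `copy_number`.
#' @return A validated data frame.
#' @export
read_cnv <- function(path) {
  cnv <- read_tsv_empty_ok(path, c("gene_id", "cell_line", "copy_number"))
  cnv$copy_number <- as.numeric(cnv$copy_number)
  validate_knowledge(cnv, "cnv")
}

#' Pathway-grouped correlation matrix with a direct-reaction mask
#'
#' Builds the matrix behind the pathway overlay heat map: the
#' `top_pathways` pathways with the most annotated genes (ties broken
#' alphabetically), rows being the annotated genes grouped by pathway and
#' columns the annotated compounds grouped by pathway, with the quadrant
#' correlation of each gene-compound pair as cell value and a logical
#' mask marking the cells that an annotation entry links as a direct
#' reaction. Genes or compounds assigned to several of the selected
#' pathways appear once per pathway block. Only ids present in the
#' screened records are used; with no overlap an empty overlay is
#' returned with a warning.
#'
#' @param records a [screen_pairs()] table.
#' @param annotation an annotation data frame (see [read_annotation()]).
#' @param top_pathways number of pathways retained (default 9).
#' @return A list of class `pathway_overlay`: `pqc` (matrix), `mask`
#'   (logical matrix, same shape), `rows`/`cols` (data frames of
#'   `pathway` and id) and `pathways`.
#' @export
overlay_matrix <- function(records, annotation, top_pathways = 9) {
  annotation <- validate_annotation(annotation)
  genes_in <- unique(records$gene_id)
  cmp_in <- unique(records$metabolite_id)
  ann <- annotation[annotation$gene_id %in% genes_in &
                      annotation$compound_id %in% cmp_in, , drop = FALSE]
  if (nrow(ann) == 0) {
    warning("no annotation entries overlap the screened pairs")
    emp <- matrix(numeric(), 0, 0)
    return(structure(list(pqc = emp, mask = matrix(logical(), 0, 0),
                          rows = data.frame(pathway = character(),
                                            gene_id = character()),
                          cols = data.frame(pathway = character(),
                                            compound_id = character()),
                          pathways = character()),
                     class = "pathway_overlay"))
  }
  n_genes_pw <- vapply(split(ann$gene_id, ann$pathway),
                       function(g) length(unique(g)), integer(1))
  pw <- names(sort(n_genes_pw, decreasing = TRUE))
  # sort() on the named vector breaks count ties alphabetically only if
  # we enforce it ourselves:
  pw <- names(n_genes_pw)[order(-n_genes_pw, names(n_genes_pw))]
  pw <- pw[seq_len(min(top_pathways, length(pw)))]

  rows <- do.call(rbind, lapply(pw, function(p) {
    g <- sort(unique(ann$gene_id[ann$pathway == p]))
    data.frame(pathway = rep(p, length(g)), gene_id = g,
               stringsAsFactors = FALSE)
  }))
  cols <- do.call(rbind, lapply(pw, function(p) {
    cc <- sort(unique(ann$compound_id[ann$pathway == p]))
    data.frame(pathway = rep(p, length(cc)), compound_id = cc,
               stringsAsFactors = FALSE)
  }))

  rec_key <- paste(records$gene_id, records$metabolite_id, sep = "~")
  cell_gene <- rep(rows$gene_id, times = nrow(cols))
  cell_cmp <- rep(cols$compound_id, each = nrow(rows))
  idx <- match(paste(cell_gene, cell_cmp, sep = "~"), rec_key)
  pqc <- matrix(records$pqc[idx], nrow = nrow(rows), ncol = nrow(cols))
  ann_key <- unique(paste(ann$gene_id, ann$compound_id, sep = "~"))
  mask <- matrix(paste(cell_gene, cell_cmp, sep = "~") %in% ann_key,
                 nrow = nrow(rows), ncol = nrow(cols))
  rownames(pqc) <- rownames(mask) <- paste(rows$pathway, rows$gene_id,
                                           sep = "|")
  colnames(pqc) <- colnames(mask) <- paste(cols$pathway, cols$compound_id,
                                           sep = "|")
  structure(list(pqc = pqc, mask = mask, rows = rows, cols = cols,
                 pathways = pw),
            class = "pathway_overlay")
}

#' Cross-reference outlier-driven pairs with mutation and CNV tables
#'
#' For every `outlier_driven` pair, reports the mutation and CNV rows
#' whose gene matches the pair's gene and whose cell line is among the
#' samples flagged as bivariate outliers for that pair — the situation
#' where an extreme gene-metabolite point coincides with a documented
#' genomic event in the same gene and cell line. Matches are ordered by
#' the pair's Pearson correlation, descending.
#'
#' @param records a classified pair table.
#' @param mutations mutation data frame (`gene_id`, `cell_line`).
#' @param cnv CNV data frame (`gene_id`, `cell_line`, `copy_number`).
#' @param flags per-sample flag table from [add_outlier_stats()].
#' @return A data frame with `gene_id`, `metabolite_id`, `cell_line`,
#'   `evidence` (`"mutation"` or `"cnv"`), `copy_number` (`NA` for
#'   mutations) and `pcc`.
#' @export
crossref_structural <- function(records, mutations, cnv, flags) {
  mutations <- validate_knowledge(mutations, "mutation")
  cnv <- validate_knowledge(cnv, "cnv")
  od <- records[!is.na(records$category) &
                  records$category == "outlier_driven", , drop = FALSE]
  empty <- data.frame(gene_id = character(), metabolite_id = character(),
                      cell_line = character(), evidence = character(),
                      copy_number = numeric(), pcc = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(od) == 0) return(empty)
  out <- vector("list", nrow(od))
  for (i in seq_len(nrow(od))) {
    g <- od$gene_id[i]; m <- od$metabolite_id[i]
    fl <- flags[flags$gene_id == g & flags$metabolite_id == m &
                  flags$flagged == 1, , drop = FALSE]
    if (nrow(fl) == 0) next
    mm <- mutations[mutations$gene_id == g &
                      mutations$cell_line %in% fl$sample_id, , drop = FALSE]
    cc <- cnv[cnv$gene_id == g & cnv$cell_line %in% fl$sample_id, ,
              drop = FALSE]
    res <- rbind(
      if (nrow(mm)) data.frame(gene_id = g, metabolite_id = m,
                               cell_line = mm$cell_line,
                               evidence = "mutation",
                               copy_number = NA_real_, pcc = od$pcc[i],
                               stringsAsFactors = FALSE),
      if (nrow(cc)) data.frame(gene_id = g, metabolite_id = m,
                               cell_line = cc$cell_line, evidence = "cnv",
                               copy_number = cc$copy_number,
                               pcc = od$pcc[i], stringsAsFactors = FALSE))
    out[[i]] <- res
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(-out$pcc, out$gene_id, out$metabolite_id,
                   out$cell_line), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage of screened correlations by direct-reaction annotation
#'
#' Quantifies how many annotated direct gene-compound relationships are
#' visible in the screen and how many of them reach a high quadrant
#' correlation — on real panels only a minority do — plus the
#' complementary count of high-PQC pairs lacking any annotation, the
#' candidates for indirect relationships.
#'
#' @param records a screened pair table.
#' @param annotation annotation data frame.
#' @param pqc_high PQC threshold defining "high" (default 0.5).
#' @return A list with `n_direct_total` (distinct annotated pairs with
#'   both ids in the screen), `n_direct_defined` (of those, with a
#'   defined PQC), `n_direct_high`, and `n_high_unannotated`.
#' @export
annotation_coverage <- function(records, annotation, pqc_high = 0.5) {
  annotation <- validate_annotation(annotation)
  rec_key <- paste(records$gene_id, records$metabolite_id, sep = "~")
  ann_key <- unique(paste(annotation$gene_id, annotation$compound_id,
                          sep = "~"))
  idx <- match(ann_key, rec_key)
  idx <- idx[!is.na(idx)]
  pqc <- records$pqc[idx]
  high <- !is.na(records$pqc) & records$pqc >= pqc_high
  list(n_direct_total = length(idx),
       n_direct_defined = sum(!is.na(pqc)),
       n_direct_high = sum(!is.na(pqc) & pqc >= pqc_high),
       n_high_unannotated = sum(high & !(rec_key %in% ann_key)))
}

#' Export a pathway overlay as TSV files
#'
#' Writes `matrix.tsv` and `mask.tsv` with identical row and column
#' headers (`pathway|id`).
#'
#' @param overlay a [overlay_matrix()] result.
#' @param directory output directory.
#' @return Invisibly, the paths written.
#' @export
write_overlay <- function(overlay, directory) {
  stopifnot(inherits(overlay, "pathway_overlay"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  mpath <- file.path(directory, "matrix.tsv")
  kpath <- file.path(directory, "mask.tsv")
  write_matrix_tsv(overlay$pqc, mpath, "row_id")
  mk <- overlay$mask * 1L
  storage.mode(mk) <- "integer"
  df <- data.frame(rownames(mk), mk, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("row_id", colnames(mk))
  write_tsv_file(df, kpath)
  invisible(c(matrix = mpath, mask = kpath))
}
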