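#' Decision thresholds for pair classification
#'
#' Thresholds of the rule-based classifier that separates outlier-driven
#' pairs from steady-state associations. The outlier rule follows the
#' empirical criterion that a high Pearson correlation with a near-zero
#' quadrant correlation and fewer than 3 multidimensional outliers is
#' almost always an artifact of one or two extreme cell lines:
#' `pcc > 0.6`, `pqc < 0.3`, `n_outliers < 3`, plus a low post-removal
#' Pearson correlation (`pcc_rm < 0.3`). The association rule requires
#' both correlations to be high (`pqc >= 0.5` and `pcc >= 0.3`). All
#' inequalities on `pcc`/`pqc` are strict for the outlier rule; boundary
#' values fall through to the next rule.
#'
#' @param pcc_outlier_min,pqc_outlier_max,max_outliers,pcc_rm_max
#'   outlier-driven rule operands (`max_outliers` is an exclusive bound).
#' @param pqc_assoc_min,pcc_assoc_min association rule operands.
#' @return A validated list of class `decision_thresholds`.
#' @export
decision_thresholds <- function(pcc_outlier_min = 0.6,
                                pqc_outlier_max = 0.3,
                                max_outliers = 3,
                                pqc_assoc_min = 0.5,
                                pcc_assoc_min = 0.3,
                                pcc_rm_max = 0.3) {
  th <- list(pcc_outlier_min = pcc_outlier_min,
             pqc_outlier_max = pqc_outlier_max,
             max_outliers = as.integer(max_outliers),
             pqc_assoc_min = pqc_assoc_min,
             pcc_assoc_min = pcc_assoc_min,
             pcc_rm_max = pcc_rm_max)
  vals <- unlist(th[c("pcc_outlier_min", "pqc_outlier_max", "pqc_assoc_min",
                      "pcc_assoc_min", "pcc_rm_max")])
  if (any(vals < 0 | vals > 1)) {
    stop("correlation thresholds must be in [0, 1]", call. = FALSE)
  }
  if (th$pqc_outlier_max >= th$pqc_assoc_min) {
    stop("pqc_outlier_max must be below pqc_assoc_min", call. = FALSE)
  }
  if (th$max_outliers < 1) stop("max_outliers must be >= 1", call. = FALSE)
  class(th) <- "decision_thresholds"
  th
}

#' Classify screened gene-metabolite pairs
#'
#' Assigns each pair exactly one category:
#' \describe{
#'   \item{`outlier_driven`}{`pcc > pcc_outlier_min` and
#'     `pqc < pqc_outlier_max` and `n_outliers < max_outliers` and
#'     `pcc_rm < pcc_rm_max` — a high classical correlation that
#'     collapses once a small number of robustly flagged samples is
#'     removed; the signature of a cell-line-specific genomic event.}
#'   \item{`robust_association`}{otherwise, `pqc >= pqc_assoc_min` and
#'     `pcc >= pcc_assoc_min` — a steady-state association supported by
#'     both estimators.}
#'   \item{`none`}{everything else, including pairs where a rule operand
#'     is undefined (undefined statistics never satisfy a rule).}
#'   \item{`insufficient_n`}{pre-assigned by [screen_pairs()]; passes
#'     through unchanged.}
#' }
#'
#' @param records a [screen_pairs()] table, with outlier statistics
#'   filled by [add_outlier_stats()] for the candidate pairs.
#' @param thresholds a [decision_thresholds()].
#' @return The records with the `category` column filled. The number of
#'   pairs whose outlier-rule operands were undefined while the pcc/pqc
#'   premise held is stored in the attribute `undefined_operands`.
#' @export
classify_pairs <- function(records, thresholds = decision_thresholds()) {
  th <- thresholds
  keep <- !is.na(records$category) & records$category == "insufficient_n"

  pcc <- records$pcc; pqc <- records$pqc
  n_out <- records$n_outliers; pcc_rm <- records$pcc_rm
  def <- function(v, test) !is.na(v) & test
  premise <- def(pcc, pcc > th$pcc_outlier_min) &
    def(pqc, pqc < th$pqc_outlier_max)
  outlier <- premise & def(n_out, n_out < th$max_outliers) &
    def(pcc_rm, pcc_rm < th$pcc_rm_max)
  assoc <- !outlier & def(pqc, pqc >= th$pqc_assoc_min) &
    def(pcc, pcc >= th$pcc_assoc_min)

  cat_ <- rep("none", nrow(records))
  cat_[assoc] <- "robust_association"
  cat_[outlier] <- "outlier_driven"
  cat_[keep] <- "insufficient_n"
  records$category <- cat_
  # premise held but the outlier statistics were never computed/defined
  undef <- premise & !keep & (is.na(n_out) | is.na(pcc_rm))
  attr(records, "undefined_operands") <- sum(undef)
  attr(records, "thresholds") <- th
  records
}

#' Rank screened pairs by a correlation statistic
#'
#' Stable descending sort by `pcc` or `pqc`, optionally restricted to a
#' gene subset (e.g. the genes carried by a mutation catalogue). Ties
#' are broken by gene id then metabolite id; pairs with an undefined
#' statistic sink to the bottom.
#'
#' @param records a (classified) pair table.
#' @param gene_subset character vector of gene ids, or `NULL` for all.
#' @param by `"pcc"` or `"pqc"`.
#' @return The reordered subset of `records`.
#' @export
rank_candidates <- function(records, gene_subset = NULL,
                            by = c("pcc", "pqc")) {
  by <- match.arg(by)
  if (!is.null(gene_subset)) {
    records <- records[records$gene_id %in% gene_subset, , drop = FALSE]
  }
  if (nrow(records) == 0) return(records)
  v <- records[[by]]
  ord <- order(is.na(v), -ifelse(is.na(v), -Inf, v),
               records$gene_id, records$metabolite_id)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a classified pair table
#'
#' Counts pairs per category and, when planted ground truth is supplied,
#' reports precision and recall of the `outlier_driven` calls against the
#' planted outlier pairs and of the `robust_association` calls against
#' the planted true pairs.
#'
#' @param records a classified pair table.
#' @param truth optional ground truth as returned by [generate_panel()].
#' @return A list of class `screen_report` with `counts` and, if truth
#'   was given, `outlier_precision`, `outlier_recall`, `assoc_precision`,
#'   `assoc_recall`.
#' @export
screen_report <- function(records, truth = NULL) {
  lev <- c("robust_association", "outlier_driven", "none", "insufficient_n")
  counts <- table(factor(records$category, levels = lev))
  out <- list(counts = counts)
  if (!is.null(truth)) {
    key <- function(g, m) paste(g, m, sep = "~")
    pred_out <- key(records$gene_id, records$metabolite_id)[
      records$category == "outlier_driven"]
    true_out <- key(truth$outlier_pairs$gene_id,
                    truth$outlier_pairs$metabolite_id)
    pred_as <- key(records$gene_id, records$metabolite_id)[
      records$category == "robust_association"]
    true_as <- key(truth$true_pairs$gene_id, truth$true_pairs$metabolite_id)
    pr <- function(pred, tru) {
      c(precision = if (length(pred)) mean(pred %in% tru) else NA_real_,
        recall = if (length(tru)) mean(tru %in% pred) else NA_real_)
    }
    po <- pr(pred_out, true_out)
    pa <- pr(pred_as, true_as)
    out$outlier_precision <- po[["precision"]]
    out$outlier_recall <- po[["recall"]]
    out$assoc_precision <- pa[["precision"]]
    out$assoc_recall <- pa[["recall"]]
  }
  class(out) <- "screen_report"
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat("pair categories:\n")
  print(x$counts)
  if (!is.null(x$outlier_precision)) {
    cat(sprintf("outlier_driven vs truth: precision %.3f, recall %.3f\n",
                x$outlier_precision, x$outlier_recall))
    cat(sprintf("robust_association vs truth: precision %.3f, recall %.3f\n",
                x$assoc_precision, x$assoc_recall))
  }
  invisible(x)
}
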