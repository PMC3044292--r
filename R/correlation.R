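#' Pearson correlation over pairwise-complete samples
#'
#' Classical Pearson correlation coefficient (PCC) computed over the
#' samples where both vectors are observed. Undefined results (fewer than
#' 3 complete pairs, or a constant complete sub-vector) are reported as
#' `NA`, never coerced to zero.
#'
#' @param x,y numeric vectors of equal length; `NA` allowed.
#' @return A list with `r` (the correlation or `NA`) and `n_complete`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, n_complete = n))
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(list(r = NA_real_, n_complete = n))
  }
  list(r = cor(xs, ys), n_complete = n)
}

#' Pairwise quadrant correlation (PQC)
#'
#' Robust correlation from the signs of median-centered values. Over the
#' pairwise-complete samples, with `u = sign(x - median(x))` and
#' `v = sign(y - median(y))`, the raw quadrant statistic is
#' `q = sum(u * v) / n` (values exactly at the median contribute zero to
#' the numerator; the denominator is unchanged). With
#' `sine_transform = TRUE` (the default) the returned value is
#' `sin(pi * q / 2)`, which makes the estimator consistent for the
#' correlation of a bivariate normal and hence comparable in magnitude
#' to the Pearson coefficient. Undefined below 3 complete pairs.
#'
#' @param x,y numeric vectors of equal length; `NA` allowed.
#' @param sine_transform apply the normal-consistency transform.
#' @return A list with `r` and `n_complete`.
#' @examples
#' quadrant_cor(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))$r # sin(2 * pi / 5)
#' @export
quadrant_cor <- function(x, y, sine_transform = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, n_complete = n))
  xs <- x[ok]; ys <- y[ok]
  u <- sign(xs - median(xs))
  v <- sign(ys - median(ys))
  q <- sum(u * v) / n
  r <- if (sine_transform) sin(pi * q / 2) else q
  list(r = r, n_complete = n)
}

#' Screen all gene-metabolite pairs of a panel
#'
#' Computes the Pearson and pairwise quadrant correlations for every
#' gene x metabolite pair (or a supplied subset of pairs) over
#' pairwise-complete samples, and initialises the pair-record table used
#' by the rest of the pipeline. Outlier statistics (`n_outliers`,
#' `pcc_rm`, `pqc_rm`) are left `NA` here and filled by
#' [add_outlier_stats()]; the final `category` is assigned by
#' [classify_pairs()], except that pairs with fewer than `min_complete`
#' complete samples are marked `insufficient_n` immediately.
#'
#' @param panel an [omics_panel()].
#' @param min_complete minimum number of pairwise-complete samples for a
#'   pair to enter classification (default 10).
#' @param pairs optional data frame with columns `gene_id` and
#'   `metabolite_id` restricting the screen to the listed pairs.
#' @param sine_transform passed to [quadrant_cor()].
#' @return A data frame with one row per pair, ordered by gene id then
#'   metabolite id, with columns `gene_id`, `metabolite_id`, `n_complete`,
#'   `pcc`, `pqc`, `n_outliers`, `pcc_rm`, `pqc_rm`, `category`.
#' @export
screen_pairs <- function(panel, min_complete = 10, pairs = NULL,
                         sine_transform = TRUE) {
  stopifnot(inherits(panel, "omics_panel"))
  G <- panel$genes
  M <- panel$metabolites
  if (nrow(G) == 0 || nrow(M) == 0) {
    stop("panel has an empty feature matrix", call. = FALSE)
  }

  if (!is.null(pairs)) {
    stopifnot(all(c("gene_id", "metabolite_id") %in% names(pairs)))
    pairs <- pairs[order(pairs$gene_id, pairs$metabolite_id), , drop = FALSE]
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      x <- G[pairs$gene_id[i], ]
      y <- M[pairs$metabolite_id[i], ]
      p <- pearson_cor(x, y)
      q <- quadrant_cor(x, y, sine_transform)
      c(n = p$n_complete, pcc = p$r, pqc = q$r)
    })
    res <- do.call(rbind, res)
    rec <- data.frame(gene_id = pairs$gene_id,
                      metabolite_id = pairs$metabolite_id,
                      n_complete = as.integer(res[, "n"]),
                      pcc = res[, "pcc"], pqc = res[, "pqc"],
                      stringsAsFactors = FALSE)
  } else {
    gid <- sort(rownames(G))
    mid <- sort(rownames(M))
    Gs <- G[gid, , drop = FALSE]
    Ms <- M[mid, , drop = FALSE]
    ncomp <- (!is.na(Gs)) %*% t(!is.na(Ms))
    pcc <- suppressWarnings(cor(t(Gs), t(Ms),
                                use = "pairwise.complete.obs"))
    pcc[!is.finite(pcc)] <- NA_real_
    pcc[ncomp < 3] <- NA_real_
    pqc <- pqc_matrix(Gs, Ms, sine_transform)
    # one row per (gene, metabolite), genes as the slow index
    rec <- data.frame(
      gene_id = rep(gid, each = length(mid)),
      metabolite_id = rep(mid, times = length(gid)),
      n_complete = as.integer(t(ncomp)),
      pcc = as.vector(t(pcc)),
      pqc = as.vector(t(pqc)),
      stringsAsFactors = FALSE)
  }

  rec$n_outliers <- NA_integer_
  rec$pcc_rm <- NA_real_
  rec$pqc_rm <- NA_real_
  rec$category <- NA_character_
  rec$category[rec$n_complete < min_complete] <- "insufficient_n"
  attr(rec, "min_complete") <- min_complete
  attr(rec, "sine_transform") <- sine_transform
  rownames(rec) <- NULL
  rec
}

# Quadrant correlations for all gene x metabolite pairs.  When the gene
# matrix is complete (the usual case), the pairwise-complete subset of a
# pair depends only on the metabolite's missingness, so the computation
# vectorises per metabolite; otherwise fall back to the per-pair form.
pqc_matrix <- function(G, M, sine_transform) {
  ng <- nrow(G); nm <- nrow(M)
  out <- matrix(NA_real_, ng, nm, dimnames = list(rownames(G), rownames(M)))
  if (!anyNA(G)) {
    for (j in seq_len(nm)) {
      idx <- which(!is.na(M[j, ]))
      n <- length(idx)
      if (n < 3) next
      X <- G[, idx, drop = FALSE]
      med <- apply(X, 1, median)
      U <- sign(X - med)
      v <- sign(M[j, idx] - median(M[j, idx]))
      q <- as.vector(U %*% v) / n
      out[, j] <- if (sine_transform) sin(pi * q / 2) else q
    }
  } else {
    for (i in seq_len(ng)) {
      for (j in seq_len(nm)) {
        out[i, j] <- quadrant_cor(G[i, ], M[j, ], sine_transform)$r
      }
    }
  }
  out
}
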