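#' Flag bivariate outlier samples for one gene-metabolite pair
#'
#' Computes robust Mahalanobis distances of the pairwise-complete
#' samples in the 2-D gene-metabolite scatter from an [mcd_fit()] and
#' flags every sample whose squared distance exceeds the
#' `chi-square(2, quantile)` cutoff, scaled by a simulation-calibrated
#' finite-sample factor so the false-flag rate stays near its nominal
#' level at the 20-40 complete samples typical of non-imputed metabolite
#' pairs. With `quantile = 1` the cutoff is infinite and nothing is
#' flagged.
#'
#' Pairs with fewer than `min_complete` complete samples, or with a
#' degenerate (collinear) scatter, are not an error: a flag object with
#' the corresponding `status` and zero flagged samples is returned so
#' that panel-wide loops can skip them.
#'
#' @param x,y numeric vectors of equal length (`NA` allowed); names are
#'   used as sample ids when present.
#' @param quantile chi-square coverage for the cutoff (default 0.975).
#' @param min_complete minimum complete-pair count (default 10).
#' @param method,seed,n_starts passed to [mcd_fit()].
#' @return An object of class `outlier_flag`: `status` (`"ok"`,
#'   `"insufficient_n"` or `"degenerate"`), `sample_ids`,
#'   `robust_distance` (per complete sample), `cutoff`,
#'   `flagged_samples`, `estimator`, `h`, `n_complete`.
#' @export
flag_outliers <- function(x, y, quantile = 0.975, min_complete = 10,
                          method = "auto", seed = 1, n_starts = 500) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  base <- list(sample_ids = ids[ok], robust_distance = numeric(),
               cutoff = NA_real_, flagged_samples = character(),
               estimator = NA_character_, h = NA_integer_, n_complete = n)
  if (n < max(min_complete, 6)) {
    base$status <- "insufficient_n"
    return(structure(base, class = "outlier_flag"))
  }
  pts <- cbind(x[ok], y[ok])
  fit <- tryCatch(mcd_fit(pts, method = method, seed = seed,
                          n_starts = n_starts),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    base$status <- "degenerate"
    return(structure(base, class = "outlier_flag"))
  }
  d <- sqrt(mahalanobis(pts, fit$location, fit$scatter))
  # chi-square cutoff with the simulation-calibrated finite-sample factor;
  # without it the asymptotic 0.975 cutoff badly over-flags at n ~ 20-30
  cutoff <- if (quantile >= 1) Inf else {
    sqrt(qchisq(quantile, df = 2) * mcd_cutoff_factor(n))
  }
  flagged <- ids[ok][d > cutoff]
  structure(
    list(status = "ok", sample_ids = ids[ok], robust_distance = d,
         cutoff = cutoff, flagged_samples = flagged,
         estimator = fit$method, h = fit$h, n_complete = n),
    class = "outlier_flag")
}

#' @export
print.outlier_flag <- function(x, ...) {
  cat("outlier_flag [", x$status, "]: n_complete =", x$n_complete)
  if (x$status == "ok") {
    cat(",", length(x$flagged_samples), "flagged (cutoff",
        sprintf("%.3f", x$cutoff), ",", x$estimator, "MCD)")
  }
  cat("\n")
  invisible(x)
}

#' Recompute correlations after outlier removal
#'
#' Drops the flagged samples of an [flag_outliers()] result and
#' recomputes the Pearson and quadrant correlations on the remaining
#' pairwise-complete samples. Undefined when fewer than 3 samples
#' remain. With zero flagged samples the inputs are returned unchanged
#' (up to recomputation).
#'
#' @param x,y the same vectors the flag was computed on.
#' @param flag an `outlier_flag`.
#' @param sine_transform passed to [quadrant_cor()].
#' @return A list with `pcc_rm`, `pqc_rm` and `n_used`.
#' @export
recompute_after_removal <- function(x, y, flag, sine_transform = TRUE) {
  stopifnot(inherits(flag, "outlier_flag"))
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  drop <- ids %in% flag$flagged_samples
  p <- pearson_cor(x[!drop], y[!drop])
  q <- quadrant_cor(x[!drop], y[!drop], sine_transform)
  list(pcc_rm = p$r, pqc_rm = q$r, n_used = p$n_complete)
}

#' Add per-pair outlier statistics to a screened pair table
#'
#' Runs [flag_outliers()] and [recompute_after_removal()] for each
#' selected pair of a [screen_pairs()] table and fills the `n_outliers`,
#' `pcc_rm` and `pqc_rm` columns. By default only candidate pairs are
#' processed — those whose Pearson correlation exceeds the
#' `pcc_outlier_min` threshold, the only pairs for which the
#' outlier-driven decision rule ever consults these statistics — since a
#' robust fit per gene x metabolite pair is the expensive step of the
#' pipeline. Use `candidates = "all"` to process every pair with enough
#' complete samples.
#'
#' @param panel the [omics_panel()] the records were screened from.
#' @param records a [screen_pairs()] table.
#' @param thresholds a [decision_thresholds()]; supplies the candidate
#'   cutoff.
#' @param candidates `"rule"` (default) or `"all"`.
#' @param quantile chi-square coverage for flagging.
#' @param min_complete minimum complete-pair count.
#' @param seed base seed; each pair gets a deterministic sub-seed derived
#'   from its ids, so results do not depend on which other pairs are
#'   processed.
#' @param n_starts random starts for the fast MCD search.
#' @return A list with `records` (the updated table) and `flags` (a long
#'   data frame with one row per complete sample of each processed pair:
#'   `gene_id`, `metabolite_id`, `sample_id`, `robust_distance`,
#'   `cutoff`, `flagged`).
#' @export
add_outlier_stats <- function(panel, records,
                              thresholds = decision_thresholds(),
                              candidates = c("rule", "all"),
                              quantile = 0.975, min_complete = 10,
                              seed = 1, n_starts = 500) {
  stopifnot(inherits(panel, "omics_panel"))
  candidates <- match.arg(candidates)
  sel <- if (candidates == "all") {
    which(records$n_complete >= min_complete)
  } else {
    which(!is.na(records$pcc) & records$pcc > thresholds$pcc_outlier_min &
            records$n_complete >= min_complete)
  }
  base <- substream_seed(seed, "mcd")
  flag_rows <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    g <- records$gene_id[i]
    m <- records$metabolite_id[i]
    x <- panel$genes[g, ]
    y <- panel$metabolites[m, ]
    fl <- flag_outliers(x, y, quantile = quantile,
                        min_complete = min_complete,
                        seed = pair_seed(base, g, m), n_starts = n_starts)
    if (fl$status != "ok") next
    records$n_outliers[i] <- length(fl$flagged_samples)
    rm_ <- recompute_after_removal(x, y, fl,
                                   sine_transform =
                                     isTRUE(attr(records, "sine_transform")))
    records$pcc_rm[i] <- rm_$pcc_rm
    records$pqc_rm[i] <- rm_$pqc_rm
    flag_rows[[k]] <- data.frame(
      gene_id = g, metabolite_id = m, sample_id = fl$sample_ids,
      robust_distance = fl$robust_distance, cutoff = fl$cutoff,
      flagged = as.integer(fl$sample_ids %in% fl$flagged_samples),
      stringsAsFactors = FALSE)
  }
  flags <- do.call(rbind, flag_rows)
  if (is.null(flags)) {
    flags <- data.frame(gene_id = character(), metabolite_id = character(),
                        sample_id = character(), robust_distance = numeric(),
                        cutoff = numeric(), flagged = integer(),
                        stringsAsFactors = FALSE)
  }
  rownames(flags) <- NULL
  list(records = records, flags = flags)
}
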