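# Class-removal analysis: random-forest out-of-bag error, backward
# feature elimination, progressive removal of the worst classes and the
# random-removal null.

#' Median-impute missing values per feature
#'
#' Random forests require complete inputs; non-imputed metabolite values
#' are filled with the per-feature median before classification.
#'
#' @param features samples x features numeric matrix.
#' @return The matrix with `NA`s replaced; the number of imputed cells is
#'   reported with a message.
#' @export
impute_median <- function(features) {
  n_imp <- sum(is.na(features))
  if (n_imp == 0) return(features)
  for (j in seq_len(ncol(features))) {
    miss <- is.na(features[, j])
    if (any(miss)) {
      med <- median(features[, j], na.rm = TRUE)
      if (is.na(med)) med <- 0
      features[miss, j] <- med
    }
  }
  message("impute_median: filled ", n_imp, " missing values")
  features
}

#' Extract a classification feature matrix from a panel
#'
#' @param panel an [omics_panel()].
#' @param source `"metabolites"` or `"genes"`.
#' @return A samples x features matrix (median-imputed when needed) with
#'   the class labels attached as the `"labels"` attribute.
#' @export
panel_features <- function(panel, source = c("metabolites", "genes")) {
  source <- match.arg(source)
  m <- t(panel[[source]])
  if (anyNA(m)) m <- impute_median(m)
  attr(m, "labels") <- factor(panel$samples$class)
  m
}

#' Out-of-bag classification error
#'
#' Fits a seeded random forest and reports the out-of-bag error: the
#' misclassification rate of each sample predicted by the trees whose
#' bootstrap did not contain it. Plain (non-stratified) bootstrap, the
#' default of the underlying implementation.
#'
#' @param features samples x features numeric matrix (`NA`s are
#'   median-imputed per feature first).
#' @param labels class label per sample; at least 2 classes.
#' @param n_trees forest size (default 1000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return A list with `oob_error`, `per_class_misclassified` (named
#'   counts), `per_class_size`, `votes` and `predicted`.
#' @export
oob_error <- function(features, labels, n_trees = 1000, seed = 1) {
  features <- as.matrix(features)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
  if (length(labels) != nrow(features)) {
    stop("labels must match rows of features", call. = FALSE)
  }
  if (anyNA(features)) features <- impute_median(features)
  rf <- with_seed(seed,
                  randomForest::randomForest(x = features, y = labels,
                                             ntree = n_trees))
  pred <- rf$predicted
  mis <- pred != labels
  list(oob_error = mean(mis),
       per_class_misclassified = tapply(mis, labels, sum),
       per_class_size = table(labels),
       votes = rf$votes,
       predicted = pred)
}

#' Backward feature elimination with an out-of-bag 1-SE rule
#'
#' Ranks features by permutation importance from a single initial forest
#' (importance is not recomputed as the set shrinks), then repeatedly
#' drops the least important `drop_fraction` of the remaining features,
#' refitting and recording the out-of-bag error at each set size. The
#' selected set is the smallest one whose error is within
#' `se_rule` standard errors of the minimum, with
#' `s.e. = sqrt(p * (1 - p) / n)` at the minimum error `p`.
#'
#' @param features samples x features matrix.
#' @param labels class labels.
#' @param drop_fraction fraction of remaining features dropped per round;
#'   `0` returns the full feature set.
#' @param se_rule multiplier on the standard error (default 1).
#' @param n_trees forest size per fit.
#' @param seed RNG seed.
#' @return A list with `selected` (feature names), `trace` (data frame of
#'   `n_features`, `oob_error`), `min_oob`, `se` and `drop_step` (named
#'   integer: elimination round at which each feature was dropped; `NA`
#'   for features in the final surviving set).
#' @export
backward_select <- function(features, labels, drop_fraction = 0.2,
                            se_rule = 1.0, n_trees = 1000, seed = 1) {
  features <- as.matrix(features)
  labels <- droplevels(factor(labels))
  if (anyNA(features)) features <- impute_median(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  base <- substream_seed(seed, "select")
  rf0 <- with_seed(base,
                   randomForest::randomForest(x = features, y = labels,
                                              ntree = n_trees,
                                              importance = TRUE))
  imp <- randomForest::importance(rf0, type = 1)[, 1]
  ranked <- names(sort(imp, decreasing = TRUE))  # stable: ties keep order

  drop_step <- stats::setNames(rep(NA_integer_, length(ranked)), ranked)
  trace <- data.frame(n_features = length(ranked),
                      oob_error = mean(rf0$predicted != labels))
  current <- ranked
  round_i <- 0L
  if (drop_fraction > 0) {
    repeat {
      ndrop <- max(1L, floor(drop_fraction * length(current)))
      if (length(current) - ndrop < 2) break
      round_i <- round_i + 1L
      dropped <- current[(length(current) - ndrop + 1):length(current)]
      drop_step[dropped] <- round_i
      current <- current[seq_len(length(current) - ndrop)]
      fit <- with_seed(base + round_i,
                       randomForest::randomForest(
                         x = features[, current, drop = FALSE], y = labels,
                         ntree = n_trees))
      trace <- rbind(trace, data.frame(n_features = length(current),
                                       oob_error = mean(fit$predicted !=
                                                          labels)))
    }
  }
  min_oob <- min(trace$oob_error)
  se <- sqrt(min_oob * (1 - min_oob) / length(labels))
  ok <- trace$oob_error <= min_oob + se_rule * se
  sel_n <- min(trace$n_features[ok])
  selected <- ranked[seq_len(sel_n)]
  list(selected = selected, trace = trace, min_oob = min_oob, se = se,
       drop_step = drop_step)
}

#' Progressive removal of the classes that drive classification error
#'
#' Starting from the full panel, repeatedly removes the class with the
#' largest count of out-of-bag misclassified samples (ties broken in
#' favour of the smaller class, then label order), refits and records
#' the out-of-bag error. This traces how much a few heterogeneous or
#' under-sampled classes dominate the error of the full panel.
#'
#' @param features samples x features matrix.
#' @param labels class labels.
#' @param n_steps number of classes to remove; must be at most
#'   `nlevels(labels) - 2`.
#' @param n_trees,seed forest parameters.
#' @return A data frame of class `removal_trace` with columns `step`,
#'   `removed_class` (`NA` at step 0), `oob_error`, `n_classes`; the
#'   per-step per-class misclassification counts and remaining class
#'   sets are attached as attributes `per_class` and `remaining`.
#' @export
progressive_removal <- function(features, labels, n_steps, n_trees = 1000,
                                seed = 1) {
  features <- as.matrix(features)
  labels <- droplevels(factor(labels))
  if (n_steps >= nlevels(labels) - 1) {
    stop("n_steps must be below the number of classes minus 1",
         call. = FALSE)
  }
  base <- substream_seed(seed, "forest")
  keep <- rep(TRUE, length(labels))
  rows <- vector("list", n_steps + 1)
  per_class <- vector("list", n_steps + 1)
  remaining <- vector("list", n_steps + 1)
  removed <- NA_character_
  for (step in 0:n_steps) {
    lab <- droplevels(labels[keep])
    fit <- oob_error(features[keep, , drop = FALSE], lab,
                     n_trees = n_trees, seed = base + step)
    rows[[step + 1]] <- data.frame(step = step, removed_class = removed,
                                   oob_error = fit$oob_error,
                                   n_classes = nlevels(lab),
                                   stringsAsFactors = FALSE)
    per_class[[step + 1]] <- fit$per_class_misclassified
    remaining[[step + 1]] <- levels(lab)
    if (step < n_steps) {
      removed <- worst_class(fit$per_class_misclassified,
                             fit$per_class_size)
      keep <- keep & labels != removed
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_class") <- per_class
  attr(out, "remaining") <- remaining
  class(out) <- c("removal_trace", "data.frame")
  out
}

# class with the most OOB-misclassified samples; ties go to the smaller
# class, then to label order
worst_class <- function(mis_counts, sizes) {
  mis <- as.vector(mis_counts)
  sz <- as.vector(sizes[names(mis_counts)])
  ord <- order(-mis, sz, names(mis_counts))
  names(mis_counts)[ord[1]]
}

#' Random class-removal null for the progressive-removal trace
#'
#' For each step `k`, draws `reps` random subsets of `k` classes from the
#' full class set, removes them, refits and averages the out-of-bag
#' error. This estimates how much the error improves merely because
#' fewer classes make an easier problem, the baseline against which the
#' targeted progressive removal is judged. Draws that repeat a class
#' subset reuse its fitted error.
#'
#' @param features,labels,n_trees,seed as in [progressive_removal()].
#' @param n_steps number of removal steps.
#' @param reps random draws per step (default 500).
#' @return A data frame with `step`, `null_mean_oob`, `null_reps`
#'   (step 0 is the full-panel error).
#' @export
random_removal_null <- function(features, labels, n_steps, reps = 500,
                                n_trees = 1000, seed = 1) {
  features <- as.matrix(features)
  labels <- droplevels(factor(labels))
  if (n_steps >= nlevels(labels) - 1) {
    stop("n_steps must be below the number of classes minus 1",
         call. = FALSE)
  }
  cls <- levels(labels)
  base <- substream_seed(seed, "null")
  cache <- new.env(parent = emptyenv())
  oob_without <- function(drop_set) {
    key <- paste0("drop:", paste(drop_set, collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    keep <- !(labels %in% drop_set)
    # per-subset seed derived from the subset itself, so results do not
    # depend on the order in which subsets happen to be drawn
    s <- (base + sum(utf8ToInt(key)) * 131L) %% 2147483647L
    val <- oob_error(features[keep, , drop = FALSE],
                     droplevels(labels[keep]),
                     n_trees = n_trees, seed = s)$oob_error
    cache[[key]] <- val
    val
  }
  full <- oob_without(character())
  rows <- data.frame(step = 0L, null_mean_oob = full, null_reps = reps)
  for (k in seq_len(n_steps)) {
    draws <- with_seed(base + 7919L * k,
                       replicate(reps, sort(sample(cls, k)),
                                 simplify = FALSE))
    vals <- vapply(draws, oob_without, numeric(1))
    rows <- rbind(rows, data.frame(step = k, null_mean_oob = mean(vals),
                                   null_reps = reps))
  }
  rows
}

#' Combined class-removal analysis
#'
#' Runs [progressive_removal()] and [random_removal_null()] on the same
#' inputs and merges them into one trace suitable for export.
#'
#' @inheritParams random_removal_null
#' @return A data frame with `step`, `removed_class`, `oob_error`,
#'   `null_mean_oob`, `null_reps`.
#' @export
class_removal_analysis <- function(features, labels, n_steps, reps = 500,
                                   n_trees = 1000, seed = 1) {
  prog <- progressive_removal(features, labels, n_steps,
                              n_trees = n_trees, seed = seed)
  null <- random_removal_null(features, labels, n_steps, reps = reps,
                              n_trees = n_trees, seed = seed)
  merge(as.data.frame(prog)[, c("step", "removed_class", "oob_error")],
        null, by = "step")
}
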