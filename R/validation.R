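# Canonical validation-study configurations.  These encode, in one
# place, the synthetic study conditions under which the package's
# recovery properties are measured (tests and the acceptance script both
# use them); the methods vignette discusses the choices.

#' Panel configurations for the built-in validation studies
#'
#' Two reduced, structure-preserving panel layouts used to measure the
#' pipeline's recovery properties on planted ground truth:
#' \describe{
#'   \item{`"outlier_screen"`}{25 cell lines in two classes, a 25 x 16
#'     feature grid, no class structure, 4 planted linear couplings and 5
#'     planted single-sample spikes of 8 residual SDs on
#'     background-uncorrelated pairs, light missingness. Pairwise-complete
#'     counts land near 22, the analysis size at which a single extreme
#'     cell line can push the Pearson correlation past 0.6 (the regime of
#'     interest for the outlier rule; on much larger complete samples a
#'     lone spike can no longer dominate the PCC).}
#'   \item{`"class_removal"`}{38 samples in 6 classes, including one
#'     2-sample class and one class with 4-fold inflated within-class
#'     variance; 60 metabolite features, 60% of them carrying class
#'     signal; 20% missingness. The layout reproduces, at reduced size,
#'     a panel whose classification error is dominated by one tiny and
#'     one heterogeneous class.}
#' }
#'
#' @param type which study.
#' @param seed master seed for the panel draw.
#' @return A [panel_config()].
#' @export
validation_panel_config <- function(type = c("outlier_screen",
                                             "class_removal"),
                                    seed = 1) {
  type <- match.arg(type)
  switch(type,
    outlier_screen = panel_config(
      n_samples = 25, class_sizes = c(a = 13, b = 12),
      n_genes = 25, n_metabolites_known = 6, n_metabolites_unknown = 10,
      informative_gene_fraction = 0, informative_metabolite_fraction = 0,
      missing_rate = 0.08, n_true_pairs = 4,
      true_pair_slope_range = c(1, 2),
      n_outlier_pairs = 5, outlier_magnitude_sd = 8,
      heterogeneous_classes = character(),
      n_background_mutations = 8, n_background_cnv = 4, seed = seed),
    class_removal = panel_config(
      n_samples = 38,
      class_sizes = c(a = 8, b = 8, c = 8, d = 7, e = 5, f = 2),
      n_genes = 20, n_metabolites_known = 30, n_metabolites_unknown = 30,
      informative_gene_fraction = 0,
      informative_metabolite_fraction = 0.6,
      metabolite_class_effect_sd = 2, metabolite_noise_sd = 1.5,
      missing_rate = 0.2, n_true_pairs = 0, n_outlier_pairs = 0,
      heterogeneous_classes = "c", heterogeneity_factor = 4,
      n_background_mutations = 0, n_background_cnv = 0, seed = seed))
}

#' Simulated feature matrix with class-marker features
#'
#' Builds the feature-selection benchmark: `n_features` standard-normal
#' features over `n_classes` equally sized classes, where the first
#' `n_markers` features are each the sole marker of one non-baseline
#' class (that class's values are shifted by `effect`). Every marker is
#' therefore informative and non-redundant: dropping one makes its class
#' indistinguishable from the baseline class.
#'
#' @param n_per_class samples per class.
#' @param n_classes number of classes (first class is the unmarked
#'   baseline); must exceed `n_markers`.
#' @param n_features total feature count.
#' @param n_markers number of marker features.
#' @param effect mean shift of a marker in its class, in noise-SD units.
#' @param seed RNG seed.
#' @return A list with `features` (samples x features, named columns,
#'   markers first) and `labels` (factor).
#' @export
marker_feature_matrix <- function(n_per_class = 10, n_classes = 6,
                                  n_features = 200, n_markers = 5,
                                  effect = 2.5, seed = 1) {
  stopifnot(n_classes > n_markers, n_features >= n_markers)
  n <- n_per_class * n_classes
  labels <- factor(rep(c("base", paste0("c", seq_len(n_classes - 1))),
                       each = n_per_class))
  X <- with_seed(seed, matrix(rnorm(n * n_features), n, n_features))
  for (j in seq_len(n_markers)) {
    in_class <- labels == paste0("c", j)
    X[in_class, j] <- X[in_class, j] + effect
  }
  colnames(X) <- paste0("f", seq_len(n_features))
  list(features = X, labels = labels)
}
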