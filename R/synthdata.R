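#' Configuration for a synthetic omics panel
#'
#' Describes a cell-line panel with paired transcriptome and metabolome
#' measurements. Defaults emulate the structure of the public NCI-60
#' panel: 57 cell lines in 9 cancer classes (one class with only 2
#' lines), ~1.2e4 gene expression profiles on a log2-like scale, 124
#' known plus 218 unknown metabolites on an arbitrary continuous scale,
#' metabolite noise well above transcript noise, per-cell missingness in
#' the metabolite matrix, a handful of planted linear gene-metabolite
#' couplings, planted single-sample extreme outlier pairs backed by a
#' mutation or copy-number record, and high within-class heterogeneity
#' for the breast, ovarian and CNS classes.
#'
#' @param n_samples number of cell lines.
#' @param class_sizes named integer vector of per-class sample counts;
#'   must sum to `n_samples`. Names become class labels.
#' @param n_genes,n_metabolites_known,n_metabolites_unknown feature counts.
#' @param informative_gene_fraction,informative_metabolite_fraction
#'   fraction of features carrying class-specific mean shifts.
#' @param gene_class_effect_sd,metabolite_class_effect_sd SD of the
#'   per-class mean shifts of informative features.
#' @param gene_noise_sd,metabolite_noise_sd residual noise SDs; the
#'   metabolite default is three times the gene default, reflecting the
#'   much noisier metabolome platform.
#' @param missing_rate per-cell missingness probability for metabolite
#'   values (missing completely at random); must be in `[0, 1)`. The
#'   default leaves a typical pair with 25-35 pairwise-complete samples
#'   out of 57, matching the analysis sizes seen when non-imputed
#'   metabolite measurements are screened on such panels.
#' @param n_true_pairs number of planted linear gene-metabolite couplings.
#' @param true_pair_slope_range length-2 numeric; slopes drawn uniformly.
#' @param n_outlier_pairs number of planted background-uncorrelated pairs
#'   with one spiked sample each.
#' @param outlier_magnitude_sd displacement of the spiked sample, in
#'   units of that sample's own residual SD (including any heterogeneity
#'   inflation), applied to the metabolite (and, when `spike_gene`, the
#'   gene) coordinate.
#' @param spike_gene spike the gene coordinate as well (default `TRUE`;
#'   a cell line with a genomic event typically shows an extreme value on
#'   both axes, which is what inflates the Pearson correlation).
#' @param heterogeneous_classes class names (or indices into
#'   `class_sizes`) whose within-class noise is inflated.
#' @param heterogeneity_factor multiplier on the residual SD within
#'   heterogeneous classes.
#' @param mutation_fraction probability that a planted outlier pair is
#'   backed by a mutation record rather than a CNV record.
#' @param n_background_mutations,n_background_cnv extra knowledge rows
#'   unrelated to planted outliers (decoys for the cross-reference).
#' @param n_pathways number of annotation pathways generated.
#' @param annotated_true_fraction fraction of planted true pairs (with a
#'   known compound) that receive a direct-reaction annotation entry.
#' @param seed master seed; all generator randomness derives from it
#'   through fixed per-component substreams.
#' @return A validated list of class `panel_config`.
#' @export
panel_config <- function(n_samples = 57,
                         class_sizes = c(melanoma = 8, nsclc = 8, colon = 7,
                                         ovarian = 7, renal = 7, breast = 6,
                                         cns = 6, leukemia = 6, prostate = 2),
                         n_genes = 11961,
                         n_metabolites_known = 124,
                         n_metabolites_unknown = 218,
                         informative_gene_fraction = 0.2,
                         informative_metabolite_fraction = 0.3,
                         gene_class_effect_sd = 1.0,
                         metabolite_class_effect_sd = 1.0,
                         gene_noise_sd = 0.5,
                         metabolite_noise_sd = 1.5,
                         missing_rate = 0.45,
                         n_true_pairs = 50,
                         true_pair_slope_range = c(0.5, 2),
                         n_outlier_pairs = 20,
                         outlier_magnitude_sd = 8,
                         spike_gene = TRUE,
                         heterogeneous_classes = c("breast", "ovarian", "cns"),
                         heterogeneity_factor = 3,
                         mutation_fraction = 0.6,
                         n_background_mutations = 150,
                         n_background_cnv = 60,
                         n_pathways = 9,
                         annotated_true_fraction = 0.2,
                         seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples),
              class_sizes = class_sizes,
              n_genes = as.integer(n_genes),
              n_metabolites_known = as.integer(n_metabolites_known),
              n_metabolites_unknown = as.integer(n_metabolites_unknown),
              informative_gene_fraction = informative_gene_fraction,
              informative_metabolite_fraction = informative_metabolite_fraction,
              gene_class_effect_sd = gene_class_effect_sd,
              metabolite_class_effect_sd = metabolite_class_effect_sd,
              gene_noise_sd = gene_noise_sd,
              metabolite_noise_sd = metabolite_noise_sd,
              missing_rate = missing_rate,
              n_true_pairs = as.integer(n_true_pairs),
              true_pair_slope_range = true_pair_slope_range,
              n_outlier_pairs = as.integer(n_outlier_pairs),
              outlier_magnitude_sd = outlier_magnitude_sd,
              spike_gene = isTRUE(spike_gene),
              heterogeneous_classes = heterogeneous_classes,
              heterogeneity_factor = heterogeneity_factor,
              mutation_fraction = mutation_fraction,
              n_background_mutations = as.integer(n_background_mutations),
              n_background_cnv = as.integer(n_background_cnv),
              n_pathways = as.integer(n_pathways),
              annotated_true_fraction = annotated_true_fraction,
              seed = as.integer(seed))
  validate_panel_config(cfg)
  class(cfg) <- "panel_config"
  cfg
}

validate_panel_config <- function(cfg) {
  cs <- cfg$class_sizes
  if (is.null(names(cs)) || any(!nzchar(names(cs)))) {
    names(cs) <- paste0("class", seq_along(cs))
    cfg$class_sizes <- cs
  }
  if (sum(cs) != cfg$n_samples) {
    stop("sum(class_sizes) must equal n_samples", call. = FALSE)
  }
  counts <- c(cfg$n_samples, cs, cfg$n_genes, cfg$n_metabolites_known,
              cfg$n_metabolites_unknown, cfg$n_true_pairs,
              cfg$n_outlier_pairs, cfg$n_background_mutations,
              cfg$n_background_cnv, cfg$n_pathways)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$gene_noise_sd < 0 || cfg$metabolite_noise_sd < 0 ||
      cfg$outlier_magnitude_sd <= 0) {
    stop("noise SDs must be non-negative and outlier_magnitude_sd positive",
         call. = FALSE)
  }
  if (length(cfg$true_pair_slope_range) != 2 ||
      diff(cfg$true_pair_slope_range) < 0) {
    stop("true_pair_slope_range must be a non-decreasing length-2 interval",
         call. = FALSE)
  }
  n_mets <- cfg$n_metabolites_known + cfg$n_metabolites_unknown
  n_planted <- cfg$n_true_pairs + cfg$n_outlier_pairs
  if (n_planted > as.double(cfg$n_genes) * n_mets) {
    stop("more planted pairs than gene x metabolite cells", call. = FALSE)
  }
  # planted pairs use distinct genes and distinct metabolites so each
  # coupling is identifiable against the generator's truth
  if (n_planted > cfg$n_genes || n_planted > n_mets) {
    stop("planted pairs require n_true_pairs + n_outlier_pairs distinct ",
         "genes and metabolites", call. = FALSE)
  }
  hc <- cfg$heterogeneous_classes
  if (is.numeric(hc)) hc <- names(cs)[hc]
  if (!all(hc %in% c(names(cs)))) {
    # silently drop labels absent from this configuration's class set
    hc <- intersect(hc, names(cs))
  }
  cfg$heterogeneous_classes <- hc
  invisible(cfg)
}

#' Generate a synthetic panel with known ground truth
#'
#' Draws a panel under the structural model described in
#' [panel_config()]. Informative features get class-specific mean
#' shifts; planted true pairs set the metabolite row to
#' `slope * gene + noise`; planted outlier pairs keep the metabolite row
#' as independent noise but displace exactly one sample by
#' `outlier_magnitude_sd` residual SDs; metabolite values are then masked
#' missing-completely-at-random, never at a spiked cell (so planted
#' outliers remain observable). Each planted outlier pair is backed by
#' exactly one mutation or CNV row naming the same gene and the spiked
#' cell line. Identical seeds give bit-identical output.
#'
#' @param config a [panel_config()].
#' @return A list with elements `panel` (an [omics_panel()]) and `truth`
#'   (`true_pairs`, `outlier_pairs`, `mutation_table`, `cnv_table`,
#'   `class_labels`).
#' @examples
#' gp <- generate_panel(panel_config(n_genes = 50, n_metabolites_known = 10,
#'                                   n_metabolites_unknown = 10,
#'                                   n_true_pairs = 3, n_outlier_pairs = 2,
#'                                   n_background_mutations = 5,
#'                                   n_background_cnv = 5, seed = 42))
#' gp$panel
#' @export
generate_panel <- function(config = panel_config()) {
  if (!inherits(config, "panel_config")) {
    config <- do.call(panel_config, config)
  }
  cfg <- validate_panel_config(unclass(config))
  cs <- cfg$class_sizes
  if (is.null(names(cs))) names(cs) <- paste0("class", seq_along(cs))
  n <- cfg$n_samples
  n_mets <- cfg$n_metabolites_known + cfg$n_metabolites_unknown
  classes <- rep(names(cs), times = cs)
  hetero <- classes %in% cfg$heterogeneous_classes
  hfac <- ifelse(hetero, cfg$heterogeneity_factor, 1)
  seed <- cfg$seed

  # --- identifiers -------------------------------------------------------
  ids <- with_seed(substream_seed(seed, "ids"), {
    known <- paste0("C", sprintf("%05d", sort(sample(10000:99999,
                                                     cfg$n_metabolites_known))))
    unknown <- paste0("X-", sort(sample(1000:9999,
                                        cfg$n_metabolites_unknown)))
    list(genes = sprintf("G%05d", seq_len(cfg$n_genes)),
         mets = c(known, unknown))
  })
  sample_ids <- paste0(toupper(substr(classes, 1, 2)), "_",
                       unlist(lapply(cs, seq_len), use.names = FALSE))

  # --- gene matrix -------------------------------------------------------
  mu_g <- with_seed(substream_seed(seed, "gene_base"),
                    rnorm(cfg$n_genes, mean = 8, sd = 2))
  n_inf_g <- round(cfg$informative_gene_fraction * cfg$n_genes)
  gene_fx <- with_seed(substream_seed(seed, "gene_class"), {
    idx <- if (n_inf_g > 0) sort(sample(cfg$n_genes, n_inf_g)) else integer()
    eff <- matrix(rnorm(length(idx) * length(cs),
                        sd = cfg$gene_class_effect_sd),
                  nrow = length(idx))
    list(idx = idx, eff = eff)
  })
  G <- with_seed(substream_seed(seed, "gene_noise"), {
    noise <- matrix(rnorm(cfg$n_genes * n), nrow = cfg$n_genes)
    sweep(noise, 2, cfg$gene_noise_sd * hfac, `*`)
  })
  G <- G + mu_g
  if (length(gene_fx$idx)) {
    cls_idx <- match(classes, names(cs))
    G[gene_fx$idx, ] <- G[gene_fx$idx, ] + gene_fx$eff[, cls_idx, drop = FALSE]
  }

  # --- metabolite matrix -------------------------------------------------
  mu_m <- with_seed(substream_seed(seed, "met_base"),
                    rnorm(n_mets, mean = 10, sd = 2))
  n_inf_m <- round(cfg$informative_metabolite_fraction * n_mets)
  met_fx <- with_seed(substream_seed(seed, "met_class"), {
    idx <- if (n_inf_m > 0) sort(sample(n_mets, n_inf_m)) else integer()
    eff <- matrix(rnorm(length(idx) * length(cs),
                        sd = cfg$metabolite_class_effect_sd),
                  nrow = length(idx))
    list(idx = idx, eff = eff)
  })
  M <- with_seed(substream_seed(seed, "met_noise"), {
    noise <- matrix(rnorm(n_mets * n), nrow = n_mets)
    sweep(noise, 2, cfg$metabolite_noise_sd * hfac, `*`)
  })
  M <- M + mu_m
  if (length(met_fx$idx)) {
    cls_idx <- match(classes, names(cs))
    M[met_fx$idx, ] <- M[met_fx$idx, ] + met_fx$eff[, cls_idx, drop = FALSE]
  }

  # --- planted pairs -----------------------------------------------------
  # planted genes/metabolites come from the non-informative pools so the
  # coupling (or its absence, for outlier pairs) is not confounded with
  # class structure
  n_planted <- cfg$n_true_pairs + cfg$n_outlier_pairs
  plant <- with_seed(substream_seed(seed, "pairs"), {
    free_g <- setdiff(seq_len(cfg$n_genes), gene_fx$idx)
    free_m <- setdiff(seq_len(n_mets), met_fx$idx)
    if (length(free_g) < n_planted || length(free_m) < n_planted) {
      stop("not enough non-informative features to plant ", n_planted,
           " pairs; lower the informative fractions or pair counts",
           call. = FALSE)
    }
    gsel <- sample(free_g, n_planted)
    msel <- sample(free_m, n_planted)
    slopes <- runif(cfg$n_true_pairs, cfg$true_pair_slope_range[1],
                    cfg$true_pair_slope_range[2])
    list(true_g = gsel[seq_len(cfg$n_true_pairs)],
         true_m = msel[seq_len(cfg$n_true_pairs)],
         out_g = gsel[cfg$n_true_pairs + seq_len(cfg$n_outlier_pairs)],
         out_m = msel[cfg$n_true_pairs + seq_len(cfg$n_outlier_pairs)],
         slopes = slopes)
  })
  if (cfg$n_true_pairs > 0) {
    M[plant$true_m, ] <- with_seed(substream_seed(seed, "coupling"), {
      noise <- matrix(rnorm(cfg$n_true_pairs * n), nrow = cfg$n_true_pairs)
      noise <- sweep(noise, 2, cfg$metabolite_noise_sd * hfac, `*`)
      plant$slopes * G[plant$true_g, , drop = FALSE] + noise
    })
  }
  spiked <- integer(cfg$n_outlier_pairs)
  if (cfg$n_outlier_pairs > 0) {
    spiked <- with_seed(substream_seed(seed, "spikes"),
                        sample(n, cfg$n_outlier_pairs, replace = TRUE))
    for (k in seq_len(cfg$n_outlier_pairs)) {
      # displacement in units of the spiked sample's own residual SD
      # (heterogeneous classes have inflated residuals)
      f <- hfac[spiked[k]]
      M[plant$out_m[k], spiked[k]] <- M[plant$out_m[k], spiked[k]] +
        cfg$outlier_magnitude_sd * cfg$metabolite_noise_sd * f
      if (cfg$spike_gene) {
        G[plant$out_g[k], spiked[k]] <- G[plant$out_g[k], spiked[k]] +
          cfg$outlier_magnitude_sd * cfg$gene_noise_sd * f
      }
    }
  }

  # --- missingness (MCAR per metabolite cell, spiked cells exempt) -------
  if (cfg$missing_rate > 0) {
    mask <- with_seed(substream_seed(seed, "missing"),
                      matrix(runif(n_mets * n) < cfg$missing_rate,
                             nrow = n_mets))
    for (k in seq_len(cfg$n_outlier_pairs)) {
      mask[plant$out_m[k], spiked[k]] <- FALSE
    }
    M[mask] <- NA_real_
  }

  rownames(G) <- ids$genes; colnames(G) <- sample_ids
  rownames(M) <- ids$mets; colnames(M) <- sample_ids

  # --- mutation / CNV knowledge -----------------------------------------
  knowledge <- with_seed(substream_seed(seed, "knowledge"), {
    is_mut <- runif(cfg$n_outlier_pairs) < cfg$mutation_fraction
    mut <- data.frame(gene_id = ids$genes[plant$out_g[is_mut]],
                      cell_line = sample_ids[spiked[is_mut]],
                      stringsAsFactors = FALSE)
    cnv <- data.frame(gene_id = ids$genes[plant$out_g[!is_mut]],
                      cell_line = sample_ids[spiked[!is_mut]],
                      copy_number = round(runif(sum(!is_mut), 6, 16), 2),
                      stringsAsFactors = FALSE)
    # decoy rows on genes not involved in planted outlier pairs
    decoy_pool <- setdiff(seq_len(cfg$n_genes), plant$out_g)
    if (cfg$n_background_mutations > 0) {
      mut <- rbind(mut, data.frame(
        gene_id = ids$genes[sample(decoy_pool, cfg$n_background_mutations,
                                   replace = TRUE)],
        cell_line = sample_ids[sample(n, cfg$n_background_mutations,
                                      replace = TRUE)],
        stringsAsFactors = FALSE))
    }
    if (cfg$n_background_cnv > 0) {
      cnv <- rbind(cnv, data.frame(
        gene_id = ids$genes[sample(decoy_pool, cfg$n_background_cnv,
                                   replace = TRUE)],
        cell_line = sample_ids[sample(n, cfg$n_background_cnv,
                                      replace = TRUE)],
        copy_number = round(runif(cfg$n_background_cnv, 0.5, 8), 2),
        stringsAsFactors = FALSE))
    }
    list(mutations = unique(mut), cnv = unique(cnv), is_mut = is_mut)
  })

  annotation <- generate_annotation(cfg, ids, plant, seed)

  panel <- omics_panel(G, M,
                       data.frame(sample_id = sample_ids, class = classes,
                                  stringsAsFactors = FALSE),
                       annotation = annotation)
  truth <- list(
    true_pairs = data.frame(gene_id = ids$genes[plant$true_g],
                            metabolite_id = ids$mets[plant$true_m],
                            slope = plant$slopes, stringsAsFactors = FALSE),
    outlier_pairs = data.frame(gene_id = ids$genes[plant$out_g],
                               metabolite_id = ids$mets[plant$out_m],
                               sample_id = sample_ids[spiked],
                               stringsAsFactors = FALSE),
    mutation_table = knowledge$mutations,
    cnv_table = knowledge$cnv,
    class_labels = stats::setNames(classes, sample_ids)
  )
  list(panel = panel, truth = truth)
}

# EHMN-like annotation: pathways with decreasing gene counts, entries
# linking genes to known compounds, plus direct-reaction entries for a
# fraction of the planted true pairs (only a minority of strong
# correlations map to curated reactions on real panels).
generate_annotation <- function(cfg, ids, plant, seed) {
  n_known <- cfg$n_metabolites_known
  if (cfg$n_pathways == 0 || n_known == 0) return(NULL)
  with_seed(substream_seed(seed, "annotation"), {
    pw <- sprintf("pathway_%02d", seq_len(cfg$n_pathways))
    g_counts <- pmax(3L, round(seq(14, 4, length.out = cfg$n_pathways)))
    c_counts <- pmax(2L, round(seq(8, 3, length.out = cfg$n_pathways)))
    g_counts <- pmin(g_counts, cfg$n_genes)
    c_counts <- pmin(c_counts, n_known)
    rows <- vector("list", cfg$n_pathways)
    for (i in seq_len(cfg$n_pathways)) {
      gset <- sample(ids$genes, g_counts[i])
      cset <- sample(ids$mets[seq_len(n_known)], c_counts[i])
      rows[[i]] <- data.frame(
        gene_id = gset,
        compound_id = sample(cset, g_counts[i], replace = TRUE),
        reaction_id = paste0("R", sprintf("%05d",
                                          sample(10000:99999, g_counts[i]))),
        pathway = pw[i], stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)
    # direct entries for a fraction of the planted true pairs whose
    # metabolite is a known compound
    tk <- which(plant$true_m <= n_known)
    n_direct <- round(cfg$annotated_true_fraction * length(tk))
    if (n_direct > 0) {
      pick <- sample(tk, n_direct)
      ann <- rbind(ann, data.frame(
        gene_id = ids$genes[plant$true_g[pick]],
        compound_id = ids$mets[plant$true_m[pick]],
        reaction_id = paste0("R", sprintf("%05d",
                                          sample(10000:99999, n_direct))),
        pathway = sample(pw, n_direct, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    unique(ann)
  })
}
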