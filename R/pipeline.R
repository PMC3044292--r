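#' Pipeline configuration
#'
#' Collects every tunable of an end-to-end run. `panel` configures the
#' synthetic panel written by the `simulate` step; for real data, point
#' `indir` at a directory holding the [write_panel()] file set and skip
#' `simulate`. The default demonstration panel is a reduced one (400
#' genes, 90 metabolites) so a full run stays interactive; panel-scale
#' screens simply take longer.
#'
#' @param outdir output directory (also the input directory of the later
#'   steps unless `indir` is given).
#' @param indir directory with the input file set; defaults to `outdir`.
#' @param seed master seed; mandatory for every stochastic stage, and it
#'   overrides the seed inside `panel`.
#' @param panel a [panel_config()] for the `simulate` step.
#' @param thresholds a [decision_thresholds()].
#' @param min_complete minimum pairwise-complete samples per pair.
#' @param outlier_quantile chi-square coverage for outlier flagging.
#' @param candidates outlier-stat scope, `"rule"` or `"all"`.
#' @param mcd_starts random starts of the fast MCD search.
#' @param n_trees forest size for the class-removal step.
#' @param n_steps progressive-removal steps.
#' @param null_reps random-removal draws per step.
#' @param drop_fraction,se_rule backward-selection parameters.
#' @param feature_source features used for classification
#'   (`"metabolites"` or `"genes"`).
#' @param top_pathways pathways retained by the annotation overlay.
#' @param pqc_high threshold used by [annotation_coverage()].
#' @param sine_transform apply the PQC normal-consistency transform.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "metacouple_out",
                            indir = NULL,
                            seed = 1,
                            panel = panel_config(
                              n_genes = 400,
                              n_metabolites_known = 40,
                              n_metabolites_unknown = 50,
                              n_true_pairs = 10,
                              n_outlier_pairs = 5,
                              n_background_mutations = 40,
                              n_background_cnv = 20),
                            thresholds = decision_thresholds(),
                            min_complete = 10,
                            outlier_quantile = 0.975,
                            candidates = "rule",
                            mcd_starts = 500,
                            n_trees = 500,
                            n_steps = 3,
                            null_reps = 500,
                            drop_fraction = 0.2,
                            se_rule = 1.0,
                            feature_source = "metabolites",
                            top_pathways = 9,
                            pqc_high = 0.5,
                            sine_transform = TRUE) {
  if (is.null(indir)) indir <- outdir
  cfg <- list(outdir = outdir, indir = indir, seed = as.integer(seed),
              panel = panel, thresholds = thresholds,
              min_complete = min_complete,
              outlier_quantile = outlier_quantile, candidates = candidates,
              mcd_starts = mcd_starts, n_trees = n_trees, n_steps = n_steps,
              null_reps = null_reps, drop_fraction = drop_fraction,
              se_rule = se_rule, feature_source = feature_source,
              top_pathways = top_pathways, pqc_high = pqc_high,
              sine_transform = isTRUE(sine_transform))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `panel` and
#' `thresholds` are nested maps passed to [panel_config()] and
#' [decision_thresholds()]. Unset keys keep their defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  require_input_file(path)
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), c("panel", "thresholds"))]
  if (!is.null(raw$panel)) {
    pc <- raw$panel
    if (!is.null(pc$class_sizes)) pc$class_sizes <- unlist(pc$class_sizes)
    if (!is.null(pc$true_pair_slope_range)) {
      pc$true_pair_slope_range <- unlist(pc$true_pair_slope_range)
    }
    args$panel <- do.call(panel_config, pc)
  }
  if (!is.null(raw$thresholds)) {
    args$thresholds <- do.call(decision_thresholds, raw$thresholds)
  }
  do.call(pipeline_config, args)
}

#' Run the analysis pipeline
#'
#' Executes one named step or the whole chain
#' `simulate -> correlate -> outliers -> screen -> classify -> annotate`.
#' Every step reads its inputs from, and writes its outputs to, the
#' configured directories, so steps can be re-run independently;
#' re-running with unchanged inputs and seed reproduces the output files
#' byte for byte. A `run_manifest.txt` (package version, configuration
#' hash, seed) and a `run.log` listing every threshold actually applied
#' are written alongside the results.
#'
#' File outputs per step: `simulate` the [write_panel()] set;
#' `correlate` `pairs.tsv`; `outliers` `outliers.tsv` (+ updated
#' `pairs.tsv`); `screen` categorised `pairs.tsv`, `report.tsv` and
#' `candidates.tsv`; `classify` `removal_trace.tsv` and `selection.tsv`;
#' `annotate` `matrix.tsv`, `mask.tsv`, `matches.tsv`, `coverage.tsv`.
#'
#' @param step one of `"simulate"`, `"correlate"`, `"outliers"`,
#'   `"screen"`, `"classify"`, `"annotate"`, `"all"`.
#' @param config a [pipeline_config()].
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(step = c("all", "simulate", "correlate", "outliers",
                                  "screen", "classify", "annotate"),
                         config = pipeline_config()) {
  step <- match.arg(step)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  steps <- if (step == "all") {
    c("simulate", "correlate", "outliers", "screen", "classify", "annotate")
  } else step
  log_lines <- character()
  logit <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  for (s in steps) {
    switch(s,
           simulate = step_simulate(config, logit),
           correlate = step_correlate(config, logit),
           outliers = step_outliers(config, logit),
           screen = step_screen(config, logit),
           classify = step_classify(config, logit),
           annotate = step_annotate(config, logit))
  }
  write_manifest(config, steps)
  writeLines(log_lines, file.path(config$outdir, "run.log"))
  invisible(config$outdir)
}

out_path <- function(config, f) file.path(config$outdir, f)
in_path <- function(config, f) {
  p <- file.path(config$indir, f)
  # outputs of earlier steps land in outdir; fall back there
  if (!file.exists(p) && file.exists(file.path(config$outdir, f))) {
    p <- file.path(config$outdir, f)
  }
  require_input_file(p)
  p
}

step_simulate <- function(config, logit) {
  pc <- config$panel
  pc$seed <- config$seed
  gp <- generate_panel(pc)
  write_panel(gp$panel, gp$truth, config$outdir)
  logit("simulate: seed=", config$seed, " genes=", nrow(gp$panel$genes),
        " metabolites=", nrow(gp$panel$metabolites),
        " samples=", ncol(gp$panel$genes))
}

load_panel_inputs <- function(config) {
  for (f in c("genes.tsv", "metabolites.tsv", "samples.tsv")) in_path(config, f)
  read_panel(dirname(in_path(config, "genes.tsv")))
}

step_correlate <- function(config, logit) {
  pr <- load_panel_inputs(config)
  rec <- screen_pairs(pr$panel, min_complete = config$min_complete,
                      sine_transform = config$sine_transform)
  write_pairs(rec, out_path(config, "pairs.tsv"))
  logit("correlate: ", nrow(rec), " pairs, min_complete=",
        config$min_complete, ", sine_transform=", config$sine_transform)
}

step_outliers <- function(config, logit) {
  pr <- load_panel_inputs(config)
  rec <- read_pairs(in_path(config, "pairs.tsv"))
  res <- add_outlier_stats(pr$panel, rec, thresholds = config$thresholds,
                           candidates = config$candidates,
                           quantile = config$outlier_quantile,
                           min_complete = config$min_complete,
                           seed = config$seed,
                           n_starts = config$mcd_starts)
  write_pairs(res$records, out_path(config, "pairs.tsv"))
  write_tsv_file(res$flags, out_path(config, "outliers.tsv"))
  logit("outliers: quantile=", config$outlier_quantile,
        " candidates=", config$candidates, " pairs_processed=",
        length(unique(paste(res$flags$gene_id, res$flags$metabolite_id))))
}

step_screen <- function(config, logit) {
  rec <- read_pairs(in_path(config, "pairs.tsv"))
  rec <- classify_pairs(rec, config$thresholds)
  write_pairs(rec, out_path(config, "pairs.tsv"))
  truth <- NULL
  tp <- file.path(config$indir, "truth_pairs.tsv")
  if (!file.exists(tp)) tp <- file.path(config$outdir, "truth_pairs.tsv")
  if (file.exists(tp)) {
    truth <- read_panel(dirname(tp))$truth
  }
  rep_ <- screen_report(rec, truth)
  counts <- as.data.frame(rep_$counts, stringsAsFactors = FALSE)
  names(counts) <- c("category", "count")
  metrics <- data.frame(category = character(), count = numeric())
  if (!is.null(rep_$outlier_precision)) {
    metrics <- data.frame(
      category = c("outlier_precision", "outlier_recall",
                   "assoc_precision", "assoc_recall"),
      count = c(rep_$outlier_precision, rep_$outlier_recall,
                rep_$assoc_precision, rep_$assoc_recall))
  }
  write_tsv_file(rbind(counts, metrics), out_path(config, "report.tsv"))
  cand <- rank_candidates(rec[rec$category == "outlier_driven", ,
                              drop = FALSE], by = "pcc")
  write_pairs(cand, out_path(config, "candidates.tsv"))
  th <- config$thresholds
  logit("screen: pcc_outlier_min=", th$pcc_outlier_min,
        " pqc_outlier_max=", th$pqc_outlier_max,
        " max_outliers=", th$max_outliers,
        " pcc_rm_max=", th$pcc_rm_max,
        " pqc_assoc_min=", th$pqc_assoc_min,
        " pcc_assoc_min=", th$pcc_assoc_min)
}

step_classify <- function(config, logit) {
  pr <- load_panel_inputs(config)
  feats <- suppressMessages(panel_features(pr$panel, config$feature_source))
  labels <- attr(feats, "labels")
  n_steps <- min(config$n_steps, nlevels(labels) - 2)
  trace <- class_removal_analysis(feats, labels, n_steps,
                                  reps = config$null_reps,
                                  n_trees = config$n_trees,
                                  seed = config$seed)
  write_tsv_file(trace, out_path(config, "removal_trace.tsv"))
  sel <- backward_select(feats, labels, drop_fraction = config$drop_fraction,
                         se_rule = config$se_rule,
                         n_trees = config$n_trees, seed = config$seed)
  seldf <- data.frame(feature_id = names(sel$drop_step),
                      step_dropped = as.integer(sel$drop_step),
                      selected = as.integer(names(sel$drop_step) %in%
                                              sel$selected),
                      stringsAsFactors = FALSE)
  write_tsv_file(seldf, out_path(config, "selection.tsv"))
  logit("classify: source=", config$feature_source, " n_trees=",
        config$n_trees, " n_steps=", n_steps, " null_reps=",
        config$null_reps, " drop_fraction=", config$drop_fraction,
        " se_rule=", config$se_rule)
}

step_annotate <- function(config, logit) {
  rec <- read_pairs(in_path(config, "pairs.tsv"))
  ann <- read_annotation(in_path(config, "annotation.tsv"))
  mut <- read_mutations(in_path(config, "mutations.tsv"))
  cnv <- read_cnv(in_path(config, "cnv.tsv"))
  flags <- read_tsv_empty_ok(in_path(config, "outliers.tsv"),
                             c("gene_id", "metabolite_id", "sample_id",
                               "robust_distance", "cutoff", "flagged"))
  flags$flagged <- as.integer(flags$flagged)
  ov <- suppressWarnings(overlay_matrix(rec, ann,
                                        top_pathways = config$top_pathways))
  if (nrow(ov$pqc) > 0) {
    write_overlay(ov, config$outdir)
  } else {
    write_tsv_file(data.frame(row_id = character()),
                   out_path(config, "matrix.tsv"))
    write_tsv_file(data.frame(row_id = character()),
                   out_path(config, "mask.tsv"))
  }
  matches <- crossref_structural(rec, mut, cnv, flags)
  write_tsv_file(matches, out_path(config, "matches.tsv"))
  cov <- annotation_coverage(rec, ann, pqc_high = config$pqc_high)
  write_tsv_file(data.frame(stat = names(cov),
                            value = as.numeric(unlist(cov))),
                 out_path(config, "coverage.tsv"))
  logit("annotate: top_pathways=", config$top_pathways,
        " pqc_high=", config$pqc_high, " matches=", nrow(matches))
}

write_manifest <- function(config, steps) {
  cfg_yaml <- yaml::as.yaml(unclass_config(config))
  cfg_path <- out_path(config, "config.yaml")
  writeLines(cfg_yaml, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  writeLines(c(
    paste0("metacouple_version: ", as.character(packageVersion("metacouple"))),
    paste0("config_md5: ", hash),
    paste0("seed: ", config$seed),
    paste0("steps: ", paste(steps, collapse = ","))),
    out_path(config, "run_manifest.txt"))
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$panel <- unclass(cfg$panel)
  cfg$panel$class_sizes <- as.list(cfg$panel$class_sizes)
  cfg$thresholds <- unclass(cfg$thresholds)
  cfg
}

# pairs.tsv round trip: floats with 6 significant digits, NA token "NA"
write_pairs <- function(records, path) {
  write_tsv_file(records[, c("gene_id", "metabolite_id", "n_complete",
                             "pcc", "pqc", "n_outliers", "pcc_rm", "pqc_rm",
                             "category"), drop = FALSE], path)
}

read_pairs <- function(path) {
  df <- read_tsv_empty_ok(path, c("gene_id", "metabolite_id", "n_complete",
                                  "pcc", "pqc", "n_outliers", "pcc_rm",
                                  "pqc_rm", "category"))
  df$n_complete <- as.integer(df$n_complete)
  df$n_outliers <- as.integer(df$n_outliers)
  for (j in c("pcc", "pqc", "pcc_rm", "pqc_rm")) df[[j]] <- as.numeric(df[[j]])
  df$category <- as.character(df$category)
  df
}
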