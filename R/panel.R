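#' Construct an omics panel
#'
#' Bundles a gene expression matrix and a metabolite abundance matrix
#' measured on the same samples, together with sample class labels and
#' optional gene-compound-pathway annotation. Matrices are features in
#' rows and samples in columns, the usual omics convention. The gene
#' matrix must be complete; the metabolite matrix may contain `NA`
#' (non-imputed measurements) which all downstream correlation code
#' handles pairwise-complete.
#'
#' Metabolite feature ids double as compound identifiers: known compounds
#' carry a KEGG-style id (e.g. `"C00022"`), unknown compounds an
#' `"X-<int>"` id (e.g. `"X-2005"`). Unknowns never match annotation.
#'
#' @param genes numeric matrix, genes x samples, no missing values.
#' @param metabolites numeric matrix, metabolites x samples, `NA` allowed.
#' @param samples data frame with columns `sample_id` and `class`;
#'   `sample_id` must equal the matrix column names, in order.
#' @param annotation optional data frame of gene-compound links with
#'   columns `gene_id`, `compound_id`, `reaction_id`, `pathway`.
#' @return An object of class `omics_panel`.
#' @seealso [generate_panel()] for synthetic panels, [screen_pairs()] for
#'   the correlation screen.
#' @export
omics_panel <- function(genes, metabolites, samples, annotation = NULL) {
  stopifnot(is.matrix(genes), is.numeric(genes),
            is.matrix(metabolites), is.numeric(metabolites),
            is.data.frame(samples))
  if (!all(c("sample_id", "class") %in% names(samples))) {
    stop("'samples' needs columns sample_id and class", call. = FALSE)
  }
  sid <- as.character(samples$sample_id)
  if (anyDuplicated(sid)) stop("duplicated sample ids", call. = FALSE)
  if (!identical(colnames(genes), sid) ||
      !identical(colnames(metabolites), sid)) {
    stop("matrix column names must match samples$sample_id in order",
         call. = FALSE)
  }
  if (anyNA(genes)) stop("gene matrix must be complete", call. = FALSE)
  if ((nrow(genes) > 0 && is.null(rownames(genes))) ||
      (nrow(metabolites) > 0 && is.null(rownames(metabolites)))) {
    stop("matrices need feature ids as row names", call. = FALSE)
  }
  if (!is.null(annotation)) annotation <- validate_annotation(annotation)
  structure(
    list(genes = genes, metabolites = metabolites,
         samples = data.frame(sample_id = sid,
                              class = as.character(samples$class),
                              stringsAsFactors = FALSE),
         annotation = annotation),
    class = "omics_panel")
}

#' @export
print.omics_panel <- function(x, ...) {
  cat("omics_panel:", nrow(x$genes), "genes x", ncol(x$genes), "samples;",
      nrow(x$metabolites), "metabolites (",
      sum(metabolite_known(x)), "known /",
      sum(!metabolite_known(x)), "unknown );",
      length(unique(x$samples$class)), "classes\n")
  miss <- mean(is.na(x$metabolites))
  cat(sprintf("  metabolite missingness: %.1f%%", 100 * miss))
  if (!is.null(x$annotation)) {
    cat(";", nrow(x$annotation), "annotation entries")
  }
  cat("\n")
  invisible(x)
}

# Known-compound flag, derived from the id convention.
metabolite_known <- function(panel) {
  !startsWith(rownames(panel$metabolites), "X-")
}

validate_annotation <- function(annotation) {
  need <- c("gene_id", "compound_id", "reaction_id", "pathway")
  if (!all(need %in% names(annotation))) {
    stop("annotation needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (any(!nzchar(annotation$gene_id)) || any(!nzchar(annotation$compound_id))) {
    stop("annotation gene_id/compound_id must be non-empty", call. = FALSE)
  }
  annotation
}

validate_knowledge <- function(tab, what = c("mutation", "cnv")) {
  what <- match.arg(what)
  need <- c("gene_id", "cell_line")
  if (what == "cnv") need <- c(need, "copy_number")
  if (!all(need %in% names(tab))) {
    stop(what, " table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (nrow(tab) && (any(!nzchar(tab$gene_id)) || any(!nzchar(tab$cell_line)))) {
    stop(what, " table keys must be non-empty", call. = FALSE)
  }
  tab
}

empty_truth <- function(class_labels = character()) {
  list(
    true_pairs = data.frame(gene_id = character(), metabolite_id = character(),
                            slope = numeric(), stringsAsFactors = FALSE),
    outlier_pairs = data.frame(gene_id = character(),
                               metabolite_id = character(),
                               sample_id = character(),
                               stringsAsFactors = FALSE),
    mutation_table = data.frame(gene_id = character(), cell_line = character(),
                                stringsAsFactors = FALSE),
    cnv_table = data.frame(gene_id = character(), cell_line = character(),
                           copy_number = numeric(), stringsAsFactors = FALSE),
    class_labels = class_labels
  )
}

#' Write a panel and its ground truth to a directory of TSV files
#'
#' Emits the full file set used by the pipeline: `genes.tsv`,
#' `metabolites.tsv` (matrices, 17 significant digits so values round-trip
#' exactly), `samples.tsv`, `annotation.tsv`, `mutations.tsv`, `cnv.tsv`
#' and `truth_pairs.tsv`. All files are tab-separated UTF-8 with a header
#' row; missing values are written as `NA`.
#'
#' @param panel an [omics_panel()].
#' @param truth ground-truth list as returned by [generate_panel()], or
#'   `NULL` for a real panel (empty truth tables are written).
#' @param directory output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_panel <- function(panel, truth = NULL, directory) {
  stopifnot(inherits(panel, "omics_panel"))
  if (is.null(truth)) truth <- empty_truth(panel$samples$class)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)

  write_matrix_tsv(panel$genes, p("genes.tsv"), "gene_id")
  write_matrix_tsv(panel$metabolites, p("metabolites.tsv"), "metabolite_id")
  write_tsv_file(panel$samples, p("samples.tsv"))

  ann <- panel$annotation
  if (is.null(ann)) {
    ann <- data.frame(gene_id = character(), compound_id = character(),
                      reaction_id = character(), pathway = character(),
                      stringsAsFactors = FALSE)
  }
  write_tsv_file(ann, p("annotation.tsv"))
  write_tsv_file(truth$mutation_table, p("mutations.tsv"))
  write_tsv_file(truth$cnv_table, p("cnv.tsv"))

  tp <- truth$true_pairs
  op <- truth$outlier_pairs
  tr <- rbind(
    data.frame(gene_id = tp$gene_id, metabolite_id = tp$metabolite_id,
               kind = rep("true", nrow(tp)), slope = tp$slope,
               spiked_sample = rep(NA_character_, nrow(tp)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = op$gene_id, metabolite_id = op$metabolite_id,
               kind = rep("outlier", nrow(op)),
               slope = rep(NA_real_, nrow(op)),
               spiked_sample = op$sample_id, stringsAsFactors = FALSE))
  write_tsv_file(tr, p("truth_pairs.tsv"), num_digits = 17L)

  files <- c(genes = p("genes.tsv"), metabolites = p("metabolites.tsv"),
             samples = p("samples.tsv"), annotation = p("annotation.tsv"),
             mutations = p("mutations.tsv"), cnv = p("cnv.tsv"),
             truth_pairs = p("truth_pairs.tsv"))
  invisible(files)
}

#' Read a panel written by [write_panel()]
#'
#' @param directory directory holding the TSV file set.
#' @return A list with elements `panel` (an [omics_panel()]) and `truth`
#'   (ground-truth tables; empty data frames for real panels).
#' @export
read_panel <- function(directory) {
  p <- function(f) file.path(directory, f)
  genes <- read_matrix_tsv(p("genes.tsv"))
  mets <- read_matrix_tsv(p("metabolites.tsv"))
  samples <- read_tsv_file(p("samples.tsv"))
  samples$sample_id <- as.character(samples$sample_id)
  samples$class <- as.character(samples$class)
  ann <- read_tsv_empty_ok(p("annotation.tsv"),
                           c("gene_id", "compound_id", "reaction_id",
                             "pathway"))
  panel <- omics_panel(genes, mets, samples, annotation = ann)

  mut <- read_tsv_empty_ok(p("mutations.tsv"), c("gene_id", "cell_line"))
  cnv <- read_tsv_empty_ok(p("cnv.tsv"),
                           c("gene_id", "cell_line", "copy_number"))
  if (nrow(cnv)) cnv$copy_number <- as.numeric(cnv$copy_number)
  tr <- read_tsv_empty_ok(p("truth_pairs.tsv"),
                          c("gene_id", "metabolite_id", "kind", "slope",
                            "spiked_sample"))
  truth <- empty_truth(stats::setNames(samples$class, samples$sample_id))
  if (nrow(tr)) {
    tt <- tr[tr$kind == "true", , drop = FALSE]
    oo <- tr[tr$kind == "outlier", , drop = FALSE]
    truth$true_pairs <- data.frame(gene_id = tt$gene_id,
                                   metabolite_id = tt$metabolite_id,
                                   slope = as.numeric(tt$slope),
                                   stringsAsFactors = FALSE)
    truth$outlier_pairs <- data.frame(gene_id = oo$gene_id,
                                      metabolite_id = oo$metabolite_id,
                                      sample_id = oo$spiked_sample,
                                      stringsAsFactors = FALSE)
  }
  truth$mutation_table <- mut
  truth$cnv_table <- cnv
  list(panel = panel, truth = truth)
}

# Reader tolerant of header-only files; enforces the expected columns.
read_tsv_empty_ok <- function(path, cols) {
  df <- read_tsv_file(path)
  if (!all(cols %in% names(df))) {
    stop("'", path, "' lacks required columns ",
         paste(setdiff(cols, names(df)), collapse = ", "), call. = FALSE)
  }
  for (j in names(df)) if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  for (j in intersect(c("gene_id", "compound_id", "reaction_id", "pathway",
                        "cell_line", "metabolite_id", "kind",
                        "spiked_sample"), names(df))) {
    df[[j]] <- as.character(df[[j]])
  }
  df[, cols, drop = FALSE]
}
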