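# Internal helpers: seeded substreams and strict TSV I/O.

# Component offsets for the seed-substream hierarchy.  Every stochastic
# component reseeds from the master seed plus its own fixed offset, so
# adding a new component never perturbs the draws of earlier ones.
.substream_offsets <- c(
  ids = 1L, gene_base = 2L, gene_class = 3L, gene_noise = 4L,
  met_base = 5L, met_class = 6L, met_noise = 7L, pairs = 8L,
  coupling = 9L, spikes = 10L, missing = 11L, knowledge = 12L,
  annotation = 13L, mcd = 14L, forest = 15L, null = 16L, select = 17L
)

substream_seed <- function(seed, component) {
  off <- .substream_offsets[[component]]
  (as.integer(seed) %% 1000003L) * 1024L + off
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-pair seed: stable under changes to the candidate set.
pair_seed <- function(base, gene_id, metabolite_id) {
  h <- sum(utf8ToInt(paste0(gene_id, "~", metabolite_id)) *
             seq_along(utf8ToInt(paste0(gene_id, "~", metabolite_id))))
  (as.integer(base) + (h %% 100003L) * 31L) %% 2147483647L
}

# Format numerics for TSV export: NA -> "NA", otherwise signif digits via %g.
fmt_num <- function(x, digits = 6L) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_file <- function(df, path, num_digits = 6L) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- fmt_num(df[[j]], num_digits)
    }
  }
  ok <- tryCatch({
    write.table(df, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA", eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write '", path, "': ", conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

require_input_file <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("input file not found: ", path),
                        class = c("metacouple_missing_input", "error")))
  }
  invisible(path)
}

# Strict TSV reader: checks the file is rectangular and reports the first
# offending line number on malformed input.
read_tsv_file <- function(path) {
  require_input_file(path)
  nf <- tryCatch(count.fields(path, sep = "\t", quote = "", comment.char = ""),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(nf) == 0) stop("empty file: ", path, call. = FALSE)
  bad <- which(nf != nf[1])
  if (length(bad)) {
    stop("malformed TSV '", path, "': line ", bad[1] + 0L, " has ", nf[bad[1]],
         " fields, expected ", nf[1], call. = FALSE)
  }
  read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = "NA", comment.char = "")
}

# Read a feature-by-sample numeric matrix whose first column is the
# feature id and whose header row carries sample ids.
read_matrix_tsv <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  # 17 significant digits so values survive a write/read round trip exactly
  write_tsv_file(df, path, num_digits = 17L)
}
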