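# Independent oracles and small fixture builders.

# Brute-force quadrant correlation, written directly from the sign
# formula with explicit loops; deliberately independent of the package's
# vectorised implementation.
brute_pqc <- function(x, y, sine_transform = TRUE) {
  stopifnot(length(x) == length(y))
  cx <- c(); cy <- c()
  for (i in seq_along(x)) {
    if (!is.na(x[i]) && !is.na(y[i])) {
      cx <- c(cx, x[i])
      cy <- c(cy, y[i])
    }
  }
  n <- length(cx)
  if (n < 3) return(list(r = NA_real_, n_complete = n))
  mx <- median(cx)
  my <- median(cy)
  s <- 0
  for (i in seq_len(n)) {
    u <- if (cx[i] > mx) 1 else if (cx[i] < mx) -1 else 0
    v <- if (cy[i] > my) 1 else if (cy[i] < my) -1 else 0
    s <- s + u * v
  }
  q <- s / n
  list(r = if (sine_transform) sin(pi * q / 2) else q, n_complete = n)
}

# Random vector pair with missing values, for oracle-equivalence loops.
random_missing_pair <- function(seed) {
  set.seed(seed)
  n <- sample(5:25, 1)
  x <- rnorm(n)
  y <- rnorm(n)
  x[runif(n) < 0.15] <- NA
  y[runif(n) < 0.15] <- NA
  list(x = x, y = y)
}

# A minimal deterministic panel built by hand (no generator involved).
tiny_panel <- function(n_genes = 4, n_mets = 3, n = 12, seed = 11) {
  set.seed(seed)
  sid <- sprintf("S%02d", seq_len(n))
  G <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)), sid))
  met_ids <- ifelse(seq_len(n_mets) %% 3 == 0,
                    sprintf("X-%04d", 1000 + seq_len(n_mets)),
                    sprintf("C%05d", seq_len(n_mets)))
  M <- matrix(rnorm(n_mets * n), n_mets, n,
              dimnames = list(met_ids, sid))
  omics_panel(G, M, data.frame(sample_id = sid,
                               class = rep(c("a", "b"), length.out = n)))
}

# Bivariate pair with zero background slope and one concordant spike.
spiked_pair <- function(n = 25, spike = 8, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rnorm(n)
  x[1] <- x[1] + spike
  y[1] <- y[1] + spike
  names(x) <- names(y) <- sprintf("S%02d", seq_len(n))
  list(x = x, y = y, spiked = "S01")
}
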