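test_that("exhaustive MCD excludes gross outliers from its subset", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(20, sd = 0.3), 10, 2),
               matrix(c(8, 9, 8.5, 9.5), 2, 2))
  fit <- mcd_fit(pts, h = 8, method = "exhaustive")
  expect_false(any(c(11, 12) %in% fit$raw$subset))
  expect_false(any(c(11, 12) %in% fit$support))
  expect_identical(fit$h, 8L)
  # distant points have much larger robust distances than the cluster
  d <- mahalanobis(pts, fit$location, fit$scatter)
  expect_gt(min(d[11:12]), 10 * max(d[1:10]))
})

test_that("exhaustive MCD attains a determinant no worse than an independent search", {
  skip_if_not_installed("MASS")
  for (s in 1:10) {
    set.seed(s)
    n <- 12
    pts <- cbind(rnorm(n), rnorm(n))
    if (s %% 3 == 0) pts[1, ] <- pts[1, ] + 5
    h <- ceiling((n + 3) / 2)
    ours <- mcd_fit(pts, method = "exhaustive")
    ref <- MASS::cov.mcd(pts, quantile.used = h)
    det_ours <- det(cov(pts[ours$raw$subset, ]))
    det_ref <- det(cov(pts[ref$best, ]))
    expect_lte(det_ours, det_ref + 1e-12)
  }
})

test_that("fast and exhaustive searches find the same support on small n", {
  for (s in 1:10) {
    set.seed(s + 40)
    pts <- cbind(rnorm(12), rnorm(12))
    fe <- mcd_fit(pts, method = "exhaustive")
    ff <- mcd_fit(pts, method = "fast", seed = s)
    expect_identical(fe$support, ff$support)
  }
})

test_that("degenerate point clouds raise a singular-scatter error", {
  x <- seq_len(10)
  expect_error(mcd_fit(cbind(x, 2 * x + 3)), "collinear")
  jit <- cbind(rep(1, 10), rep(2, 10)) + matrix(rnorm(20, sd = 1e-10), 10, 2)
  expect_error(mcd_fit(jit), "collinear|singular")
  expect_error(mcd_fit(cbind(rnorm(5), rnorm(5))), "at least 6")
  expect_error(mcd_fit(cbind(rnorm(10), rnorm(10)), h = 5), "h must lie")
})

test_that("mcd_fit is affine equivariant and its flags are invariant", {
  A <- matrix(c(2, 0.5, -1, 1.5), 2, 2)
  b <- c(3, -2)
  for (s in 1:20) {
    set.seed(s)
    n <- sample(c(12, 20, 30), 1)
    pts <- cbind(rnorm(n), rnorm(n))
    pts[1, ] <- pts[1, ] + 6
    f1 <- mcd_fit(pts, seed = s)
    f2 <- mcd_fit(pts %*% t(A) + rep(b, each = n), seed = s)
    expect_identical(f1$support, f2$support)
    expect_equal(f2$location, as.vector(A %*% f1$location + b),
                 tolerance = 1e-8)
    expect_equal(f2$scatter, A %*% f1$scatter %*% t(A), tolerance = 1e-8)
  }
})

test_that("flag_outliers isolates a planted extreme sample", {
  p <- spiked_pair(n = 25, spike = 8, seed = 3)
  fl <- flag_outliers(p$x, p$y, seed = 1)
  expect_identical(fl$status, "ok")
  expect_identical(fl$flagged_samples, p$spiked)
  # oracle: classical Mahalanobis distance computed without the spiked
  # point confirms it is the lone extreme sample
  others <- names(p$x) != p$spiked
  S <- cov(cbind(p$x[others], p$y[others]))
  mu <- c(mean(p$x[others]), mean(p$y[others]))
  d2 <- mahalanobis(cbind(p$x, p$y), mu, S)
  expect_identical(names(which(d2 > qchisq(0.975, 2))), p$spiked)
})

test_that("flagging respects the quantile bound and the completeness floor", {
  p <- spiked_pair(n = 25, spike = 8, seed = 3)
  expect_length(flag_outliers(p$x, p$y, quantile = 1, seed = 1)$flagged_samples,
                0)
  short <- flag_outliers(rnorm(8), rnorm(8), min_complete = 10)
  expect_identical(short$status, "insufficient_n")
  x <- 1:20
  degen <- flag_outliers(x, 2 * x, min_complete = 10)
  expect_identical(degen$status, "degenerate")
})

test_that("false-flag rate on clean correlated data is near its nominal level", {
  tot <- 0
  for (s in 1:200) {
    set.seed(s + 5000)
    x <- rnorm(30)
    y <- 0.5 * x + rnorm(30)
    tot <- tot + length(flag_outliers(x, y, seed = s)$flagged_samples)
  }
  # nominal expectation 30 * 0.025 = 0.75 flags per pair
  expect_equal(tot / 200, 0.75, tolerance = 0.3)
})

test_that("removal recomputation collapses spike-driven correlations", {
  drops <- 0; total <- 0
  for (s in 1:100) {
    p <- spiked_pair(n = 25, spike = 8, seed = s)
    before <- pearson_cor(p$x, p$y)$r
    fl <- flag_outliers(p$x, p$y, seed = s)
    rm_ <- recompute_after_removal(p$x, p$y, fl)
    total <- total + 1
    drops <- drops + (abs(rm_$pcc_rm) <= abs(before) + 1e-12)
    if (s <= 20) expect_lt(rm_$pcc_rm, 0.3)
  }
  # removing flagged samples essentially never inflates the correlation
  expect_gte(drops, 97)
})

test_that("removal with zero flags is the identity and small remainders go undefined", {
  p <- spiked_pair(n = 20, spike = 8, seed = 2)
  none <- flag_outliers(p$x, p$y, quantile = 1, seed = 1)
  rm_ <- recompute_after_removal(p$x, p$y, none)
  expect_identical(rm_$pcc_rm, pearson_cor(p$x, p$y)$r)
  expect_identical(rm_$pqc_rm, quadrant_cor(p$x, p$y)$r)
  all_but_two <- structure(list(flagged_samples = names(p$x)[-(1:2)]),
                           class = "outlier_flag")
  rm2 <- recompute_after_removal(p$x, p$y, all_but_two)
  expect_true(is.na(rm2$pcc_rm) && is.na(rm2$pqc_rm))
})

test_that("add_outlier_stats fills candidate rows and emits a flag table", {
  gp <- generate_panel(validation_panel_config("outlier_screen", seed = 1))
  rec <- screen_pairs(gp$panel)
  res <- add_outlier_stats(gp$panel, rec, seed = 1)
  done <- !is.na(res$records$n_outliers)
  # only rule candidates (pcc above the outlier threshold) are processed
  expect_true(all(res$records$pcc[done] > 0.6))
  expect_true(all(res$records$n_complete[done] >= res$records$n_outliers[done]))
  expect_setequal(unique(paste(res$flags$gene_id, res$flags$metabolite_id)),
                  paste(res$records$gene_id, res$records$metabolite_id)[done])
  expect_identical(sum(res$flags$flagged),
                   sum(res$records$n_outliers, na.rm = TRUE))
  # per-pair seeds make results independent of the candidate set
  res2 <- add_outlier_stats(gp$panel, rec, candidates = "all", seed = 1)
  i <- which(done)[1]
  expect_identical(res2$records$n_outliers[i], res$records$n_outliers[i])
  expect_identical(res2$records$pcc_rm[i], res$records$pcc_rm[i])
})
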