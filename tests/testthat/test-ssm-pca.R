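test_that("SSM residuals are exactly double-centered", {
  # purely additive subject + region structure leaves zero residuals
  a <- withr::with_seed(1, rnorm(6)); b <- withr::with_seed(2, rnorm(9))
  X_add <- outer(a, rep(1, 9)) + outer(rep(1, 6), b)
  expect_lt(max(abs(ssm_residual(X_add))), 1e-12)

  X <- withr::with_seed(3, matrix(rnorm(6 * 9), 6, 9))
  R <- ssm_residual(X)
  expect_lt(max(abs(rowMeans(R))), 1e-10)
  expect_lt(max(abs(colMeans(R))), 1e-10)

  # 3x3 hand-worked example
  X3 <- rbind(c(1, 2, 3), c(4, 6, 8), c(5, 5, 11))
  R3 <- rbind(c(2, 2, -4), c(-1, 2, -1), c(-1, -4, 5)) / 3
  expect_equal(unclass(ssm_residual(X3)), R3, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(ssm_residual(matrix(1, 1, 5)), ">= 2")
})

test_that("SSM residuals vanish for noiseless pattern-free cohorts", {
  cc <- cohort_config(n_subjects = 8, n_regions = 15, pattern_mode = "none",
                      noise_sd = 0, global_scale_sd = 0.2, seed = 4)
  tab <- build_energetics_table(generate_regional_cohort(cc))
  expect_lt(max(abs(ssm_residual(tab$rep))), 1e-10)
})

test_that("PCA of the residual profile matches the eigendecomposition oracle", {
  for (seed in 1:4) {
    R <- ssm_residual(withr::with_seed(seed, matrix(rnorm(5 * 7), 5, 7)))
    comps <- pca_components(R)
    oracle <- oracle_pca_eigen(unclass(R))
    k <- length(comps$vaf)
    expect_equal(comps$sdev, oracle$sdev[seq_len(k)], tolerance = 1e-8)
    expect_equal(comps$vaf, oracle$vaf[seq_len(k)], tolerance = 1e-8)
    for (j in seq_len(k)) {
      expect_equal(abs(sum(comps$weights[, j] * oracle$weights[, j])), 1,
                   tolerance = 1e-8)
    }
    expect_equal(sum(comps$vaf), 100, tolerance = 1e-6)
    # scores are mutually orthogonal and reproduce R %*% weights
    g <- crossprod(comps$scores)
    expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
    expect_equal(comps$scores, unclass(R) %*% comps$weights,
                 tolerance = 1e-10)
  }

  # rank-1 residual: single component, VAF 100, weights proportional
  s <- c(-2, -1, 0, 1, 2); w <- unit_norm(c(2, -1, -1, 1, 0, -1))
  R1 <- s %o% w
  comps1 <- pca_components(ssm_residual(R1 + 0))
  expect_equal(comps1$vaf[1], 100, tolerance = 1e-8)
  expect_equal(abs(sum(comps1$weights[, 1] * w)), 1, tolerance = 1e-10)

  expect_error(pca_components(matrix(1:6, 2, 3)), "double-centered")
})

test_that("component filtering applies the VAF and t-test gates", {
  n <- 12
  split <- factor(rep(c("younger", "older"), each = 6),
                  levels = c("younger", "older"))
  mk <- function(vaf, scores) {
    structure(list(weights = diag(length(vaf))[, seq_along(vaf)],
                   scores = scores, vaf = vaf,
                   sdev = sqrt(vaf)), class = "pattern_components")
  }
  sep <- c(rnorm(6, 0, 0.2), rnorm(6, 3, 0.2))
  flat <- rep(c(-1, 1), 6)
  # below the VAF gate: excluded however separating
  keep <- filter_components(mk(c(4.9, 95.1), cbind(sep, sep)), split)
  expect_false(1L %in% keep)
  # identical group distributions: excluded by the t gate
  keep2 <- filter_components(mk(c(50, 50), cbind(sep, flat)), split)
  expect_equal(as.integer(keep2), 1L)

  # planted strong group effect on PC1 retained in >= 95% of replicates
  hits <- 0L
  for (r in 1:50) {
    X <- withr::with_seed(100 + r, {
      outer(c(rnorm(6, 0, 0.3), rnorm(6, 2, 0.3)), unit_norm(1:8)) +
        matrix(rnorm(n * 8, 0, 0.3), n, 8)
    })
    comps <- pca_components(ssm_residual(X))
    hits <- hits + (1L %in% filter_components(comps, split))
  }
  expect_gte(hits / 50, 0.95)
})

test_that("AIC-stepwise recombination selects separating components only", {
  n <- 20
  split <- factor(rep(c("younger", "older"), each = 10),
                  levels = c("younger", "older"))
  mk2 <- function(s1, s2) {
    w <- qr.Q(qr(matrix(rnorm(12 * 2), 12, 2)))
    structure(list(weights = w, scores = cbind(s1, s2), vaf = c(60, 40),
                   sdev = c(2, 1)), class = "pattern_components")
  }
  # a single component uncorrelated with the groups: intercept-only wins
  withr::with_seed(5, {
    flat <- rnorm(n)
    expect_null(stepwise_logistic_aic(mk2(flat, flat), split,
                                      candidates = 1L))
  })

  # strong separator + pure noise: exactly the former in >= 95% of runs
  picks <- withr::with_seed(6, {
    vapply(1:100, function(r) {
      comps <- mk2(as.numeric(split == "older") + rnorm(n, 0, 0.15),
                   rnorm(n))
      fit <- stepwise_logistic_aic(comps, split)
      !is.null(fit) && identical(fit$selected, 1L)
    }, logical(1))
  })
  expect_gte(mean(picks), 0.95)

  # combined weights always have unit norm
  withr::with_seed(7, {
    comps <- mk2(as.numeric(split == "older") * 3 + rnorm(n, 0, 0.5),
                 as.numeric(split == "older") * 2 + rnorm(n, 0, 0.5))
    fit <- stepwise_logistic_aic(comps, split)
    expect_equal(sum(fit$weights^2), 1, tolerance = 1e-12)
  })
})

test_that("cross-validation recovers a rank-1 planted signal exactly", {
  # exactly rank-1 metric matrix: every training fold finds the same
  # pattern, so the CV spread collapses to zero
  n <- 16; p <- 30
  ages <- seq(36, 79, length.out = n)
  w <- unit_norm(withr::with_seed(9, rnorm(p)))
  X <- (0.2 * (ages - mean(ages))) %o% w
  pat <- crossvalidate_pattern(X, ages, n_iter = 20, seed = 2,
                               metric = "rep")
  expect_lt(max(pat$weight_sd), 1e-10)
  # double demeaning removes the region-mean component of the planted
  # direction, so the recoverable pattern is the centered weight vector
  expect_equal(abs(cosine_similarity(pat$weights, w - mean(w))), 1,
               tolerance = 1e-10)
  expect_equal(pat$age_fit$r2, 1, tolerance = 1e-10)

  pat2 <- crossvalidate_pattern(X, ages, n_iter = 20, seed = 2,
                                metric = "rep")
  expect_identical(pat$weights, pat2$weights)
  expect_identical(pat$scores, pat2$scores)
})

test_that("cross-validation recovers the planted pattern from a noiseless cohort", {
  # the z-scoring of linear-scale values is mildly nonlinear in the
  # planted log-scale expression, so recovery is near-exact, not exact
  cc <- cohort_config(n_subjects = 16, n_regions = 30, noise_sd = 0,
                      global_scale_sd = 0, pattern_mode = "concordant",
                      seed = 9)
  ds <- generate_regional_cohort(cc)
  tab <- build_energetics_table(ds)
  pat <- crossvalidate_pattern(tab$rep, ds$ages, n_iter = 20, seed = 2,
                               metric = "rep")
  expect_gt(abs(cosine_similarity(pat$weights, ds$planted_pattern)), 0.9)
})

test_that("pattern scores orient with age and separate the groups", {
  base <- make_cohort("concordant", seed = 11)
  pat <- crossvalidate_pattern(base$table$rep, base$ds$ages, n_iter = 50,
                               seed = 3, metric = "rep")
  expect_gt(cor(pat$scores, base$ds$ages), 0)
  expect_lt(pat$separation$p, 0.01)
  expect_gt(pat$age_fit$r2, 0.5)
  # projection of full-cohort residuals is invariant to subject/region
  # constant offsets of the input matrix
  X2 <- base$table$rep + 5 + outer(seq_len(24) * 0.1, rep(1, 97))
  expect_equal(as.numeric(unclass(ssm_residual(X2)) %*% pat$weights),
               pat$scores, tolerance = 1e-8)
})

test_that("excluding two moderate-weight regions barely moves the age fit", {
  base <- make_cohort("concordant", seed = 11)
  pat <- crossvalidate_pattern(base$table$rep, base$ds$ages, n_iter = 60,
                               seed = 5, metric = "rep")
  mid <- order(abs(pat$weights))[c(40, 41)]  # moderate, not top, weights
  pat_drop <- crossvalidate_pattern(base$table$rep[, -mid],
                                    base$ds$ages, n_iter = 60, seed = 5,
                                    metric = "rep")
  expect_lt(abs(pat$age_fit$r2 - pat_drop$age_fit$r2), 0.05)
})

test_that("Cohen's d uses the pooled SD", {
  split6 <- factor(rep(c("younger", "older"), each = 3),
                   levels = c("younger", "older"))
  s <- separation_stats(c(1, 2, 3, 4, 5, 6), split6)
  expect_equal(s$d, 3)            # pooled SD = 1
  expect_equal(s$t, 3 / sqrt(2 / 3), tolerance = 1e-12)

  s0 <- separation_stats(c(1, 2, 3, 1, 2, 3), split6)
  expect_equal(s0$d, 0)

  expect_error(separation_stats(1:3, factor(c("younger", "younger", "older"),
                                            levels = c("younger", "older"))),
               ">= 2")
})

test_that("the age relationship is an r-squared with honest degeneracy flags", {
  ages <- seq(35, 80, length.out = 10)
  fit <- age_relationship(ages, ages)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_true(is.na(age_relationship(rep(1, 10), ages)$r2))

  # permutation null: p-values approximately uniform
  pvals <- withr::with_seed(10, {
    vapply(1:200, function(i) {
      age_relationship(sample(ages), ages)$p
    }, numeric(1))
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.001)
})

test_that("the display mask applies the weight-minus-SD rule bilaterally", {
  mk_pat <- function(w, sd) {
    structure(list(weights = w, weight_sd = sd,
                   region_names = names(w),
                   config = list(metric = "rep")),
              class = "covariance_pattern")
  }
  w <- c(L1 = 1.5, R1 = 0.2, L2 = -1.5, R2 = 0.1) # already SD-scaled below
  w <- w / sd(w)
  p1 <- mk_pat(w, sd = setNames(rep(0, 4), names(w)))
  m1 <- display_mask(p1, threshold = 1)
  expect_true(m1[["L1"]] && m1[["L2"]])
  expect_false(m1[["R1"]])
  # large weight with large CV spread is hidden
  p2 <- mk_pat(w, sd = setNames(rep(abs(w[["L1"]]), 4), names(w)))
  expect_false(any(display_mask(p2, threshold = 1)))
  # bilateral partner shown when one side passes
  lat <- c(L1 = "R1", R1 = "L1", L2 = "R2", R2 = "L2")
  m3 <- display_mask(p1, threshold = 1, laterality = lat)
  expect_true(m3[["R1"]] && m3[["R2"]])
  # sign-symmetric pattern gives a symmetric mask
  expect_equal(unname(m1[c("L1", "L2")]), c(TRUE, TRUE))
})

test_that("post-hoc regional trends decompose rEP linearly", {
  base <- make_cohort("concordant", seed = 11)
  tr <- posthoc_region_trends(base$table, 5)
  expect_true(all(is.finite(tr)))
  # covariances (not correlations) rotate exactly
  ages <- base$ds$ages
  cov_rep <- cov(base$table$rep[, 5], ages)
  cov_b <- cov(base$table$z_cbf[, 5], ages)
  cov_g <- cov(base$table$z_cmrglu[, 5], ages)
  expect_equal(cov_rep, (cov_b + cov_g) / sqrt(2), tolerance = 1e-12)

  # a planted linear trend in one region is recovered
  n <- 24
  ages2 <- seq(35, 80, length.out = n)
  z <- withr::with_seed(12, matrix(rnorm(n * 6, 0, 0.1), n, 6))
  zb2 <- withr::with_seed(13, matrix(rnorm(n * 6, 0, 0.1), n, 6))
  z[, 3] <- z[, 3] + 0.05 * (ages2 - mean(ages2))
  rot <- rotate_energetics(zb2, z)
  tab2 <- structure(list(z_cmrglu = z, z_cbf = zb2, rep = rot$rep,
                         rag = rot$rag, ages = ages2,
                         subject_ids = as.character(1:n),
                         region_names = letters[1:6]),
                    class = "energetics_table")
  expect_gt(posthoc_region_trends(tab2, 3)[["z_cmrglu"]], 0.9)
  expect_lt(abs(posthoc_region_trends(tab2, 1)[["z_cmrglu"]]), 0.5)
})
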