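# Scaled Subprofile Model PCA (SSM-PCA) derivation of age-related spatial
# covariance patterns: double-demeaned residual profiles, SVD-based PCA,
# VAF/t-test component filtering, forward-stepwise logistic recombination
# under AIC, repeated stratified k-fold cross-validation, and score
# projection with separation and age-relationship summaries.

#' SSM residual profile by double demeaning
#'
#' `R = X - row_means - col_means + grand_mean` (exact double-centering in
#' one pass): removes subject-global and region-mean effects so remaining
#' variance reflects between-subject topographic differences.
#'
#' @param X Subjects x regions numeric matrix (>= 2 each).
#' @return Matrix of class `residual_profile`; every row and column mean is
#'   zero to machine precision.
#' @export
ssm_residual <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need >= 2 subjects and regions", call. = FALSE)
  assert_finite(c(X), "data matrix")
  R <- X - rowMeans(X) - rep(colMeans(X), each = nrow(X)) + mean(X)
  class(R) <- c("residual_profile", class(R))
  R
}

is_double_centered <- function(R, tol = 1e-8) {
  max(abs(rowMeans(R)), abs(colMeans(R))) < tol * max(1, max(abs(R)))
}

#' Principal components of an SSM residual profile
#'
#' Singular value decomposition of the residual profile: region weights are
#' the right singular vectors (unit norm), subject scores are the
#' projections `R %*% weights`, and each component's VAF is
#' `100 * sigma_k^2 / sum(sigma^2)`, in descending order.
#'
#' @param R Double-centered matrix from [ssm_residual()].
#' @param tol Relative singular-value threshold below which components are
#'   dropped as numerically null.
#' @return List of class `pattern_components`: `weights` (regions x k),
#'   `scores` (subjects x k), `vaf` (percent), `sdev`.
#' @export
pca_components <- function(R, tol = 1e-10) {
  R <- unclass(as.matrix(R))
  if (!is_double_centered(R)) {
    stop("input must be double-centered (use ssm_residual)", call. = FALSE)
  }
  sv <- svd(R)
  keep <- sv$d > tol * max(sv$d, 0) & sv$d > 0
  if (!any(keep)) stop("residual profile is numerically zero", call. = FALSE)
  d <- sv$d[keep]
  structure(list(weights = sv$v[, keep, drop = FALSE],
                 scores = sv$u[, keep, drop = FALSE] %*% diag(d, length(d)),
                 vaf = 100 * d^2 / sum(sv$d^2),
                 sdev = d),
            class = "pattern_components")
}

#' Filter components by VAF and group separation
#'
#' Keeps components that (i) explain more than `vaf_min` percent VAF and
#' (ii) separate the younger vs older groups via their subject scores with
#' a two-tailed pooled-variance t-test p below `p_max`.
#'
#' @param components A [pca_components()] result.
#' @param split Younger/older factor (one entry per subject).
#' @param vaf_min VAF threshold, percent. Default 5.
#' @param p_max t-test p-value threshold. Default 0.2.
#' @return Integer vector of retained component indices (possibly empty),
#'   with the per-component p-values as attribute `p`.
#' @export
filter_components <- function(components, split, vaf_min = 5, p_max = 0.2) {
  stopifnot(inherits(components, "pattern_components"))
  split <- as.factor(split)
  old <- split == "older"
  if (!any(old) || all(old)) stop("both groups must be non-empty", call. = FALSE)
  k <- length(components$vaf)
  pvals <- rep(NA_real_, k)
  keep <- logical(k)
  for (j in seq_len(k)) {
    if (components$vaf[j] <= vaf_min) next
    pvals[j] <- pooled_t(components$scores[old, j],
                         components$scores[!old, j])$p
    keep[j] <- pvals[j] < p_max
  }
  structure(which(keep), p = pvals)
}

# One forward-stepwise logistic fit. `scores` holds candidate component
# scores (columns, ordered by VAF), `y` is 0/1 older-group membership.
# Returns NULL when the intercept-only model has the lowest AIC.
stepwise_fit <- function(scores, y) {
  n <- length(y)
  aic_of <- function(Xd) {
    fit <- suppressWarnings(
      stats::glm.fit(Xd, y, family = stats::binomial(),
                     control = list(maxit = 50))
    )
    if (!is.finite(fit$aic)) Inf else fit$aic
  }
  intercept <- matrix(1, n, 1)
  current_aic <- aic_of(intercept)
  selected <- integer(0)
  remaining <- seq_len(ncol(scores))
  repeat {
    if (length(remaining) == 0L) break
    trial <- vapply(remaining, function(j) {
      aic_of(cbind(intercept, scores[, c(selected, j), drop = FALSE]))
    }, numeric(1))
    best <- which.min(trial)
    if (trial[best] < current_aic) {
      selected <- c(selected, remaining[best])
      remaining <- remaining[-best]
      current_aic <- trial[best]
    } else break
  }
  if (length(selected) == 0L) return(NULL)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(intercept, scores[, selected, drop = FALSE]), y,
                   family = stats::binomial(), control = list(maxit = 50))
  )
  list(selected = selected, coef = fit$coefficients[-1], aic = current_aic)
}

#' Combine filtered components by AIC-stepwise logistic regression
#'
#' Forward stepwise over the candidate components (ordered by VAF): at each
#' step the component whose subject scores, added as a logistic predictor
#' of older-group membership, most lowers AIC is added; the search stops
#' when no addition lowers AIC. The combined region weights are the
#' coefficient-weighted sum of the selected component weights, renormalized
#' to unit norm. AIC is `2k - 2 log L` from the unpenalized likelihood
#' (intercept included). Logistic fits use iteratively reweighted least
#' squares with a capped iteration count; under perfect separation at small
#' n the deviance collapses to ~0 and AIC reduces to `2k`, which is exactly
#' the ranking the stepwise search needs, so no penalization is applied.
#'
#' @param components A [pca_components()] result.
#' @param split Younger/older factor.
#' @param candidates Integer indices of candidate components (e.g. from
#'   [filter_components()]); defaults to all.
#' @return `NULL` if the intercept-only model wins; otherwise a list with
#'   unit-norm `weights`, `coef`, `selected` (component indices), `aic`.
#' @export
stepwise_logistic_aic <- function(components, split,
                                  candidates = seq_along(components$vaf)) {
  stopifnot(inherits(components, "pattern_components"))
  if (length(candidates) == 0L) return(NULL)
  split <- as.factor(split)
  y <- as.integer(split == "older")
  fit <- stepwise_fit(components$scores[, candidates, drop = FALSE], y)
  if (is.null(fit)) return(NULL)
  sel <- candidates[fit$selected]
  w <- components$weights[, sel, drop = FALSE] %*% fit$coef
  list(weights = unit_norm(as.numeric(w)), coef = fit$coef,
       selected = sel, aic = fit$aic)
}

# Derive one combined pattern from a training subset of the metric matrix.
derive_fold_pattern <- function(X, split, train, vaf_min, p_max) {
  sp <- split[train]
  if (sum(sp == "younger") < 2L || sum(sp == "older") < 2L) return(NULL)
  R <- ssm_residual(X[train, , drop = FALSE])
  comps <- pca_components(R)
  keep <- filter_components(comps, sp, vaf_min = vaf_min, p_max = p_max)
  if (length(keep) == 0L) return(NULL)
  fit <- stepwise_logistic_aic(comps, sp, candidates = keep)
  if (is.null(fit)) return(NULL)
  fit
}

#' Cross-validated age-related covariance pattern
#'
#' Repeats `n_iter` random stratified `k_folds`-fold partitions of the
#' cohort. On each training set (all folds but one) the full derivation is
#' re-run from scratch: SSM residuals, PCA, VAF/t filtering, AIC-stepwise
#' logistic recombination. Each resulting unit-norm pattern is sign-aligned
#' to a running mean reference (flipped when the dot product is negative).
#' The final weights are the mean over all retained fold-patterns
#' (renormalized to unit norm) and `weight_sd` their per-region SD; final
#' subject scores are the projection of the full-cohort residual profile
#' onto the final weights, with the orientation fixed so the score-age
#' correlation is positive ("expression increases with age").
#'
#' @param X Subjects x regions metric matrix (rEP or rAG).
#' @param ages Subject ages, years.
#' @param cutoff Younger/older cutoff age. Default 60.
#' @param n_iter Number of cross-validation iterations. Default 500.
#' @param k_folds Folds per iteration. Default 5.
#' @param vaf_min,p_max Component filter thresholds (percent VAF, t-test p).
#' @param seed Integer seed for fold assignment.
#' @param metric Label stored with the pattern.
#' @return Object of class `covariance_pattern`: `weights`, `weight_sd`,
#'   `scores`, `separation` (t, p, Cohen's d), `age_fit` (r2, p),
#'   `components_used` (selection frequency by component rank),
#'   `n_patterns` (folds that yielded a model), `config`.
#' @export
crossvalidate_pattern <- function(X, ages, cutoff = 60, n_iter = 500,
                                  k_folds = 5, vaf_min = 5, p_max = 0.2,
                                  seed = 1L, metric = "metric") {
  X <- as.matrix(X)
  n <- nrow(X)
  split <- age_group_split(ages, cutoff)
  if (sum(split == "younger") < 2L || sum(split == "older") < 2L) {
    stop("both age groups need >= 2 subjects", call. = FALSE)
  }
  patterns <- matrix(NA_real_, nrow = n_iter * k_folds, ncol = ncol(X))
  used <- integer(0)
  npat <- 0L
  ref <- NULL
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      # stratified fold assignment: shuffle within each age group
      fold <- integer(n)
      for (g in levels(split)) {
        idx <- which(split == g)
        fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
      }
      for (f in seq_len(k_folds)) {
        train <- fold != f
        fit <- derive_fold_pattern(X, split, train, vaf_min, p_max)
        if (is.null(fit)) next
        w <- fit$weights
        if (is.null(ref)) {
          ref <- w
        } else if (sum(w * ref) < 0) {
          w <- -w
        }
        npat <- npat + 1L
        patterns[npat, ] <- w
        ref <- ref + (w - ref) / npat   # running mean reference
        used <- c(used, fit$selected)
      }
    }
  })
  if (npat == 0L) {
    stop(sprintf(paste0("pattern derivation failed: all %d x %d-fold ",
                        "iterations yielded empty models (no component ",
                        "passed VAF > %g%% and t-test p < %g, or AIC never ",
                        "improved)"), n_iter, k_folds, vaf_min, p_max),
         call. = FALSE)
  }
  patterns <- patterns[seq_len(npat), , drop = FALSE]
  w_mean <- colMeans(patterns)
  w_final <- unit_norm(w_mean)
  w_sd <- apply(patterns, 2, stats::sd)
  if (npat == 1L) w_sd <- rep(0, ncol(X))

  R_full <- ssm_residual(X)
  scores <- as.numeric(unclass(R_full) %*% w_final)
  r_age <- suppressWarnings(stats::cor(scores, ages))
  if (is.na(r_age)) {
    # degenerate: orient by making the largest-|weight| region positive
    if (w_final[which.max(abs(w_final))] < 0) {
      w_final <- -w_final; scores <- -scores
    }
  } else if (r_age < 0) {
    w_final <- -w_final; scores <- -scores
  }
  sep <- separation_stats(scores, split)
  fit_age <- age_relationship(scores, ages)
  structure(list(weights = stats::setNames(w_final, colnames(X)),
                 weight_sd = stats::setNames(w_sd, colnames(X)),
                 scores = scores, separation = sep, age_fit = fit_age,
                 components_used = table(factor(used)),
                 n_patterns = npat,
                 region_names = colnames(X),
                 config = list(metric = metric, cutoff = cutoff,
                               n_iter = n_iter, k_folds = k_folds,
                               vaf_min = vaf_min, p_max = p_max,
                               seed = seed)),
            class = "covariance_pattern")
}

#' @export
print.covariance_pattern <- function(x, ...) {
  cat(sprintf("covariance_pattern (%s): %d regions, %d CV patterns retained\n",
              x$config$metric, length(x$weights), x$n_patterns))
  cat(sprintf("  separation: t = %.2f, p = %.2g, Cohen's d = %.2f\n",
              x$separation$t, x$separation$p, x$separation$d))
  cat(sprintf("  age fit: r2 = %.3f, p = %.2g\n", x$age_fit$r2, x$age_fit$p))
  invisible(x)
}

#' Group-separation statistics for pattern scores
#'
#' Two-sample two-tailed pooled-variance t-test of older vs younger scores
#' plus Cohen's d (mean difference over pooled SD).
#'
#' @param scores Per-subject pattern expression scores.
#' @param split Younger/older factor.
#' @return List with `t`, `df`, `p`, `d`.
#' @export
separation_stats <- function(scores, split) {
  split <- as.factor(split)
  old <- split == "older"
  if (sum(old) < 2L || sum(!old) < 2L) {
    stop("both groups need >= 2 subjects", call. = FALSE)
  }
  pooled_t(scores[old], scores[!old])
}

#' Age relationship of pattern scores
#'
#' Squared Pearson correlation between scores and age, with its two-tailed
#' p-value.
#'
#' @param scores Per-subject scores.
#' @param ages Subject ages.
#' @return List with `r2`, `r`, `p`; `r2` is `NA` (flagged) for constant
#'   scores.
#' @export
age_relationship <- function(scores, ages) {
  if (length(scores) != length(ages)) stop("length mismatch", call. = FALSE)
  if (stats::sd(scores) == 0 || stats::sd(ages) == 0) {
    return(list(r2 = NA_real_, r = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  ct <- stats::cor.test(scores, ages)
  list(r2 = unname(ct$estimate^2), r = unname(ct$estimate), p = ct$p.value)
}

#' Display mask for a covariance pattern
#'
#' Regions are displayed when `|w| - sd(w) > threshold` after the unit-norm
#' weights are standardized to SD 1 across regions (the weight SDs are
#' scaled by the same factor). With a laterality map, the bilateral partner
#' of any displayed region is displayed too.
#'
#' @param pattern A [crossvalidate_pattern()] result.
#' @param threshold Display threshold. Default 1.
#' @param laterality Optional named character vector mapping each region to
#'   its contralateral partner.
#' @return Logical vector over regions (`TRUE` = displayed).
#' @export
display_mask <- function(pattern, threshold = 1, laterality = NULL) {
  stopifnot(inherits(pattern, "covariance_pattern"))
  s <- stats::sd(pattern$weights)
  if (s == 0) stop("degenerate constant weights", call. = FALSE)
  w <- pattern$weights / s
  w_sd <- pattern$weight_sd / s
  shown <- (abs(w) - w_sd) > threshold
  if (!is.null(laterality)) {
    partners <- laterality[names(shown)[shown]]
    partners <- partners[!is.na(partners) & partners %in% names(shown)]
    shown[partners] <- TRUE
  }
  shown
}

#' Post-hoc age trends of the energetics quantities in one region
#'
#' Pearson correlations of z(CMRglu), z(CBF), rEP and rAG with age for a
#' single region — illustrative decompositions of how a pattern's regional
#' changes manifest, not strict statistical tests.
#'
#' @param table An [build_energetics_table()] result.
#' @param region Region name or column index.
#' @param ages Subject ages; defaults to `table$ages`.
#' @return Named numeric vector of Pearson r for `z_cmrglu`, `z_cbf`,
#'   `rep`, `rag`.
#' @export
posthoc_region_trends <- function(table, region, ages = table$ages) {
  stopifnot(inherits(table, "energetics_table"))
  vapply(c(z_cmrglu = "z_cmrglu", z_cbf = "z_cbf", rep = "rep", rag = "rag"),
         function(q) stats::cor(table[[q]][, region], ages), numeric(1))
}
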