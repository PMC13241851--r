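# Partial Least Squares Correlation (PLSC) between regional metrics and
# clinical variables: SVD of the clinical-by-region correlation matrix,
# permutation inference on the singular values, and bootstrap stability of
# the region saliences.

#' Fit a PLSC model
#'
#' Column-standardizes `X` (subjects x regions) and `Y` (subjects x
#' clinical variables), forms the clinical-by-region correlation matrix
#' `C = t(Ys) %*% Xs / (n - 1)` and decomposes it as `C = U S t(V)`. The
#' brain saliences are the columns of `V`, the clinical saliences the
#' columns of `U`; brain scores are `Xs %*% V` and clinical scores
#' `Ys %*% U`.
#'
#' @param X Subjects x regions numeric matrix.
#' @param Y Subjects x clinical matrix/data frame (no constant column).
#'   Conventional coding: age as-is, sex as +/-0.5 (both are standardized).
#' @return Object of class `plsc_result`: `brain_saliences` (regions x LV),
#'   `clinical_saliences` (variables x LV), `singular_values`,
#'   `brain_scores`, `clinical_scores`.
#' @export
plsc_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3L) stop("need >= 3 subjects", call. = FALSE)
  if (nrow(Y) != n) stop("X and Y must have the same subjects", call. = FALSE)
  if (any(apply(Y, 2, stats::sd) == 0)) {
    stop("constant clinical column", call. = FALSE)
  }
  Xs <- scale(X); Ys <- scale(Y)
  # regions with zero variance carry no correlation signal; keep them as 0
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  C <- crossprod(Ys, Xs) / (n - 1)
  sv <- svd(C)
  structure(list(brain_saliences = sv$v,
                 clinical_saliences = sv$u,
                 singular_values = sv$d,
                 brain_scores = Xs %*% sv$v,
                 clinical_scores = Ys %*% sv$u,
                 clinical_names = colnames(Y),
                 region_names = colnames(X)),
            class = "plsc_result")
}

#' Permutation significance of PLSC latent variables
#'
#' Permutes the subject rows of `Y` `n_perm` times, refits, and reports for
#' each latent variable `p_k = (1 + #{perm sigma_k >= observed sigma_k}) /
#' (n_perm + 1)`.
#'
#' @param X,Y As in [plsc_fit()].
#' @param n_perm Number of permutations. Default 1000.
#' @param seed Integer seed.
#' @return Numeric vector of permutation p-values per latent variable, in
#'   `(0, 1]`.
#' @export
plsc_permutation <- function(X, Y, n_perm = 1000, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  obs <- plsc_fit(X, Y)$singular_values
  n <- nrow(X)
  exceed <- integer(length(obs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      d <- plsc_fit(X, Y[sample.int(n), , drop = FALSE])$singular_values
      exceed <- exceed + (d >= obs)
    }
  })
  (1 + exceed) / (n_perm + 1)
}

# Orthogonal Procrustes rotation aligning B to A (both p x k).
procrustes_rotation <- function(B, A) {
  sv <- svd(crossprod(B, A))
  sv$u %*% t(sv$v)
}

#' Bootstrap stability ratios for PLSC region saliences
#'
#' Resamples subjects with replacement, refits, Procrustes-aligns each
#' resampled brain-salience matrix to the original (resolving sign and
#' rotation indeterminacy), and reports per region and latent variable the
#' ratio of the original salience to the bootstrap SD.
#'
#' @param X,Y As in [plsc_fit()].
#' @param n_boot Number of bootstrap resamples. Default 500.
#' @param seed Integer seed.
#' @return Matrix (regions x LV) of bootstrap ratios.
#' @export
plsc_bootstrap <- function(X, Y, n_boot = 500, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  fit <- plsc_fit(X, Y)
  V <- fit$brain_saliences
  n <- nrow(X)
  acc <- array(NA_real_, dim = c(dim(V), n_boot))
  withr::with_seed(seed, {
    b <- 1L
    guard <- 0L
    while (b <= n_boot) {
      idx <- sample.int(n, replace = TRUE)
      Yb <- Y[idx, , drop = FALSE]
      if (any(apply(Yb, 2, stats::sd) == 0)) {
        guard <- guard + 1L
        if (guard > 100L * n_boot) stop("degenerate bootstrap resamples", call. = FALSE)
        next
      }
      Vb <- plsc_fit(X[idx, , drop = FALSE], Yb)$brain_saliences
      acc[, , b] <- Vb %*% procrustes_rotation(Vb, V)
      b <- b + 1L
    }
  })
  sds <- apply(acc, c(1, 2), stats::sd)
  ratio <- V / sds
  ratio[sds == 0] <- sign(V[sds == 0]) * Inf
  ratio[sds == 0 & V == 0] <- 0
  dimnames(ratio) <- list(fit$region_names, NULL)
  ratio
}
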