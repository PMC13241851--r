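# Internal helpers shared across modules.

assert_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("%s must be non-empty, numeric and finite", what), call. = FALSE)
  }
  invisible(x)
}

#' Normalize a vector to unit Euclidean norm
#'
#' @param w Numeric vector.
#' @return `w / sqrt(sum(w^2))`.
#' @export
unit_norm <- function(w) {
  assert_finite(w, "weight vector")
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-300) stop("cannot normalize a zero vector", call. = FALSE)
  w / nrm
}

#' Cosine similarity between two weight vectors
#'
#' Used to quantify spatial-pattern recovery (e.g. recovered vs planted
#' region weights); both vectors are unit-normalized first.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  sum(unit_norm(a) * unit_norm(b))
}

# Two-sample pooled-variance t statistic, p-value and Cohen's d.
# Equal-variance form: the component filter and separation statistics both
# use the classic Student t (not Welch).
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations", call. = FALSE)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 <= 0) {
    tstat <- if (delta == 0) 0 else sign(delta) * Inf
    d <- tstat
  } else {
    tstat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
    d <- delta / sqrt(sp2)
  }
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p, d = d)
}

#' Derive a stage-specific sub-seed from the pipeline seed
#'
#' All stochastic stages draw from a single integer seed; each stage uses a
#' deterministic sub-seed so stages can be rerun in isolation and in any
#' order. Stage names are fixed; the derivation is
#' `(seed * 31 + stage index) mod 1073741789` (kept below 2^30 so small
#' additive offsets stay in integer range).
#'
#' @param seed Integer master seed.
#' @param stage One of `"cohort"`, `"tac"`, `"disease"`, `"folds_rep"`,
#'   `"folds_rag"`, `"plsc_rep"`, `"plsc_rag"`, `"compare"`.
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, stage = c("cohort", "tac", "disease", "folds_rep",
                                        "folds_rag", "plsc_rep", "plsc_rag",
                                        "compare")) {
  stage <- match.arg(stage)
  idx <- match(stage, c("cohort", "tac", "disease", "folds_rep", "folds_rag",
                        "plsc_rep", "plsc_rag", "compare"))
  as.integer((abs(as.numeric(seed)) * 31 + idx) %% 1073741789)
}
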