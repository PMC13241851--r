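# Independent oracles and small fixtures used across the suite. These are
# deliberately naive (enumeration, closed forms, fine-grid quadrature) and
# share no code with the implementation paths they check.

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || anyNA(a)) b else a
}

# Frame mid-times of a 4x1, 3x2, 8x5, 1x10 minute dynamic schedule.
frame_mid_times <- function() {
  ends <- cumsum(c(rep(1, 4), rep(2, 3), rep(5, 8), 10))
  starts <- c(0, ends[-length(ends)])
  (starts + ends) / 2
}

# Closed-form impulse response of the irreversible 2TC model convolved with
# the plasma input on a fine grid (trapezoid quadrature).
oracle_2tc_tissue <- function(K1, k2, k3, input_fn, t_eval, dt = 0.002) {
  vapply(t_eval, function(t) {
    if (t <= 0) return(0)
    s <- seq(0, t, by = dt)
    h <- if (k2 + k3 == 0) rep(1, length(s)) else
      k3 / (k2 + k3) + k2 / (k2 + k3) * exp(-(k2 + k3) * (t - s))
    pracma::trapz(s, K1 * input_fn(s) * h)
  }, numeric(1))
}

# Exhaustive 1-D 3-means: minimal within-cluster sum of squares over all
# boundary pairs of the sorted values.
oracle_kmeans3_1d <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- list(wss = Inf)
  for (b1 in 1:(n - 2)) {
    for (b2 in (b1 + 1):(n - 1)) {
      groups <- list(xs[1:b1], xs[(b1 + 1):b2], xs[(b2 + 1):n])
      wss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
      if (wss < best$wss) best <- list(wss = wss, b1 = b1, b2 = b2)
    }
  }
  best
}

# Exhaustive search over voxel subsets (size >= min_voxels) minimizing the
# venous-sample residual of the mean candidate TAC.
oracle_idif_min_sse <- function(tacs, frame_times, venous, min_voxels) {
  nv <- nrow(tacs)
  best <- Inf
  for (size in min_voxels:nv) {
    combos <- utils::combn(nv, size)
    for (j in seq_len(ncol(combos))) {
      m <- colMeans(tacs[combos[, j], , drop = FALSE])
      at <- stats::approx(frame_times, m, xout = venous$time)$y
      best <- min(best, sum((at - venous$value)^2))
    }
  }
  best
}

# All permutations of 1..n (tiny n only), for exact permutation p-values.
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(combinat_perms(n - 1L), function(p) {
      c(i, setdiff(seq_len(n), i)[p])
    })
  }))
}

# Brute-force PCA of a residual matrix via eigendecomposition of t(R) R.
oracle_pca_eigen <- function(R) {
  ev <- eigen(crossprod(R), symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-12
  list(weights = ev$vectors[, keep, drop = FALSE],
       sdev = sqrt(ev$values[keep]),
       vaf = 100 * ev$values[keep] / sum(pmax(ev$values, 0)))
}

# Default-sized synthetic cohort + energetics table, memoized per seed/mode
# so acceptance and unit tests can share the expensive generation.
make_cohort <- local({
  cache <- list()
  function(mode = "concordant", seed = 11, ...) {
    key <- paste(mode, seed, ...)
    if (is.null(cache[[key]])) {
      ds <- generate_regional_cohort(
        cohort_config(pattern_mode = mode, seed = seed, ...))
      cache[[key]] <<- list(ds = ds, table = build_energetics_table(ds))
    }
    cache[[key]]
  }
})
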