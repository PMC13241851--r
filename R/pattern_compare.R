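# Comparison of age-related energetics patterns with externally supplied
# disease-related metabolic patterns: regionalized Topographic Profile
# Rating (TPR) subject scores, Spearman weight correlations, Pearson score
# correlations, and Bonferroni adjustment over the comparison family.

#' Topographic Profile Rating scores against a disease pattern
#'
#' For each subject, the regional CMRglu profile is log-transformed
#' (natural log), the regional global mean rate `rGMR = mean(log rCMRglu)`
#' is subtracted along with the pattern's group mean profile to give the
#' subject residual profile `rSRP = log(rCMRglu) - rGMR - rGMP`, and the
#' score is the projection of `rSRP` onto the disease pattern weights
#' `rDRP`. Score magnitudes are not clinically meaningful (no
#' standardization is applied); only their covariance with other expression
#' measures is of interest.
#'
#' By default the rDRP weights are mean-centered across regions before
#' projection, which makes scores exactly invariant to per-subject global
#' scaling of CMRglu; set `center_rdrp = FALSE` for the raw projection.
#'
#' @param rcmrglu Subjects x regions strictly positive CMRglu matrix, with
#'   region columns aligned to `dp$region_names`.
#' @param dp A [disease_pattern()].
#' @param center_rdrp Mean-center the weights before projection (default
#'   `TRUE`).
#' @return Object of class `tpr_scores`: `rsrp` (subjects x regions),
#'   `scores` (per subject), `label`.
#' @export
tpr_scores <- function(rcmrglu, dp, center_rdrp = TRUE) {
  stopifnot(inherits(dp, "disease_pattern"))
  rcmrglu <- as.matrix(rcmrglu)
  if (ncol(rcmrglu) != length(dp$region_names)) {
    stop("region count mismatch with disease pattern", call. = FALSE)
  }
  if (!is.null(colnames(rcmrglu)) &&
      !identical(colnames(rcmrglu), dp$region_names)) {
    stop("region names do not align with disease pattern", call. = FALSE)
  }
  if (any(rcmrglu <= 0) || anyNA(rcmrglu)) {
    stop("CMRglu must be strictly positive", call. = FALSE)
  }
  L <- log(rcmrglu)
  rgmr <- rowMeans(L)
  rsrp <- L - rgmr - rep(dp$rgmp, each = nrow(L))
  w <- if (center_rdrp) dp$rdrp - mean(dp$rdrp) else dp$rdrp
  structure(list(rsrp = rsrp, scores = as.numeric(rsrp %*% w),
                 label = dp$label, centered = center_rdrp),
            class = "tpr_scores")
}

#' Spatial similarity of two region-weight patterns
#'
#' Spearman rank correlation (average ranks on ties) with a two-tailed
#' t-approximation p-value; rank correlation is used because topological
#' similarity need not be linear.
#'
#' @param p1,p2 Aligned per-region weight vectors, n >= 4.
#' @return List with `rho` and `p`.
#' @export
compare_weights <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("patterns must align", call. = FALSE)
  if (length(p1) < 4L) stop("need >= 4 regions", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(p1, p2, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Expression similarity of two subject-score vectors
#'
#' Pearson correlation with its two-tailed p-value.
#'
#' @param s1,s2 Per-subject score vectors, n >= 3.
#' @return List with `rho` and `p`.
#' @export
compare_scores <- function(s1, s2) {
  if (length(s1) != length(s2)) stop("scores must align", call. = FALSE)
  if (length(s1) < 3L) stop("need >= 3 subjects", call. = FALSE)
  ct <- stats::cor.test(s1, s2, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Bonferroni adjustment over a comparison family
#'
#' `min(1, m * p)` per value. In the standard analysis each family has
#' m = 6 comparisons ({rEP, rAG} x {PDRP, PDCP, ADRP}).
#'
#' @param p_values Raw p-values.
#' @param m Family size; defaults to `length(p_values)`.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("family size must be >= 1", call. = FALSE)
  pmin(1, m * p_values)
}

#' Regionalize a voxelwise disease pattern
#'
#' Averages a voxelwise pattern volume and its group-mean-profile volume
#' over the labelled regions (via [aggregate_roi()]), yielding a regional
#' disease pattern usable with [tpr_scores()].
#'
#' @param voxel_pattern,voxel_gmp 3-D parametric volumes on the label grid.
#' @param labels A [label_volume()].
#' @param label Pattern label.
#' @param drop_missing Drop regions absent from the grid (default `FALSE`:
#'   absent regions raise an error so misalignment is not silent).
#' @return A [disease_pattern()].
#' @export
regionalize_voxel_pattern <- function(voxel_pattern, voxel_gmp, labels,
                                      label = "DRP", drop_missing = FALSE) {
  rdrp <- aggregate_roi(voxel_pattern, labels)
  rgmp <- aggregate_roi(voxel_gmp, labels)
  miss <- is.na(rdrp) | is.na(rgmp)
  if (any(miss)) {
    if (!drop_missing) {
      stop(sprintf("labels absent from grid: %s",
                   paste(names(rdrp)[miss], collapse = ", ")), call. = FALSE)
    }
    rdrp <- rdrp[!miss]; rgmp <- rgmp[!miss]
  }
  disease_pattern(names(rdrp), rdrp, rgmp, label)
}

#' Compare age-related patterns with disease patterns
#'
#' Builds the full comparison report: for each (age-related pattern,
#' disease pattern) pair, the Spearman correlation of region weights and
#' the Pearson correlation of subject scores (TPR expression vs pattern
#' expression), with Bonferroni adjustment within each family.
#'
#' @param age_patterns Named list of [crossvalidate_pattern()] results.
#' @param disease_patterns Named list of [disease_pattern()] objects.
#' @param rcmrglu Subjects x regions CMRglu matrix for TPR scoring.
#' @param m Bonferroni family size; defaults to the number of pairs.
#' @return Data frame with columns `pair`, `family`, `rho`, `p_raw`,
#'   `p_adjusted`.
#' @export
compare_patterns <- function(age_patterns, disease_patterns, rcmrglu,
                             m = length(age_patterns) * length(disease_patterns)) {
  rows <- list()
  for (an in names(age_patterns)) {
    ap <- age_patterns[[an]]
    for (dn in names(disease_patterns)) {
      dp <- disease_patterns[[dn]]
      cw <- compare_weights(ap$weights, dp$rdrp)
      ts <- tpr_scores(rcmrglu, dp)
      cs <- compare_scores(ap$scores, ts$scores)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(an, "vs", dn),
        family = c("weights", "scores"),
        rho = c(cw$rho, cs$rho),
        p_raw = c(cw$p, cs$p),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_adjusted[sel] <- bonferroni(out$p_raw[sel], m = m)
  }
  out
}
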