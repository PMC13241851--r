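# Relative energy production (rEP) and relative aerobic glycolysis (rAG):
# per-subject z-scoring of regional CMRglu and CBF across regions followed
# by a 45-degree rotation in the [z(CBF), z(CMRglu)] plane. rEP is the
# projection onto the line of unity (concurrence of flow and metabolism);
# rAG is the orthogonal distance from it (discordance, a proxy for aerobic
# glycolysis under spatially uniform oxygen extraction).

#' Z-score a regional value vector
#'
#' `(v - mean(v)) / sd(v)` over regions, with the sample SD (denominator
#' N - 1). Fails on missing values or zero variance; gaps must be resolved
#' upstream.
#'
#' @param values Numeric regional vector (>= 2 regions).
#' @return Z-scored vector with mean 0 and sample SD 1.
#' @export
zscore_regions <- function(values) {
  assert_finite(values, "regional values")
  if (length(values) < 2L) stop("need >= 2 regions", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance across regions", call. = FALSE)
  (values - mean(values)) / s
}

#' Rotate z-scored (CBF, CMRglu) into (rEP, rAG)
#'
#' The 45-degree change of basis: `rep = (z_cbf + z_cmrglu) / sqrt(2)`,
#' `rag = (z_cmrglu - z_cbf) / sqrt(2)`. Positive rAG means relative
#' CMRglu exceeds relative CBF. Vectorized over inputs.
#'
#' @param z_cbf,z_cmrglu Finite numeric scalars/vectors/matrices.
#' @return List with components `rep` and `rag` shaped like the inputs.
#' @export
rotate_energetics <- function(z_cbf, z_cmrglu) {
  if (anyNA(z_cbf) || anyNA(z_cmrglu) ||
      any(!is.finite(z_cbf)) || any(!is.finite(z_cmrglu))) {
    stop("inputs must be finite", call. = FALSE)
  }
  s2 <- sqrt(2)
  list(rep = (z_cbf + z_cmrglu) / s2, rag = (z_cmrglu - z_cbf) / s2)
}

#' Build the per-subject energetics table
#'
#' Z-scores each subject's CMRglu and CBF profiles across regions, then
#' applies the rotation element-wise. Invariant to per-subject positive
#' rescaling or additive offsets of either raw modality.
#'
#' @param ds A [regional_dataset()].
#' @return Object of class `energetics_table`: matrices `z_cmrglu`,
#'   `z_cbf`, `rep`, `rag` (subjects x regions) plus `subject_ids`,
#'   `region_names`, `ages`, `sex`.
#' @export
build_energetics_table <- function(ds) {
  stopifnot(inherits(ds, "regional_dataset"))
  zg <- t(apply(ds$cmrglu, 1, zscore_regions))
  zb <- t(apply(ds$cbf, 1, zscore_regions))
  rot <- rotate_energetics(zb, zg)
  dimnames(zg) <- dimnames(zb) <- dimnames(rot$rep) <- dimnames(rot$rag) <-
    list(ds$subject_ids, ds$region_names)
  structure(list(z_cmrglu = zg, z_cbf = zb, rep = rot$rep, rag = rot$rag,
                 subject_ids = ds$subject_ids, region_names = ds$region_names,
                 ages = ds$ages, sex = ds$sex),
            class = "energetics_table")
}

#' @export
print.energetics_table <- function(x, ...) {
  cat(sprintf("energetics_table: %d subjects x %d regions (z_cmrglu, z_cbf, rEP, rAG)\n",
              nrow(x$rep), ncol(x$rep)))
  invisible(x)
}

#' Split subjects into younger/older age groups
#'
#' Subjects with age <= `cutoff` are "younger", the rest "older". The
#' default cutoff of 60 years splits a broad-age-range cohort into groups
#' of approximately equal size while maximizing their mean-age difference.
#'
#' @param ages Numeric ages, years.
#' @param cutoff Cutoff age; boundary subjects go to the younger group.
#' @return Factor with levels `younger`, `older`.
#' @export
age_group_split <- function(ages, cutoff = 60) {
  assert_finite(ages, "ages")
  factor(ifelse(ages <= cutoff, "younger", "older"),
         levels = c("younger", "older"))
}

#' Older-minus-younger group shifts per region
#'
#' Subtracts the younger-group regional mean from the older-group regional
#' mean for each of the four energetics quantities, giving the directional
#' shift of the cohort with age.
#'
#' @param table An [build_energetics_table()] result.
#' @param split Factor from [age_group_split()] (levels younger/older).
#' @return List of per-region shift vectors: `rep`, `rag`, `z_cmrglu`,
#'   `z_cbf`.
#' @export
group_shift <- function(table, split) {
  stopifnot(inherits(table, "energetics_table"))
  split <- as.factor(split)
  if (sum(split == "younger") == 0L || sum(split == "older") == 0L) {
    stop("both age groups must be non-empty", call. = FALSE)
  }
  old <- split == "older"
  shift_of <- function(m) colMeans(m[old, , drop = FALSE]) -
    colMeans(m[!old, , drop = FALSE])
  list(rep = shift_of(table$rep), rag = shift_of(table$rag),
       z_cmrglu = shift_of(table$z_cmrglu), z_cbf = shift_of(table$z_cbf))
}
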