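# Kinetic and volumetric quantification: Patlak graphical analysis of FDG
# net uptake, lumped-constant scaling to CMRglu, a simplified image-derived
# input-function selection, ROI aggregation of parametric volumes, and the
# k-means subdivision of the putamen along the anterior-posterior axis.

#' Construct a time-activity curve
#'
#' @param times Frame mid-times, minutes; strictly increasing.
#' @param values Activity concentration per frame (kBq/mL).
#' @return Object of class `time_activity_curve`.
#' @export
time_activity_curve <- function(times, values) {
  assert_finite(times, "times"); assert_finite(values, "values")
  if (length(times) != length(values)) stop("length mismatch", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "time_activity_curve")
}

#' Construct a plasma input curve
#'
#' @param times Sample times, minutes; strictly increasing.
#' @param values Plasma activity concentration (kBq/mL), non-negative.
#' @return Object of class `plasma_input_curve`.
#' @export
plasma_input_curve <- function(times, values) {
  assert_finite(times, "times"); assert_finite(values, "values")
  if (length(times) != length(values)) stop("length mismatch", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("plasma values must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "plasma_input_curve")
}

#' Patlak graphical estimation of the net uptake rate Ki
#'
#' Ordinary least-squares fit of the Patlak plot over late frames:
#' \deqn{C_t(t)/C_p(t) = K_i \int_0^t C_p \, d\tau / C_p(t) + V}
#' The cumulative plasma integral is computed by the trapezoid rule on the
#' input grid and both plasma terms are linearly interpolated to the frame
#' mid-times; frames with time >= `t_star` enter the fit.
#'
#' @param tac A [time_activity_curve()].
#' @param input_fn A [plasma_input_curve()]; should be densely sampled.
#' @param t_star Start of the linear phase, minutes. Default 20 (frames at
#'   or beyond 20 minutes of the 4x1, 3x2, 8x5, 1x10 min schedule).
#' @return Object of class `ki_estimate`: `ki` (per minute), `intercept`
#'   (distribution volume term), `r2`, `n_points`.
#' @export
patlak_ki <- function(tac, input_fn, t_star = 20) {
  stopifnot(inherits(tac, "time_activity_curve"),
            inherits(input_fn, "plasma_input_curve"))
  use <- tac$times >= t_star
  if (sum(use) < 2L) stop("need >= 2 frames at or after t_star", call. = FALSE)
  cum <- pracma::cumtrapz(input_fn$times, input_fn$values)[, 1]
  cp <- stats::approx(input_fn$times, input_fn$values, xout = tac$times[use],
                      rule = 2)$y
  icp <- stats::approx(input_fn$times, cum, xout = tac$times[use], rule = 2)$y
  if (any(cp <= 0)) stop("zero or negative plasma value at a used frame", call. = FALSE)
  x <- icp / cp
  y <- tac$values[use] / cp
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, sum(y^2))) 1 else
    max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(ki = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n_points = sum(use)),
            class = "ki_estimate")
}

#' @export
print.ki_estimate <- function(x, ...) {
  cat(sprintf("Patlak Ki = %.5f /min (intercept %.4f, r2 %.4f, %d frames)\n",
              x$ki, x$intercept, x$r2, x$n_points))
  invisible(x)
}

#' Convert a net uptake rate to CMRglu
#'
#' \eqn{CMRglu = K_i \, C_{glu} / LC} with the lumped constant accounting
#' for phosphorylation differences between glucose and FDG.
#'
#' @param ki Net FDG uptake rate, per minute (or a `ki_estimate`).
#' @param cglu Plasma glucose concentration, mmol/L.
#' @param lc Lumped constant; default 0.65.
#' @return CMRglu on the scale of `ki * cglu`.
#' @export
cmrglu_from_ki <- function(ki, cglu, lc = 0.65) {
  if (inherits(ki, "ki_estimate")) ki <- ki$ki
  if (lc <= 0) stop("lumped constant must be > 0", call. = FALSE)
  if (any(cglu < 0)) stop("plasma glucose must be >= 0", call. = FALSE)
  ki * cglu / lc
}

#' Select an image-derived input function from a dynamic volume
#'
#' Simplified spatiotemporal voxel selection: candidate voxels are those
#' whose maximum intensity over time exceeds `mip_threshold` times the
#' global maximum; a subset is then retained by greedily removing the voxel
#' whose removal most reduces the summed squared deviation between the mean
#' candidate curve (interpolated at the venous sample times) and the venous
#' samples, stopping when no removal improves the fit or when `min_voxels`
#' would be violated. This stands in for the full published selection rule,
#' whose exact constraint set is not reproduced here.
#'
#' @param dynamic_volume 4-D array (x, y, z, frame) of activity.
#' @param frame_times Frame mid-times, minutes.
#' @param venous_samples Data frame or matrix with columns `time`, `value`;
#'   at least 3 samples, inside the scan window.
#' @param mip_threshold Fraction of the global maximum in (0, 1).
#' @param min_voxels Minimum number of retained voxels. Default 3.
#' @return A [plasma_input_curve()] at the frame times (mean retained TAC),
#'   with attributes `n_candidates` and `n_retained`.
#' @export
select_idif <- function(dynamic_volume, frame_times, venous_samples,
                        mip_threshold = 0.5, min_voxels = 3L) {
  stopifnot(length(dim(dynamic_volume)) == 4L)
  if (mip_threshold <= 0 || mip_threshold >= 1) {
    stop("mip_threshold must be in (0, 1)", call. = FALSE)
  }
  venous_samples <- as.data.frame(venous_samples)
  if (nrow(venous_samples) < 3L) stop("need >= 3 venous samples", call. = FALSE)
  if (any(venous_samples$time < min(frame_times)) ||
      any(venous_samples$time > max(frame_times))) {
    stop("venous samples outside scan window", call. = FALSE)
  }
  nt <- dim(dynamic_volume)[4]
  stopifnot(nt == length(frame_times))
  vox <- matrix(dynamic_volume, ncol = nt)   # voxels x frames
  mip <- apply(vox, 1, max)
  cand <- which(mip > mip_threshold * max(mip))
  if (length(cand) == 0L) stop("no candidate voxels above threshold", call. = FALSE)
  tacs <- vox[cand, , drop = FALSE]

  sse_of <- function(rows) {
    m <- colMeans(tacs[rows, , drop = FALSE])
    at <- stats::approx(frame_times, m, xout = venous_samples$time)$y
    sum((at - venous_samples$value)^2)
  }
  retained <- seq_len(nrow(tacs))
  current <- sse_of(retained)
  while (length(retained) > min_voxels) {
    trial <- vapply(seq_along(retained),
                    function(i) sse_of(retained[-i]), numeric(1))
    best <- which.min(trial)
    if (trial[best] < current) {
      retained <- retained[-best]
      current <- trial[best]
    } else break
  }
  out <- plasma_input_curve(frame_times,
                            pmax(0, colMeans(tacs[retained, , drop = FALSE])))
  attr(out, "n_candidates") <- length(cand)
  attr(out, "n_retained") <- length(retained)
  attr(out, "residual_ss") <- current
  out
}

#' Construct a label volume
#'
#' @param array 3-D integer array of region labels (0 = background).
#' @param labels Named integer vector mapping region name -> label value.
#' @param ap_axis Which array axis (1-3) runs anterior-posterior.
#' @param anterior_high `TRUE` if larger indices along `ap_axis` are more
#'   anterior.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(array, labels, ap_axis = 2L, anterior_high = TRUE) {
  stopifnot(length(dim(array)) == 3L, all(dim(array) > 0L))
  if (is.null(names(labels)) || anyDuplicated(names(labels))) {
    stop("labels must be uniquely named", call. = FALSE)
  }
  structure(list(array = array, labels = labels,
                 ap_axis = as.integer(ap_axis),
                 anterior_high = isTRUE(anterior_high)),
            class = "label_volume")
}

#' Aggregate a parametric volume over labelled regions
#'
#' @param volume 3-D numeric array on the same grid as `labels`.
#' @param labels A [label_volume()].
#' @return Named numeric vector of per-region means; regions whose label is
#'   absent from the grid are `NA` (missing, not zero).
#' @export
aggregate_roi <- function(volume, labels) {
  stopifnot(inherits(labels, "label_volume"))
  if (!all(dim(volume) == dim(labels$array))) {
    stop("volume and label grids do not match", call. = FALSE)
  }
  out <- vapply(labels$labels, function(lb) {
    sel <- labels$array == lb
    if (!any(sel)) return(NA_real_)
    mean(volume[sel])
  }, numeric(1))
  names(out) <- names(labels$labels)
  out
}

# Exact 1-D 3-means. In one dimension the k-means optimum partitions the
# sorted values into contiguous intervals, so the global minimum of the
# within-cluster sum of squares is found by enumerating the two interval
# boundaries over the distinct values (deterministic; a Lloyd refinement
# from quantile seeds can stall in local optima when many values tie).
# Among equal-WSS partitions the first in enumeration order wins, which
# places boundary ties in the lower-value (more anterior, on the
# anteriority scale used by the caller) cluster.
kmeans3_1d_exact <- function(x) {
  ux <- sort(unique(x))
  xs <- sort(x)
  n <- length(xs)
  css <- function(v) if (length(v) < 2L) 0 else sum((v - mean(v))^2)
  best <- NULL
  for (i in 1:(length(ux) - 2L)) {
    for (j in (i + 1L):(length(ux) - 1L)) {
      g1 <- xs[xs <= ux[i]]
      g2 <- xs[xs > ux[i] & xs <= ux[j]]
      g3 <- xs[xs > ux[j]]
      wss <- css(g1) + css(g2) + css(g3)
      if (is.null(best) || wss < best$wss) {
        best <- list(wss = wss, b1 = ux[i], b2 = ux[j])
      }
    }
  }
  assign <- ifelse(x <= best$b1, 1L, ifelse(x <= best$b2, 2L, 3L))
  list(assign = assign, wss = best$wss,
       centers = vapply(1:3, function(k) mean(x[assign == k]), numeric(1)))
}

#' Subdivide a putamen label along the anterior-posterior axis
#'
#' 1-D k-means with k = 3 on the anterior-posterior voxel indices of the
#' putamen segmentation, yielding anterior, middle and posterior
#' subregions. The 1-D objective is solved exactly by enumerating interval
#' boundaries over the sorted indices (equivalent to a fully converged
#' Lloyd iteration, but deterministic and immune to local optima), with
#' boundary ties assigned to the more anterior cluster.
#'
#' @param labels A [label_volume()].
#' @param putamen_label Integer label value (or region name) to subdivide.
#' @return A new `label_volume` in which the putamen label is replaced by
#'   three labels named `<region>_anterior`, `<region>_middle`,
#'   `<region>_posterior`.
#' @export
subdivide_putamen <- function(labels, putamen_label) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.character(putamen_label)) {
    region_name <- putamen_label
    putamen_label <- labels$labels[[putamen_label]]
  } else {
    region_name <- names(labels$labels)[match(putamen_label, labels$labels)]
  }
  idx <- which(labels$array == putamen_label, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("putamen label absent from grid", call. = FALSE)
  ap <- idx[, labels$ap_axis]
  if (length(unique(ap)) < 3L) {
    stop("fewer than 3 distinct anterior-posterior indices", call. = FALSE)
  }
  # Work on an anteriority scale (smaller = more anterior) so boundary
  # ties resolve to the more anterior cluster.
  ant <- if (labels$anterior_high) -as.numeric(ap) else as.numeric(ap)
  km <- kmeans3_1d_exact(ant)
  rank_of <- seq_len(3L)   # clusters already ordered along the scale

  new_labels <- max(labels$labels) + seq_len(3L)
  names(new_labels) <- paste0(region_name, c("_anterior", "_middle", "_posterior"))
  arr <- labels$array
  for (k in seq_len(3L)) {
    sel <- idx[rank_of[km$assign] == k, , drop = FALSE]
    arr[sel] <- new_labels[k]
  }
  lab_map <- c(labels$labels[labels$labels != putamen_label], new_labels)
  label_volume(arr, lab_map, ap_axis = labels$ap_axis,
               anterior_high = labels$anterior_high)
}
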