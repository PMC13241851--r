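# Synthetic cohort generation: regional CMRglu/CBF cohorts with a planted
# age-linked spatial pattern, dynamic time-activity curves from the
# irreversible two-tissue-compartment model, and toy disease-related
# patterns. Every downstream stage of the pipeline is testable against
# these generators without access to subject scans.

#' Default structural subdivisions for a region set
#'
#' Allocates `n` regions across the eight structural subdivisions used in
#' the analysis (basal ganglia, cerebellum, frontal, parietal, occipital,
#' temporal, limbic, other), with proportions loosely matching a whole-brain
#' cortical + subcortical parcellation.
#'
#' @param n Number of regions.
#' @return Character vector of length `n` of subdivision labels.
#' @export
default_region_groups <- function(n) {
  props <- c(basal_ganglia = 10, cerebellum = 6, frontal = 20, parietal = 12,
             occipital = 10, temporal = 14, limbic = 12, other = 13)
  counts <- floor(props / sum(props) * n)
  rem <- n - sum(counts)
  counts["other"] <- counts["other"] + rem
  rep(names(counts), times = counts)
}

#' Configuration for a synthetic regional cohort
#'
#' The generative model is log-additive: for subject \eqn{i}, region
#' \eqn{r} and modality \eqn{m},
#' \deqn{\log v_{i,r,m} = g_i + b_{m,r} + e_i P_{m,r} + \epsilon_{i,r,m}}
#' with per-subject global factor \eqn{g_i \sim N(0, \sigma_g^2)}, a
#' region-specific baseline profile \eqn{b_{m,r}}, pattern expression
#' \eqn{e_i = s\,(age_i - \overline{age}) + \Delta\,[age_i > 60]} and noise
#' \eqn{\epsilon \sim N(0, \sigma^2)}. The planted unit-norm pattern enters
#' both modalities with equal sign in `"concordant"` mode (an energy
#' production effect, visible in rEP), with opposite signs in
#' `"discordant"` mode (an aerobic-glycolysis effect, visible in rAG), and
#' not at all in `"none"` mode. Linear-scale values are exponentials of the
#' log model, so per-subject global factors are multiplicative and are
#' removed exactly by per-subject z-scoring.
#'
#' Baseline profiles for the two modalities share one regional shape
#' (log-sd 0.15) around log(30) umol/100g/min for CMRglu and
#' log(45) mL/100g/min for CBF: regional glucose use and perfusion are
#' tightly spatially coupled in the healthy brain, and the shared shape
#' means discordance arises only from planted patterns and noise.
#'
#' @param n_subjects Number of subjects (>= 4). Default 24.
#' @param n_regions Number of regions (>= 3). Default 97.
#' @param age_range Two-element numeric, years; ages drawn uniformly.
#' @param baseline_cmrglu,baseline_cbf Optional per-region mean
#'   log-intensities; defaults drawn deterministically from `seed`.
#' @param planted_pattern Optional per-region weights; normalized to unit
#'   Euclidean norm. Default: unit-normalized Gaussian draw from `seed`.
#' @param pattern_mode `"concordant"`, `"discordant"` or `"none"`.
#' @param age_slope Expression units per year of age. Default 0.25.
#' @param group_effect Additional expression offset for subjects older than
#'   60 years. Default 0.
#' @param noise_sd Log-scale additive noise SD. Default 0.3.
#' @param global_scale_sd Log-scale SD of the per-subject global factor.
#' @param sex Optional 0/1 vector; default alternates (balanced).
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 24L, n_regions = 97L,
                          age_range = c(35, 80),
                          baseline_cmrglu = NULL, baseline_cbf = NULL,
                          planted_pattern = NULL,
                          pattern_mode = c("concordant", "discordant", "none"),
                          age_slope = 0.25, group_effect = 0,
                          noise_sd = 0.3, global_scale_sd = 0.1,
                          sex = NULL, seed = 1L) {
  pattern_mode <- match.arg(pattern_mode)
  if (n_subjects < 4L) stop("n_subjects must be >= 4", call. = FALSE)
  if (n_regions < 3L) stop("n_regions must be >= 3", call. = FALSE)
  assert_finite(age_range, "age_range")
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop("age_range must be (min, max) with min < max", call. = FALSE)
  }
  assert_finite(c(age_slope, group_effect, noise_sd, global_scale_sd),
                "config values")
  if (noise_sd < 0 || global_scale_sd < 0) {
    stop("noise_sd and global_scale_sd must be >= 0", call. = FALSE)
  }

  if (is.null(baseline_cmrglu) || is.null(baseline_cbf)) {
    shape <- withr::with_seed(derive_seed(seed, "cohort") + 1L,
                              stats::rnorm(n_regions, 0, 0.15))
    if (is.null(baseline_cmrglu)) baseline_cmrglu <- log(30) + shape
    if (is.null(baseline_cbf)) baseline_cbf <- log(45) + shape
  }
  if (length(baseline_cmrglu) != n_regions || length(baseline_cbf) != n_regions) {
    stop("baseline profiles must have length n_regions", call. = FALSE)
  }
  assert_finite(baseline_cmrglu, "baseline_cmrglu")
  assert_finite(baseline_cbf, "baseline_cbf")

  if (pattern_mode != "none") {
    if (is.null(planted_pattern)) {
      planted_pattern <- withr::with_seed(derive_seed(seed, "cohort") + 2L,
                                          stats::rnorm(n_regions))
    }
    if (length(planted_pattern) != n_regions) {
      stop("planted_pattern must have length n_regions", call. = FALSE)
    }
    planted_pattern <- unit_norm(planted_pattern)
  } else {
    planted_pattern <- rep(0, n_regions)
  }

  if (!is.null(sex)) {
    if (length(sex) != n_subjects || !all(sex %in% c(0, 1))) {
      stop("sex must be a 0/1 vector of length n_subjects", call. = FALSE)
    }
  } else {
    sex <- rep_len(c(0L, 1L), n_subjects)
  }

  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 age_range = as.numeric(age_range),
                 baseline_cmrglu = baseline_cmrglu,
                 baseline_cbf = baseline_cbf,
                 planted_pattern = planted_pattern,
                 pattern_mode = pattern_mode,
                 age_slope = age_slope, group_effect = group_effect,
                 noise_sd = noise_sd, global_scale_sd = global_scale_sd,
                 sex = as.integer(sex), seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic regional CMRglu/CBF cohort
#'
#' Draws, in this fixed stream order: subject ages (uniform over
#' `age_range`), per-subject global factors, CMRglu noise, CBF noise. The
#' result is deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `regional_dataset`: list with positive matrices `cmrglu` and
#'   `cbf` (subjects x regions), `ages`, `sex`, `region_names`,
#'   `region_groups`, `subject_ids`, and generative provenance
#'   (`planted_pattern`, `pattern_mode`, `expression`).
#' @export
generate_regional_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects; p <- config$n_regions
  draws <- withr::with_seed(derive_seed(config$seed, "cohort"), {
    ages <- stats::runif(n, config$age_range[1], config$age_range[2])
    global <- stats::rnorm(n, 0, config$global_scale_sd)
    noise_glu <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    noise_cbf <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    list(ages = ages, global = global, noise_glu = noise_glu,
         noise_cbf = noise_cbf)
  })
  ages <- draws$ages
  expr <- config$age_slope * (ages - mean(ages)) +
    config$group_effect * (ages > 60)

  p_glu <- switch(config$pattern_mode,
                  concordant = config$planted_pattern,
                  discordant = config$planted_pattern,
                  none = rep(0, p))
  p_cbf <- switch(config$pattern_mode,
                  concordant = config$planted_pattern,
                  discordant = -config$planted_pattern,
                  none = rep(0, p))

  log_glu <- outer(draws$global, rep(1, p)) +
    outer(rep(1, n), config$baseline_cmrglu) +
    outer(expr, p_glu) + draws$noise_glu
  log_cbf <- outer(draws$global, rep(1, p)) +
    outer(rep(1, n), config$baseline_cbf) +
    outer(expr, p_cbf) + draws$noise_cbf

  region_names <- sprintf("R%03d", seq_len(p))
  regional_dataset(cmrglu = exp(log_glu), cbf = exp(log_cbf), ages = ages,
                   sex = config$sex, region_names = region_names,
                   region_groups = default_region_groups(p),
                   subject_ids = sprintf("S%02d", seq_len(n)),
                   planted_pattern = config$planted_pattern,
                   pattern_mode = config$pattern_mode, expression = expr)
}

#' Construct and validate a regional dataset
#'
#' @param cmrglu,cbf Positive subjects x regions matrices (same dims).
#' @param ages Numeric vector of subject ages (years).
#' @param sex 0/1 vector per subject.
#' @param region_names Unique region labels.
#' @param region_groups Structural subdivision per region.
#' @param subject_ids Subject identifiers.
#' @param planted_pattern,pattern_mode,expression Optional generative
#'   provenance (kept for recovery analyses on synthetic cohorts).
#' @return Object of class `regional_dataset`.
#' @export
regional_dataset <- function(cmrglu, cbf, ages, sex, region_names,
                             region_groups = NULL, subject_ids = NULL,
                             planted_pattern = NULL, pattern_mode = NULL,
                             expression = NULL) {
  cmrglu <- as.matrix(cmrglu); cbf <- as.matrix(cbf)
  if (!all(dim(cmrglu) == dim(cbf))) {
    stop("cmrglu and cbf must share dimensions", call. = FALSE)
  }
  if (anyNA(cmrglu) || anyNA(cbf) || any(!is.finite(cmrglu)) ||
      any(!is.finite(cbf)) || any(cmrglu <= 0) || any(cbf <= 0)) {
    stop("regional matrices must contain only finite positive values",
         call. = FALSE)
  }
  if (length(ages) != nrow(cmrglu)) stop("ages length mismatch", call. = FALSE)
  if (anyDuplicated(region_names)) stop("duplicate region names", call. = FALSE)
  if (length(region_names) != ncol(cmrglu)) {
    stop("region_names length mismatch", call. = FALSE)
  }
  if (is.null(region_groups)) region_groups <- rep("other", ncol(cmrglu))
  if (is.null(subject_ids)) subject_ids <- sprintf("S%02d", seq_len(nrow(cmrglu)))
  dimnames(cmrglu) <- dimnames(cbf) <- list(subject_ids, region_names)
  structure(list(cmrglu = cmrglu, cbf = cbf, ages = as.numeric(ages),
                 sex = as.integer(sex), region_names = region_names,
                 region_groups = region_groups, subject_ids = subject_ids,
                 planted_pattern = planted_pattern,
                 pattern_mode = pattern_mode, expression = expression),
            class = "regional_dataset")
}

#' @export
print.regional_dataset <- function(x, ...) {
  cat(sprintf("regional_dataset: %d subjects x %d regions\n",
              nrow(x$cmrglu), ncol(x$cmrglu)))
  cat(sprintf("  ages %.1f-%.1f (mean %.1f); pattern_mode: %s\n",
              min(x$ages), max(x$ages), mean(x$ages),
              if (is.null(x$pattern_mode)) "unknown" else x$pattern_mode))
  invisible(x)
}

#' Default gamma-variate plasma input model
#'
#' A bolus peaking near 1 minute with a slow recirculation washout:
#' \eqn{C_p(t) = A[(t/t_p)^\alpha e^{\alpha(1 - t/t_p)} +
#' w (1 - e^{-t/2}) e^{-t/60}]}.
#'
#' @param t Time, minutes.
#' @param A Peak amplitude, kBq/mL.
#' @param alpha Gamma-variate shape. Default 3.
#' @param t_peak Peak time, minutes. Default 1.
#' @param tail Recirculation fraction of peak. Default 0.2.
#' @return Plasma activity at `t`.
#' @export
gamma_variate_input <- function(t, A = 100, alpha = 3, t_peak = 1, tail = 0.2) {
  bolus <- ifelse(t <= 0, 0, (t / t_peak)^alpha * exp(alpha * (1 - t / t_peak)))
  recirc <- ifelse(t <= 0, 0, tail * (1 - exp(-t / 2)) * exp(-t / 60))
  A * (bolus + recirc)
}

#' Simulate time-activity curves from the irreversible 2TC model
#'
#' Integrates \eqn{dC_1/dt = K_1 C_p - (k_2 + k_3) C_1},
#' \eqn{dC_2/dt = k_3 C_1} numerically (`deSolve::ode`, lsoda) and samples
#' the total tissue activity \eqn{C_1 + C_2} at the frame mid-times. The
#' asymptotic net uptake rate is \eqn{K_i = K_1 k_3 / (k_2 + k_3)}.
#'
#' @param kinetics Named numeric `c(K1=, k2=, k3=)` (per minute), or a list
#'   of such vectors for several tissue curves.
#' @param frame_times Strictly increasing frame mid-times, minutes.
#' @param input_fn Plasma input function of time; default
#'   [gamma_variate_input()].
#' @param noise_sd SD of additive Gaussian noise on the tissue curves.
#' @param input_dt Sampling interval (minutes) of the returned plasma grid.
#' @param seed Seed for the optional noise.
#' @return List with `tacs` (list of `time_activity_curve`) and `input`
#'   (a `plasma_input_curve` on a fine grid from 0 to the last frame).
#' @export
generate_tacs <- function(kinetics, frame_times,
                          input_fn = gamma_variate_input,
                          noise_sd = 0, input_dt = 0.05, seed = 1L) {
  if (length(frame_times) == 0L) stop("empty frame schedule", call. = FALSE)
  assert_finite(frame_times, "frame_times")
  if (any(diff(frame_times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (!is.list(kinetics)) kinetics <- list(kinetics)
  for (k in kinetics) {
    assert_finite(k, "rate constants")
    if (length(k) != 3L || any(k < 0)) {
      stop("kinetics must be non-negative (K1, k2, k3)", call. = FALSE)
    }
  }
  grid <- seq(0, max(frame_times), by = input_dt)
  if (max(grid) < max(frame_times)) grid <- c(grid, max(frame_times))
  cp <- input_fn(grid)

  simulate_one <- function(k) {
    K1 <- k[[1]]; k2 <- k[[2]]; k3 <- k[[3]]
    deriv <- function(t, y, parms) {
      cpt <- input_fn(t)
      list(c(K1 * cpt - (k2 + k3) * y[1], k3 * y[1]))
    }
    times <- sort(unique(c(0, frame_times)))
    sol <- deSolve::ode(y = c(C1 = 0, C2 = 0), times = times, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-9, atol = 1e-9)
    tissue <- sol[match(frame_times, sol[, "time"]), "C1"] +
      sol[match(frame_times, sol[, "time"]), "C2"]
    unname(tissue)
  }
  tissues <- lapply(kinetics, simulate_one)
  if (noise_sd > 0) {
    tissues <- withr::with_seed(derive_seed(seed, "tac"), {
      lapply(tissues, function(v) v + stats::rnorm(length(v), 0, noise_sd))
    })
  }
  tacs <- lapply(tissues, function(v) time_activity_curve(frame_times, v))
  list(tacs = tacs, input = plasma_input_curve(grid, cp))
}

#' Generate a toy disease-related metabolic pattern
#'
#' Returns unit-norm region weights (rDRP) paired with a compatible group
#' mean profile (rGMP) on the log scale, standing in for externally derived
#' disease patterns. A requested Spearman-scale overlap with a reference
#' pattern is achieved by Gram-Schmidt mixing:
#' \eqn{w = \rho u + \sqrt{1-\rho^2} z_\perp} with `u` the unit reference
#' and `z_perp` a unit residual of a fresh Gaussian draw.
#'
#' @param region_names Region labels the pattern is defined on.
#' @param seed Integer seed.
#' @param overlap_with Optional reference weight vector.
#' @param overlap_rho Target correlation with `overlap_with` in `[-1, 1]`.
#' @param gmp Optional group mean profile (log scale); defaults to a
#'   baseline-like draw around log(30).
#' @param label Pattern label, e.g. `"PDRP"`.
#' @return Object of class `disease_pattern` with fields `region_names`,
#'   `rdrp`, `rgmp`, `label`.
#' @export
generate_disease_pattern <- function(region_names, seed = 1L,
                                     overlap_with = NULL, overlap_rho = 0.5,
                                     gmp = NULL, label = "synthetic-DRP") {
  p <- length(region_names)
  if (p < 3L) stop("need at least 3 regions", call. = FALSE)
  draws <- withr::with_seed(derive_seed(seed, "disease"), {
    list(w = stats::rnorm(p), g = stats::rnorm(p, log(30), 0.15))
  })
  w <- draws$w
  if (!is.null(overlap_with)) {
    if (length(overlap_with) != p) {
      stop("reference pattern length must match region count", call. = FALSE)
    }
    if (abs(overlap_rho) > 1) stop("overlap_rho must be in [-1, 1]", call. = FALSE)
    u <- unit_norm(overlap_with)
    z <- w - sum(w * u) * u
    w <- overlap_rho * u + sqrt(1 - overlap_rho^2) * unit_norm(z)
  }
  w <- unit_norm(w)
  if (is.null(gmp)) gmp <- draws$g
  if (length(gmp) != p) stop("gmp length must match region count", call. = FALSE)
  disease_pattern(region_names, w, gmp, label)
}

#' Construct and validate a disease pattern
#'
#' @param region_names Region labels.
#' @param rdrp Per-region pattern weights.
#' @param rgmp Per-region group mean profile (log scale).
#' @param label Pattern label.
#' @return Object of class `disease_pattern`.
#' @export
disease_pattern <- function(region_names, rdrp, rgmp, label = "DRP") {
  if (length(rdrp) != length(region_names) ||
      length(rgmp) != length(region_names)) {
    stop("rdrp and rgmp must align with region_names", call. = FALSE)
  }
  assert_finite(rdrp, "rdrp"); assert_finite(rgmp, "rgmp")
  if (all(rdrp == 0)) stop("pattern weights are all zero", call. = FALSE)
  structure(list(region_names = region_names, rdrp = as.numeric(rdrp),
                 rgmp = as.numeric(rgmp), label = label),
            class = "disease_pattern")
}
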