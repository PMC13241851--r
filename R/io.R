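# Standard-format I/O: tab-separated regional tables (subjects in rows,
# regions in columns, first column the subject id), time-activity / plasma
# curves as CSV (time_min,value), pattern and disease-pattern files as
# JSON, and NIfTI volumes for parametric/label images.

#' Write a regional dataset to a directory
#'
#' Emits `cmrglu.tsv` and `cbf.tsv` (subjects x regions), `subjects.tsv`
#' (id, age, sex) and `regions.tsv` (name, group). UTF-8, tab-separated,
#' header row of region names.
#'
#' @param ds A [regional_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_regional_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "regional_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cmrglu.tsv", "cbf.tsv", "subjects.tsv",
                            "regions.tsv"))
  write_matrix_tsv(ds$cmrglu, paths[1])
  write_matrix_tsv(ds$cbf, paths[2])
  utils::write.table(data.frame(id = ds$subject_ids,
                                age = sprintf("%.17g", ds$ages),
                                sex = ds$sex),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(data.frame(name = ds$region_names,
                                group = ds$region_groups),
                     paths[4], sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(paths)
}

# Doubles are serialized with 17 significant digits so write -> read is an
# exact round trip (required for byte-identical resumption of cached
# stages).
write_matrix_tsv <- function(m, path) {
  fm <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  df <- data.frame(subject = rownames(m), fm, check.names = FALSE)
  colnames(df) <- c("subject", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_regional_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, encoding = "UTF-8")
  regions <- colnames(df)[-1]
  if (anyDuplicated(regions)) {
    stop(sprintf("duplicate region columns in %s", path), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a regional dataset written by [write_regional_dataset()]
#'
#' @param dir Directory holding the four TSV files.
#' @return A [regional_dataset()].
#' @export
read_regional_dataset <- function(dir) {
  cmrglu <- read_regional_matrix(file.path(dir, "cmrglu.tsv"))
  cbf <- read_regional_matrix(file.path(dir, "cbf.tsv"))
  subj <- utils::read.delim(file.path(dir, "subjects.tsv"), encoding = "UTF-8")
  regs <- utils::read.delim(file.path(dir, "regions.tsv"), encoding = "UTF-8")
  if (!identical(colnames(cmrglu), colnames(cbf)) ||
      !identical(colnames(cmrglu), as.character(regs$name))) {
    stop("region-name mismatch between files", call. = FALSE)
  }
  regional_dataset(cmrglu, cbf, ages = subj$age, sex = subj$sex,
                   region_names = colnames(cmrglu),
                   region_groups = as.character(regs$group),
                   subject_ids = as.character(subj$id))
}

#' Write / read a sampled curve as CSV
#'
#' Two columns `time_min,value`; used for both time-activity and plasma
#' input curves.
#'
#' @param curve A `time_activity_curve` or `plasma_input_curve`.
#' @param path CSV path.
#' @return `write_curve_csv`: invisibly, `path`.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_min = curve$times, value = curve$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param type `"tac"` or `"plasma"`.
#' @return `read_curve_csv`: the curve object.
#' @export
read_curve_csv <- function(path, type = c("tac", "plasma")) {
  type <- match.arg(type)
  df <- utils::read.csv(path)
  if (!all(c("time_min", "value") %in% colnames(df))) {
    stop("malformed curve CSV header", call. = FALSE)
  }
  if (type == "tac") time_activity_curve(df$time_min, df$value)
  else plasma_input_curve(df$time_min, df$value)
}

#' Write / read a covariance pattern as JSON
#'
#' Stores metric, region names, weights and their cross-validation SDs,
#' subject scores, summary statistics and configuration (including the
#' seed) so a pattern file is self-describing and reproducible.
#'
#' @param pattern A [crossvalidate_pattern()] result.
#' @param path JSON path.
#' @param subject_ids Optional subject identifiers stored alongside scores.
#' @return `write_pattern_json`: invisibly, `path`.
#' @export
write_pattern_json <- function(pattern, path, subject_ids = NULL) {
  stopifnot(inherits(pattern, "covariance_pattern"))
  obj <- list(metric = pattern$config$metric,
              region_names = pattern$region_names,
              weights = unname(pattern$weights),
              weight_sd = unname(pattern$weight_sd),
              scores = pattern$scores,
              subject_ids = subject_ids,
              stats = list(separation = pattern$separation,
                           age_fit = pattern$age_fit,
                           n_patterns = pattern$n_patterns),
              config = pattern$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pattern_json
#' @return `read_pattern_json`: a list mirroring the stored fields (not a
#'   full `covariance_pattern`; weights/scores/stats are restored as
#'   written).
#' @export
read_pattern_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a disease pattern as JSON
#'
#' Schema: `{region_names, weights, gmp, label}`.
#'
#' @param dp A [disease_pattern()].
#' @param path JSON path.
#' @return `write_disease_pattern_json`: invisibly, `path`.
#' @export
write_disease_pattern_json <- function(dp, path) {
  stopifnot(inherits(dp, "disease_pattern"))
  jsonlite::write_json(list(region_names = dp$region_names,
                            weights = dp$rdrp, gmp = dp$rgmp,
                            label = dp$label),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_disease_pattern_json
#' @return `read_disease_pattern_json`: a [disease_pattern()].
#' @export
read_disease_pattern_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  disease_pattern(obj$region_names, obj$weights, obj$gmp, obj$label)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti for parametric and label volumes. Label
#' volumes additionally need the label map and the declared
#' anterior-posterior axis, which NIfTI headers do not carry reliably;
#' these are supplied explicitly.
#'
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @return `read_volume`: a numeric array with NIfTI attributes.
#' @export
read_volume <- function(path) {
  RNifti::readNifti(path)
}

#' @rdname read_volume
#' @param volume Numeric array.
#' @return `write_volume`: invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  RNifti::writeNifti(volume, path)
  invisible(path)
}

#' Write the energetics table
#'
#' Four TSV matrices (`z_cmrglu.tsv`, `z_cbf.tsv`, `rep.tsv`, `rag.tsv`)
#' plus a JSON sidecar recording provenance.
#'
#' @param table An [build_energetics_table()] result.
#' @param dir Output directory.
#' @param sidecar Named list merged into the sidecar JSON (e.g. cutoff,
#'   seed).
#' @return Invisibly, the paths written.
#' @export
write_energetics_table <- function(table, dir, sidecar = list()) {
  stopifnot(inherits(table, "energetics_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (q in c("z_cmrglu", "z_cbf", "rep", "rag")) {
    p <- file.path(dir, paste0(q, ".tsv"))
    write_matrix_tsv(table[[q]], p)
    paths <- c(paths, p)
  }
  sc <- file.path(dir, "energetics.json")
  jsonlite::write_json(c(list(quantities = c("z_cmrglu", "z_cbf", "rep", "rag"),
                              n_subjects = length(table$subject_ids),
                              n_regions = length(table$region_names)),
                         sidecar),
                       sc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, sc))
}
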