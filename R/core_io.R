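#' Construct a VOCExperiment from a samples-by-compounds matrix
#'
#' @param values numeric matrix, samples in rows, compounds in columns.
#'   `NA` entries mark missing (below-detection) measurements.
#' @param sample_data data.frame of per-sample metadata with at least
#'   `sample_id`; `patient_id`, `group`, `role`, `duplicate_index`,
#'   `water_content`, blood markers and `severity_score` are filled with
#'   defaults (`role = "biological"`, `duplicate_index = 1`) when absent.
#' @param compounds compound names; defaults to `colnames(values)`.
#' @return a [VOCExperiment-class].
#' @export
VOCExperiment <- function(values, sample_data, compounds = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(compounds)) stop("compound names are required")
  compounds <- normalizeCompoundNames(compounds)
  if (ncol(values) != length(compounds))
    stop("column count does not match compound list")
  sample_data <- as.data.frame(sample_data, stringsAsFactors = FALSE)
  if (is.null(sample_data$sample_id))
    stop("sample metadata must contain 'sample_id'")
  if (nrow(values) != nrow(sample_data))
    stop("row count (", nrow(values), ") does not match metadata (",
         nrow(sample_data), " samples)")
  sample_data$sample_id <- as.character(sample_data$sample_id)
  sample_data$patient_id <-
    as.character(sample_data$patient_id %||% sample_data$sample_id)
  sample_data$role <- as.character(sample_data$role %||% "biological")
  if (is.null(sample_data$group)) sample_data$group <- NA_character_
  sample_data$group <- as.character(sample_data$group)
  sample_data$duplicate_index <-
    as.integer(sample_data$duplicate_index %||% 1L)
  for (col in c("water_content", .BLOOD, "severity_score"))
    if (is.null(sample_data[[col]])) sample_data[[col]] <- NA_real_
  assay <- t(values)
  dimnames(assay) <- list(compounds, sample_data$sample_id)
  se <- SummarizedExperiment(
    assays = list(intensity = assay),
    colData = S4Vectors::DataFrame(sample_data, row.names = sample_data$sample_id))
  new("VOCExperiment", se)
}

#' Normalise compound names for join-safe matching
#'
#' Lower-cases names and collapses repeated whitespace; punctuation is
#' preserved so that distinct printed names stay distinct.
#'
#' @param x character vector of compound names.
#' @export
normalizeCompoundNames <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Packaged VOC panels
#'
#' The targeted fecal-headspace panel (62 compounds, stored verbatim from the
#' printed table, including near-synonymous entries) and the curated exhaled
#' breath panel (20 discriminatory compounds).
#'
#' @param platform `"fecal"` or `"breath"`.
#' @return a [VOCPanel-class].
#' @export
packagedPanel <- function(platform = c("fecal", "breath")) {
  platform <- match.arg(platform)
  path <- system.file("extdata", paste0("panel_", platform, ".txt"),
                      package = "vocfusion", mustWork = TRUE)
  new("VOCPanel", name = platform,
      compounds = normalizeCompoundNames(readLines(path)))
}

#' Cohort design of the PSC/IBD VOC study
#'
#' Group sizes, duplicate-expanded fecal sample counts and group mean fecal
#' water contents for the fecal platform, and group sizes for the breath
#' platform (the larger breath cohort of which the fecal participants are a
#' subset).
#'
#' @return a list with data.frames `fecal` (`group`, `n_patients`,
#'   `n_samples`, `water_mean`) and `breath` (`group`, `n_patients`).
#' @export
packagedCohortDesign <- function() {
  structure(list(
    fecal = data.frame(
      group = .GROUPS,
      n_patients = c(8L, 16L, 49L),
      n_samples = c(16L, 31L, 93L),
      water_mean = c(74.02, 80.33, 73.79)),
    breath = data.frame(
      group = .GROUPS,
      n_patients = c(16L, 47L, 53L))),
    class = "voc_cohort_design")
}

#' @export
print.voc_cohort_design <- function(x, ...) {
  cat("Cohort design\n  fecal platform (n unique patients, d samples incl. duplicates):\n")
  print(x$fecal, row.names = FALSE)
  cat("  breath platform:\n")
  print(x$breath, row.names = FALSE)
  invisible(x)
}

#' Merge PSC and PSC/IBD into one positive class
#'
#' @param x a [VOCExperiment-class] or a data.frame of sample metadata
#'   (`sample_id`, `patient_id`, `group`, `role`). Only biological samples
#'   are labelled; blanks and QC samples are excluded.
#' @return a [BinaryLabeling-class].
#' @export
mergePscGroups <- function(x) {
  sd <- if (is(x, "VOCExperiment")) sampleData(x) else as.data.frame(x)
  if (nrow(sd) && !is.null(sd$role)) sd <- sd[sd$role == "biological", , drop = FALSE]
  if (nrow(sd) == 0L)
    return(new("BinaryLabeling",
               labels = factor(character(), levels = c("IBD", "PSC")),
               sampleIds = character(), patientIds = character(),
               positivePatients = 0L, negativePatients = 0L))
  if (anyNA(sd$group) || !all(sd$group %in% .GROUPS))
    stop("unlabeled biological sample(s): ",
         paste(sd$sample_id[is.na(sd$group) | !sd$group %in% .GROUPS],
               collapse = ", "))
  lab <- factor(ifelse(sd$group == "IBD", "IBD", "PSC"),
                levels = c("IBD", "PSC"))
  per_pat <- !duplicated(sd$patient_id)
  new("BinaryLabeling", labels = lab,
      sampleIds = as.character(sd$sample_id),
      patientIds = as.character(sd$patient_id),
      positivePatients = sum(lab[per_pat] == "PSC"),
      negativePatients = sum(lab[per_pat] == "IBD"))
}

#' Read a feature table and its sample metadata from delimited text
#'
#' The table is CSV with a `sample_id` column followed by one column per
#' compound; empty cells are read as missing (`NA`), never as zero. Metadata
#' is CSV keyed by `sample_id`.
#'
#' @param path path to the intensity CSV.
#' @param meta_path path to the sample metadata CSV.
#' @return a validated [VOCExperiment-class] preserving the missingness
#'   pattern.
#' @export
readFeatureTable <- function(path, meta_path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(tab))
    stop("feature table must contain a 'sample_id' column")
  meta <- utils::read.csv(meta_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(tab$sample_id)
  missing_meta <- setdiff(ids, as.character(meta$sample_id))
  if (length(missing_meta))
    stop("metadata is missing sample_id(s): ",
         paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(as.character(meta$sample_id), ids)
  if (length(extra_meta))
    stop("metadata lists unknown sample_id(s): ",
         paste(extra_meta, collapse = ", "))
  values <- as.matrix(tab[, setdiff(colnames(tab), "sample_id"),
                          drop = FALSE])
  storage.mode(values) <- "double"
  if (any(values < 0, na.rm = TRUE))
    stop("negative intensities found in ", path)
  rownames(values) <- ids
  meta <- meta[match(ids, as.character(meta$sample_id)), , drop = FALSE]
  VOCExperiment(values, meta)
}

#' Write a feature table and its sample metadata to delimited text
#'
#' Missing entries are written as empty cells so that a read/write round trip
#' preserves the missingness pattern exactly.
#'
#' @param x a [VOCExperiment-class].
#' @param path,meta_path output CSV paths.
#' @export
writeFeatureTable <- function(x, path, meta_path) {
  m <- intensities(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  sd <- sampleData(x)
  utils::write.csv(sd, meta_path, row.names = FALSE, na = "")
  invisible(c(path, meta_path))
}

#' Restrict a VOCExperiment to samples in given roles
#'
#' @param x a [VOCExperiment-class].
#' @param roles roles to keep (default biological samples only).
#' @export
subsetByRole <- function(x, roles = "biological") {
  keep <- sampleData(x)$role %in% roles
  x[, keep]
}

#' Restrict a VOCExperiment to a set of compounds
#'
#' @param x a [VOCExperiment-class].
#' @param features compound names to keep.
#' @export
subsetFeatures <- function(x, features) {
  features <- normalizeCompoundNames(features)
  miss <- setdiff(features, rownames(x))
  if (length(miss)) stop("unknown compound(s): ", paste(miss, collapse = ", "))
  x[features, ]
}
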