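#' Intensity tables
#'
#' A protein intensity table is a wide tibble with one row per protein group
#' and one column per sample, plus the identifier columns `protein_id`
#' (lead accession, unique, the primary match key) and `gene_name` (fallback
#' match key, may be empty). The attribute `"scale"` records whether values
#' are raw linear intensities (`"linear"`) or `log10`-transformed
#' (`"log10"`); scale transitions happen only through [log10_transform()].
#' Missing quantifications are `NA`; on the linear scale all present values
#' are strictly positive.
#'
#' @param proteins Tibble or data frame with columns `protein_id` and
#'   optionally `gene_name`.
#' @param values Numeric matrix, proteins x samples, with `NA` for missing
#'   quantifications; column names are sample identifiers.
#' @param scale `"linear"` or `"log10"`.
#' @return A tibble of class `intensity_tbl`.
#' @export
intensity_tbl <- function(proteins, values, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  proteins <- tibble::as_tibble(proteins)
  if (!"protein_id" %in% names(proteins)) {
    stop("`proteins` must have a `protein_id` column", call. = FALSE)
  }
  if (!"gene_name" %in% names(proteins)) proteins$gene_name <- ""
  ids <- proteins$protein_id
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("protein_id must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  values <- as.matrix(values)
  if (nrow(values) != nrow(proteins)) {
    stop("`values` must have one row per protein", call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("`values` needs unique sample column names", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    stop("linear-scale intensities must be >= 0 (use NA for missing)",
         call. = FALSE)
  }
  out <- dplyr::bind_cols(
    proteins[c("protein_id", "gene_name")],
    tibble::as_tibble(values)
  )
  new_intensity_tbl(out, scale)
}

new_intensity_tbl <- function(x, scale) {
  x <- tibble::as_tibble(x)
  attr(x, "scale") <- scale
  class(x) <- unique(c("intensity_tbl", class(x)))
  x
}

#' @export
print.intensity_tbl <- function(x, ...) {
  cat("# Intensity table:", nrow(x), "proteins x", length(sample_ids(x)),
      "samples, scale =", intensity_scale(x), "\n")
  NextMethod()
}

#' Accessors for intensity tables
#'
#' `sample_ids()` returns the sample columns in order; `intensity_values()`
#' the proteins x samples numeric matrix (rownames = `protein_id`);
#' `intensity_scale()` the declared scale.
#'
#' @param x An `intensity_tbl`.
#' @return Character vector, numeric matrix, or scale string respectively.
#' @export
sample_ids <- function(x) {
  setdiff(names(x), c("protein_id", "gene_name"))
}

#' @rdname sample_ids
#' @export
intensity_values <- function(x) {
  m <- as.matrix(x[sample_ids(x)])
  rownames(m) <- x$protein_id
  storage.mode(m) <- "double"
  m
}

#' @rdname sample_ids
#' @export
intensity_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) "linear" else sc
}

# Rebuild an intensity_tbl keeping identifiers, replacing the value block.
set_intensity_values <- function(x, values, scale = intensity_scale(x)) {
  out <- dplyr::bind_cols(
    tibble::as_tibble(x)[c("protein_id", "gene_name")],
    tibble::as_tibble(values)
  )
  new_intensity_tbl(out, scale)
}

#' Bundle an intensity table with its sample metadata
#'
#' Checks the two against each other: every sample column must have exactly
#' one metadata record and the cohorts partition the samples.
#'
#' @param matrix An [intensity_tbl()].
#' @param meta Sample metadata tibble (see [read_sample_metadata()]).
#' @return A list of class `study_bundle` with elements `matrix` and `meta`.
#' @export
study_bundle <- function(matrix, meta) {
  ids <- sample_ids(matrix)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  if (!setequal(ids, meta$sample_id)) {
    stop("matrix samples and metadata sample_id do not match", call. = FALSE)
  }
  meta <- meta[match(ids, meta$sample_id), ]
  structure(list(matrix = matrix, meta = meta), class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("# Study bundle:", nrow(x$matrix), "proteins,", nrow(x$meta),
      "samples,", length(unique(x$meta$cohort)), "cohort(s)\n")
  invisible(x)
}

#' Split a bundle by cohort
#'
#' @param bundle A [study_bundle()].
#' @return Named list of `study_bundle`, one per cohort, in order of first
#'   appearance.
#' @export
split_cohorts <- function(bundle) {
  cohorts <- unique(bundle$meta$cohort)
  out <- lapply(cohorts, function(co) {
    keep <- bundle$meta$sample_id[bundle$meta$cohort == co]
    m <- bundle$matrix[c("protein_id", "gene_name", keep)]
    study_bundle(new_intensity_tbl(m, intensity_scale(bundle$matrix)),
                 bundle$meta[bundle$meta$cohort == co, ])
  })
  stats::setNames(out, cohorts)
}
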