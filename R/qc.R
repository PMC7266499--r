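#' Drop sparsely observed proteins
#'
#' Keeps proteins quantified in at least `min_obs` samples across the whole
#' table (row order preserved). With the study defaults this is the >= 20
#' observation filter applied before any statistics.
#'
#' @param x An [intensity_tbl()].
#' @param min_obs Minimum number of present values per protein.
#' @return A filtered `intensity_tbl`.
#' @export
filter_min_observations <- function(x, min_obs = 20) {
  stopifnot(min_obs >= 1)
  n_obs <- rowSums(!is.na(intensity_values(x)))
  keep <- n_obs >= min_obs
  if (!any(keep)) warning("no protein passes the observation filter", call. = FALSE)
  new_intensity_tbl(x[keep, ], intensity_scale(x))
}

#' Log10-transform an intensity table
#'
#' @param x An [intensity_tbl()] on the linear scale; all present values
#'   must be positive. Missing values stay missing.
#' @return An `intensity_tbl` with scale `"log10"`.
#' @export
log10_transform <- function(x) {
  if (intensity_scale(x) != "linear") {
    stop("matrix is already on the log10 scale", call. = FALSE)
  }
  vals <- intensity_values(x)
  if (any(vals <= 0, na.rm = TRUE)) {
    stop("nonpositive intensities cannot be log10-transformed", call. = FALSE)
  }
  set_intensity_values(x, log10(vals), scale = "log10")
}

#' Data completeness curve
#'
#' For each minimum sample count k, the number of proteins quantified in at
#' least k samples. The curve is non-increasing in k; its value at k = 1 is
#' the number of proteins with any observation.
#'
#' @param x An [intensity_tbl()].
#' @return A tibble with columns `min_samples` and `n_proteins`.
#' @export
completeness_curve <- function(x) {
  n_samp <- length(sample_ids(x))
  if (nrow(x) == 0 || n_samp == 0) {
    return(tibble::tibble(min_samples = integer(), n_proteins = integer()))
  }
  n_obs <- rowSums(!is.na(intensity_values(x)))
  tibble::tibble(
    min_samples = seq_len(n_samp),
    n_proteins = vapply(seq_len(n_samp), function(k) sum(n_obs >= k), 0L)
  )
}

#' Z-score proteins within a sample stratum
#'
#' Per protein, `(x - mean) / sd` over present values, computed either
#' within each cohort or across all samples. The sample (n-1) standard
#' deviation is used. Proteins with fewer than two present values in a
#' stratum -- or zero variance -- get missing Z-scores there rather than a
#' fake 0, so downstream clustering and classifiers never see manufactured
#' certainty.
#'
#' @param bundle A [study_bundle()] with a log10-scale matrix.
#' @param stratum `"within_cohort"` or `"global"`.
#' @return An `intensity_tbl` of Z-scores (attribute `scale` = `"zscore"`).
#' @export
zscore_proteins <- function(bundle, stratum = c("within_cohort", "global")) {
  stratum <- match.arg(stratum)
  if (intensity_scale(bundle$matrix) != "log10") {
    stop("Z-scoring expects a log10-scale matrix", call. = FALSE)
  }
  vals <- intensity_values(bundle$matrix)
  groups <- if (stratum == "global") rep("all", ncol(vals)) else bundle$meta$cohort
  for (g in unique(groups)) {
    cols <- which(groups == g)
    sub <- vals[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    n <- rowSums(!is.na(sub))
    ss <- rowSums(sub^2, na.rm = TRUE) - n * mu^2
    s <- sqrt(pmax(ss, 0) / pmax(n - 1, 1))
    s[n < 2 | s == 0] <- NA_real_
    vals[, cols] <- (sub - mu) / s
  }
  out <- set_intensity_values(bundle$matrix, vals)
  attr(out, "scale") <- "zscore"
  out
}

#' Median Z-score per sample group
#'
#' Collapses a Z-scored matrix to group-level abundances: per protein and
#' group, the median over present Z-scores.
#'
#' @param zmatrix Output of [zscore_proteins()].
#' @param groups Named assignment: a character vector of group labels, one
#'   per sample column (in `sample_ids(zmatrix)` order).
#' @return A tibble: `protein_id`, then one column per group.
#' @export
group_median_profile <- function(zmatrix, groups) {
  ids <- sample_ids(zmatrix)
  if (length(groups) != length(ids)) {
    stop("`groups` must label every sample column", call. = FALSE)
  }
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  vals <- intensity_values(zmatrix)
  med <- vapply(unique(groups), function(g) {
    apply(vals[, groups == g, drop = FALSE], 1, median, na.rm = TRUE)
  }, numeric(nrow(vals)))
  if (is.null(dim(med))) med <- matrix(med, nrow = nrow(vals),
                                       dimnames = list(NULL, unique(groups)))
  med[is.nan(med)] <- NA_real_
  dplyr::bind_cols(tibble::tibble(protein_id = zmatrix$protein_id),
                   tibble::as_tibble(med))
}

#' Cumulative intensity share of the most abundant proteins
#'
#' Per-protein abundance is the median over present linear intensities; the
#' function reports the fraction of total summed median intensity carried by
#' the `top_k` most abundant proteins.
#'
#' @param x An [intensity_tbl()] on the linear scale.
#' @param top_k Number of top proteins.
#' @return A fraction in `[0, 1]`, non-decreasing in `top_k`.
#' @export
cumulative_intensity_fraction <- function(x, top_k) {
  if (intensity_scale(x) != "linear") {
    stop("abundance ranking uses linear intensities", call. = FALSE)
  }
  if (top_k == 0) return(0)
  med <- apply(intensity_values(x), 1, median, na.rm = TRUE)
  med <- med[is.finite(med)]
  top_k <- min(top_k, length(med))
  sum(sort(med, decreasing = TRUE)[seq_len(top_k)]) / sum(med)
}

# CV of one candidate triple per protein: sample sd / mean over present
# values; candidates with < 2 present values are excluded (NA).
triple_cv <- function(vals, cols) {
  sub <- vals[, cols, drop = FALSE]
  n <- rowSums(!is.na(sub))
  mu <- rowMeans(sub, na.rm = TRUE)
  ss <- rowSums(sub^2, na.rm = TRUE) - n * mu^2
  cv <- sqrt(pmax(ss, 0) / pmax(n - 1, 1)) / mu
  cv[n < 2] <- NA_real_
  cv
}

#' Coefficient-of-variation report for a replicate plate design
#'
#' Intra-plate candidates are all 3-subsets of replicates within one plate;
#' inter-plate candidates take one replicate from each of three distinct
#' plates. Per candidate the CV is sample sd / mean on the linear scale
#' (candidates with fewer than two present values are excluded); the
#' protein's CV is the median over its candidates. When `cohorts` is given
#' (per sample column of `subjects`), a biological CV is added: the
#' per-cohort CV across subject samples, median across cohorts.
#'
#' @param replicates An [intensity_tbl()] of pooled-sample replicates on the
#'   linear scale.
#' @param plate_ids Plate assignment per replicate column.
#' @param cv_threshold Precision bound used for the summary counts.
#' @param subjects Optional linear-scale `intensity_tbl` of subject samples.
#' @param cohorts Cohort per subject column (required with `subjects`).
#' @return A list of class `cv_report`: `per_protein` tibble with
#'   `intra_cv`, `inter_cv` (and `biological_cv`), plus `counts` of proteins
#'   below `cv_threshold` per CV type.
#' @export
compute_cv_report <- function(replicates, plate_ids, cv_threshold = 0.20,
                              subjects = NULL, cohorts = NULL) {
  if (intensity_scale(replicates) != "linear") {
    stop("CVs are defined on linear intensities", call. = FALSE)
  }
  plate_ids <- as.character(plate_ids)
  ids <- sample_ids(replicates)
  if (length(plate_ids) != length(ids)) {
    stop("`plate_ids` must label every replicate column", call. = FALSE)
  }
  plates <- split(seq_along(ids), plate_ids)
  if (any(lengths(plates) < 3)) {
    stop("each plate needs >= 3 replicates for intra-plate triples", call. = FALSE)
  }
  if (length(plates) < 3) {
    stop("inter-plate triples need >= 3 plates", call. = FALSE)
  }
  vals <- intensity_values(replicates)

  intra_combos <- unlist(lapply(plates, function(cols) {
    asplit(combn(cols, 3), 2)
  }), recursive = FALSE)
  plate_triples <- combn(length(plates), 3)
  inter_combos <- unlist(lapply(asplit(plate_triples, 2), function(tr) {
    grid <- expand.grid(plates[[tr[1]]], plates[[tr[2]]], plates[[tr[3]]])
    lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  }), recursive = FALSE)

  median_cv <- function(combos) {
    cvs <- vapply(combos, function(cols) triple_cv(vals, cols),
                  numeric(nrow(vals)))
    if (is.null(dim(cvs))) cvs <- matrix(cvs, nrow = nrow(vals))
    apply(cvs, 1, median, na.rm = TRUE)
  }
  per_protein <- tibble::tibble(
    protein_id = replicates$protein_id,
    intra_cv = unname(median_cv(intra_combos)),
    inter_cv = unname(median_cv(inter_combos))
  )

  if (!is.null(subjects)) {
    if (is.null(cohorts)) stop("`cohorts` required with `subjects`", call. = FALSE)
    sv <- intensity_values(subjects)
    per_cohort <- vapply(unique(cohorts), function(co) {
      triple_like <- sv[, cohorts == co, drop = FALSE]
      n <- rowSums(!is.na(triple_like))
      mu <- rowMeans(triple_like, na.rm = TRUE)
      ss <- rowSums(triple_like^2, na.rm = TRUE) - n * mu^2
      cv <- sqrt(pmax(ss, 0) / pmax(n - 1, 1)) / mu
      cv[n < 2] <- NA_real_
      cv
    }, numeric(nrow(sv)))
    bio <- apply(per_cohort, 1, median, na.rm = TRUE)
    bio_tbl <- tibble::tibble(protein_id = subjects$protein_id,
                              biological_cv = bio)
    per_protein <- dplyr::left_join(per_protein, bio_tbl, by = "protein_id")
  }

  counts <- per_protein %>%
    dplyr::summarise(dplyr::across(dplyr::ends_with("_cv"),
                                   ~ sum(.x < cv_threshold, na.rm = TRUE)))
  structure(list(per_protein = per_protein, counts = counts,
                 cv_threshold = cv_threshold),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("# CV report (", nrow(x$per_protein), " proteins, threshold ",
      x$cv_threshold, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}
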