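#' Biochemical classification thresholds
#'
#' Cutoffs of the uniform biochemical AD definition (all concentrations in
#' ng/l): t-tau above 400 together with either Abeta1-42 below 550 or an
#' Abeta1-42/Abeta1-40 ratio below 0.065. The Hulstaert index is
#' Abeta1-42 / (240 + 1.18 * t-tau); scores below 1 classify as AD.
#'
#' @param ttau_cut,ab42_cut,ratio_cut Primary-rule cutoffs.
#' @param hulstaert_intercept,hulstaert_slope,hulstaert_cut Hulstaert index
#'   parameters and classification cutoff.
#' @return A list of class `clinical_thresholds`.
#' @export
clinical_thresholds <- function(ttau_cut = 400, ab42_cut = 550,
                                ratio_cut = 0.065,
                                hulstaert_intercept = 240,
                                hulstaert_slope = 1.18,
                                hulstaert_cut = 1.0) {
  vals <- c(ttau_cut, ab42_cut, ratio_cut, hulstaert_intercept,
            hulstaert_slope, hulstaert_cut)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be positive and finite", call. = FALSE)
  }
  structure(
    list(ttau_cut = ttau_cut, ab42_cut = ab42_cut, ratio_cut = ratio_cut,
         hulstaert_intercept = hulstaert_intercept,
         hulstaert_slope = hulstaert_slope, hulstaert_cut = hulstaert_cut),
    class = "clinical_thresholds"
  )
}

#' Primary biochemical AD classification
#'
#' Applies the uniform rule to one or more samples: AD iff t-tau is strictly
#' above `ttau_cut` AND (Abeta1-42 strictly below `ab42_cut` OR, when
#' Abeta1-40 is available, the 42/40 ratio strictly below `ratio_cut`).
#' Samples with t-tau or Abeta1-42 missing are `excluded`, unless
#' `control_override` is set (young emergency-department controls without
#' clinical chemistry), in which case they are `non_AD`. A missing Abeta1-40
#' only disables the ratio branch. Inequalities are strict as worded
#' ("above"/"below"): boundary values classify as non-AD.
#'
#' @param meta Data frame with columns `t_tau`, `ab42`, optionally `ab40`
#'   and `control_override` (single rows allowed).
#' @param thresholds A [clinical_thresholds()].
#' @return Character vector in `{"AD", "non_AD", "excluded"}`, one per row.
#' @export
classify_primary <- function(meta, thresholds = clinical_thresholds()) {
  meta <- tibble::as_tibble(meta)
  t_tau <- meta[["t_tau"]] %||% rep(NA_real_, nrow(meta))
  ab42 <- meta[["ab42"]] %||% rep(NA_real_, nrow(meta))
  ab40 <- meta[["ab40"]] %||% rep(NA_real_, nrow(meta))
  override <- meta[["control_override"]] %||% rep(FALSE, nrow(meta))
  override[is.na(override)] <- FALSE
  if (any(c(t_tau, ab42, ab40) < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  tau_pos <- t_tau > thresholds$ttau_cut
  ab42_pos <- ab42 < thresholds$ab42_cut
  ratio_pos <- !is.na(ab40) & ab40 > 0 & (ab42 / ab40 < thresholds$ratio_cut)
  ad <- tau_pos & (ab42_pos | ratio_pos)
  out <- ifelse(is.na(t_tau) | is.na(ab42), "excluded",
                ifelse(ad, "AD", "non_AD"))
  out[out == "excluded" & override] <- "non_AD"
  out
}

#' Hulstaert index
#'
#' `ab42 / (intercept + slope * t_tau)` with ng/l concentrations;
#' dimensionless. Scores strictly below the cutoff (1 by default) classify
#' as AD. Strictly decreasing in t-tau and increasing in Abeta1-42.
#'
#' @param ab42,t_tau Concentrations in ng/l (vectors allowed).
#' @inheritParams classify_primary
#' @return Numeric vector of index values.
#' @export
hulstaert_index <- function(ab42, t_tau, thresholds = clinical_thresholds()) {
  if (anyNA(ab42) || anyNA(t_tau)) {
    stop("hulstaert_index requires both ab42 and t_tau", call. = FALSE)
  }
  if (any(ab42 < 0) || any(t_tau < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  ab42 / (thresholds$hulstaert_intercept + thresholds$hulstaert_slope * t_tau)
}

#' Classify a set of samples under a chosen rule
#'
#' Runs either the primary biochemical rule or the Hulstaert index over a
#' metadata table and reports per-sample labels with the reason for any
#' exclusion, plus per-cohort/group summary counts.
#'
#' @param meta Sample metadata tibble.
#' @param rule `"primary"` or `"hulstaert"`.
#' @inheritParams classify_primary
#' @return A list with `labels` (tibble: `sample_id`, `label`, `reason`) and
#'   `summary` (counts per cohort x label).
#' @export
classify_cohort <- function(meta, rule = c("primary", "hulstaert"),
                            thresholds = clinical_thresholds()) {
  rule <- match.arg(rule)
  meta <- tibble::as_tibble(meta)
  override <- meta[["control_override"]] %||% rep(FALSE, nrow(meta))
  override[is.na(override)] <- FALSE
  if (rule == "primary") {
    label <- classify_primary(meta, thresholds)
    reason <- dplyr::case_when(
      label == "excluded" ~ "missing t_tau or ab42",
      is.na(meta[["t_tau"]] %||% NA_real_) & label == "non_AD" & override ~
        "control_override",
      TRUE ~ "primary rule"
    )
  } else {
    ok <- !is.na(meta[["t_tau"]] %||% NA_real_) & !is.na(meta[["ab42"]] %||% NA_real_)
    label <- rep("excluded", nrow(meta))
    idx <- hulstaert_index(ifelse(ok, meta$ab42, 0), ifelse(ok, meta$t_tau, 0),
                           thresholds)
    label[ok] <- ifelse(idx[ok] < thresholds$hulstaert_cut, "AD", "non_AD")
    label[!ok & override] <- "non_AD"
    reason <- dplyr::case_when(
      label == "excluded" ~ "missing t_tau or ab42",
      !ok & override ~ "control_override",
      TRUE ~ "hulstaert index"
    )
  }
  labels <- tibble::tibble(sample_id = meta$sample_id, label = label,
                           reason = reason)
  summary <- labels %>%
    dplyr::mutate(cohort = meta[["cohort"]] %||% "all") %>%
    dplyr::count(.data$cohort, .data$label, name = "n")
  list(labels = labels, summary = summary)
}
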