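#' Protein-covariate Pearson correlation
#'
#' Per protein: Pearson r against a numeric covariate (e.g. ELISA t-tau or
#' MMSE) over samples where both are present, the analytic two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))`, and
#' Benjamini-Hochberg q-values across the tested proteins of the cohort.
#' Proteins with fewer than `min_n` complete pairs are flagged untestable.
#'
#' @param bundle A [study_bundle()] (typically one cohort, log10 scale).
#' @param covariate Column name in `bundle$meta` (e.g. `"t_tau"`,
#'   `"mmse"`) or a numeric vector per sample. ELISA concentrations are
#'   log10-transformed first when `log10_covariate` is `TRUE`.
#' @param min_n Minimum complete pairs for a reported correlation.
#' @param log10_covariate Correlate against log10 of the covariate.
#' @return A tibble: `protein_id`, `r`, `n`, `p_value`, `q_value`.
#' @export
protein_covariate_correlation <- function(bundle, covariate = "t_tau",
                                          min_n = 5, log10_covariate = FALSE) {
  z <- if (is.character(covariate) && length(covariate) == 1) {
    bundle$meta[[covariate]]
  } else {
    covariate
  }
  if (!is.numeric(z)) stop("covariate must be numeric", call. = FALSE)
  if (log10_covariate) z <- log10(z)
  vals <- intensity_values(bundle$matrix)
  res <- apply(vals, 1, function(x) {
    ok <- !is.na(x) & !is.na(z)
    n <- sum(ok)
    if (n < min_n || sd(x[ok]) == 0 || sd(z[ok]) == 0) {
      return(c(NA_real_, n, NA_real_))
    }
    r <- cor(x[ok], z[ok])
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r, n, 2 * pt(-abs(tt), n - 2))
  })
  out <- tibble::tibble(
    protein_id = bundle$matrix$protein_id,
    r = unname(res[1, ]), n = as.integer(res[2, ]),
    p_value = unname(res[3, ])
  )
  out$q_value <- NA_real_
  testable <- !is.na(out$p_value)
  out$q_value[testable] <- bh_adjust(out$p_value[testable])
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH via [stats::p.adjust()]; output is monotone and elementwise
#' at least the input after monotonization.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Proteins correlating consistently in every cohort
#'
#' Intersects per-cohort correlation results: a protein qualifies when its
#' correlation p-value is below `alpha` in every cohort and the sign of r
#' agrees across cohorts.
#'
#' @param results Named list of [protein_covariate_correlation()] outputs.
#' @param alpha Significance level.
#' @return A tibble with per-cohort r columns and `consensus_sign`.
#' @export
multi_cohort_correlates <- function(results, alpha = 0.05) {
  if (is.null(names(results))) names(results) <- paste0("cohort", seq_along(results))
  long <- purrr::imap(results, function(tb, nm) {
    tibble::tibble(protein_id = tb$protein_id, cohort = nm, r = tb$r,
                   p = tb$p_value)
  }) %>% dplyr::bind_rows()
  hits <- long %>%
    dplyr::filter(!is.na(.data$p), .data$p < alpha) %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::filter(dplyr::n() == length(results),
                  length(unique(sign(.data$r))) == 1, all(.data$r != 0)) %>%
    dplyr::ungroup()
  if (!nrow(hits)) {
    return(tibble::tibble(protein_id = character(),
                          consensus_sign = numeric()))
  }
  wide <- tidyr::pivot_wider(hits, id_cols = "protein_id",
                             names_from = "cohort", values_from = "r",
                             names_prefix = "r_")
  # consensus sign per protein (all cohorts agree by construction)
  first_r <- hits %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::summarise(consensus_sign = sign(.data$r[1]))
  wide$consensus_sign <- unname(first_r$consensus_sign[
    match(wide$protein_id, first_r$protein_id)])
  wide
}

#' Differential abundance between MMSE strata
#'
#' Splits one cohort at an MMSE cutoff (low group strictly below the
#' cutoff, high group at or above) and delegates to
#' [differential_table()], low vs high.
#'
#' @param bundle A [study_bundle()] for a cohort with MMSE scores.
#' @param cutoff MMSE cutoff (the study swept 29 down to 21).
#' @inheritParams differential_table
#' @return A `differential_tbl` (fold changes are low / high MMSE).
#' @export
mmse_stratified_differential <- function(bundle, cutoff,
                                         config = analysis_config(),
                                         seed = config$rng_seed) {
  mmse <- bundle$meta$mmse
  keep <- !is.na(mmse)
  if (!all(keep)) {
    ids <- bundle$meta$sample_id[keep]
    bundle <- study_bundle(
      new_intensity_tbl(bundle$matrix[c("protein_id", "gene_name", ids)],
                        intensity_scale(bundle$matrix)),
      bundle$meta[keep, ])
    mmse <- mmse[keep]
  }
  low <- mmse < cutoff
  if (!any(low) || all(low)) {
    stop("MMSE cutoff ", cutoff, " produces an empty stratum", call. = FALSE)
  }
  differential_table(bundle, low, config, seed)
}

#' Global protein-protein correlation map
#'
#' Pairwise Pearson correlations over samples where both proteins are
#' present (pairs with fewer than `min_overlap` shared samples are set
#' missing), then average-linkage hierarchical clustering of the
#' correlation pattern (distance 1 - r) cut into `n_clusters` main blocks.
#' Co-regulated proteins -- neuronal panels, blood contamination -- surface
#' as clusters.
#'
#' @param x A log10-scale [intensity_tbl()].
#' @param min_overlap Minimum shared present samples per pair.
#' @param n_clusters Number of clusters to cut.
#' @return A list: `r` (protein x protein correlation matrix) and
#'   `clusters` (tibble `protein_id`, `cluster`).
#' @export
global_correlation_map <- function(x, min_overlap = 10, n_clusters = 8) {
  vals <- intensity_values(x)
  r <- cor(t(vals), use = "pairwise.complete.obs")
  present <- !is.na(vals)
  overlap <- tcrossprod(present * 1)
  r[overlap < min_overlap] <- NA_real_
  # cluster on the correlation profile; absent correlations contribute the
  # neutral value 0 so sparsely overlapping proteins stay clusterable
  r_filled <- r
  r_filled[is.na(r_filled)] <- 0
  d <- as.dist(1 - r_filled)
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, k = min(n_clusters, nrow(vals)))
  list(r = r,
       clusters = tibble::tibble(protein_id = x$protein_id,
                                 cluster = unname(cl)),
       hclust = hc)
}

#' Covariate-adjusted linear regression per protein
#'
#' Ordinary least squares of log10 protein intensity on a response of
#' interest (AD status, or log10 t-tau concentration) adjusting for age,
#' sex and cohort, with listwise deletion of incomplete samples. For
#' continuous covariates the coefficient is additionally reported scaled by
#' the covariate's interquartile range (dataset IQR unless overridden), so
#' binary and continuous estimators are comparable.
#'
#' @param bundle A [study_bundle()] with log10 matrix.
#' @param response `"status"` (needs a `status` column or `labels`) or
#'   `"t_tau"` (log10-transformed internally).
#' @param labels Optional AD indicator per sample (logical) when
#'   `response = "status"`.
#' @param covariates Adjustment columns from the metadata (default age,
#'   sex, cohort).
#' @param iqr_overrides Named numeric vector of IQRs to use instead of the
#'   dataset IQRs (e.g. `c(age = 11)`).
#' @return A tibble per protein x term: `protein_id`, `term`, `estimate`,
#'   `p_value`, `iqr_scaled` (`NA` for binary terms), `r_squared`.
#' @export
covariate_adjusted_regression <- function(bundle, response = c("status", "t_tau"),
                                          labels = NULL,
                                          covariates = c("age", "sex", "cohort"),
                                          iqr_overrides = NULL) {
  response <- match.arg(response)
  meta <- bundle$meta
  df <- tibble::tibble(.rows = nrow(meta))
  if (response == "status") {
    st <- labels %||% meta$status
    if (is.null(st)) stop("status labels required", call. = FALSE)
    df$response_var <- as.numeric(as_case_indicator(st))
    resp_name <- "status"
  } else {
    df$response_var <- log10(meta$t_tau)
    resp_name <- "log10_t_tau"
  }
  for (cv in covariates) {
    df[[cv]] <- if (cv %in% c("sex", "cohort")) factor(meta[[cv]]) else meta[[cv]]
  }
  terms <- c("response_var", covariates)
  continuous <- c("response_var"[response == "t_tau"],
                  covariates[vapply(covariates, function(cv)
                    is.numeric(df[[cv]]), TRUE)])
  iqrs <- vapply(continuous, function(cv) {
    if (!is.null(iqr_overrides) && cv %in% names(iqr_overrides)) {
      iqr_overrides[[cv]]
    } else IQR(df[[cv]], na.rm = TRUE)
  }, 0)
  # map user-facing override names onto the internal response column
  if (!is.null(iqr_overrides) && resp_name %in% names(iqr_overrides) &&
      "response_var" %in% continuous) {
    iqrs[["response_var"]] <- iqr_overrides[[resp_name]]
  }

  vals <- intensity_values(bundle$matrix)
  fml <- as.formula(paste("y ~", paste(terms, collapse = " + ")))
  out <- purrr::map_dfr(seq_len(nrow(vals)), function(i) {
    dat <- df
    dat$y <- vals[i, ]
    dat <- dat[complete.cases(dat), ]
    dropped <- vapply(covariates, function(cv)
      is.factor(dat[[cv]]) && length(unique(dat[[cv]])) < 2, TRUE)
    fml_i <- if (any(dropped)) {
      as.formula(paste("y ~", paste(c("response_var",
                                      covariates[!dropped]), collapse = " + ")))
    } else fml
    fit <- lm(fml_i, data = dat)
    if (fit$rank < length(coef(fit))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      stop("rank-deficient design; collinear term(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    sm <- summary(fit)
    co <- sm$coefficients
    term_names <- rownames(co)[-1]
    base <- sub("^response_var", resp_name, term_names)
    scaled <- vapply(term_names, function(tn) {
      raw <- sub("^response_var$", "response_var", tn)
      if (raw %in% names(iqrs)) co[tn, 1] * iqrs[[raw]] else NA_real_
    }, 0)
    tibble::tibble(
      protein_id = bundle$matrix$protein_id[i],
      term = base,
      estimate = unname(co[-1, 1]),
      p_value = unname(co[-1, 4]),
      iqr_scaled = unname(scaled),
      r_squared = sm$r.squared
    )
  })
  out
}
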