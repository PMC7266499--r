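#' Rank-based 1D annotation enrichment
#'
#' Ranks all proteins ascending by a per-protein value (typically the AD /
#' non-AD log10 fold change; ties get average ranks). For every term whose
#' membership within the dataset falls in `[term_size_min, term_size_max]`,
#' the enrichment score is
#' `s = 2 * (meanRank_in - (n + 1) / 2) / n`, in `(-1, 1)`: positive s
#' means members sit at high values (AD-elevated when values are AD deltas).
#' Significance is the two-sided Mann-Whitney test of member versus
#' non-member values ([stats::wilcox.test()]; exact enumeration for
#' n <= 25, otherwise the tie-corrected normal approximation), BH-adjusted
#' across the tested terms.
#'
#' @param values Named numeric vector of finite per-protein values; names
#'   are the protein / gene keys the catalog refers to.
#' @param catalog An annotation catalog ([read_annotations()]).
#' @param term_size_min,term_size_max Bounds on members present in
#'   `values` for a term to be tested.
#' @return A tibble: `term_id`, `n_in`, `s`, `p_value`, `q_value`.
#' @export
oned_enrichment <- function(values, catalog, term_size_min = 10,
                            term_size_max = 100) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  keys <- names(values)
  if (is.null(keys)) stop("`values` must be named by protein key", call. = FALSE)
  n <- length(values)
  rk <- rank(values)  # ascending, average ranks on ties
  rows <- purrr::pmap_dfr(
    list(catalog$term_id, catalog$members),
    function(term_id, members) {
      idx <- which(keys %in% members)
      n_in <- length(idx)
      if (n_in < term_size_min || n_in > term_size_max) return(NULL)
      s <- 2 * (mean(rk[idx]) - (n + 1) / 2) / n
      p <- if (n_in == n) {
        1  # term covers everything: no outside group to compare against
      } else {
        suppressWarnings(
          wilcox.test(values[idx], values[-idx], exact = n <= 25)$p.value
        )
      }
      tibble::tibble(term_id = term_id, n_in = n_in, s = s, p_value = p)
    })
  if (!nrow(rows)) {
    warning("no annotation term passes the size filter", call. = FALSE)
    return(tibble::tibble(term_id = character(), n_in = integer(),
                          s = numeric(), p_value = numeric(),
                          q_value = numeric()))
  }
  rows$q_value <- bh_adjust(rows$p_value)
  rows
}

#' Annotation terms consistent across cohorts
#'
#' Keeps terms with an enrichment p-value below `p_cutoff` in every cohort
#' and the same sign of the enrichment score s throughout; reports
#' per-cohort s and their mean. The default cutoff is 0.05; `p_cutoff =
#' 0.005` reproduces the stricter 0.5% preset.
#'
#' @param results Named list of per-cohort [oned_enrichment()] outputs
#'   computed against a shared catalog.
#' @param p_cutoff Per-cohort significance cutoff.
#' @return A tibble with `term_id`, per-cohort `s_` columns and `mean_s`.
#' @export
multi_cohort_terms <- function(results, p_cutoff = 0.05) {
  if (!length(results)) {
    return(tibble::tibble(term_id = character(), mean_s = numeric()))
  }
  if (is.null(names(results))) names(results) <- paste0("cohort", seq_along(results))
  long <- purrr::imap(results, function(tb, nm) {
    tibble::tibble(term_id = tb$term_id, cohort = nm, s = tb$s,
                   p = tb$p_value)
  }) %>% dplyr::bind_rows()
  if (!nrow(long)) return(tibble::tibble(term_id = character(),
                                         mean_s = numeric()))
  hits <- long %>%
    dplyr::filter(.data$p < p_cutoff) %>%
    dplyr::group_by(.data$term_id) %>%
    dplyr::filter(dplyr::n() == length(results),
                  length(unique(sign(.data$s))) == 1, all(.data$s != 0)) %>%
    dplyr::ungroup()
  if (!nrow(hits)) return(tibble::tibble(term_id = character(),
                                         mean_s = numeric()))
  wide <- tidyr::pivot_wider(hits, id_cols = "term_id",
                             names_from = "cohort", values_from = "s",
                             names_prefix = "s_")
  mean_s <- hits %>%
    dplyr::group_by(.data$term_id) %>%
    dplyr::summarise(mean_s = mean(.data$s))
  dplyr::left_join(wide, mean_s, by = "term_id")
}

#' Fisher-based membership enrichment of a protein cluster
#'
#' For each annotation term: the enrichment factor of the term inside a
#' cluster over the background `(k/|cluster|) / (K/|background|)`, the
#' two-sided Fisher exact p of the 2x2 membership table, and BH q-values
#' across terms. Used to annotate blocks of the global correlation map.
#'
#' @param cluster Character vector of protein keys (subset of `background`).
#' @param background Character vector of all dataset protein keys.
#' @param catalog Annotation catalog tibble.
#' @return A tibble: `term_id`, `n_background`, `n_cluster`,
#'   `enrichment_factor`, `p_value`, `q_value`.
#' @export
cluster_membership_enrichment <- function(cluster, background, catalog) {
  if (!all(cluster %in% background)) {
    stop("cluster must be a subset of the background", call. = FALSE)
  }
  n_bg <- length(background)
  n_cl <- length(cluster)
  rows <- purrr::pmap_dfr(
    list(catalog$term_id, catalog$members),
    function(term_id, members) {
      K <- sum(background %in% members)
      if (K == 0) return(NULL)
      k <- sum(cluster %in% members)
      factor <- (k / n_cl) / (K / n_bg)
      p <- fisher_exact_2x2(k, n_cl - k, K - k, n_bg - n_cl - (K - k))$fisher_p
      tibble::tibble(term_id = term_id, n_background = K, n_cluster = k,
                     enrichment_factor = factor, p_value = p)
    })
  if (!nrow(rows)) {
    return(tibble::tibble(term_id = character(), n_background = integer(),
                          n_cluster = integer(), enrichment_factor = numeric(),
                          p_value = numeric(), q_value = numeric()))
  }
  rows$q_value <- bh_adjust(rows$p_value)
  rows
}
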