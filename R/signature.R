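sig_column <- function(mode) switch(mode, p = "p_value", q = "q_value")

#' Directional consistency between two cohorts
#'
#' Restricts to proteins significant in both cohorts (at `alpha`, under p or
#' q values) and reports how many of them change in the same direction.
#'
#' @param table_a,table_b [differential_table()] outputs sharing a protein
#'   key space.
#' @param alpha Significance level.
#' @param mode `"p"` (raw p-values) or `"q"` (permutation q-values).
#' @return A list with `n_significant_both`, `n_consistent` and `fraction`
#'   (`NA` when no protein is significant in both).
#' @export
pairwise_consistency <- function(table_a, table_b, alpha = 0.05,
                                 mode = c("p", "q")) {
  mode <- match.arg(mode)
  col <- sig_column(mode)
  joined <- dplyr::inner_join(
    dplyr::select(table_a, "protein_id", a_sig = dplyr::all_of(col),
                  a_dir = "direction"),
    dplyr::select(table_b, "protein_id", b_sig = dplyr::all_of(col),
                  b_dir = "direction"),
    by = "protein_id"
  ) %>%
    dplyr::filter(.data$a_sig < alpha, .data$b_sig < alpha)
  n_both <- nrow(joined)
  n_cons <- sum(joined$a_dir == joined$b_dir & joined$a_dir != 0)
  list(n_significant_both = n_both, n_consistent = n_cons,
       fraction = if (n_both > 0) n_cons / n_both else NA_real_)
}

#' Cross-cohort signature
#'
#' Proteins significant in every cohort at `alpha` (under p or q), with a
#' per-protein consistency flag: consistent means the same non-zero
#' direction in all cohorts, in which case a consensus direction is
#' assigned. The signature proper is the consistent subset.
#'
#' @param tables Named list of two or more [differential_table()] outputs.
#' @inheritParams pairwise_consistency
#' @return A tibble with per-cohort `p_`, `q_`, `dir_`, `fc_` columns, plus
#'   `consistent` and `consensus_direction`; attribute `"signature"` holds
#'   the consistent protein ids.
#' @export
cross_cohort_signature <- function(tables, alpha = 0.05, mode = c("p", "q")) {
  mode <- match.arg(mode)
  if (length(tables) < 2) stop("need >= 2 cohort tables", call. = FALSE)
  if (is.null(names(tables))) names(tables) <- paste0("cohort", seq_along(tables))
  col <- sig_column(mode)
  long <- purrr::imap(tables, function(tb, nm) {
    tibble::tibble(protein_id = tb$protein_id, cohort = nm,
                   sig = tb[[col]], p = tb$p_value, q = tb$q_value,
                   dir = tb$direction, fc = tb$fold_change)
  }) %>% dplyr::bind_rows()
  hits <- long %>%
    dplyr::filter(!is.na(.data$sig), .data$sig < alpha) %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::filter(dplyr::n() == length(tables)) %>%
    dplyr::ungroup()
  if (!nrow(hits)) {
    out <- tibble::tibble(protein_id = character(), consistent = logical(),
                          consensus_direction = numeric())
    attr(out, "signature") <- character()
    return(out)
  }
  wide <- hits %>%
    tidyr::pivot_wider(id_cols = "protein_id", names_from = "cohort",
                       values_from = c("p", "q", "dir", "fc"))
  dirs <- as.matrix(wide[grep("^dir_", names(wide))])
  consistent <- apply(dirs, 1, function(d) length(unique(d)) == 1 && d[1] != 0)
  wide$consistent <- consistent
  wide$consensus_direction <- ifelse(consistent, dirs[, 1], NA_real_)
  attr(wide, "signature") <- wide$protein_id[consistent]
  wide
}

#' Fold-change concordance between two cohorts
#'
#' Pearson correlation of the log10 fold changes of proteins significant in
#' both cohorts with the same direction of change.
#'
#' @inheritParams pairwise_consistency
#' @return A list with `r` and `n` (number of proteins correlated).
#' @export
foldchange_correlation <- function(table_a, table_b, alpha = 0.05,
                                   mode = c("p", "q")) {
  mode <- match.arg(mode)
  col <- sig_column(mode)
  joined <- dplyr::inner_join(
    dplyr::select(table_a, "protein_id", a_sig = dplyr::all_of(col),
                  a_dir = "direction", a_delta = "delta_log10"),
    dplyr::select(table_b, "protein_id", b_sig = dplyr::all_of(col),
                  b_dir = "direction", b_delta = "delta_log10"),
    by = "protein_id"
  ) %>%
    dplyr::filter(.data$a_sig < alpha, .data$b_sig < alpha,
                  .data$a_dir == .data$b_dir, .data$a_dir != 0)
  if (nrow(joined) < 3) {
    stop("fewer than 3 co-significant consistent proteins", call. = FALSE)
  }
  list(r = cor(joined$a_delta, joined$b_delta), n = nrow(joined))
}

#' Two-sided Fisher exact test with sample odds ratio
#'
#' The p-value is the exact two-sided Fisher probability (sum over tables
#' with point probability at most the observed one, via
#' [stats::fisher.test()]). The odds ratio reported is the sample odds
#' ratio `(a*d)/(b*c)` -- the quantity quoted alongside contingency tables
#' in enrichment analyses -- with a Haldane 0.5 correction to every cell
#' when any cell is zero (flagged in the result).
#'
#' @param a,b,c,d Non-negative integer cell counts of the 2x2 table, rows =
#'   condition 1, columns = condition 2.
#' @return A tibble with `a`-`d`, `odds_ratio`, `fisher_p`,
#'   `haldane_corrected`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("cell counts must be >= 0 with a positive total", call. = FALSE)
  }
  p <- fisher.test(matrix(counts, 2, byrow = TRUE))$p.value
  haldane <- any(counts == 0)
  if (haldane) counts <- counts + 0.5
  or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  tibble::tibble(a = a, b = b, c = c, d = d, odds_ratio = or,
                 fisher_p = min(p, 1), haldane_corrected = haldane)
}

#' Overlap of a signature with an external study
#'
#' Matches signature proteins into an external differential table (by
#' `protein_id`, falling back to `gene_name` for unmatched ids), builds the
#' 2x2 table of signature membership versus external significance over the
#' external universe, and reports the Fisher/odds-ratio contingency result
#' plus the Pearson correlation of log10 fold changes on the overlap.
#'
#' @param signature Tibble with `protein_id`, optionally `gene_name` and
#'   `delta_log10` (consensus or mean across cohorts).
#' @param external Tibble with columns `protein_id`, optionally `gene_name`,
#'   `significant` (logical) and `delta` (log10 fold change).
#' @return A list: `n_matched`, `n_overlap` (matched and externally
#'   significant), `contingency` ([fisher_exact_2x2()] row) and `fc_r`
#'   (`NA` when fewer than 3 overlap proteins have fold changes).
#' @export
cross_study_overlap <- function(signature, external) {
  ext_ids <- external$protein_id
  hit <- match(signature$protein_id, ext_ids)
  if ("gene_name" %in% names(signature) && "gene_name" %in% names(external)) {
    miss <- is.na(hit) & nzchar(signature$gene_name %||% "")
    hit[miss] <- match(signature$gene_name[miss], external$gene_name)
  }
  matched <- which(!is.na(hit))
  if (!length(matched)) stop("no signature protein matched", call. = FALSE)
  in_sig <- seq_len(nrow(external)) %in% hit[matched]
  ext_sig <- external$significant
  a <- sum(in_sig & ext_sig)
  b <- sum(in_sig & !ext_sig)
  cc <- sum(!in_sig & ext_sig)
  dd <- sum(!in_sig & !ext_sig)
  contingency <- fisher_exact_2x2(a, b, cc, dd)
  fc_r <- NA_real_
  if ("delta" %in% names(external) && "delta_log10" %in% names(signature)) {
    ov <- matched[ext_sig[hit[matched]]]
    if (length(ov) >= 3) {
      fc_r <- cor(signature$delta_log10[ov], external$delta[hit[ov]],
                  use = "complete.obs")
    }
  }
  list(n_matched = length(matched), n_overlap = a,
       contingency = contingency, fc_r = fc_r)
}

#' Hierarchical clustering of a group median profile
#'
#' Conventions of the signature heat maps: proteins are clustered on
#' Euclidean distance of their group-median Z-scores, sample groups on
#' correlation distance (1 - Pearson r), both with average linkage.
#' Leaf orders are deterministic; ties break by input order.
#'
#' @param profile Output of [group_median_profile()].
#' @return A list with `protein_hclust`, `group_hclust`, `protein_order`
#'   (protein ids in dendrogram leaf order) and `group_order`.
#' @export
cluster_heatmap <- function(profile) {
  m <- as.matrix(profile[setdiff(names(profile), "protein_id")])
  rownames(m) <- profile$protein_id
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 proteins and >= 2 groups",
                                       call. = FALSE)
  hp <- hclust(stats::dist(m), method = "average")
  hg <- hclust(as.dist(1 - cor(m, use = "pairwise.complete.obs")),
               method = "average")
  list(protein_hclust = hp, group_hclust = hg,
       protein_order = rownames(m)[hp$order],
       group_order = colnames(m)[hg$order])
}
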