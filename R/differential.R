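#' Two-sided unpaired Student t-test
#'
#' Pooled-variance (Student) two-sample t, the form whose standard error the
#' SAM fudge factor s0 was defined for. Thin wrapper over
#' [stats::t.test()] with `var.equal = TRUE`.
#'
#' @param x,y Numeric vectors (missing values dropped); each needs at least
#'   two present values.
#' @return A list with `t`, `df` and `p`. If either group has fewer than two
#'   present values, or both groups have zero variance, all three are `NA`.
#' @export
two_sample_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  }
  if (sd(x) == 0 && sd(y) == 0) {
    # zero pooled variance: the statistic is undefined
    return(list(t = NA_real_, df = length(x) + length(y) - 2, p = NA_real_))
  }
  fit <- t.test(x, y, var.equal = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

# Pooled-variance standard error of mean(x) - mean(y).
pooled_se <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  sqrt(sp2) * sqrt(1 / nx + 1 / ny)
}

#' SAM d-statistic
#'
#' `d = (mean(x) - mean(y)) / (se_pooled + s0)` where `se_pooled` is the
#' pooled-variance standard error of the mean difference. With `s0 = 0` this
#' is exactly the Student t statistic; as s0 grows, d shrinks toward 0,
#' damping low-variance proteins.
#'
#' @inheritParams two_sample_t
#' @param s0 Non-negative fudge factor (applied on the same scale as the
#'   data, here log10 intensities).
#' @return Numeric d, `NA` when either group has < 2 present values or the
#'   denominator is zero.
#' @export
sam_d <- function(x, y, s0 = 0.001) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  denom <- pooled_se(x, y) + s0
  if (denom == 0) return(NA_real_)
  (mean(x) - mean(y)) / denom
}

# Vectorized SAM d over all proteins of a matrix for one label assignment.
# vals: proteins x samples with NA; is_x: logical per column.
matrix_sam_d <- function(vals, is_x, s0) {
  dx <- vals[, is_x, drop = FALSE]
  dy <- vals[, !is_x, drop = FALSE]
  nx <- rowSums(!is.na(dx)); ny <- rowSums(!is.na(dy))
  mx <- rowMeans(dx, na.rm = TRUE); my <- rowMeans(dy, na.rm = TRUE)
  ssx <- rowSums(dx^2, na.rm = TRUE) - nx * mx^2
  ssy <- rowSums(dy^2, na.rm = TRUE) - ny * my^2
  sp2 <- pmax(ssx + ssy, 0) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  d <- (mx - my) / (se + s0)
  d[nx < 2 | ny < 2 | (se + s0) == 0] <- NA_real_
  d
}

# All distinct assignments of `k` "x" labels to n columns, as a logical
# matrix (assignments x n). Used for exhaustive permutation enumeration.
all_label_assignments <- function(n, k) {
  sets <- combn(n, k)
  t(apply(sets, 2, function(idx) seq_len(n) %in% idx))
}

#' Permutation-based q-values for SAM statistics
#'
#' Computes observed d per protein, re-computes d under label permutations
#' (exhaustive enumeration when the number of distinct assignments does not
#' exceed `config$n_permutations`, otherwise uniform random assignments),
#' and estimates for each protein
#' `q_i = E_perm[#|d_perm| >= |d_i|] / #[|d_obs| >= |d_i|]`, clipped to
#' `[0, 1]` and monotonized so q never decreases as |d| decreases. Proteins
#' with undefined d (fewer than two present values per group) are excluded
#' from the ranking and get `NA`.
#'
#' @param vals Proteins x samples numeric matrix (log10 scale, NA allowed).
#' @param labels Logical or two-level vector per column; `TRUE`/first level
#'   is the case group.
#' @param config An [analysis_config()] (uses `s0`, `n_permutations`).
#' @param seed Integer seed for the random permutations.
#' @return A tibble with `d` and `q` per protein (input row order).
#' @export
permutation_qvalues <- function(vals, labels, config = analysis_config(),
                                seed = config$rng_seed) {
  is_x <- as_case_indicator(labels)
  if (sum(is_x) < 1 || sum(!is_x) < 1) {
    stop("both label classes must be non-empty", call. = FALSE)
  }
  n <- length(is_x); k <- sum(is_x)
  d_obs <- matrix_sam_d(vals, is_x, config$s0)

  n_distinct <- choose(n, k)
  perms <- if (n_distinct <= config$n_permutations) {
    all_label_assignments(n, k)
  } else {
    withr::with_seed(seed, {
      t(replicate(config$n_permutations,
                  seq_len(n) %in% sample.int(n, k)))
    })
  }

  ok <- which(!is.na(d_obs))
  q <- rep(NA_real_, length(d_obs))
  if (length(ok)) {
    a_obs <- abs(d_obs[ok])
    ord <- order(a_obs, decreasing = TRUE)
    a_sorted <- a_obs[ord]
    n_obs_ge <- vapply(a_sorted, function(th) sum(a_obs >= th), 0L)
    fp <- numeric(length(a_sorted))
    for (b in seq_len(nrow(perms))) {
      d_b <- matrix_sam_d(vals, perms[b, ], config$s0)
      a_b <- sort(abs(d_b[!is.na(d_b)]))
      # counts of permuted |d| >= each threshold
      fp <- fp + (length(a_b) - findInterval(a_sorted, a_b, left.open = TRUE))
    }
    fp <- fp / nrow(perms)
    q_sorted <- pmin(pmax(fp / n_obs_ge, 0), 1)
    # running minimum from the least significant end upward: q is
    # non-decreasing as |d| decreases
    q_sorted <- rev(cummin(rev(q_sorted)))
    q[ok[ord]] <- q_sorted
  }
  tibble::tibble(d = d_obs, q = q)
}

as_case_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  lev <- unique(labels[!is.na(labels)])
  if (length(lev) != 2) stop("labels must have exactly two classes", call. = FALSE)
  labels == lev[1]
}

#' Per-cohort differential abundance table
#'
#' For each protein: present-value counts per group, the mean log10
#' difference (case minus control) and its linear fold change, the Student
#' t statistic and two-sided p-value, the SAM d with s0, and the
#' permutation-based q-value. Proteins with fewer than two present values in
#' either group are retained but flagged untestable (`NA` statistics).
#'
#' @param bundle A [study_bundle()] with a log10-scale matrix (typically one
#'   cohort, see [split_cohorts()]).
#' @param labels Per-sample labels in matrix column order: logical
#'   (`TRUE` = AD) or character with levels `"AD"`/other. Samples labelled
#'   `NA` (e.g. excluded by the clinical rule) are dropped.
#' @param config An [analysis_config()].
#' @param seed Seed for the permutation stage.
#' @return A tibble of class `differential_tbl`, one row per protein.
#' @export
differential_table <- function(bundle, labels, config = analysis_config(),
                               seed = config$rng_seed) {
  vals <- intensity_values(bundle$matrix)
  if (intensity_scale(bundle$matrix) != "log10") {
    stop("differential analysis expects log10 intensities", call. = FALSE)
  }
  if (length(labels) != ncol(vals)) {
    stop("`labels` must match the matrix sample columns", call. = FALSE)
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    labels[labels == "excluded"] <- NA
    keep <- !is.na(labels)
    is_x <- labels[keep] == "AD"
  } else {
    keep <- !is.na(labels)
    is_x <- as.logical(labels[keep])
  }
  vals <- vals[, keep, drop = FALSE]

  dx <- vals[, is_x, drop = FALSE]; dy <- vals[, !is_x, drop = FALSE]
  n_ad <- rowSums(!is.na(dx)); n_ctrl <- rowSums(!is.na(dy))
  delta <- rowMeans(dx, na.rm = TRUE) - rowMeans(dy, na.rm = TRUE)
  delta[n_ad < 1 | n_ctrl < 1] <- NA_real_
  t_stat <- matrix_sam_d(vals, is_x, 0)
  df <- n_ad + n_ctrl - 2
  p <- 2 * pt(-abs(t_stat), df)
  pq <- permutation_qvalues(vals, is_x, config, seed)

  out <- tibble::tibble(
    protein_id = bundle$matrix$protein_id,
    gene_name = bundle$matrix$gene_name,
    n_AD = unname(n_ad), n_ctrl = unname(n_ctrl),
    delta_log10 = unname(delta),
    fold_change = unname(10^delta),
    t_stat = unname(t_stat),
    d_stat = unname(pq$d),
    p_value = unname(p),
    q_value = pq$q,
    direction = unname(sign(delta))
  )
  class(out) <- c("differential_tbl", class(out))
  out
}
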