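# Small in-code fixtures shared across test files.

# A tiny bundle: `n_prot` proteins x sum(group sizes) samples, optional
# shifted proteins in the "AD" group, log10 scale unless stated.
tiny_bundle <- function(n_prot = 10, n_ad = 5, n_ctrl = 5, shift_idx = integer(),
                        shift = 0.5, noise = 0.1, cohort = "c1", seed = 1) {
  withr::with_seed(seed, {
    n <- n_ad + n_ctrl
    vals <- matrix(rnorm(n_prot, 6, 0.5), n_prot, n)  # per-protein baseline
    vals[shift_idx, seq_len(n_ad)] <- vals[shift_idx, seq_len(n_ad)] + shift
    vals <- vals + rnorm(n_prot * n, 0, noise)
    colnames(vals) <- sprintf("%s_s%02d", cohort, seq_len(n))
    m <- intensity_tbl(
      tibble::tibble(protein_id = sprintf("pr%02d", seq_len(n_prot)),
                     gene_name = sprintf("g%02d", seq_len(n_prot))),
      10^vals, scale = "linear"
    )
    meta <- tibble::tibble(
      sample_id = colnames(vals), cohort = cohort,
      group_label = rep(c("AD", "ctrl"), c(n_ad, n_ctrl)),
      age = 70, sex = "female", t_tau = NA_real_, p_tau181 = NA_real_,
      ab42 = NA_real_, ab40 = NA_real_, mmse = NA_integer_,
      control_override = FALSE
    )
    list(bundle = study_bundle(log10_transform(m), meta),
         labels = meta$group_label == "AD")
  })
}

# Differential-table stub for consistency/signature tests.
diff_stub <- function(ids, p, dir, delta = dir * 0.1, q = p) {
  tibble::tibble(protein_id = ids, gene_name = "", n_AD = 10L, n_ctrl = 10L,
                 delta_log10 = delta, fold_change = 10^delta,
                 t_stat = NA_real_, d_stat = NA_real_,
                 p_value = p, q_value = q, direction = dir)
}

# Independent brute-force SAM d (scalar, no shared code with the package
# internals beyond base R).
oracle_d <- function(x, y, s0) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / (sqrt(sp2 * (1 / nx + 1 / ny)) + s0)
}

# Exhaustive-enumeration oracle for permutation q-values on a complete
# (no-NA) matrix, following the estimator definition directly.
oracle_perm_q <- function(vals, is_x, s0) {
  n <- ncol(vals); k <- sum(is_x)
  sets <- combn(n, k)
  d_of <- function(ind) {
    apply(vals, 1, function(row) oracle_d(row[ind], row[!ind], s0))
  }
  d_obs <- d_of(is_x)
  d_perm <- apply(sets, 2, function(s) d_of(seq_len(n) %in% s))
  q <- vapply(seq_along(d_obs), function(i) {
    th <- abs(d_obs[i])
    e_fp <- mean(colSums(abs(d_perm) >= th))
    min(1, e_fp / sum(abs(d_obs) >= th))
  }, 0)
  ord <- order(abs(d_obs), decreasing = TRUE)
  q[ord] <- rev(cummin(rev(q[ord])))
  q
}

# Two-sided Fisher p by direct hypergeometric enumeration (sum of tables
# with point probability <= observed, standard 1 + 1e-7 relative slack).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
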