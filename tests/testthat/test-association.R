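corr_bundle <- function(vals, covariate, cohort = "c1") {
  colnames(vals) <- paste0(cohort, "_s", seq_len(ncol(vals)))
  m <- csfsig:::new_intensity_tbl(
    dplyr::bind_cols(
      tibble::tibble(protein_id = paste0("P", seq_len(nrow(vals))),
                     gene_name = ""),
      tibble::as_tibble(vals)), "log10")
  meta <- tibble::tibble(sample_id = colnames(vals), cohort = cohort,
                         t_tau = covariate)
  study_bundle(m, meta)
}

test_that("protein-covariate correlation matches hand computation", {
  z <- c(1, 2, 3, 4)
  vals <- rbind(z, -z + 10, c(1, 3, 2, 4))
  b <- corr_bundle(vals, z)
  res <- protein_covariate_correlation(b, "t_tau", min_n = 4)
  expect_equal(res$r, c(1, -1, 0.8), tolerance = 1e-12)
  expect_lt(res$p_value[1], 1e-10)
  # r = 0.8, n = 4: t = 0.8 * sqrt(2 / 0.36) = 1.8856, p ~ 0.1999
  expect_equal(res$p_value[3], 0.2, tolerance = 1e-3)
  ct <- cor.test(vals[3, ], z)
  expect_equal(res$p_value[3], ct$p.value, tolerance = 1e-12)
  # too few complete pairs -> untestable
  vals2 <- vals; vals2[1, 1:2] <- NA
  res2 <- protein_covariate_correlation(corr_bundle(vals2, z), "t_tau",
                                        min_n = 4)
  expect_true(is.na(res2$r[1]) && is.na(res2$p_value[1]))
})

test_that("BH adjustment matches the step-up rule and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # brute-force step-up oracle on random vectors + monotonicity
  step_up <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n); out[o] <- pmin(q, 1); out
  }
  withr::with_seed(51, {
    for (i in 1:20) {
      p <- runif(sample(3:50, 1))
      expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
      expect_true(all(bh_adjust(p) >= p - 1e-12))
      # decreasing one p never increases any q
      j <- sample(length(p), 1)
      p2 <- p; p2[j] <- p2[j] / 2
      expect_true(all(bh_adjust(p2) <= bh_adjust(p) + 1e-12))
    }
  })
})

test_that("multi-cohort correlates require significance and sign agreement everywhere", {
  ids <- paste0("P", 1:4)
  mk <- function(r, p) tibble::tibble(protein_id = ids, r = r, n = 30L,
                                      p_value = p, q_value = p)
  res <- multi_cohort_correlates(list(
    a = mk(c(0.8, 0.7, 0.6, -0.5), c(0.01, 0.01, 0.20, 0.01)),
    b = mk(c(0.7, -0.6, 0.6, -0.5), c(0.01, 0.01, 0.01, 0.01)),
    c = mk(c(0.9, 0.7, 0.6, -0.4), c(0.01, 0.01, 0.01, 0.01))
  ))
  # P2 flips sign in b, P3 misses significance in a
  expect_setequal(res$protein_id, c("P1", "P4"))
  expect_equal(res$consensus_sign[res$protein_id == "P1"], 1)
  expect_equal(res$consensus_sign[res$protein_id == "P4"], -1)
})

test_that("simulated t-tau couples to the MAPT-like protein", {
  sim <- simulate_study(default_paper_config(), seed = 6)
  b <- sim$bundle
  lg <- log10_transform(b$matrix)
  cohs <- split_cohorts(study_bundle(lg, b$meta))
  res <- lapply(cohs[c("sweden", "berlin")], function(cb)
    protein_covariate_correlation(cb, "t_tau", log10_covariate = TRUE))
  hits <- multi_cohort_correlates(res, alpha = 0.05)
  expect_true(sim$truth$mapt_protein %in% hits$protein_id)
  expect_equal(hits$consensus_sign[hits$protein_id == sim$truth$mapt_protein], 1)
})

test_that("MMSE stratification splits strictly below the cutoff", {
  tb <- tiny_bundle(n_prot = 8, n_ad = 6, n_ctrl = 6, shift_idx = 1:2,
                    shift = 0.6)
  meta <- tb$bundle$meta
  meta$mmse <- c(rep(21L, 6), rep(28L, 6))
  b <- study_bundle(tb$bundle$matrix, meta)
  tab <- mmse_stratified_differential(b, 25, analysis_config(n_permutations = 50))
  expect_equal(max(tab$n_AD), 6L)   # low group = AD samples here
  # shifted proteins separate the strata (shift aligned with AD/low-MMSE)
  expect_true(all(tab$p_value[1:2] < 0.05))
  expect_error(mmse_stratified_differential(b, 50,
                                            analysis_config(n_permutations = 10)),
               "empty stratum")
})

test_that("global correlation map recovers proportional proteins and blocks", {
  withr::with_seed(52, {
    n <- 40
    base <- rnorm(n, 6, 0.1)
    f1 <- rnorm(n); f2 <- rnorm(n)
    vals <- rbind(
      6 + f1, 6 + 2 * f1,           # proportional pair
      t(replicate(4, 6 + f1 + rnorm(n, 0, 0.1))),
      t(replicate(4, 6 + f2 + rnorm(n, 0, 0.1))),
      matrix(rnorm(4 * n, 6, 1), 4, n)
    )
  })
  colnames(vals) <- paste0("s", seq_len(ncol(vals)))
  m <- csfsig:::new_intensity_tbl(
    dplyr::bind_cols(tibble::tibble(protein_id = paste0("P", 1:nrow(vals)),
                                    gene_name = ""),
                     tibble::as_tibble(vals)), "log10")
  map <- global_correlation_map(m, min_overlap = 10, n_clusters = 3)
  expect_equal(map$r[1, 2], 1, tolerance = 1e-12)
  cl <- map$clusters$cluster
  expect_equal(length(unique(cl[1:6])), 1)   # block 1 together
  expect_equal(length(unique(cl[7:10])), 1)  # block 2 together
  expect_false(cl[1] == cl[7])
  # sparse overlap pairs are masked
  vals_na <- vals
  vals_na[1, 4:40] <- NA
  m2 <- csfsig:::new_intensity_tbl(
    dplyr::bind_cols(tibble::tibble(protein_id = paste0("P", 1:nrow(vals)),
                                    gene_name = ""),
                     tibble::as_tibble(vals_na)), "log10")
  map2 <- global_correlation_map(m2, min_overlap = 10, n_clusters = 3)
  expect_true(is.na(map2$r[1, 2]))
})

test_that("covariate-adjusted regression recovers exact fits and scales by IQR", {
  n <- 40
  withr::with_seed(53, {
    age <- round(runif(n, 50, 90))
    sex <- sample(c("male", "female"), n, replace = TRUE)
    status <- rep(c(TRUE, FALSE), each = n / 2)
  })
  y <- 0.5 + 2 * age  # exact linear function of age
  vals <- matrix(y, 1, n)
  colnames(vals) <- paste0("s", 1:n)
  m <- csfsig:::new_intensity_tbl(
    dplyr::bind_cols(tibble::tibble(protein_id = "P1", gene_name = ""),
                     tibble::as_tibble(vals)), "log10")
  meta <- tibble::tibble(sample_id = colnames(vals), cohort = "c1",
                         age = age, sex = sex, t_tau = NA_real_)
  b <- study_bundle(m, meta)
  res <- suppressWarnings(  # exact fit: lm warns about perfect R^2
    covariate_adjusted_regression(b, "status", labels = status,
                                  covariates = c("age", "sex")))
  age_row <- res[res$term == "age", ]
  expect_equal(age_row$estimate, 2, tolerance = 1e-8)
  expect_equal(age_row$r_squared, 1, tolerance = 1e-8)
  expect_equal(age_row$iqr_scaled, 2 * IQR(age), tolerance = 1e-6)
  # IQR override: estimator x 11 years
  res2 <- suppressWarnings(
    covariate_adjusted_regression(b, "status", labels = status,
                                  covariates = c("age", "sex"),
                                  iqr_overrides = c(age = 11)))
  expect_equal(res2$iqr_scaled[res2$term == "age"], 22, tolerance = 1e-6)
  # binary terms carry no IQR scaling
  expect_true(is.na(res$iqr_scaled[res$term == "status"]))
  # collinear design errors with the offending column named
  meta_bad <- meta; meta_bad$age2 <- meta_bad$age
  b_bad <- study_bundle(m, meta_bad)
  expect_error(covariate_adjusted_regression(b_bad, "status", labels = status,
                                             covariates = c("age", "age2")),
               "collinear")
})

test_that("null regression p-values are roughly uniform", {
  withr::with_seed(54, {
    n <- 100
    vals <- matrix(rnorm(20 * n, 6, 1), 20, n)
    colnames(vals) <- paste0("s", 1:n)
    status <- sample(c(TRUE, FALSE), n, replace = TRUE)
    meta <- tibble::tibble(sample_id = colnames(vals), cohort = "c1",
                           age = round(runif(n, 50, 90)),
                           sex = sample(c("male", "female"), n, TRUE))
  })
  m <- csfsig:::new_intensity_tbl(
    dplyr::bind_cols(tibble::tibble(protein_id = paste0("P", 1:20),
                                    gene_name = ""),
                     tibble::as_tibble(vals)), "log10")
  res <- covariate_adjusted_regression(study_bundle(m, meta), "status",
                                       labels = status,
                                       covariates = c("age", "sex"))
  p <- res$p_value[res$term == "status"]
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
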