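test_that("pairwise consistency counts co-significant sign agreement", {
  ids <- paste0("P", 1:20)
  withr::with_seed(31, {
    p <- runif(20, 0, 0.2); dir <- sample(c(-1, 1), 20, replace = TRUE)
  })
  a <- diff_stub(ids, p, dir)
  expect_equal(pairwise_consistency(a, a)$fraction, 1.0)
  flipped <- diff_stub(ids, p, -dir)
  expect_equal(pairwise_consistency(a, flipped)$fraction, 0.0)
  # constructed: 10 co-significant, 7 matching signs
  pa <- rep(0.01, 10); pb <- rep(0.01, 10)
  da <- rep(1, 10); db <- c(rep(1, 7), rep(-1, 3))
  res <- pairwise_consistency(diff_stub(ids[1:10], pa, da),
                              diff_stub(ids[1:10], pb, db))
  expect_equal(res$n_significant_both, 10)
  expect_equal(res$fraction, 0.7)
  # empty overlap: fraction undefined
  none <- pairwise_consistency(diff_stub(ids, rep(0.9, 20), dir),
                               diff_stub(ids, rep(0.9, 20), dir))
  expect_true(is.na(none$fraction))
})

test_that("cross-cohort signature intersects cohorts and flags consistency", {
  ids <- paste0("P", 1:6)
  a <- diff_stub(ids, c(0.01, 0.01, 0.01, 0.5, 0.01, 0.01),
                 c(1, 1, -1, 1, 1, 1))
  b <- diff_stub(ids, c(0.02, 0.01, 0.01, 0.01, 0.5, 0.01),
                 c(1, 1, -1, 1, 1, -1))
  cc <- diff_stub(ids, c(0.03, 0.01, 0.01, 0.01, 0.01, 0.01),
                  c(1, 1, -1, 1, 1, 1))
  sig <- cross_cohort_signature(list(A = a, B = b, C = cc), 0.05, "p")
  # P4 and P5 fail significance somewhere, P6 flips sign
  expect_setequal(sig$protein_id, c("P1", "P2", "P3", "P6"))
  expect_setequal(attr(sig, "signature"), c("P1", "P2", "P3"))
  expect_equal(sig$consensus_direction[sig$protein_id == "P3"], -1)
  expect_false(sig$consistent[sig$protein_id == "P6"])
  # cohort order invariance
  sig2 <- cross_cohort_signature(list(C = cc, A = a, B = b), 0.05, "p")
  expect_setequal(attr(sig2, "signature"), attr(sig, "signature"))
  expect_error(cross_cohort_signature(list(a), 0.05, "p"), ">= 2")
})

test_that("fold-change correlation is 1 for proportional tables", {
  ids <- paste0("P", 1:10)
  withr::with_seed(32, delta <- rnorm(10, 0, 0.2))
  a <- diff_stub(ids, rep(0.01, 10), sign(delta), delta = delta)
  b <- diff_stub(ids, rep(0.01, 10), sign(delta), delta = 2 * delta)
  expect_equal(foldchange_correlation(a, b)$r, 1.0)
  few <- diff_stub(ids[1:2], rep(0.01, 2), c(1, 1))
  expect_error(foldchange_correlation(few, few), "fewer than 3")
})

test_that("Fisher p matches hypergeometric enumeration; OR behaves", {
  # printed worked examples: sample odds ratios round to 37 and 10
  t1 <- fisher_exact_2x2(29, 11, 95, 1349)
  expect_equal(round(t1$odds_ratio), 37)
  expect_equal(t1$odds_ratio, 29 * 1349 / (11 * 95), tolerance = 1e-12)
  expect_lt(t1$fisher_p, 1e-4)
  t2 <- fisher_exact_2x2(26, 12, 502, 2335)
  expect_equal(round(t2$odds_ratio), 10)
  expect_lt(t2$fisher_p, 1e-4)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$odds_ratio, 1)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$fisher_p, 1)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "positive total")
  # random tables vs the enumeration oracle
  withr::with_seed(33, {
    for (i in 1:80) {
      cells <- as.integer(rmultinom(1, sample(4:50, 1), runif(4, 0.1, 1)))
      got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
      expect_equal(got$fisher_p,
                   oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-12)
    }
  })
  # OR invariant under transposing rows+columns together; reciprocal under
  # swapping one margin
  expect_equal(fisher_exact_2x2(7, 3, 2, 9)$odds_ratio,
               fisher_exact_2x2(9, 2, 3, 7)$odds_ratio)
  expect_equal(fisher_exact_2x2(7, 3, 2, 9)$odds_ratio,
               1 / fisher_exact_2x2(3, 7, 9, 2)$odds_ratio)
  # zero cell triggers the Haldane correction
  h <- fisher_exact_2x2(5, 0, 3, 9)
  expect_true(h$haldane_corrected)
  expect_equal(h$odds_ratio, (5.5 * 9.5) / (0.5 * 3.5))
})

test_that("cross-study overlap builds the printed contingency table", {
  # external universe of 2875 proteins, 528 significant, 38 matched
  # signature proteins of which 26 overlap the significant set
  ext_ids <- sprintf("E%04d", 1:2875)
  significant <- rep(FALSE, 2875)
  significant[1:528] <- TRUE
  withr::with_seed(34, delta_ext <- rnorm(2875, 0, 0.1))
  external <- tibble::tibble(protein_id = ext_ids, gene_name = "",
                             significant = significant, delta = delta_ext)
  sig_ids <- c(ext_ids[1:26], ext_ids[600:611])  # 26 significant + 12 not
  sig <- tibble::tibble(protein_id = sig_ids, gene_name = "",
                        delta_log10 = delta_ext[match(sig_ids, ext_ids)])
  res <- cross_study_overlap(sig, external)
  expect_equal(res$n_matched, 38)
  expect_equal(res$n_overlap, 26)
  ct <- res$contingency
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(26, 12, 502, 2335))
  expect_equal(round(ct$odds_ratio), 10)
  expect_equal(res$fc_r, 1)  # deltas copied from the external table
  # gene-name fallback matching
  sig_gene <- tibble::tibble(protein_id = "nomatch", gene_name = "GENE1",
                             delta_log10 = 0.1)
  ext2 <- tibble::tibble(protein_id = c("x1", "x2"),
                         gene_name = c("GENE1", "GENE2"),
                         significant = c(TRUE, FALSE), delta = c(0.1, 0))
  expect_equal(cross_study_overlap(sig_gene, ext2)$n_matched, 1)
  expect_error(cross_study_overlap(
    tibble::tibble(protein_id = "zz", gene_name = ""), ext2), "matched")
})

test_that("heat-map clustering merges identical groups first and separates effects", {
  withr::with_seed(35, prof <- tibble::tibble(
    protein_id = paste0("P", 1:12),
    ad1 = rnorm(12), ctrl1 = rnorm(12)
  ))
  prof$ad2 <- prof$ad1  # identical group
  hm <- cluster_heatmap(prof)
  merge1 <- hm$group_hclust$merge[1, ]
  expect_true(all(merge1 < 0))  # two singleton leaves merge first
  expect_setequal(colnames(prof)[-1][-merge1], c("ad1", "ad2"))
  expect_equal(hm$group_hclust$height[1], 0, tolerance = 1e-12)
  # permuting protein order preserves merge heights
  perm <- c(4:12, 1:3)
  hm2 <- cluster_heatmap(prof[perm, ])
  expect_equal(sort(hm2$protein_hclust$height),
               sort(hm$protein_hclust$height), tolerance = 1e-12)
  expect_error(cluster_heatmap(prof[1, ]), ">= 2")
})

test_that("strong simulated effects cluster AD groups away from controls", {
  tb1 <- tiny_bundle(n_prot = 30, n_ad = 10, n_ctrl = 10, shift_idx = 1:10,
                     shift = 0.4, cohort = "c1", seed = 41)
  tb2 <- tiny_bundle(n_prot = 30, n_ad = 10, n_ctrl = 10, shift_idx = 1:10,
                     shift = 0.4, cohort = "c2", seed = 42)
  meta <- dplyr::bind_rows(tb1$bundle$meta, tb2$bundle$meta)
  m <- dplyr::inner_join(tibble::as_tibble(tb1$bundle$matrix),
                         tibble::as_tibble(tb2$bundle$matrix),
                         by = c("protein_id", "gene_name"))
  mat <- csfsig:::new_intensity_tbl(m, "log10")
  z <- zscore_proteins(study_bundle(mat, meta), "within_cohort")
  groups <- paste(meta$cohort, meta$group_label, sep = "_")
  prof <- group_median_profile(z, groups)
  hm <- cluster_heatmap(prof)
  # the top split puts the two AD groups on one side
  k2 <- cutree(hm$group_hclust, 2)
  expect_equal(length(unique(k2[grep("_AD", names(k2))])), 1)
  expect_true(all(k2[grep("_AD", names(k2))] != k2[grep("ctrl", names(k2))]))
})
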