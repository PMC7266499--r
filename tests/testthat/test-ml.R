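test_that("decision tree handles separable, XOR and pure inputs", {
  x1 <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
               dimnames = list(NULL, "f1"))
  y1 <- c(0, 0, 0, 1, 1, 1)
  t1 <- fit_decision_tree(x1, y1, max_depth = 1)
  expect_equal(sum(!is.na(t1$nodes$feature)), 1)
  expect_equal(predict(t1, x1, type = "class"), y1)
  # XOR needs depth 2
  xx <- cbind(f1 = c(0, 0, 1, 1), f2 = c(0, 1, 0, 1))
  yy <- c(0, 1, 1, 0)
  tx1 <- fit_decision_tree(xx, yy, max_depth = 1)
  expect_lt(mean(predict(tx1, xx, type = "class") == yy), 1)
  tx2 <- fit_decision_tree(xx, yy, max_depth = 2)
  expect_equal(predict(tx2, xx, type = "class"), yy)
  # pure input: single leaf
  tp <- fit_decision_tree(x1, rep(1, 6), max_depth = 3)
  expect_equal(nrow(tp$nodes), 1)
  expect_error(fit_decision_tree(x1[0, , drop = FALSE], numeric()), "empty")
  expect_error(fit_decision_tree(matrix(NA_real_, 2, 1), c(0, 1)), "imputed")
})

test_that("tree fits are deterministic and respect the tie-break rule", {
  withr::with_seed(71, {
    x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- as.integer(x[, 2] + 0.3 * rnorm(50) > 0)
  })
  ta <- fit_decision_tree(x, y, max_depth = 3)
  tb <- fit_decision_tree(x, y, max_depth = 3)
  expect_identical(ta$nodes, tb$nodes)
  # duplicated feature: deterministic tie-break picks the lower index
  xd <- cbind(f1 = x[, 2], f2 = x[, 2])
  td <- fit_decision_tree(xd, y, max_depth = 1)
  expect_equal(td$nodes$feature[1], 1L)
})

test_that("minimum depth search reports depth, features and failures", {
  x1 <- matrix(c(1:6), ncol = 1, dimnames = list(NULL, "f1"))
  res <- min_depth_for_full_training_accuracy(x1, c(0, 0, 0, 1, 1, 1))
  expect_equal(res$depth, 1)
  expect_equal(res$features, "f1")
  # conflicting duplicates make accuracy 1 unreachable
  xc <- matrix(c(1, 1, 2), ncol = 1, dimnames = list(NULL, "f1"))
  expect_error(min_depth_for_full_training_accuracy(xc, c(0, 1, 1), 4),
               "not reached")
})

test_that("feature-rank stability finds deterministic roots and splits ties", {
  x <- cbind(good = c(1, 2, 3, 10, 11, 12), noise = c(5, 1, 4, 2, 6, 3))
  y <- c(0, 0, 0, 1, 1, 1)
  st <- feature_rank_stability(x, y, n_repeats = 25, seed = 1)
  expect_equal(st$rank1_freq[st$feature == "good"], 1)
  # two identical features share rank 1 through random tie-breaking
  xd <- cbind(a = x[, 1], b = x[, 1])
  std <- feature_rank_stability(xd, y, n_repeats = 60, seed = 2)
  expect_equal(sum(std$rank1_freq), 1)
  expect_true(all(std$rank1_freq > 0.2))
  st1 <- feature_rank_stability(x, y, n_repeats = 1, seed = 3)
  expect_true(all(st1$rank1_freq %in% c(0, 1)))
})

test_that("feature tables select proteins and impute as asked", {
  tb <- tiny_bundle(n_prot = 5, n_ad = 4, n_ctrl = 4)
  m <- tb$bundle$matrix
  vals <- intensity_values(m)
  vals[2, 1] <- NA
  z <- csfsig:::set_intensity_values(m, vals)
  attr(z, "scale") <- "zscore"
  ft <- prepare_feature_table(z, c("pr02", "pr04"), impute_zero = TRUE)
  expect_equal(dim(ft), c(8, 2))
  expect_equal(ft[1, "pr02"], 0)
  ft_na <- prepare_feature_table(z, c("pr02", "pr04"), impute_zero = FALSE)
  expect_true(is.na(ft_na[1, "pr02"]))
  expect_error(prepare_feature_table(z, character()), "empty")
  expect_error(prepare_feature_table(z, "nope"), "nope")
})

test_that("ROC/AUC equals the pairwise concordance oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(1:10, c(rep(0, 5), rep(1, 5)))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  auc_oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  withr::with_seed(72, {
    for (i in 1:25) {
      n <- sample(10:200, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
      expect_equal(roc_auc(s, y)$auc, auc_oracle(s, y), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(73, {
    y <- rbinom(100, 1, 0.45)
    s <- y * 0.8 + rnorm(100)
  })
  expect_equal(roc_auc(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("confusion metrics reproduce the printed study performance", {
  m <- confusion_metrics(72, 16, 95, 14)
  expect_equal(round(m$sensitivity, 2), 0.82)
  expect_equal(round(m$specificity, 2), 0.87)
  expect_equal(round(m$accuracy, 2), 0.85)
  expect_equal(confusion_metrics(10, 0, 10, 0),
               tibble::tibble(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_equal(unlist(confusion_metrics(0, 10, 10, 0)),
               c(sensitivity = 0, specificity = 1, accuracy = 0.5))
  expect_error(confusion_metrics(0, 0, 5, 5), "invalid")
})

test_that("k-fold evaluation partitions samples and scores separable data", {
  withr::with_seed(74, {
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    x <- cbind(f1 = y * 3 + rnorm(n, 0, 0.1), f2 = rnorm(n))
  })
  rep <- kfold_evaluate(x, y, config = ml_config(k_folds = 5, seed = 4,
                                                 backend = "tree"))
  expect_equal(sort(unique(rep$predictions$fold)), 1:5)
  expect_equal(tabulate(rep$predictions$fold), rep(12L, 5))  # each sample once
  expect_equal(rep$mean_auc, 1)
  expect_equal(rep$metrics$accuracy, 1)
  g <- glance(rep)
  expect_equal(g$tp + g$fn, 30)
  expect_equal(nrow(tidy(rep)), 5)
})

test_that("xgboost backend beats chance on signal and stays near 0.5 on noise", {
  withr::with_seed(75, {
    n <- 120
    y <- rep(c(0, 1), each = n / 2)
    x <- cbind(f1 = y + rnorm(n, 0, 0.5), f2 = rnorm(n), f3 = rnorm(n))
    y_null <- sample(y)
  })
  rep_sig <- kfold_evaluate(x, y, config = ml_config(seed = 5))
  expect_gt(rep_sig$mean_auc, 0.85)
  rep_null <- kfold_evaluate(x, y_null, config = ml_config(seed = 5))
  expect_lt(abs(rep_null$mean_auc - 0.5), 0.15)
})

test_that("iterative feature addition finds the plateau", {
  withr::with_seed(76, {
    n <- 80
    y <- rep(c(0, 1), each = n / 2)
    x <- cbind(info = y * 3 + rnorm(n, 0.1), n1 = rnorm(n), n2 = rnorm(n))
  })
  cfg <- ml_config(k_folds = 4, seed = 6, backend = "tree",
                   plateau_epsilon = 0.01)
  res <- iterative_feature_addition(x, y, c("info", "n1", "n2"), cfg)
  expect_equal(res$selected_count, 1)
  cfg_big <- ml_config(k_folds = 4, seed = 6, backend = "tree",
                       plateau_epsilon = 1)
  expect_equal(iterative_feature_addition(x, y, colnames(x),
                                          cfg_big)$selected_count, 1)
  expect_error(iterative_feature_addition(x, y, character(), cfg), "empty")
})
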