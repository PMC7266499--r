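# Axis-aligned CART-style decision tree with Gini impurity, exhaustive best
# splits, and controlled tie-breaking. Hand-rolled because the feature-rank
# stability resampling needs (a) deterministic tie-breaks (lowest feature
# index, then lowest threshold) and (b) optional randomized tie-breaking,
# neither of which off-the-shelf tree learners expose.

gini_impurity <- function(pos, n) {
  p <- pos / n
  1 - p^2 - (1 - p)^2
}

# Best split of one node. Returns NULL when no split reduces impurity.
# On ties within 1e-12 of the best decrease: deterministic -> lowest
# feature index then lowest threshold; random -> uniform choice.
best_split <- function(x, y, randomize = FALSE) {
  n <- length(y)
  parent <- n * gini_impurity(sum(y), n)
  cand <- list()
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    ord <- order(xj)
    xs <- xj[ord]; ys <- y[ord]
    cut_ok <- which(diff(xs) > 0)
    if (!length(cut_ok)) next
    cum_pos <- cumsum(ys)
    i <- cut_ok
    left_n <- i; right_n <- n - i
    left_pos <- cum_pos[i]; right_pos <- sum(y) - left_pos
    weighted <- left_n * gini_impurity(left_pos, left_n) +
      right_n * gini_impurity(right_pos, right_n)
    dec <- parent - weighted
    best <- max(dec)
    # zero-decrease splits are kept: greedy Gini gains nothing at the root
    # of XOR-like patterns, yet deeper splits resolve them
    if (best < -1e-12) next
    at <- i[dec >= best - 1e-12]
    cand[[length(cand) + 1]] <- tibble::tibble(
      feature = j, threshold = (xs[at] + xs[at + 1]) / 2,
      decrease = dec[dec >= best - 1e-12]
    )
  }
  if (!length(cand)) return(NULL)
  cand <- dplyr::bind_rows(cand)
  top <- max(cand$decrease)
  cand <- cand[cand$decrease >= top - 1e-12, , drop = FALSE]
  pick <- if (randomize) sample.int(nrow(cand), 1) else 1L
  cand <- cand[order(cand$feature, cand$threshold), ]
  if (randomize) cand <- cand[pick, , drop = FALSE]
  as.list(cand[1, ])
}

#' Fit an axis-aligned decision tree (Gini impurity, best splits)
#'
#' Grows a binary classification tree to `max_depth`, choosing at each node
#' the (feature, threshold) pair with the largest Gini impurity decrease.
#' Equal-quality splits break deterministically by lowest feature index and
#' then lowest threshold, or uniformly at random when
#' `tie_break = "random"` (used by the stability resampling). With a fixed
#' seed the fit is fully deterministic.
#'
#' @param x Numeric matrix, samples x features, no missing values; column
#'   names are feature names.
#' @param y Binary labels (logical or 0/1), at least one sample per class
#'   for a split to be attempted.
#' @param max_depth Maximum depth (root splits at depth 1).
#' @param tie_break `"deterministic"` or `"random"`.
#' @return An object of class `csf_tree` with a `nodes` tibble
#'   (`id`, `depth`, `feature`, `threshold`, `left`, `right`, `n`, `prob`,
#'   `decrease`).
#' @export
fit_decision_tree <- function(x, y, max_depth = 6,
                              tie_break = c("deterministic", "random")) {
  tie_break <- match.arg(tie_break)
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty training data", call. = FALSE)
  if (anyNA(x)) stop("tree features must be imputed (no NA)", call. = FALSE)
  y <- as.integer(as.logical(y))
  nodes <- list()
  grow <- function(idx, depth) {
    id <- length(nodes) + 1L
    node <- list(id = id, depth = depth, feature = NA_integer_,
                 threshold = NA_real_, left = NA_integer_,
                 right = NA_integer_, n = length(idx),
                 prob = mean(y[idx]), decrease = NA_real_)
    nodes[[id]] <<- node
    pure <- node$prob %in% c(0, 1)
    if (pure || depth > max_depth) return(id)
    sp <- best_split(x[idx, , drop = FALSE], y[idx],
                     randomize = tie_break == "random")
    if (is.null(sp)) return(id)
    go_left <- x[idx, sp$feature] <= sp$threshold
    nodes[[id]]$feature <<- sp$feature
    nodes[[id]]$threshold <<- sp$threshold
    nodes[[id]]$decrease <<- sp$decrease
    nodes[[id]]$left <<- grow(idx[go_left], depth + 1L)
    nodes[[id]]$right <<- grow(idx[!go_left], depth + 1L)
    id
  }
  grow(seq_len(nrow(x)), 1L)
  nodes <- dplyr::bind_rows(lapply(nodes, tibble::as_tibble))
  structure(list(nodes = nodes, feature_names = colnames(x),
                 max_depth = max_depth),
            class = "csf_tree")
}

#' @export
print.csf_tree <- function(x, ...) {
  splits <- x$nodes[!is.na(x$nodes$feature), ]
  cat("# Decision tree:", nrow(splits), "split(s), depth",
      max(x$nodes$depth) - 1L, "\n")
  invisible(x)
}

#' Predict with a decision tree
#'
#' @param object A `csf_tree`.
#' @param newdata Numeric matrix with the training feature columns.
#' @param type `"prob"` (leaf class-1 frequency) or `"class"`.
#' @param ... Unused.
#' @return Numeric vector of probabilities or 0/1 classes.
#' @export
predict.csf_tree <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  nd <- object$nodes
  out <- vapply(seq_len(nrow(newdata)), function(i) {
    id <- 1L
    while (!is.na(nd$feature[id])) {
      id <- if (newdata[i, nd$feature[id]] <= nd$threshold[id]) {
        nd$left[id]
      } else {
        nd$right[id]
      }
    }
    nd$prob[id]
  }, 0)
  if (type == "class") as.numeric(out >= 0.5) else out
}

# Features in tree order: root first, then by level, within a level by
# impurity decrease (largest first). Returns feature name vector.
tree_feature_order <- function(tree) {
  splits <- tree$nodes[!is.na(tree$nodes$feature), ]
  splits <- splits[order(splits$depth, -splits$decrease, splits$id), ]
  tree$feature_names[unique(splits$feature)]
}

#' @describeIn fit_decision_tree Tidy per-node summary of a fitted tree.
#' @param x A `csf_tree`.
#' @param ... Unused.
#' @export
tidy.csf_tree <- function(x, ...) {
  nd <- x$nodes
  nd$feature_name <- ifelse(is.na(nd$feature), NA_character_,
                            x$feature_names[nd$feature])
  nd
}
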