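# Compact random-forest classifier (bagged CART, Gini splitting, random
# feature subsets). Written in-package because no tree ensemble package is
# available in the target environment; the surface is the minimal one the
# blood-matrix classification needs: class-probability prediction for AUROC.

# Best Gini split for one feature. Returns c(score, cut) or NULL.
.best_cut <- function(xj, yint, K) {
  o <- order(xj)
  xs <- xj[o]; ys <- yint[o]
  n <- length(xs)
  if (n < 2L || xs[1L] == xs[n]) return(NULL)
  cum <- vapply(seq_len(K), function(k) cumsum(ys == k), numeric(n))
  cumL <- cum[-n, , drop = FALSE]
  tot <- cum[n, ]
  nl <- seq_len(n - 1L)
  nr <- n - nl
  giniL <- 1 - rowSums((cumL / nl)^2)
  giniR <- 1 - rowSums((sweep(-cumL, 2L, tot, "+") / nr)^2)
  score <- (nl * giniL + nr * giniR) / n
  valid <- xs[-n] < xs[-1L]
  if (!any(valid)) return(NULL)
  score[!valid] <- Inf
  i <- which.min(score)
  c(score[i], (xs[i] + xs[i + 1L]) / 2)
}

.grow_tree <- function(x, yint, K, mtry, min_split) {
  n <- length(yint)
  prob <- tabulate(yint, K) / n
  if (n < min_split || max(prob) == 1)
    return(list(leaf = TRUE, prob = prob))
  node_gini <- 1 - sum(prob^2)
  feats <- sample.int(ncol(x), mtry)
  best <- NULL
  for (j in feats) {
    cut <- .best_cut(x[, j], yint, K)
    if (is.null(cut)) next
    if (is.null(best) || cut[1L] < best$score)
      best <- list(score = cut[1L], var = j, cut = cut[2L])
  }
  if (is.null(best) || best$score >= node_gini - 1e-12)
    return(list(leaf = TRUE, prob = prob))
  left <- x[, best$var] <= best$cut
  list(leaf = FALSE, var = best$var, cut = best$cut,
       left = .grow_tree(x[left, , drop = FALSE], yint[left], K, mtry,
                         min_split),
       right = .grow_tree(x[!left, , drop = FALSE], yint[!left], K, mtry,
                          min_split))
}

.tree_prob <- function(tree, x) {
  out <- matrix(NA_real_, nrow(x), length(.leaf_prob_len(tree)))
  assign_rows <- function(node, rows) {
    if (!length(rows)) return()
    if (node$leaf) {
      out[rows, ] <<- matrix(node$prob, length(rows),
                             length(node$prob), byrow = TRUE)
      return()
    }
    left <- x[rows, node$var] <= node$cut
    assign_rows(node$left, rows[left])
    assign_rows(node$right, rows[!left])
  }
  assign_rows(tree, seq_len(nrow(x)))
  out
}

.leaf_prob_len <- function(node) {
  while (!node$leaf) node <- node$left
  node$prob
}

#' Fit a random-forest classifier
#'
#' Bagged fully grown CART trees with Gini splitting and `mtry` random
#' candidate features per node; leaves store class proportions and
#' prediction averages them across trees.
#'
#' @param x numeric matrix (samples x features).
#' @param y factor of class labels.
#' @param ntree number of trees.
#' @param mtry candidate features per split (default `floor(sqrt(p))`).
#' @param min_split minimum node size eligible for splitting.
#' @return An `rf_model` list.
#' @export
rf_fit <- function(x, y, ntree = 200L, mtry = NULL, min_split = 2L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) .stopf("x rows and y length differ")
  if (nlevels(y) < 2L) .stopf("need at least two classes")
  K <- nlevels(y)
  yint <- as.integer(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    boot <- sample.int(nrow(x), nrow(x), replace = TRUE)
    trees[[t]] <- .grow_tree(x[boot, , drop = FALSE], yint[boot], K, mtry,
                             min_split)
  }
  structure(list(trees = trees, levels = levels(y), mtry = mtry),
            class = "rf_model")
}

#' @rdname rf_fit
#' @param model an `rf_model`.
#' @param newdata numeric matrix of samples to classify.
#' @return [rf_predict()]: matrix of class probabilities (samples x classes).
#' @export
rf_predict <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  acc <- matrix(0, nrow(newdata), length(model$levels))
  for (tree in model$trees) acc <- acc + .tree_prob(tree, newdata)
  acc <- acc / length(model$trees)
  colnames(acc) <- model$levels
  acc
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling.
#'
#' @param scores numeric scores, higher = more positive.
#' @param positive logical vector marking the positive class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) .stopf("need both classes for AUROC")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
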