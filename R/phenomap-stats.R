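# Blood-matrix pheno-mapping statistics: paired Wilcoxon dissimilarity
# counts with Benjamini-Hochberg correction, Friedman time-point tests,
# person-held-out random-forest classification with AUROC, PCA, pooled class
# SDs and the ceramide/PC marker ratios.

# Align a concentration matrix with its design; rownames are sample ids.
.match_design <- function(conc, design) {
  if (is.null(rownames(conc))) .stopf("concentration matrix needs sample ids as rownames")
  idx <- match(rownames(conc), design$sample_id)
  if (any(is.na(idx)))
    .stopf("samples missing from design: %s",
           paste(rownames(conc)[is.na(idx)], collapse = ", "))
  if (any(conc < 0, na.rm = TRUE)) .stopf("negative concentrations")
  design[idx, , drop = FALSE]
}

# Two-sided Wilcoxon signed-rank p-value for paired differences.
# "pratt" keeps zero differences in the ranking (normal approximation with
# zero and tie corrections); "wilcoxon" drops them and delegates to
# stats::wilcox.test (exact when possible).
.signed_rank_p <- function(d, zero_method = "pratt") {
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    if (length(d) == 0L) return(1)
    return(suppressWarnings(stats::wilcox.test(d)$p.value))
  }
  n <- length(d)
  nz <- sum(d == 0)
  if (nz == n) return(1)
  r <- rank(abs(d))
  T_plus <- sum(r[d > 0])
  mn <- (n * (n + 1) - nz * (nz + 1)) / 4
  v <- (n * (n + 1) * (2 * n + 1) - nz * (nz + 1) * (2 * nz + 1)) / 24
  ties <- table(r[d != 0])
  v <- v - sum(ties^3 - ties) / 48
  if (v <= 0) return(1)
  z <- (T_plus - mn - sign(T_plus - mn) * 0.5) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

#' Pairwise Wilcoxon dissimilarity between blood matrices
#'
#' For every pair of matrices, samples are paired by (individual, time
#' point) and a two-sided Wilcoxon signed-rank test is run per lipid;
#' Benjamini-Hochberg correction is applied across lipids within the pair and
#' the dissimilarity entry is the count of q-values below `alpha` (0 = the
#' two matrices are indistinguishable).
#'
#' @param conc samples x lipids concentration matrix (sample ids as
#'   rownames).
#' @param design study design data frame.
#' @param alpha significance level after correction.
#' @param zero_method zero-difference handling: `"pratt"` (kept in the
#'   ranking, default) or `"wilcoxon"` (dropped).
#' @return A list with `dissimilarity` (symmetric matrix of rejection
#'   counts, zero diagonal), `tests` (per pair and lipid: p and q values).
#' @export
pairwise_wilcoxon <- function(conc, design, alpha = 0.05,
                              zero_method = c("pratt", "wilcoxon")) {
  zero_method <- match.arg(zero_method)
  des <- .match_design(conc, design)
  mats <- sort(unique(des$matrix))
  if (length(mats) < 2L) .stopf("need at least two matrices")
  D <- matrix(0L, length(mats), length(mats), dimnames = list(mats, mats))
  tests <- list()
  key <- paste(des$individual, des$time_point, sep = "|")
  for (a in seq_along(mats)) for (b in seq_along(mats)) {
    if (b <= a) next
    ia <- which(des$matrix == mats[a]); ib <- which(des$matrix == mats[b])
    ka <- key[ia]; kb <- key[ib]
    miss <- c(setdiff(ka, kb), setdiff(kb, ka))
    if (length(miss))
      .stopf("unpaired (individual, time_point) keys between %s and %s: %s",
             mats[a], mats[b], paste(unique(miss), collapse = ", "))
    ib <- ib[match(ka, kb)]
    p <- vapply(seq_len(ncol(conc)), function(j)
      .signed_rank_p(conc[ia, j] - conc[ib, j], zero_method), numeric(1L))
    q <- stats::p.adjust(p, method = "BH")
    D[a, b] <- D[b, a] <- sum(q < alpha)
    tests[[paste(mats[a], mats[b], sep = " vs ")]] <-
      data.frame(lipid = colnames(conc) %||% seq_len(ncol(conc)),
                 p = p, q = q, stringsAsFactors = FALSE)
  }
  list(dissimilarity = D, tests = tests)
}

#' Friedman test for time-point stability
#'
#' Per lipid, a Friedman test of the time points with (individual, matrix)
#' combinations as blocks; every block must be observed at every time point.
#' Benjamini-Hochberg correction is applied across lipids.
#'
#' @inheritParams pairwise_wilcoxon
#' @return A data frame per lipid with `statistic`, `p`, `q`, plus the
#'   rejection count at `alpha` as the `n_rejected` attribute.
#' @export
friedman_timepoints <- function(conc, design, alpha = 0.05) {
  des <- .match_design(conc, design)
  block <- paste(des$individual, des$matrix, sep = "|")
  tp <- as.character(des$time_point)
  tps <- sort(unique(tp))
  blocks <- sort(unique(block))
  idx <- matrix(NA_integer_, length(blocks), length(tps),
                dimnames = list(blocks, tps))
  for (i in seq_along(block)) idx[block[i], tp[i]] <- i
  if (any(is.na(idx)))
    .stopf("incomplete blocks: every (individual, matrix) needs every time point")
  res <- lapply(seq_len(ncol(conc)), function(j) {
    m <- matrix(conc[as.vector(idx), j], nrow(idx), ncol(idx))
    ft <- suppressWarnings(stats::friedman.test(m))
    c(statistic = unname(ft$statistic), p = ft$p.value)
  })
  out <- data.frame(lipid = colnames(conc) %||% seq_len(ncol(conc)),
                    statistic = vapply(res, `[[`, numeric(1L), "statistic"),
                    p = vapply(res, `[[`, numeric(1L), "p"),
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  attr(out, "n_rejected") <- sum(out$q < alpha, na.rm = TRUE)
  out
}

#' Random-forest classification of blood matrices with person-held-out folds
#'
#' Cross-validation uses one fold per individual (leave-one-individual-out)
#' so that no person contributes to both training and test data, repeated
#' `n_repeats` times with distinct classifier seeds (the paper-style
#' "3 x 4" scheme for 3 repeats and 4 individuals). Multiclass mode trains
#' one forest on all matrices and reports the macro-averaged one-vs-rest
#' AUROC over the pooled held-out probabilities; pairwise mode trains one
#' forest per matrix pair and reports the binary AUROC per pair.
#'
#' @inheritParams pairwise_wilcoxon
#' @param mode `"multiclass"` or `"pairwise"`.
#' @param n_repeats cross-validation repeats (classifier seed varies).
#' @param seed base random seed.
#' @param ntree,mtry forest size passed to [rf_fit()].
#' @return A list with `auroc` (data frame: repeat, pair/overall, AUROC),
#'   `mean_auroc` (named by pair, or scalar for multiclass) and
#'   `fold_report` proving that train and test individuals are disjoint in
#'   every fold of every repeat.
#' @export
rf_classify <- function(conc, design, mode = c("multiclass", "pairwise"),
                        n_repeats = 3L, seed = 1L, ntree = 200L, mtry = NULL) {
  mode <- match.arg(mode)
  des <- .match_design(conc, design)
  y_all <- as.character(des$matrix)
  indiv <- as.character(des$individual)
  folds <- sort(unique(indiv))
  if (length(folds) < 2L) .stopf("need at least two individuals")
  per_class <- tapply(indiv, y_all, function(i) length(unique(i)))
  if (any(per_class < 2L))
    .stopf("class present in only one individual: %s",
           paste(names(per_class)[per_class < 2L], collapse = ", "))
  fold_report <- list()
  audit <- function(rep_i, fold, train_idx, test_idx) {
    fold_report[[length(fold_report) + 1L]] <<- data.frame(
      rep = rep_i, fold = fold,
      n_train = length(train_idx), n_test = length(test_idx),
      leakage = length(intersect(unique(indiv[train_idx]),
                                 unique(indiv[test_idx]))) > 0L,
      stringsAsFactors = FALSE)
  }
  run_cv <- function(rows, y, rep_i) {
    prob <- matrix(NA_real_, length(rows), length(unique(y)),
                   dimnames = list(NULL, sort(unique(y))))
    for (fold in unique(indiv[rows])) {
      test <- which(indiv[rows] == fold)
      train <- which(indiv[rows] != fold)
      audit(rep_i, fold, rows[train], rows[test])
      model <- rf_fit(conc[rows[train], , drop = FALSE],
                      factor(y[train], levels = sort(unique(y))),
                      ntree = ntree, mtry = mtry)
      prob[test, model$levels] <- rf_predict(model,
                                             conc[rows[test], , drop = FALSE])
    }
    prob
  }
  results <- list()
  for (rep_i in seq_len(n_repeats)) {
    set.seed(seed + rep_i - 1L)
    if (mode == "multiclass") {
      rows <- seq_len(nrow(conc))
      prob <- run_cv(rows, y_all, rep_i)
      per_class_auc <- vapply(colnames(prob), function(cl)
        auroc(prob[, cl], y_all == cl), numeric(1L))
      results[[length(results) + 1L]] <-
        data.frame(rep = rep_i, pair = "multiclass",
                   auroc = mean(per_class_auc), stringsAsFactors = FALSE)
    } else {
      mats <- sort(unique(y_all))
      for (a in seq_along(mats)) for (b in seq_along(mats)) {
        if (b <= a) next
        rows <- which(y_all %in% c(mats[a], mats[b]))
        prob <- run_cv(rows, y_all[rows], rep_i)
        results[[length(results) + 1L]] <- data.frame(
          rep = rep_i, pair = paste(mats[a], mats[b], sep = " vs "),
          auroc = auroc(prob[, mats[a]], y_all[rows] == mats[a]),
          stringsAsFactors = FALSE)
      }
    }
  }
  auroc_df <- do.call(rbind, results)
  mean_auroc <- tapply(auroc_df$auroc, auroc_df$pair, mean)
  list(auroc = auroc_df, mean_auroc = mean_auroc,
       fold_report = do.call(rbind, fold_report))
}

#' PCA scores of a concentration matrix
#'
#' Concentrations are log10-transformed (zeros imputed to half the smallest
#' positive value) and column-standardized before the decomposition.
#'
#' @param conc samples x lipids concentration matrix.
#' @param n_components number of score columns to return.
#' @return A list with `scores`, `explained_variance` (fractions over all
#'   components) and `dropped` (constant lipids excluded from the
#'   decomposition).
#' @export
pca_scores <- function(conc, n_components = 2L) {
  conc <- as.matrix(conc)
  if (nrow(conc) < 2L || ncol(conc) < 2L)
    .stopf("need at least 2 samples and 2 lipids")
  if (any(conc < 0, na.rm = TRUE)) .stopf("negative concentrations")
  pos <- conc[conc > 0]
  if (!length(pos)) .stopf("all-zero concentration matrix")
  x <- log10(ifelse(conc == 0, min(pos) / 2, conc))
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0] %||% which(sds == 0)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) < 2L) .stopf("matrix is constant: nothing to decompose")
  x <- scale(x)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  n_components <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev, dropped = dropped)
}

#' Pooled standard deviation
#'
#' `sqrt( sum((n_i - 1) var_i) / sum(n_i - 1) )`.
#'
#' @param variances per-group variances.
#' @param ns per-group observation counts.
#' @return Pooled SD.
#' @export
pooled_sd <- function(variances, ns) {
  if (length(variances) != length(ns)) .stopf("lengths differ")
  w <- ns - 1
  if (sum(w) <= 0) .stopf("no degrees of freedom to pool")
  sqrt(sum(w * variances) / sum(w))
}

#' Pooled per-class SD of time-point variation
#'
#' Per blood matrix and lipid, the variance of the concentrations across that
#' matrix's samples (all time points); variances are pooled across the lipids
#' of each class and the square root reported as the class SD.
#'
#' @inheritParams pairwise_wilcoxon
#' @param class_map named character vector mapping lipid (column) names to
#'   class labels.
#' @return Data frame with `matrix`, `lipid_class`, `pooled_sd`, `n_lipids`.
#'   Classes with no lipids in the matrix are omitted with a warning.
#' @export
pooled_class_sd <- function(conc, design, class_map) {
  des <- .match_design(conc, design)
  lipids <- colnames(conc)
  if (is.null(lipids)) .stopf("concentration matrix needs lipid column names")
  classes <- sort(unique(class_map))
  rows <- list()
  for (m in sort(unique(des$matrix))) {
    sel <- des$matrix == m
    n_i <- sum(sel)
    if (n_i < 2L) .stopf("matrix %s has fewer than 2 samples", m)
    for (cl in classes) {
      members <- lipids[lipids %in% names(class_map)[class_map == cl]]
      if (!length(members)) {
        warning(sprintf("class %s has no lipids in the matrix; omitted", cl))
        next
      }
      v <- apply(conc[sel, members, drop = FALSE], 2L, stats::var)
      rows[[length(rows) + 1L]] <- data.frame(
        matrix = m, lipid_class = cl,
        pooled_sd = pooled_sd(v, rep(n_i, length(v))),
        n_lipids = length(members), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cardiovascular marker-ratio inputs
#'
#' The four ceramide/phosphatidylcholine quantities feeding the published
#' CERT2 risk score (the score's coefficients are not computed here): the
#' molar ratios Cer d18:1_24:1 / Cer d18:1_24:0, Cer d18:1_16:0 / PC 38:5
#' and Cer d18:1_18:0 / PC 14:0_22:6 plus the PC 16:0_16:0 concentration,
#' per sample.
#'
#' @param conc samples x lipids molar concentration matrix with lipid names
#'   as column names.
#' @return Data frame with one row per sample and the four marker columns.
#' @export
marker_ratios <- function(conc) {
  need <- c("Cer d18:1_24:1", "Cer d18:1_24:0", "Cer d18:1_16:0", "PC 38:5",
            "Cer d18:1_18:0", "PC 14:0_22:6", "PC 16:0_16:0")
  missing <- setdiff(need, colnames(conc))
  if (length(missing))
    .stopf("missing species: %s", paste(missing, collapse = ", "))
  denom <- c("Cer d18:1_24:0", "PC 38:5", "PC 14:0_22:6")
  for (d in denom)
    if (any(conc[, d] == 0)) .stopf("zero denominator: %s", d)
  data.frame(
    sample_id = rownames(conc) %||% seq_len(nrow(conc)),
    cer241_cer240 = conc[, "Cer d18:1_24:1"] / conc[, "Cer d18:1_24:0"],
    cer160_pc385 = conc[, "Cer d18:1_16:0"] / conc[, "PC 38:5"],
    cer180_pc140226 = conc[, "Cer d18:1_18:0"] / conc[, "PC 14:0_22:6"],
    pc160160 = conc[, "PC 16:0_16:0"],
    stringsAsFactors = FALSE, check.names = TRUE, row.names = NULL)
}
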