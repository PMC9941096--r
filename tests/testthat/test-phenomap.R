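test_that("pairwise_wilcoxon: identical matrices give a zero entry", {
  des <- paired_design(c("I1", "I2", "I3"), c("t0", "t1", "t2"),
                       c("plasma", "serum"))
  set.seed(41)
  base <- matrix(rlnorm(9 * 20), 9, 20)
  conc <- rbind(base, base)   # serum identical to plasma
  rownames(conc) <- des$sample_id[order(match(des$matrix,
                                              c("plasma", "serum")))]
  colnames(conc) <- sprintf("L%02d", 1:20)
  res <- pairwise_wilcoxon(conc, des)
  expect_equal(res$dissimilarity["plasma", "serum"], 0)
  expect_true(isSymmetric(res$dissimilarity))
  expect_equal(diag(res$dissimilarity), c(plasma = 0, serum = 0))
})

test_that("pairwise_wilcoxon detects planted shifts; BH is a subset of raw", {
  set.seed(42)
  n_ind <- 7; n_tp <- 3; n_lip <- 60; n_shift <- 25
  des <- paired_design(sprintf("I%d", 1:n_ind), sprintf("t%d", 1:n_tp),
                       c("A", "B"))
  n_pair <- n_ind * n_tp
  a <- matrix(rlnorm(n_pair * n_lip), n_pair, n_lip)
  b <- matrix(rlnorm(n_pair * n_lip), n_pair, n_lip)
  b[, seq_len(n_shift)] <- b[, seq_len(n_shift)] * 8   # large effect
  conc <- rbind(a, b)
  rownames(conc) <- c(des$sample_id[des$matrix == "A"],
                      des$sample_id[des$matrix == "B"])
  colnames(conc) <- sprintf("L%02d", seq_len(n_lip))
  res <- pairwise_wilcoxon(conc, des)
  t1 <- res$tests[["A vs B"]]
  hits <- t1$lipid[t1$q < 0.05]
  # essentially all shifted lipids rejected; FDR keeps null leakage tiny
  expect_gte(sum(hits %in% sprintf("L%02d", 1:n_shift)), n_shift - 3)
  expect_lte(sum(!hits %in% sprintf("L%02d", 1:n_shift)), 2)
  # BH rejections are a subset of uncorrected rejections
  expect_true(all(t1$q >= t1$p - 1e-12))
  expect_true(all(which(t1$q < 0.05) %in% which(t1$p < 0.05)))
})

test_that("pairwise_wilcoxon reports missing pairs", {
  des <- paired_design(c("I1", "I2"), c("t0", "t1"), c("A", "B"))
  des <- des[des$sample_id != "I2_B_t1", ]
  conc <- matrix(rlnorm(nrow(des) * 3), nrow(des), 3)
  rownames(conc) <- des$sample_id
  colnames(conc) <- c("L1", "L2", "L3")
  expect_error(pairwise_wilcoxon(conc, des), "I2|t1")
})

test_that("friedman_timepoints: stability, power and block checks", {
  des <- paired_design(sprintf("I%d", 1:4), c("t0", "t1", "t2"),
                       c("plasma", "serum"))
  set.seed(43)
  n <- nrow(des)
  conc <- matrix(rlnorm(n * 10), n, 10)
  colnames(conc) <- sprintf("L%02d", 1:10)
  rownames(conc) <- des$sample_id
  # identical values at all time points -> no rejections
  stable <- conc
  for (i in sprintf("I%d", 1:4)) for (m in c("plasma", "serum")) {
    rows <- des$sample_id[des$individual == i & des$matrix == m]
    stable[rows, ] <- rep(stable[rows[1], ], each = length(rows))
  }
  fr <- friedman_timepoints(stable, des)
  expect_equal(attr(fr, "n_rejected"), 0)

  # one lipid with a strong planted time trend is rejected
  trend <- conc
  t2 <- des$sample_id[des$time_point == "t2"]
  t1 <- des$sample_id[des$time_point == "t1"]
  trend[t1, "L01"] <- trend[t1, "L01"] * 10
  trend[t2, "L01"] <- trend[t2, "L01"] * 100
  fr2 <- friedman_timepoints(trend, des)
  expect_lt(fr2$q[fr2$lipid == "L01"], 0.05)

  expect_error(friedman_timepoints(conc[-1, , drop = FALSE], des[-1, ]),
               "incomplete")
})

test_that("rf_classify separates shifted classes and audits folds", {
  set.seed(44)
  des <- paired_design(sprintf("I%d", 1:4), c("t0", "t1", "t2"),
                       c("A", "B"))
  n <- nrow(des)
  conc <- matrix(rnorm(n * 15), n, 15)
  conc[des$matrix == "B", 1:10] <- conc[des$matrix == "B", 1:10] + 8
  conc <- conc - min(conc)  # keep concentrations non-negative
  rownames(conc) <- des$sample_id
  colnames(conc) <- sprintf("L%02d", 1:15)
  res <- rf_classify(conc, des, mode = "pairwise", n_repeats = 2L,
                     seed = 44, ntree = 60L)
  expect_equal(unname(res$mean_auroc[["A vs B"]]), 1.0)
  expect_false(any(res$fold_report$leakage))
  # the fold partition is exactly the set of individuals, every repeat
  for (r in unique(res$fold_report$rep))
    expect_setequal(res$fold_report$fold[res$fold_report$rep == r],
                    sprintf("I%d", 1:4))

  multi <- rf_classify(conc, des, mode = "multiclass", n_repeats = 1L,
                       seed = 44, ntree = 60L)
  expect_gt(multi$mean_auroc[["multiclass"]], 0.95)

  # a class confined to one individual cannot be cross-validated
  bad <- des
  bad$matrix[bad$individual == "I1" & bad$matrix == "A"] <- "C"
  expect_error(rf_classify(conc, bad), "one individual")
})

test_that("pca_scores standardizes, reports variance and matches eigen", {
  set.seed(45)
  conc <- matrix(rlnorm(5 * 4), 5, 4)
  rownames(conc) <- sprintf("S%d", 1:5)
  colnames(conc) <- sprintf("L%d", 1:4)
  res <- pca_scores(conc, n_components = 2)
  expect_equal(sum(res$explained_variance), 1)

  # oracle: eigendecomposition of the covariance of the transformed matrix
  x <- scale(log10(conc))
  ev <- eigen(stats::cov(x))
  scores_oracle <- x %*% ev$vectors[, 1:2]
  for (j in 1:2)
    expect_equal(abs(res$scores[, j]), abs(scores_oracle[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$explained_variance[1:2] * sum(ev$values),
               ev$values[1:2], tolerance = 1e-8, ignore_attr = TRUE)

  # duplicated sample -> identical score coordinates
  dup <- rbind(conc, conc[3, , drop = FALSE])
  rownames(dup)[6] <- "S3b"
  res2 <- pca_scores(dup)
  expect_equal(res2$scores["S3b", ], res2$scores["S3", ],
               ignore_attr = TRUE)

  expect_error(pca_scores(matrix(1, 4, 3)), "constant")
})

test_that("pooled SD matches the weighted-variance formula", {
  expect_equal(pooled_sd(c(2, 2, 2), c(5, 5, 5)), sqrt(2))
  expect_equal(pooled_sd(c(1, 3), c(6, 6)), sqrt(2))
  set.seed(46)
  v <- runif(10); n <- sample(3:9, 10, replace = TRUE)
  expect_equal(pooled_sd(v, n), sqrt(sum((n - 1) * v) / sum(n - 1)))
})

test_that("pooled_class_sd pools per matrix and class; single lipid = plain SD", {
  des <- paired_design(c("I1", "I2"), c("t0", "t1", "t2"), c("A", "B"))
  set.seed(47)
  conc <- matrix(rlnorm(nrow(des) * 3), nrow(des), 3)
  colnames(conc) <- c("PC a", "PC b", "Cer a")
  rownames(conc) <- des$sample_id
  cmap <- c("PC a" = "PC", "PC b" = "PC", "Cer a" = "Cer")
  res <- pooled_class_sd(conc, des, cmap)
  rows_a <- des$sample_id[des$matrix == "A"]
  v1 <- var(conc[rows_a, "PC a"]); v2 <- var(conc[rows_a, "PC b"])
  expect_equal(res$pooled_sd[res$matrix == "A" & res$lipid_class == "PC"],
               sqrt((v1 + v2) / 2))
  expect_equal(res$pooled_sd[res$matrix == "A" & res$lipid_class == "Cer"],
               sd(conc[rows_a, "Cer a"]))
})

test_that("marker_ratios computes the CERT2 inputs", {
  conc <- matrix(c(2, 4, 3, 6, 5, 2.5, 1.2), 1, 7)
  colnames(conc) <- c("Cer d18:1_24:1", "Cer d18:1_24:0", "Cer d18:1_16:0",
                      "PC 38:5", "Cer d18:1_18:0", "PC 14:0_22:6",
                      "PC 16:0_16:0")
  rownames(conc) <- "S1"
  r <- marker_ratios(conc)
  expect_equal(r$cer241_cer240, 0.5)
  expect_equal(r$cer160_pc385, 0.5)
  expect_equal(r$cer180_pc140226, 2)
  expect_equal(r$pc160160, 1.2)

  expect_error(marker_ratios(conc[, -4, drop = FALSE]), "PC 38:5")
  conc0 <- conc; conc0[, "Cer d18:1_24:0"] <- 0
  expect_error(marker_ratios(conc0), "zero denominator")
})
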