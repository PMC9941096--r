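test_that("fit_calibration recovers exact power-law coefficients", {
  # linear: areaRatio = 2 * concRatio
  m <- fit_calibration(truth_points(2, 1, 100))
  expect_equal(m$c1, 2, tolerance = 1e-12)
  expect_equal(m$c2, 1, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$accuracy, rep(100, 7), tolerance = 1e-9)
  expect_true(all(m$accuracy_ok))

  # power law: areaRatio = 0.5 * concRatio^0.8 -> c2 = 1/0.8 = 1.25
  m2 <- fit_calibration(truth_points(0.5, 1.25, 100))
  expect_equal(m2$c1, 0.5, tolerance = 1e-12)
  expect_equal(m2$c2, 1.25, tolerance = 1e-12)

  expect_error(fit_calibration(truth_points(2, 1, 100)[1:2, ]), "3")
})

test_that("fit_calibration recovers coefficients under 2% noise (median)", {
  # reduced-seed version of the acceptance simulation
  errs <- sapply(1:40, function(s) {
    cfg <- simulation_config(seed = 1000 + s,
                             calibration = list(c1 = 1.2, c2 = 1.1,
                                                conc_is = 100,
                                                conc_es = 5 * 2^(0:6),
                                                noise_cv = 0.02))
    m <- fit_calibration(gen_calibration(cfg)$points)
    c(abs(m$c1 / 1.2 - 1), abs(m$c2 / 1.1 - 1))
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("quantify_multipoint implements the A/B/C arithmetic", {
  m <- fit_calibration(truth_points(1, 1, 50))
  ctx <- quant_context(final_volume = 360, sample_volume = 20)
  abc <- quantify_multipoint(2e5, 1e5, m, ctx, adduct_mass = 900)
  expect_equal(abc[["A"]], 100)    # ratio 2, c1 = 1, c2 = 1, C_IS = 50
  expect_equal(abc[["B"]], 1800)   # x 360/20
  expect_equal(abc[["C"]], 2.0)    # / 900 Da

  # identity point: ratio equal to c1 with c2 = 1 -> A = C_IS
  m2 <- fit_calibration(truth_points(3, 1, 80))
  expect_equal(quantify_multipoint(3e5, 1e5, m2, ctx, 700)[["A"]], 80,
               tolerance = 1e-9)

  expect_error(quantify_multipoint(1e5, 0, m, ctx, 900), "ISTD")
  expect_error(quantify_multipoint(1e5, 1e5, m, ctx, NULL), "adduct_mass")
})

test_that("quantifying the calibration points reproduces nominals", {
  pts <- truth_points(1.7, 1.2, 120)
  m <- fit_calibration(pts)
  ctx <- quant_context()
  back <- sapply(seq_len(nrow(pts)), function(i)
    quantify_multipoint(pts$area_es[i], pts$area_is[i], m, ctx, 800)[["A"]])
  expect_equal(back, pts$conc_es, tolerance = 1e-9)
  expect_equal(m$accuracy, rep(100, nrow(pts)), tolerance = 1e-9)
})

test_that("quantify_onepoint matches its defining arithmetic", {
  cal <- calibration_points(100, 100, 1.5e5, 1e5)  # concRatio 1, areaRatio 1.5
  ctx <- quant_context()
  abc <- quantify_onepoint(3e5, 1e5, cal[1, ], ctx, adduct_mass = 900)
  expect_equal(abc[["A"]], 200)   # m = 1.5, sample ratio 3 -> (3/1.5)*100

  # sample ratio equal to the calibrant ratio -> A = C_ES of the calibrant
  cal2 <- calibration_points(40, 100, 2e5, 1e5)
  abc2 <- quantify_onepoint(2e5, 1e5, cal2[1, ], ctx, adduct_mass = 900)
  expect_equal(abc2[["A"]], 40, tolerance = 1e-12)
})

test_that("one-point equals multi-point on noise-free linear data", {
  pts <- truth_points(2.4, 1, 100)
  m <- fit_calibration(pts)
  ctx <- quant_context()
  set.seed(31)
  areas <- runif(20, 1e4, 1e6)
  istd <- 1e5
  for (k in c(2L, 4L, 6L)) {
    for (a in areas) {
      mp <- quantify_multipoint(a, istd, m, ctx, 850)
      op <- quantify_onepoint(a, istd, pts[k, ], ctx, 850)
      expect_equal(op, mp, tolerance = 1e-12)
    }
  }
})

test_that("llod_lloq implements 3.3 and 10 sigma over slope", {
  expect_equal(llod_lloq(1, 1), c(llod = 3.3, lloq = 10))
  expect_equal(llod_lloq(0, 5), c(llod = 0, lloq = 0))
  expect_equal(llod_lloq(0.2, 4), c(llod = 0.165, lloq = 0.5))
  set.seed(32)
  for (s in runif(10, 0.01, 10)) {
    lim <- llod_lloq(s, runif(1, 0.1, 5))
    expect_equal(lim[["lloq"]] / lim[["llod"]], 10 / 3.3, tolerance = 1e-12)
  }
  expect_error(llod_lloq(1, 0), "slope")
})

test_that("recovery and matrix effect are ratios of group means", {
  r <- recovery_matrix_effect(pre_spike = c(70, 90), post_spike = c(90, 110),
                              neat = c(100, 100))
  expect_equal(r[["recovery_pct"]], 80)
  expect_equal(r[["matrix_effect_pct"]], 100)

  set.seed(33)
  pre <- runif(8, 50, 150); post <- runif(8, 50, 150)
  neat <- runif(8, 50, 150); noex <- runif(8, 50, 150)
  r2 <- recovery_matrix_effect(pre, post, neat, noex)
  expect_equal(r2[["recovery_pct"]], 100 * mean(pre) / mean(post))
  expect_equal(r2[["matrix_effect_pct"]], 100 * mean(post) / mean(neat))
  expect_equal(r2[["recovery_no_extraction_pct"]],
               100 * mean(noex) / mean(post))
  expect_error(recovery_matrix_effect(numeric(0), post, neat), "empty")
})

test_that("cv_percent is the sample CV", {
  expect_equal(cv_percent(rep(7, 5)), 0)
  expect_equal(cv_percent(c(90, 110)), 14.14214, tolerance = 1e-5)
  set.seed(34)
  v <- rlnorm(50)
  expect_equal(cv_percent(v), 100 * sqrt(sum((v - mean(v))^2) /
                                           (length(v) - 1)) / mean(v))
  expect_error(cv_percent(c(-1, 1)), "zero mean")
  expect_error(cv_percent(5), "2 values")
})

test_that("validate_batch flags layout violations", {
  cal_set <- function(set) data.frame(
    sample_id = sprintf("CAL%d_%d", set, 1:7), individual = NA,
    matrix = NA, time_point = NA, dilution_volume = NA,
    batch_role = sprintf("calibration_point_%d", 1:7), nominal_conc = 1:7,
    stringsAsFactors = FALSE)
  qc <- function(id) data.frame(sample_id = id, individual = NA, matrix = NA,
                                time_point = NA, dilution_volume = NA,
                                batch_role = "QC", nominal_conc = NA,
                                stringsAsFactors = FALSE)
  smp <- function(id) data.frame(sample_id = id, individual = "I1",
                                 matrix = "plasma", time_point = "day0",
                                 dilution_volume = NA, batch_role = "sample",
                                 nominal_conc = NA, stringsAsFactors = FALSE)
  good <- rbind(qc("QC1"), cal_set(1), smp("S1"), qc("QC2"), cal_set(2),
                smp("S2"), qc("QC3"), cal_set(3))
  expect_length(validate_batch(good)$flags, 0)

  two_sets <- rbind(qc("QC1"), cal_set(1), qc("QC2"), cal_set(2), qc("QC3"))
  expect_match(validate_batch(two_sets)$flags, "calibration", all = FALSE)

  no_qc_first <- rbind(smp("S1"), qc("QC1"), cal_set(1), qc("QC2"),
                       cal_set(2), qc("QC3"), cal_set(3))
  expect_match(validate_batch(no_qc_first)$flags, "first injection",
               all = FALSE)
})

test_that("quantification never consumes recursive values", {
  runs <- replicate_runs(data.frame(mz = c(760.585, 720.5), rt = c(10, 11),
                                    ccs = c(290, 285),
                                    area = c(2e5, 1e5)), 3)
  # drop the analyte from S03, then fill it recursively
  runs[["S03"]] <- runs[["S03"]][1, ]
  bt <- align_buckets(runs)
  k_istd <- which(abs(bt$buckets$mz - 760.585) < 0.01)
  k_an <- which(abs(bt$buckets$mz - 720.5) < 0.01)
  bt <- recursive_fill(bt, list(S03 = ft(720.5, 11, 285, area = 999)))
  expect_identical(bt$provenance[k_an, "S03"], "recursive")

  m <- fit_calibration(truth_points(1, 1, 100))
  q <- quantify_bucket_table(bt, bt$buckets$bucket_id[k_istd], m,
                             quant_context(), 800)
  expect_true(is.na(q$C[k_an, "S03"]))          # recursive value excluded
  expect_true(all(is.finite(q$C[k_an, c("S01", "S02")])))
  # B/A is the dilution factor everywhere it is defined
  ratio <- q$B / q$A
  expect_true(all(abs(ratio[is.finite(ratio)] - 18) < 1e-9))
})
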