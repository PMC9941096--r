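# Internal-standard based molar quantification.
#
# The calibration model is areaRatio = c1 * concRatio^(1/c2), with
# areaRatio = A_ES/A_IS and concRatio = C_ES/C_IS, fitted by ordinary least
# squares in log-log space. Concentration on column:
#   A [ng/mL] = ((area_analyte/area_istd) / c1)^c2 * C_IS
#   B [ng/mL] = A * final_volume / sample_volume
#   C [nmol/mL] = B / adduct_mass
# Detection limits follow the bioanalytical convention LLOD = 3.3 sigma/s and
# LLOQ = 10 sigma/s, with sigma the residual SD and s the slope of an
# ordinary linear regression of response on concentration ratio.

#' Calibration points
#'
#' One row per point of the serial external-standard dilution: nominal
#' external-standard concentration, ISTD concentration and the two peak
#' areas. All values must be strictly positive.
#'
#' @param conc_es,conc_is concentrations in ng/mL.
#' @param area_es,area_is peak areas (arbitrary counts).
#' @return A `calibration_points` data frame.
#' @export
calibration_points <- function(conc_es, conc_is, area_es, area_is) {
  df <- data.frame(conc_es = as.numeric(conc_es),
                   conc_is = as.numeric(conc_is),
                   area_es = as.numeric(area_es),
                   area_is = as.numeric(area_is))
  if (any(!is.finite(as.matrix(df))) || any(as.matrix(df) <= 0))
    .stopf("calibration points must be strictly positive and finite")
  class(df) <- c("calibration_points", "data.frame")
  df
}

#' Fit the multi-point calibration model
#'
#' Fits `areaRatio = c1 * concRatio^(1/c2)` by OLS of log(areaRatio) on
#' log(concRatio): the slope maps to 1/c2 and the intercept to log(c1).
#' Per-point accuracy is 100 x back-calculated / nominal concentration, with
#' the bioanalytical acceptance band of 80-120 %; failing points are flagged,
#' not dropped. `sigma` (residual SD of the area ratios) and `slope_s` (slope
#' of area ratio on concentration ratio) come from an auxiliary ordinary
#' linear regression and feed [llod_lloq()].
#'
#' @param points a [calibration_points()] data frame (>= 3 distinct
#'   concentrations).
#' @param accuracy_band acceptance band for back-calculated accuracy (%).
#' @return A `calibration_model` list: `c1`, `c2`, `conc_is`, `r_squared`,
#'   `accuracy` (per point, %), `accuracy_ok`, `sigma`, `slope_s`, `llod`,
#'   `lloq`, `points`.
#' @export
fit_calibration <- function(points, accuracy_band = c(80, 120)) {
  if (!all(c("conc_es", "conc_is", "area_es", "area_is") %in% names(points)))
    .stopf("calibration points need conc_es, conc_is, area_es, area_is")
  if (any(as.matrix(points[, c("conc_es", "conc_is", "area_es",
                               "area_is")]) <= 0))
    .stopf("calibration points must be strictly positive")
  if (nrow(points) < 3L) .stopf("need at least 3 calibration points")
  conc_ratio <- points$conc_es / points$conc_is
  if (length(unique(conc_ratio)) < 3L)
    .stopf("need at least 3 distinct concentration ratios")
  area_ratio <- points$area_es / points$area_is
  fit <- stats::lm(log(area_ratio) ~ log(conc_ratio))
  slope <- unname(stats::coef(fit)[2L])
  if (slope <= 0) .stopf("non-positive log-log slope: response does not rise")
  c2 <- 1 / slope
  c1 <- exp(unname(stats::coef(fit)[1L]))
  # noise-free fixtures trigger summary.lm's perfect-fit warning; harmless
  r_squared <- suppressWarnings(summary(fit)$r.squared)
  back <- (area_ratio / c1)^c2 * points$conc_is       # ng/mL on column
  accuracy <- 100 * back / points$conc_es
  lin <- stats::lm(area_ratio ~ conc_ratio)
  sigma <- suppressWarnings(summary(lin)$sigma)
  slope_s <- unname(stats::coef(lin)[2L])
  lim <- llod_lloq(sigma, slope_s)
  structure(list(c1 = c1, c2 = c2, conc_is = points$conc_is[1L],
                 r_squared = r_squared, accuracy = accuracy,
                 accuracy_ok = accuracy >= accuracy_band[1L] &
                   accuracy <= accuracy_band[2L],
                 sigma = sigma, slope_s = slope_s,
                 llod = lim[["llod"]], lloq = lim[["lloq"]],
                 points = points),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("<calibration_model: c1 = %.4g, c2 = %.4g, r2 = %.4f, ",
                     "LLOD = %.4g, LLOQ = %.4g>\n"),
              x$c1, x$c2, x$r_squared, x$llod, x$lloq))
  invisible(x)
}

#' Quantification context
#'
#' Volumes and per-analyte constants shared by the quantification routines.
#' Defaults are the platform's extraction protocol: 20 uL sample extracted
#' and reconstituted in 360 uL.
#'
#' @param final_volume reconstitution volume in uL.
#' @param sample_volume extracted sample volume in uL.
#' @param adduct_mass measured adduct mass in Da (scalar or named per analyte).
#' @return A `quant_context` list.
#' @export
quant_context <- function(final_volume = 360, sample_volume = 20,
                          adduct_mass = NULL) {
  if (final_volume <= 0 || sample_volume <= 0)
    .stopf("volumes must be positive")
  structure(list(final_volume = final_volume, sample_volume = sample_volume,
                 adduct_mass = adduct_mass), class = "quant_context")
}

.quant_abc <- function(A, ctx, adduct_mass) {
  if (is.null(adduct_mass) || !is.finite(adduct_mass) || adduct_mass <= 0)
    .stopf("missing or non-positive adduct_mass")
  A <- unname(A)
  B <- A * ctx$final_volume / ctx$sample_volume
  c(A = A, B = B, C = B / unname(adduct_mass))
}

#' Multi-point quantification
#'
#' `A = ((area_analyte/area_istd)/c1)^c2 * C_IS` (ng/mL on column),
#' `B = A * final_volume/sample_volume` (ng/mL in sample),
#' `C = B / adduct_mass` (nmol/mL).
#'
#' @param area_analyte,area_istd peak areas; the ISTD area must be positive.
#' @param model a fitted [fit_calibration()] model.
#' @param ctx a [quant_context()].
#' @param adduct_mass measured adduct mass in Da (overrides the context).
#' @return Named numeric vector `c(A, B, C)`.
#' @export
quantify_multipoint <- function(area_analyte, area_istd, model, ctx,
                                adduct_mass = ctx$adduct_mass) {
  if (!inherits(model, "calibration_model"))
    .stopf("model must come from fit_calibration()")
  if (!is.finite(area_istd) || area_istd <= 0) .stopf("zero or missing ISTD area")
  if (!is.finite(area_analyte) || area_analyte < 0)
    .stopf("invalid analyte area")
  A <- ((area_analyte / area_istd) / model$c1)^model$c2 * model$conc_is
  .quant_abc(A, ctx, adduct_mass)
}

#' One-point quantification
#'
#' A single calibrant point defines `m = areaRatio_ES / concRatio_ES`; then
#' `A = (areaRatio_sample / m) * C_IS` and B, C follow the multi-point
#' arithmetic. The calibrant point (e.g. the 2nd, 4th or 6th of the series)
#' is chosen by the caller.
#'
#' @param area_analyte,area_istd sample peak areas.
#' @param calibrant one row of [calibration_points()] (subset with `[k, ]`).
#' @param ctx a [quant_context()].
#' @param adduct_mass measured adduct mass in Da.
#' @return Named numeric vector `c(A, B, C)`.
#' @export
quantify_onepoint <- function(area_analyte, area_istd, calibrant, ctx,
                              adduct_mass = ctx$adduct_mass) {
  if (nrow(calibrant) != 1L) .stopf("select exactly one calibrant point")
  if (any(as.matrix(calibrant[, c("conc_es", "conc_is", "area_es",
                                  "area_is")]) <= 0))
    .stopf("invalid calibrant point")
  if (!is.finite(area_istd) || area_istd <= 0) .stopf("zero or missing ISTD area")
  m <- (calibrant$area_es / calibrant$area_is) /
    (calibrant$conc_es / calibrant$conc_is)
  A <- ((area_analyte / area_istd) / m) * calibrant$conc_is
  .quant_abc(A, ctx, adduct_mass)
}

#' Lower limits of detection and quantification
#'
#' `LLOD = 3.3 sigma / s`, `LLOQ = 10 sigma / s`, with sigma the standard
#' deviation of the responses and s the slope of the calibration curve.
#'
#' @param sigma residual standard deviation of responses (>= 0).
#' @param slope_s slope of the calibration curve (> 0).
#' @return Named numeric vector `c(llod, lloq)`.
#' @export
llod_lloq <- function(sigma, slope_s) {
  if (!is.finite(slope_s) || slope_s <= 0) .stopf("slope must be positive")
  if (!is.finite(sigma) || sigma < 0) .stopf("sigma must be >= 0")
  c(llod = 3.3 * sigma / slope_s, lloq = 10 * sigma / slope_s)
}

#' Recovery and matrix-effect percentages
#'
#' Ratio-of-means arithmetic over labeled ISTD peak-area groups:
#' recovery% = 100 * mean(pre-extraction spike) / mean(post-extraction
#' spike); matrix effect% = 100 * mean(post-extraction spike) / mean(neat
#' solvent). When a `no_extraction` group is supplied, its analogous ratios
#' are reported too.
#'
#' @param pre_spike,post_spike,neat numeric area vectors (non-empty).
#' @param no_extraction optional area vector of diluted, unextracted samples.
#' @return Named numeric vector with `recovery_pct`, `matrix_effect_pct` and,
#'   when applicable, `recovery_no_extraction_pct`,
#'   `matrix_effect_no_extraction_pct`.
#' @export
recovery_matrix_effect <- function(pre_spike, post_spike, neat,
                                   no_extraction = NULL) {
  for (g in list(pre_spike, post_spike, neat))
    if (length(g) == 0L) .stopf("empty group in recovery computation")
  out <- c(recovery_pct = 100 * mean(pre_spike) / mean(post_spike),
           matrix_effect_pct = 100 * mean(post_spike) / mean(neat))
  if (!is.null(no_extraction)) {
    if (length(no_extraction) == 0L) .stopf("empty no_extraction group")
    out <- c(out,
             recovery_no_extraction_pct =
               100 * mean(no_extraction) / mean(post_spike),
             matrix_effect_no_extraction_pct =
               100 * mean(no_extraction) / mean(neat))
  }
  out
}

#' Coefficient of variation in percent
#'
#' `100 * sd(values) / mean(values)` (sample SD).
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) .stopf("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) .stopf("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Validate an acquisition batch layout
#'
#' Checks the platform's sequence rules: at least three 7-point calibration
#' sets, at least three QC injections, and a QC as the first injection of the
#' sequence (system suitability).
#'
#' @param design study design data frame ordered by injection; `batch_role`
#'   uses `sample`, `blank`, `QC`, `calibration_point_<k>` and an optional
#'   `calibration_set` column groups calibration points into sets (without
#'   it, contiguous calibration blocks count as one set each).
#' @param min_calibration_sets,min_qc layout minima.
#' @return A list with `flags` (character vector, empty when compliant) and
#'   `counts`.
#' @export
validate_batch <- function(design, min_calibration_sets = 3L, min_qc = 3L) {
  role <- design$batch_role
  flags <- character(0)
  is_cal <- grepl("^calibration_point", role)
  if ("calibration_set" %in% names(design)) {
    n_sets <- length(unique(design$calibration_set[is_cal]))
  } else {
    blocks <- rle(is_cal)
    n_sets <- sum(blocks$values)
  }
  n_qc <- sum(role == "QC")
  if (n_sets < min_calibration_sets)
    flags <- c(flags, sprintf("only %d calibration set(s); need >= %d",
                              n_sets, min_calibration_sets))
  if (n_qc < min_qc)
    flags <- c(flags, sprintf("only %d QC sample(s); need >= %d", n_qc,
                              min_qc))
  if (length(role) == 0L || role[1L] != "QC")
    flags <- c(flags, "first injection is not a QC")
  list(flags = flags,
       counts = c(calibration_sets = n_sets, qc = n_qc,
                  samples = sum(role == "sample")))
}

#' Quantify a bucket table with provenance exclusion
#'
#' Applies [quantify_multipoint()] to every (bucket, sample) cell, never
#' consuming a value obtained by recursive gap filling: recursive cells are
#' excluded (NA) by construction.
#'
#' @param bt an annotated `bucket_table`.
#' @param istd_bucket_id bucket id of the internal standard.
#' @param model a [fit_calibration()] model.
#' @param ctx a [quant_context()].
#' @param adduct_mass adduct mass in Da (scalar, applied to all buckets, or a
#'   named vector by bucket id).
#' @return A list of matrices `A`, `B`, `C` (buckets x samples, NA where the
#'   analyte or ISTD value is missing or recursive).
#' @export
quantify_bucket_table <- function(bt, istd_bucket_id, model, ctx,
                                  adduct_mass) {
  ki <- match(istd_bucket_id, bt$buckets$bucket_id)
  if (is.na(ki)) .stopf("ISTD bucket '%s' not in table", istd_bucket_id)
  usable <- bt$values
  usable[bt$provenance != "primary"] <- NA_real_
  istd <- usable[ki, ]
  A <- B <- C <- matrix(NA_real_, n_buckets(bt), length(bt$samples),
                        dimnames = dimnames(bt$values))
  for (k in seq_len(n_buckets(bt))) {
    am <- if (length(adduct_mass) > 1L)
      adduct_mass[[bt$buckets$bucket_id[k]]] else adduct_mass
    for (s in seq_along(bt$samples)) {
      if (!is.finite(usable[k, s]) || !is.finite(istd[s]) || istd[s] <= 0)
        next
      abc <- quantify_multipoint(usable[k, s], istd[s], model, ctx, am)
      A[k, s] <- abc[["A"]]; B[k, s] <- abc[["B"]]; C[k, s] <- abc[["C"]]
    }
  }
  list(A = A, B = B, C = C)
}
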