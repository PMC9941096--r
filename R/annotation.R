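# 4D library annotation with banded confidence scoring.
#
# Confidence per dimension follows the platform's band rule: a deviation at or
# below the tight bound scores 1, decays linearly to 0 at the loose bound and
# is rejected beyond it (bands 1-3 ppm mass accuracy, 0.1-0.5 min RT,
# 0.2-1.5 A^2 CCS, MS/MS score 900-500). The spectral match compounds fit,
# reverse fit and purity on a 0-1000 scale.

#' Confidence score bands
#'
#' Tight/loose bounds per dimension and the MS/MS score thresholds: 900 marks
#' a good confident match, 500 is the lower acceptance cut-off.
#'
#' @param ppm_tight,ppm_loose mass accuracy band (ppm).
#' @param rt_tight,rt_loose RT band (min).
#' @param ccs_tight,ccs_loose CCS band (A^2).
#' @param ms2_good,ms2_cutoff MS/MS score thresholds on the 0-1000 scale.
#' @return A `score_bands` list.
#' @export
score_bands <- function(ppm_tight = 1, ppm_loose = 3, rt_tight = 0.1,
                        rt_loose = 0.5, ccs_tight = 0.2, ccs_loose = 1.5,
                        ms2_good = 900, ms2_cutoff = 500) {
  if (ppm_tight >= ppm_loose || rt_tight >= rt_loose || ccs_tight >= ccs_loose)
    .stopf("tight bound must be below the loose bound in every dimension")
  if (!(0 <= ms2_cutoff && ms2_cutoff <= ms2_good && ms2_good <= 1000))
    .stopf("need 0 <= ms2_cutoff <= ms2_good <= 1000")
  structure(list(ppm_tight = ppm_tight, ppm_loose = ppm_loose,
                 rt_tight = rt_tight, rt_loose = rt_loose,
                 ccs_tight = ccs_tight, ccs_loose = ccs_loose,
                 ms2_good = ms2_good, ms2_cutoff = ms2_cutoff),
            class = "score_bands")
}

# Linear band decay; NA beyond the loose bound (= rejection).
.band_score <- function(dev, tight, loose) {
  ifelse(dev <= tight, 1,
         ifelse(dev <= loose, (loose - dev) / (loose - tight), NA_real_))
}

#' Spectral match score (fit, reverse fit, purity)
#'
#' Peaks are paired greedily by nearest m/z within `match_window_da`, each
#' peak joining at most one pair. `fit` is the cosine similarity over the
#' union of peaks using square-root intensities, `reverse_fit` the same
#' cosine restricted to reference peaks, `purity` the matched fraction of the
#' total query intensity. The combined score is
#' `1000 * (0.5 fit + 0.3 reverse_fit + 0.2 purity)`; the weights are
#' configurable and recorded in the result.
#'
#' @param query,reference [spectrum()] objects (non-empty).
#' @param match_window_da peak pairing window in Da.
#' @param weights named weights for `fit`, `reverse_fit`, `purity`
#'   (normalized to sum 1).
#' @return A list with `fit`, `reverse_fit`, `purity`, `combined` (0-1000)
#'   and `weights`.
#' @export
spectral_score <- function(query, reference, match_window_da = 0.01,
                           weights = c(fit = 0.5, reverse_fit = 0.3,
                                       purity = 0.2)) {
  if (!inherits(query, "ms2_spectrum") || !inherits(reference, "ms2_spectrum"))
    .stopf("spectral_score expects ms2_spectrum objects")
  if (match_window_da <= 0) .stopf("match_window_da must be positive")
  weights <- weights / sum(weights)
  nq <- length(query$mz); nr <- length(reference$mz)
  dmz <- abs(outer(query$mz, reference$mz, "-"))
  cand <- which(dmz <= match_window_da, arr.ind = TRUE)
  pair_q <- pair_r <- integer(0)
  if (nrow(cand)) {
    cand <- cand[order(dmz[cand]), , drop = FALSE]
    used_q <- logical(nq); used_r <- logical(nr)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (!used_q[i] && !used_r[j]) {
        used_q[i] <- TRUE; used_r[j] <- TRUE
        pair_q <- c(pair_q, i); pair_r <- c(pair_r, j)
      }
    }
  }
  un_q <- setdiff(seq_len(nq), pair_q)
  un_r <- setdiff(seq_len(nr), pair_r)
  # aligned sqrt-intensity vectors over the union of peaks
  x <- c(sqrt(query$intensity[pair_q]), sqrt(query$intensity[un_q]),
         rep(0, length(un_r)))
  y <- c(sqrt(reference$intensity[pair_r]), rep(0, length(un_q)),
         sqrt(reference$intensity[un_r]))
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  fit <- cosine(x, y)
  ref_rows <- c(seq_along(pair_q), length(pair_q) + length(un_q) +
                  seq_along(un_r))
  reverse_fit <- cosine(x[ref_rows], y[ref_rows])
  tot_q <- sum(query$intensity)
  purity <- if (tot_q == 0) 0 else sum(query$intensity[pair_q]) / tot_q
  combined <- 1000 * (weights[["fit"]] * fit +
                        weights[["reverse_fit"]] * reverse_fit +
                        weights[["purity"]] * purity)
  list(fit = fit, reverse_fit = reverse_fit, purity = purity,
       combined = combined, weights = weights)
}

# Natural isotope abundances by nominal mass offset (IUPAC 2021 rounding).
.ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  D = 1,                       # label: pure 2H, no pattern contribution
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  P = 1,
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  Na = 1, F = 1, I = 1,
  Cl = c(0.7576, 0, 0.2424),
  K = c(0.932581, 0.000117, 0.067302))

#' Parse an elemental formula
#'
#' @param formula e.g. `"C40H80NO8P"`; `D` denotes deuterium.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) .stopf("empty formula")
  toks <- regmatches(formula,
                     gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1L]]
  toks <- toks[nzchar(toks)]
  leftover <- gsub("([A-Z][a-z]?)([0-9]*)", "", formula)
  if (nzchar(leftover)) .stopf("cannot parse formula '%s'", formula)
  counts <- integer(0)
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", t)))
    if (is.na(n)) n <- 1L
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  bad <- setdiff(names(counts), names(.ISOTOPES))
  if (length(bad))
    .stopf("unknown element symbol(s): %s", paste(bad, collapse = ", "))
  counts
}

#' Predict isotope-pattern intensity ratios
#'
#' Elementwise convolution of the natural isotope distributions: each
#' element's per-atom abundance vector (indexed by nominal mass offset) is
#' self-convolved `count` times and the element polynomials are multiplied.
#'
#' @param formula elemental formula string.
#' @param max_offset highest isotopologue offset to report (default 2).
#' @return Named numeric vector `c(m1 = M+1/M, m2 = M+2/M, ...)`.
#' @export
predict_isotope_ratios <- function(formula, max_offset = 2L) {
  counts <- parse_formula(formula)
  len <- max_offset + 1L
  conv <- function(a, b) {
    out <- numeric(len)
    for (i in seq_len(len))
      for (j in seq_len(len - i + 1L))
        out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    out
  }
  dist <- c(1, numeric(max_offset))
  for (el in names(counts)) {
    base <- numeric(len)
    ab <- .ISOTOPES[[el]]
    base[seq_len(min(len, length(ab)))] <- ab[seq_len(min(len, length(ab)))]
    for (k in seq_len(counts[[el]])) dist <- conv(dist, base)
  }
  ratios <- dist[-1L] / dist[1L]
  names(ratios) <- paste0("m", seq_len(max_offset))
  ratios
}

#' Isotope pattern quality score
#'
#' Compares observed isotopologue ratios (M+1/M and optionally M+2/M) with
#' the prediction from the elemental formula. The score is
#' `max(0, 1 - mean relative deviation)`; it is absent (`NA`) when no isotope
#' peaks were observed.
#'
#' @param observed_ratios numeric vector of observed ratios, M+1/M first;
#'   `NULL` or empty when no isotope peaks were seen.
#' @param formula elemental formula string.
#' @return Score in `[0, 1]`, or `NA_real_` when absent.
#' @export
isotope_score <- function(observed_ratios, formula) {
  if (is.null(observed_ratios) || length(observed_ratios) == 0L)
    return(NA_real_)
  pred <- predict_isotope_ratios(formula,
                                 max_offset = length(observed_ratios))
  pred <- pred[seq_along(observed_ratios)]
  max(0, 1 - mean(abs(observed_ratios - pred) / pred))
}

#' Score one bucket against one library entry
#'
#' Applies the band rule per dimension (deviation <= tight scores 1, linear
#' decay to the loose bound, rejection beyond it). The MS/MS sub-score is
#' `(combined - ms2_cutoff) / (1000 - ms2_cutoff)` clipped to `[0, 1]`, with
#' rejection below the cut-off. The composite is the unweighted mean of the
#' available sub-scores; missing dimensions are omitted, with the tier
#' carrying the penalty: `full_4D` when an accepted MS/MS match exists,
#' `no_MS2` when no spectrum was available, `rejected` otherwise.
#'
#' @param bucket list or one-row data frame with `mz`, `rt`, `ccs` and
#'   optionally `polarity`.
#' @param entry one analyte-list row (ppm deviation is computed against its
#'   empirical `expected_mz`).
#' @param bands a [score_bands()].
#' @param reference_spectrum,query_spectrum optional [spectrum()] objects for
#'   the MS/MS dimension.
#' @param observed_isotope_ratios optional observed M+1/M (, M+2/M) ratios.
#' @param dimensions coordinate dimensions to enforce (subset of
#'   `c("mz", "rt", "ccs")`); dropping one loosens the match.
#' @param match_window_da,weights passed to [spectral_score()].
#' @return An `annotation` list with deviations, sub-scores, `ms2_score`,
#'   `composite` and `tier`.
#' @export
score_annotation <- function(bucket, entry, bands = score_bands(),
                             reference_spectrum = NULL, query_spectrum = NULL,
                             observed_isotope_ratios = NULL,
                             dimensions = c("mz", "rt", "ccs"),
                             match_window_da = 0.01,
                             weights = c(fit = 0.5, reverse_fit = 0.3,
                                         purity = 0.2)) {
  bpol <- bucket$polarity %||% NULL
  if (!is.null(bpol) && !is.na(entry$polarity) &&
      !identical(as.character(bpol), as.character(entry$polarity)))
    .stopf("polarity mismatch: bucket is %s, entry is %s", bpol,
           entry$polarity)
  ppm <- abs(bucket$mz - entry$expected_mz) / entry$expected_mz * 1e6
  d_rt <- abs(bucket$rt - entry$expected_rt)
  d_ccs <- abs(bucket$ccs - entry$expected_ccs)
  sub <- c(
    mz = if ("mz" %in% dimensions)
      .band_score(ppm, bands$ppm_tight, bands$ppm_loose) else NA_real_,
    rt = if ("rt" %in% dimensions)
      .band_score(d_rt, bands$rt_tight, bands$rt_loose) else NA_real_,
    ccs = if ("ccs" %in% dimensions)
      .band_score(d_ccs, bands$ccs_tight, bands$ccs_loose) else NA_real_)
  rejected <- any(is.na(sub[dimensions]))
  ms2_score <- NA_real_
  has_spectrum <- !is.null(reference_spectrum) && !is.null(query_spectrum)
  if (has_spectrum) {
    ms2_score <- spectral_score(query_spectrum, reference_spectrum,
                                match_window_da, weights)$combined
    if (ms2_score < bands$ms2_cutoff) rejected <- TRUE
    sub <- c(sub, ms2 = min(1, max(0, (ms2_score - bands$ms2_cutoff) /
                                     (1000 - bands$ms2_cutoff))))
  }
  iso <- isotope_score(observed_isotope_ratios,
                       if (is.null(observed_isotope_ratios)) NA else
                         entry$formula)
  if (!is.na(iso)) sub <- c(sub, isotope = iso)
  composite <- if (rejected) 0 else mean(sub, na.rm = TRUE)
  tier <- if (rejected) "rejected" else if (has_spectrum) "full_4D" else
    "no_MS2"
  structure(list(name = entry$name, adduct = entry$adduct, ppm = ppm,
                 d_rt = d_rt, d_ccs = d_ccs, sub_scores = sub,
                 ms2_score = ms2_score, composite = composite, tier = tier),
            class = "annotation")
}

#' Annotate a bucket table against a 4D library
#'
#' Every bucket is scored against every library entry passing the loose
#' bounds of the enforced dimensions; the accepted candidate with the best
#' composite wins, ties broken by higher MS/MS score, then smaller ppm, then
#' smaller RT deviation. Buckets with several accepted candidates are flagged
#' for curation and all accepted candidates are retained in the report.
#'
#' @param bt a `bucket_table`.
#' @param library analyte-list data frame of matching polarity.
#' @param bands a [score_bands()].
#' @param spectra named list of reference spectra keyed by the library's
#'   `spectrum_id`.
#' @param query_spectra optional named list of per-bucket query spectra keyed
#'   by `bucket_id`.
#' @param dimensions coordinate dimensions to enforce.
#' @return The `bucket_table` with `annotations` (best hit per annotated
#'   bucket: name, adduct, deviations, ms2_score, composite, tier,
#'   n_candidates, multi_hit) and a `candidates` attribute listing all
#'   accepted candidates.
#' @export
annotate_table <- function(bt, library, bands = score_bands(),
                           spectra = list(), query_spectra = list(),
                           dimensions = c("mz", "rt", "ccs")) {
  if (nrow(library) == 0L) .stopf("empty library")
  if (!is.na(bt$polarity) && !identical(unique(library$polarity), bt$polarity))
    .stopf("library polarity (%s) does not match table polarity (%s)",
           unique(library$polarity), bt$polarity)
  best <- list()
  all_cand <- list()
  for (k in seq_len(n_buckets(bt))) {
    bk <- list(mz = bt$buckets$mz[k], rt = bt$buckets$rt[k],
               ccs = bt$buckets$ccs[k], polarity = bt$polarity)
    qsp <- query_spectra[[bt$buckets$bucket_id[k]]]
    ppm <- abs(bk$mz - library$expected_mz) / library$expected_mz * 1e6
    pass <- rep(TRUE, nrow(library))
    if ("mz" %in% dimensions) pass <- pass & ppm <= bands$ppm_loose
    if ("rt" %in% dimensions)
      pass <- pass & abs(bk$rt - library$expected_rt) <= bands$rt_loose
    if ("ccs" %in% dimensions)
      pass <- pass & abs(bk$ccs - library$expected_ccs) <= bands$ccs_loose
    cands <- list()
    for (j in which(pass)) {
      entry <- library[j, ]
      rsp <- if (!is.na(entry$spectrum_id)) spectra[[entry$spectrum_id]] else
        NULL
      ann <- score_annotation(bk, entry, bands, reference_spectrum = rsp,
                              query_spectrum = qsp, dimensions = dimensions)
      if (ann$tier != "rejected") cands[[length(cands) + 1L]] <- ann
    }
    if (!length(cands)) next
    o <- order(-vapply(cands, `[[`, numeric(1L), "composite"),
               -vapply(cands, function(a)
                 ifelse(is.na(a$ms2_score), -Inf, a$ms2_score), numeric(1L)),
               vapply(cands, `[[`, numeric(1L), "ppm"),
               vapply(cands, `[[`, numeric(1L), "d_rt"))
    top <- cands[[o[1L]]]
    bid <- bt$buckets$bucket_id[k]
    best[[length(best) + 1L]] <- data.frame(
      bucket_id = bid, name = top$name, adduct = top$adduct, ppm = top$ppm,
      d_rt = top$d_rt, d_ccs = top$d_ccs, ms2_score = top$ms2_score,
      composite = top$composite, tier = top$tier,
      n_candidates = length(cands), multi_hit = length(cands) > 1L,
      stringsAsFactors = FALSE)
    all_cand[[bid]] <- do.call(rbind, lapply(cands, function(a)
      data.frame(bucket_id = bid, name = a$name, adduct = a$adduct,
                 composite = a$composite, tier = a$tier,
                 stringsAsFactors = FALSE)))
  }
  out <- bt
  out$annotations <- if (length(best)) do.call(rbind, best) else
    data.frame(bucket_id = character(), name = character(),
               adduct = character(), ppm = numeric(), d_rt = numeric(),
               d_ccs = numeric(), ms2_score = numeric(), composite = numeric(),
               tier = character(), n_candidates = integer(),
               multi_hit = logical(), stringsAsFactors = FALSE)
  out$log <- c(out$log, list(list(stage = "annotate", n_in = n_buckets(bt),
                                  n_out = nrow(out$annotations))))
  attr(out, "candidates") <- all_cand
  out
}
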