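# Cross-sample feature selection: alignment of replicate runs into a bucket
# table, recursive gap filling at a lowered detection threshold, presence
# filtering, blank subtraction, cross-experiment overlap matching and the
# dilution-response filter. Every stage returns a subset of its input buckets
# so the selection funnel is monotone by construction.

#' Bucket-table accessors
#'
#' A bucket table is the aligned features x samples container: per bucket a
#' consensus (m/z, RT, CCS) coordinate triple plus the seeding feature's
#' coordinates, a `values` matrix of peak areas (NA where missing) and a
#' `provenance` matrix over \{primary, recursive, missing\}.
#'
#' @param bt a `bucket_table`.
#' @return `n_buckets()`: integer bucket count.
#' @export
n_buckets <- function(bt) nrow(bt$buckets)

.new_bucket_table <- function(buckets, values, provenance, samples, polarity,
                              annotations = NULL, log = list()) {
  rownames(values) <- rownames(provenance) <- buckets$bucket_id
  colnames(values) <- colnames(provenance) <- samples
  structure(list(buckets = buckets, values = values, provenance = provenance,
                 samples = samples, polarity = polarity,
                 annotations = annotations, log = log),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("<bucket_table: %d buckets x %d samples (%s mode)>\n",
              n_buckets(x), length(x$samples), x$polarity))
  invisible(x)
}

# Subset a bucket table to the given bucket indices, appending a log record.
.bt_subset <- function(bt, idx, stage, extra = list()) {
  out <- bt
  out$buckets <- bt$buckets[idx, , drop = FALSE]
  out$values <- bt$values[idx, , drop = FALSE]
  out$provenance <- bt$provenance[idx, , drop = FALSE]
  if (!is.null(bt$annotations))
    out$annotations <- bt$annotations[bt$annotations$bucket_id %in%
                                        out$buckets$bucket_id, , drop = FALSE]
  out$log <- c(bt$log, list(c(list(stage = stage, n_in = n_buckets(bt),
                                   n_out = length(idx)), extra)))
  out
}

#' Align features across runs into a bucket table
#'
#' Greedy centroid clustering: all features are pooled across runs and sorted
#' by descending peak area (ties broken lexicographically by m/z, RT, CCS,
#' sample id). The highest unassigned feature seeds a bucket; every unassigned
#' feature inside the seed's tolerance box joins, at most one per sample (the
#' nearest by normalized Chebyshev distance, ties to the lower m/z). The
#' consensus coordinate is the area-weighted mean of the members; the seed's
#' coordinates are retained as the bucket's box center. The procedure is
#' deterministic and invariant to the input ordering of runs and features.
#'
#' @param runs named list of [feature_table()]s (names are the sample ids),
#'   all of the same polarity.
#' @param tolerances a [tolerance_set()].
#' @return A `bucket_table`. Member references are kept in
#'   `buckets$members` (a list column of per-sample pooled-row indices).
#' @export
align_buckets <- function(runs, tolerances = tolerance_set()) {
  if (length(runs) < 1L) .stopf("align_buckets needs at least one run")
  if (is.null(names(runs)) || any(!nzchar(names(runs))))
    .stopf("runs must be a named list (names are sample ids)")
  pols <- unique(vapply(runs, function(r) attr(r, "polarity") %||% NA_character_,
                        character(1L)))
  pols <- pols[!is.na(pols)]
  if (length(pols) > 1L)
    .stopf("mixed polarities in runs: %s", paste(pols, collapse = ", "))
  polarity <- if (length(pols)) pols else "negative"
  samples <- names(runs)

  pool <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    if (nrow(r) == 0L) return(NULL)
    data.frame(mz = r$mz, rt = r$rt, ccs = r$ccs, area = r$area,
               sample = i, run_row = seq_len(nrow(r)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pool) || nrow(pool) == 0L)
    return(.new_bucket_table(
      data.frame(bucket_id = character(), mz = numeric(), rt = numeric(),
                 ccs = numeric(), seed_mz = numeric(), seed_rt = numeric(),
                 seed_ccs = numeric(), stringsAsFactors = FALSE),
      matrix(NA_real_, 0L, length(samples)),
      matrix("missing", 0L, length(samples)), samples, polarity))

  ord <- order(-pool$area, pool$mz, pool$rt, pool$ccs,
               samples[pool$sample], method = "radix")
  pool <- pool[ord, ]
  n <- nrow(pool)
  assigned <- logical(n)
  bucket_of <- integer(n)
  seeds <- integer(0)
  next_unassigned <- 1L
  b <- 0L
  while (next_unassigned <= n) {
    while (next_unassigned <= n && assigned[next_unassigned])
      next_unassigned <- next_unassigned + 1L
    if (next_unassigned > n) break
    b <- b + 1L
    s <- next_unassigned
    seeds <- c(seeds, s)
    cand <- which(!assigned &
                    .in_box(pool$mz, pool$rt, pool$ccs,
                            pool$mz[s], pool$rt[s], pool$ccs[s], tolerances))
    if (length(cand) > 1L) {
      d <- .cheb_dist(pool$mz[cand], pool$rt[cand], pool$ccs[cand],
                      pool$mz[s], pool$rt[s], pool$ccs[s], tolerances)
      o <- order(d, pool$mz[cand], method = "radix")
      cand <- cand[o]
      cand <- cand[!duplicated(pool$sample[cand])]
    }
    assigned[cand] <- TRUE
    bucket_of[cand] <- b
  }

  buckets <- data.frame(bucket_id = sprintf("B%05d", seq_len(b)),
                        mz = NA_real_, rt = NA_real_, ccs = NA_real_,
                        seed_mz = pool$mz[seeds], seed_rt = pool$rt[seeds],
                        seed_ccs = pool$ccs[seeds], stringsAsFactors = FALSE)
  values <- matrix(NA_real_, b, length(samples))
  prov <- matrix("missing", b, length(samples))
  members <- vector("list", b)
  for (k in seq_len(b)) {
    m <- which(bucket_of == k)
    w <- pool$area[m]
    if (sum(w) == 0) w <- rep(1, length(m))
    buckets$mz[k] <- sum(pool$mz[m] * w) / sum(w)
    buckets$rt[k] <- sum(pool$rt[m] * w) / sum(w)
    buckets$ccs[k] <- sum(pool$ccs[m] * w) / sum(w)
    values[k, pool$sample[m]] <- pool$area[m]
    prov[k, pool$sample[m]] <- "primary"
    members[[k]] <- data.frame(sample = samples[pool$sample[m]],
                               run_row = pool$run_row[m],
                               stringsAsFactors = FALSE)
  }
  buckets$members <- members
  .new_bucket_table(buckets, values, prov, samples, polarity,
                    log = list(list(stage = "align", n_in = n, n_out = b)))
}

#' Fill missing bucket values from low-threshold runs
#'
#' Targeted second-pass gap filling: for every (bucket, sample) cell with
#' provenance `missing`, the nearest feature of that sample's low-threshold
#' run lying inside the bucket's tolerance box (centered on the consensus
#' coordinates) is inserted with provenance `recursive`. Primary values are
#' never overwritten. Ties on the normalized distance go to the lower m/z.
#'
#' @param bt a `bucket_table`.
#' @param low_threshold_runs named list of [feature_table()]s re-extracted at
#'   a lower detection threshold; names must be samples of `bt`.
#' @param tolerances a [tolerance_set()].
#' @return The filled `bucket_table`.
#' @export
recursive_fill <- function(bt, low_threshold_runs,
                           tolerances = tolerance_set()) {
  unknown <- setdiff(names(low_threshold_runs), bt$samples)
  if (length(unknown))
    .stopf("sample id(s) absent from bucket table: %s",
           paste(unknown, collapse = ", "))
  out <- bt
  n_filled <- 0L
  for (sid in names(low_threshold_runs)) {
    run <- low_threshold_runs[[sid]]
    if (nrow(run) == 0L) next
    col <- match(sid, bt$samples)
    for (k in which(out$provenance[, col] == "missing")) {
      hit <- which(.in_box(run$mz, run$rt, run$ccs, out$buckets$mz[k],
                           out$buckets$rt[k], out$buckets$ccs[k], tolerances))
      if (!length(hit)) next
      d <- .cheb_dist(run$mz[hit], run$rt[hit], run$ccs[hit],
                      out$buckets$mz[k], out$buckets$rt[k],
                      out$buckets$ccs[k], tolerances)
      best <- hit[order(d, run$mz[hit], method = "radix")][1L]
      out$values[k, col] <- run$area[best]
      out$provenance[k, col] <- "recursive"
      n_filled <- n_filled + 1L
    }
  }
  out$log <- c(out$log, list(list(stage = "recursive_fill",
                                  n_in = n_buckets(bt),
                                  n_out = n_buckets(bt),
                                  n_filled = n_filled)))
  out
}

#' Presence rule for bucket retention
#'
#' The platform's two-threshold occurrence rule: gap filling is attempted for
#' buckets seen in at least `t_seed` of `n_samples` analyses and a bucket is
#' retained only if present in `t_final` of `n_samples` analyses after
#' filling (defaults 17 and 32 of 32).
#'
#' @param n_samples number of analyses in the batch.
#' @param t_seed minimum first-pass (primary) presence.
#' @param t_final minimum presence counting primary + recursive values.
#' @return A `presence_rule` list.
#' @export
presence_rule <- function(n_samples = 32L, t_seed = 17L, t_final = 32L) {
  if (!(1L <= t_seed && t_seed <= t_final && t_final <= n_samples))
    .stopf("need 1 <= t_seed <= t_final <= n_samples")
  structure(list(n_samples = as.integer(n_samples),
                 t_seed = as.integer(t_seed),
                 t_final = as.integer(t_final)), class = "presence_rule")
}

#' Filter buckets by presence counts
#'
#' Keeps a bucket iff its primary presence reaches `t_seed` and its
#' primary + recursive presence reaches `t_final`.
#'
#' @param bt a `bucket_table`.
#' @param rule a [presence_rule()].
#' @return The filtered `bucket_table`; per-bucket counts are attached as the
#'   `presence_counts` attribute and in the stage log.
#' @export
presence_filter <- function(bt, rule = presence_rule()) {
  primary <- rowSums(bt$provenance == "primary")
  filled <- primary + rowSums(bt$provenance == "recursive")
  keep <- which(primary >= rule$t_seed & filled >= rule$t_final)
  counts <- data.frame(bucket_id = bt$buckets$bucket_id, primary = primary,
                       filled = filled, kept = seq_len(n_buckets(bt)) %in% keep,
                       stringsAsFactors = FALSE)
  out <- .bt_subset(bt, keep, "presence_filter",
                    list(t_seed = rule$t_seed, t_final = rule$t_final))
  attr(out, "presence_counts") <- counts
  out
}

#' Remove buckets matching a blank (background) run
#'
#' A bucket is removed iff any feature of the blank run lies inside its
#' tolerance box. With `min_ratio` set, a matched bucket survives when its
#' median sample area exceeds `min_ratio` times the largest in-box blank area
#' (off by default; the platform's rule is plain in-box removal).
#'
#' @param bt a `bucket_table`.
#' @param blank_run a [feature_table()] of the solvent blank.
#' @param tolerances a [tolerance_set()].
#' @param min_ratio optional sample/blank intensity override.
#' @return The filtered `bucket_table`; removed bucket ids are logged and
#'   attached as the `blank_removed` attribute.
#' @export
background_subtract <- function(bt, blank_run, tolerances = tolerance_set(),
                                min_ratio = NULL) {
  hit <- vapply(seq_len(n_buckets(bt)), function(k) {
    inbox <- .in_box(blank_run$mz, blank_run$rt, blank_run$ccs,
                     bt$buckets$mz[k], bt$buckets$rt[k], bt$buckets$ccs[k],
                     tolerances)
    if (!any(inbox)) return(FALSE)
    if (is.null(min_ratio)) return(TRUE)
    med <- stats::median(bt$values[k, ], na.rm = TRUE)
    !is.finite(med) || med < min_ratio * max(blank_run$area[inbox])
  }, logical(1L))
  out <- .bt_subset(bt, which(!hit), "background_subtract",
                    list(n_removed = sum(hit)))
  attr(out, "blank_removed") <- bt$buckets$bucket_id[hit]
  out
}

#' Match features between two experiments
#'
#' Pairs features whose coordinates agree within the tolerance box
#' (`|dmz| < d_mz`, `|drt| <= d_rt`, `|dccs| <= d_ccs`). In the default
#' one-to-one mode each feature joins at most one pair, assigned greedily by
#' ascending normalized Chebyshev distance; `mode = "all_pairs"` returns every
#' in-box pair.
#'
#' @param features_a,features_b [feature_table()]s of the same polarity.
#' @param tolerances a [tolerance_set()].
#' @param mode `"one_to_one"` (default) or `"all_pairs"`.
#' @return A list with `pairs` (data frame of `idx_a`, `idx_b`, `dist`),
#'   `unmatched_a` and `unmatched_b` (row indices).
#' @export
overlap_match <- function(features_a, features_b,
                          tolerances = tolerance_set(),
                          mode = c("one_to_one", "all_pairs")) {
  mode <- match.arg(mode)
  pa <- attr(features_a, "polarity"); pb <- attr(features_b, "polarity")
  if (!is.null(pa) && !is.null(pb) && !identical(pa, pb))
    .stopf("polarity mismatch between the two experiments")
  cand <- do.call(rbind, lapply(seq_len(nrow(features_a)), function(i) {
    j <- which(.in_box(features_b$mz, features_b$rt, features_b$ccs,
                       features_a$mz[i], features_a$rt[i], features_a$ccs[i],
                       tolerances))
    if (!length(j)) return(NULL)
    data.frame(idx_a = i, idx_b = j,
               dist = .cheb_dist(features_b$mz[j], features_b$rt[j],
                                 features_b$ccs[j], features_a$mz[i],
                                 features_a$rt[i], features_a$ccs[i],
                                 tolerances))
  }))
  if (is.null(cand))
    cand <- data.frame(idx_a = integer(), idx_b = integer(), dist = numeric())
  if (mode == "one_to_one" && nrow(cand)) {
    cand <- cand[order(cand$dist, cand$idx_a, cand$idx_b), ]
    used_a <- logical(nrow(features_a)); used_b <- logical(nrow(features_b))
    take <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (!used_a[cand$idx_a[r]] && !used_b[cand$idx_b[r]]) {
        take[r] <- TRUE
        used_a[cand$idx_a[r]] <- TRUE
        used_b[cand$idx_b[r]] <- TRUE
      }
    }
    cand <- cand[take, ]
  }
  list(pairs = cand,
       unmatched_a = setdiff(seq_len(nrow(features_a)), cand$idx_a),
       unmatched_b = setdiff(seq_len(nrow(features_b)), cand$idx_b))
}

#' Dilution-response filter parameters
#'
#' A genuine matrix-derived feature must track the amount of matrix loaded:
#' the per-level mean areas must correlate positively with the dilution
#' volumes (Pearson r >= 0.9) and, after normalization, spread by more than
#' `sd_min` (default 0.1). The SD criterion has no natural scale on raw
#' areas, so per-bucket level means are scaled to max = 1 by default.
#'
#' @param r_min Pearson threshold in `[-1, 1]`.
#' @param sd_min minimum SD of the normalized level means.
#' @param normalization `"max_scale"` (default), `"none"` or `"log10"`.
#' @return A `dilution_filter_params` list.
#' @export
dilution_filter_params <- function(r_min = 0.9, sd_min = 0.1,
                                   normalization = c("max_scale", "none",
                                                     "log10")) {
  if (r_min < -1 || r_min > 1) .stopf("r_min must lie in [-1, 1]")
  if (sd_min < 0) .stopf("sd_min must be >= 0")
  structure(list(r_min = r_min, sd_min = sd_min,
                 normalization = match.arg(normalization)),
            class = "dilution_filter_params")
}

#' Filter buckets by dilution response
#'
#' For each bucket the mean area at each dilution level is computed (missing
#' values count as zero signal), the level means are normalized per
#' `params$normalization`, and the bucket is kept iff the Pearson correlation
#' of the raw level means with the dilution volumes reaches `r_min` and the
#' SD of the normalized means exceeds `sd_min`. Constant level means make the
#' correlation undefined and remove the bucket with reason `"constant"`.
#'
#' @param bt a `bucket_table` of the dilution experiment.
#' @param design study design with `sample_id` and `dilution_volume` for the
#'   samples of `bt` (>= 3 distinct levels required).
#' @param params a [dilution_filter_params()].
#' @return A list with `kept` and `removed` bucket tables plus `diagnostics`
#'   (per bucket: r, normalized-mean SD, decision and reason).
#' @export
dilution_response_filter <- function(bt, design,
                                     params = dilution_filter_params()) {
  vol <- design$dilution_volume[match(bt$samples, design$sample_id)]
  if (any(is.na(vol)))
    .stopf("samples without dilution_volume in design: %s",
           paste(bt$samples[is.na(vol)], collapse = ", "))
  levels_ <- sort(unique(vol))
  if (length(levels_) < 3L)
    .stopf("dilution design needs >= 3 distinct levels, got %d",
           length(levels_))
  vals <- bt$values
  vals[bt$provenance == "missing"] <- 0
  r <- sdn <- rep(NA_real_, n_buckets(bt))
  reason <- rep("", n_buckets(bt))
  keep <- logical(n_buckets(bt))
  for (k in seq_len(n_buckets(bt))) {
    means <- vapply(levels_, function(v) mean(vals[k, vol == v]), numeric(1L))
    if (stats::sd(means) == 0) {
      reason[k] <- "constant"
      sdn[k] <- 0
      next
    }
    r[k] <- stats::cor(means, levels_)
    norm <- switch(params$normalization,
                   max_scale = means / max(means),
                   none = means,
                   log10 = log10(pmax(means, .Machine$double.xmin)))
    sdn[k] <- stats::sd(norm)
    keep[k] <- is.finite(r[k]) && r[k] >= params$r_min && sdn[k] > params$sd_min
    if (!keep[k])
      reason[k] <- if (!is.finite(r[k]) || r[k] < params$r_min)
        "low_correlation" else "low_sd"
  }
  diagnostics <- data.frame(bucket_id = bt$buckets$bucket_id, r = r,
                            sd_norm = sdn, kept = keep, reason = reason,
                            stringsAsFactors = FALSE)
  list(kept = .bt_subset(bt, which(keep), "dilution_response_filter",
                         list(r_min = params$r_min, sd_min = params$sd_min)),
       removed = .bt_subset(bt, which(!keep), "dilution_response_filter"),
       diagnostics = diagnostics)
}

#' Write / read a bucket table as plain text
#'
#' Values and consensus coordinates go to `<prefix>_values.tsv` (one row per
#' bucket, one column per sample) with a `<prefix>_provenance.tsv` side file.
#'
#' @param bt a `bucket_table`.
#' @param prefix path prefix for the two files.
#' @return [read_bucket_table()]: a `bucket_table` (member references are not
#'   round-tripped).
#' @export
write_bucket_table <- function(bt, prefix) {
  meta <- bt$buckets[, c("bucket_id", "mz", "rt", "ccs", "seed_mz", "seed_rt",
                         "seed_ccs")]
  .write_tsv(cbind(meta, as.data.frame(bt$values)),
             paste0(prefix, "_values.tsv"))
  .write_tsv(cbind(meta["bucket_id"], as.data.frame(bt$provenance)),
             paste0(prefix, "_provenance.tsv"))
  invisible(prefix)
}

#' @rdname write_bucket_table
#' @param polarity polarity label to attach.
#' @export
read_bucket_table <- function(prefix, polarity = "negative") {
  vals <- utils::read.table(paste0(prefix, "_values.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
  prov <- utils::read.table(paste0(prefix, "_provenance.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
  meta_cols <- c("bucket_id", "mz", "rt", "ccs", "seed_mz", "seed_rt",
                 "seed_ccs")
  samples <- setdiff(names(vals), meta_cols)
  pm <- as.matrix(prov[, samples, drop = FALSE])
  pm[is.na(pm) | pm == ""] <- "missing"
  .new_bucket_table(vals[, meta_cols], as.matrix(vals[, samples, drop = FALSE]),
                    pm, samples, polarity)
}
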