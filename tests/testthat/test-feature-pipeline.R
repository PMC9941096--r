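# Independent re-implementation of the alignment rule, used as oracle: plain
# nested loops, no vectorization shared with the package code path.
oracle_align <- function(runs, tol) {
  rows <- list()
  for (s in names(runs)) {
    r <- runs[[s]]
    for (i in seq_len(nrow(r)))
      rows[[length(rows) + 1]] <- list(mz = r$mz[i], rt = r$rt[i],
                                       ccs = r$ccs[i], area = r$area[i],
                                       sample = s)
  }
  key <- sapply(rows, function(x) sprintf("%.9f|%.9f|%.9f|%s", x$mz, x$rt,
                                          x$ccs, x$sample))
  ord <- order(-sapply(rows, `[[`, "area"), sapply(rows, `[[`, "mz"),
               sapply(rows, `[[`, "rt"), sapply(rows, `[[`, "ccs"),
               sapply(rows, `[[`, "sample"))
  rows <- rows[ord]; key <- key[ord]
  assigned <- rep(FALSE, length(rows))
  buckets <- list()
  for (s_i in seq_along(rows)) {
    if (assigned[s_i]) next
    seed <- rows[[s_i]]
    members <- list()
    for (smp in unique(sapply(rows, `[[`, "sample"))) {
      best <- NULL; best_d <- Inf; best_mz <- Inf
      for (j in seq_along(rows)) {
        if (assigned[j] || rows[[j]]$sample != smp) next
        f <- rows[[j]]
        if (!(abs(f$mz - seed$mz) < tol$d_mz_abs &&
              abs(f$rt - seed$rt) <= tol$d_rt &&
              abs(f$ccs - seed$ccs) <= tol$d_ccs)) next
        d <- max(abs(f$mz - seed$mz) / tol$d_mz_abs,
                 abs(f$rt - seed$rt) / tol$d_rt,
                 abs(f$ccs - seed$ccs) / tol$d_ccs)
        if (d < best_d || (d == best_d && f$mz < best_mz)) {
          best <- j; best_d <- d; best_mz <- f$mz
        }
      }
      if (!is.null(best)) members[[length(members) + 1]] <- best
    }
    idx <- unlist(members)
    assigned[idx] <- TRUE
    buckets[[length(buckets) + 1]] <- sort(key[idx])
  }
  buckets
}

test_that("align_buckets groups identical features and splits distant m/z", {
  runs <- replicate_runs(data.frame(mz = 760.5851, rt = 10, ccs = 290), 2)
  bt <- align_buckets(runs)
  expect_equal(n_buckets(bt), 1L)
  expect_equal(sum(bt$provenance == "primary"), 2L)
  expect_equal(bt$buckets$mz, 760.5851)

  # 0.010 Da apart with d_mz = 0.002 -> two buckets
  two <- list(A = ft(c(760.585, 760.595), c(10, 10), c(290, 290)))
  expect_equal(n_buckets(align_buckets(two)), 2L)
})

test_that("align_buckets matches the exhaustive oracle on random features", {
  set.seed(11)
  tol <- tolerance_set()
  runs <- lapply(1:5, function(i)
    ft(mz = 700 + round(runif(10), 3) / 2,
       rt = 9 + round(runif(10), 2), ccs = 280 + round(runif(10), 1) * 2,
       area = round(runif(10, 1e3, 1e6)), sample_id = sprintf("S%02d", i)))
  names(runs) <- sprintf("S%02d", 1:5)
  bt <- align_buckets(runs, tol)

  expected <- oracle_align(runs, tol)
  got <- lapply(seq_len(n_buckets(bt)), function(k) {
    m <- bt$buckets$members[[k]]
    sort(sapply(seq_len(nrow(m)), function(i) {
      r <- runs[[m$sample[i]]][m$run_row[i], ]
      sprintf("%.9f|%.9f|%.9f|%s", r$mz, r$rt, r$ccs, m$sample[i])
    }))
  })
  expect_setequal(sapply(got, paste, collapse = ";"),
                  sapply(expected, paste, collapse = ";"))

  # every member lies in its seed's tolerance box; one member per sample
  for (k in seq_len(n_buckets(bt))) {
    m <- bt$buckets$members[[k]]
    expect_false(anyDuplicated(m$sample) > 0)
    for (i in seq_len(nrow(m))) {
      r <- runs[[m$sample[i]]][m$run_row[i], ]
      expect_lt(abs(r$mz - bt$buckets$seed_mz[k]), tol$d_mz_abs)
      expect_lte(abs(r$rt - bt$buckets$seed_rt[k]), tol$d_rt)
      expect_lte(abs(r$ccs - bt$buckets$seed_ccs[k]), tol$d_ccs)
    }
  }
})

test_that("align_buckets is invariant to run and feature ordering", {
  set.seed(12)
  runs <- lapply(1:4, function(i)
    ft(mz = 700 + round(runif(20), 3), rt = 9 + round(runif(20), 2),
       ccs = 280 + round(runif(20), 1), area = round(runif(20, 1e3, 1e6))))
  names(runs) <- sprintf("S%02d", 1:4)
  bt1 <- align_buckets(runs)
  shuffled <- lapply(rev(runs), function(r) {
    r2 <- r[sample(nrow(r)), ]
    attr(r2, "polarity") <- attr(r, "polarity")
    class(r2) <- class(r)
    r2
  })
  bt2 <- align_buckets(shuffled)
  expect_equal(n_buckets(bt1), n_buckets(bt2))
  o1 <- order(bt1$buckets$mz, bt1$buckets$rt)
  o2 <- order(bt2$buckets$mz, bt2$buckets$rt)
  expect_equal(bt1$buckets$mz[o1], bt2$buckets$mz[o2])
  expect_equal(bt1$values[o1, names(runs)], bt2$values[o2, names(runs)],
               ignore_attr = TRUE)
})

test_that("mixed polarities refuse to align", {
  runs <- list(A = ft(700, 9, 280),
               B = ft(700, 9, 280, polarity = "positive"))
  expect_error(align_buckets(runs), "polarit")
})

test_that("recursive_fill inserts nearest in-box candidates only", {
  runs <- replicate_runs(data.frame(mz = 760.585, rt = 10, ccs = 290), 3)
  runs[["S03"]] <- ft(999.9, 1, 100, sample_id = "S03")  # S03 misses it
  bt <- align_buckets(runs)
  k <- which(abs(bt$buckets$mz - 760.585) < 0.01)
  expect_identical(bt$provenance[k, "S03"], "missing")

  low <- list(S03 = ft(760.5853, 10.01, 290.02, area = 500))
  filled <- recursive_fill(bt, low)
  expect_identical(filled$provenance[k, "S03"], "recursive")
  expect_equal(filled$values[k, "S03"], 500, ignore_attr = TRUE)

  # out-of-box candidate stays missing
  far <- recursive_fill(bt, list(S03 = ft(760.60, 10.0, 290.0, area = 500)))
  expect_identical(far$provenance[k, "S03"], "missing")

  # two in-box candidates: nearer wins; exact tie -> lower m/z
  two <- recursive_fill(bt, list(
    S03 = ft(c(760.5851, 760.5858), c(10, 10), c(290, 290),
             area = c(111, 222))))
  expect_equal(two$values[k, "S03"], 111, ignore_attr = TRUE)
  tie <- recursive_fill(bt, list(
    S03 = ft(bt$buckets$mz[k] + c(-0.0005, 0.0005),
             rep(bt$buckets$rt[k], 2), rep(bt$buckets$ccs[k], 2),
             area = c(333, 444))))
  expect_equal(tie$values[k, "S03"], 333, ignore_attr = TRUE)

  expect_error(recursive_fill(bt, list(NOPE = ft(700, 9, 280))), "NOPE")
})

test_that("presence_filter applies the two-threshold occurrence rule", {
  n <- 32L
  mk <- function(primary, recursive) {
    prov <- matrix("missing", 1, n)
    prov[1, seq_len(primary)] <- "primary"
    if (recursive > 0)
      prov[1, primary + seq_len(recursive)] <- "recursive"
    vals <- matrix(NA_real_, 1, n)
    vals[prov != "missing"] <- 1
    structure(list(buckets = data.frame(bucket_id = "B1", mz = 700, rt = 9,
                                        ccs = 280, seed_mz = 700, seed_rt = 9,
                                        seed_ccs = 280),
                   values = vals, provenance = prov,
                   samples = sprintf("S%02d", 1:n), polarity = "negative",
                   annotations = NULL, log = list()),
              class = "bucket_table")
  }
  rule <- presence_rule(32, 17, 32)
  expect_equal(n_buckets(presence_filter(mk(17, 15), rule)), 1L)  # kept
  expect_equal(n_buckets(presence_filter(mk(16, 16), rule)), 0L)  # dropped
  expect_equal(n_buckets(presence_filter(mk(17, 14), rule)), 0L)  # 31 < 32
  expect_equal(n_buckets(presence_filter(mk(0, 0), rule)), 0L)
  expect_error(presence_rule(32, 20, 18), "t_seed")
})

test_that("background_subtract removes exactly the blank-matched buckets", {
  set.seed(13)
  coords <- data.frame(mz = 700 + (1:10) * 0.5, rt = 9 + (1:10) * 0.3,
                       ccs = 280 + (1:10) * 2)
  bt <- align_buckets(list(S01 = ft(coords$mz, coords$rt, coords$ccs)))
  blank <- ft(coords$mz[c(2, 5, 9)], coords$rt[c(2, 5, 9)],
              coords$ccs[c(2, 5, 9)])
  out <- background_subtract(bt, blank)
  expect_equal(n_buckets(out), 7L)

  # oracle: set difference by explicit box test
  tol <- tolerance_set()
  hit <- sapply(seq_len(n_buckets(bt)), function(k)
    any(abs(blank$mz - bt$buckets$mz[k]) < tol$d_mz_abs &
          abs(blank$rt - bt$buckets$rt[k]) <= tol$d_rt &
          abs(blank$ccs - bt$buckets$ccs[k]) <= tol$d_ccs))
  expect_setequal(out$buckets$bucket_id, bt$buckets$bucket_id[!hit])

  # a bucket 1.0 min away from every blank feature is kept
  far <- background_subtract(bt, ft(coords$mz, coords$rt + 1.0, coords$ccs))
  expect_equal(n_buckets(far), 10L)
})

test_that("overlap_match enforces the tolerance box and one-to-one pairing", {
  a <- ft(760.585, 10, 290)
  expect_equal(nrow(overlap_match(a, ft(760.585, 10, 290))$pairs), 1L)
  expect_equal(nrow(overlap_match(a, ft(760.585, 10, 290.3))$pairs), 0L)
  expect_equal(nrow(overlap_match(a, ft(760.585, 10.05, 290.1))$pairs), 1L)

  # 20 features vs a shuffled, jittered copy (within half tolerance):
  # the true pairing is the unique optimal assignment
  set.seed(14)
  n <- 20
  base <- data.frame(mz = 700 + (1:n) * 0.1, rt = 9 + (1:n) * 0.2,
                     ccs = 280 + (1:n) * 1.5)
  fa <- ft(base$mz, base$rt, base$ccs)
  perm <- sample(n)
  fb <- ft(base$mz[perm] + runif(n, -0.0009, 0.0009),
           base$rt[perm] + runif(n, -0.045, 0.045),
           base$ccs[perm] + runif(n, -0.09, 0.09))
  res <- overlap_match(fa, fb)
  expect_equal(nrow(res$pairs), n)
  expect_equal(res$pairs$idx_b[order(res$pairs$idx_a)], order(perm))
  expect_length(res$unmatched_a, 0)

  # widening any tolerance never loses matches on separated features
  for (tol in list(tolerance_set(0.004, 0.1, 0.2),
                   tolerance_set(0.002, 0.3, 0.2),
                   tolerance_set(0.002, 0.1, 0.6)))
    expect_gte(nrow(overlap_match(fa, fb, tol)$pairs), n)
})

test_that("dilution_response_filter keeps responders and drops flat/inverted", {
  vols <- c(2, 1, 0.5, 0.25, 0.125, 0.0625)
  design <- data.frame(sample_id = sprintf("D%d", 1:6),
                       dilution_volume = vols)
  mk_bt <- function(areas) {
    vals <- matrix(areas, nrow = 1)
    structure(list(buckets = data.frame(bucket_id = "B1", mz = 700, rt = 9,
                                        ccs = 280, seed_mz = 700, seed_rt = 9,
                                        seed_ccs = 280),
                   values = vals,
                   provenance = matrix("primary", 1, 6),
                   samples = design$sample_id, polarity = "negative",
                   annotations = NULL, log = list()),
              class = "bucket_table")
  }
  prop <- dilution_response_filter(mk_bt(1000 * vols), design)
  expect_equal(n_buckets(prop$kept), 1L)
  expect_equal(prop$diagnostics$r, 1)
  expect_gt(prop$diagnostics$sd_norm, 0.3)

  flat <- dilution_response_filter(mk_bt(rep(1000, 6)), design)
  expect_equal(n_buckets(flat$kept), 0L)
  expect_identical(flat$diagnostics$reason, "constant")

  inv <- dilution_response_filter(mk_bt(5000 - 1000 * vols), design)
  expect_equal(n_buckets(inv$kept), 0L)
  expect_equal(inv$diagnostics$r, -1)

  short <- design
  short$dilution_volume <- rep(c(2, 1), 3)   # only two distinct levels
  expect_error(
    dilution_response_filter(mk_bt(1000 * vols), short),
    ">= 3")
})

test_that("bucket tables round-trip through text files", {
  runs <- replicate_runs(data.frame(mz = c(760.585, 720.5),
                                    rt = c(10, 11), ccs = c(290, 285)), 3)
  bt <- align_buckets(runs)
  prefix <- file.path(withr::local_tempdir(), "bt")
  write_bucket_table(bt, prefix)
  back <- read_bucket_table(prefix)
  expect_equal(n_buckets(back), n_buckets(bt))
  expect_equal(back$values, bt$values, tolerance = 1e-6)
  expect_equal(back$provenance, bt$provenance)
})
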