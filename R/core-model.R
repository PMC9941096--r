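# Domain types and plain-text I/O shared by all pipeline stages.
#
# Feature tables, analyte lists and study designs are delimited text
# (tab preferred, comma accepted); spectra are NIST-style MSP with an MGF
# reader for convenience. All coordinates are kept as doubles; nothing is
# rounded on I/O beyond the precision of the source file.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

POLARITIES <- c("positive", "negative")

.check_polarity <- function(polarity) {
  if (length(polarity) != 1L || !polarity %in% POLARITIES)
    .stopf("polarity must be one of %s", paste(POLARITIES, collapse = ", "))
  polarity
}

# Delimiter auto-detection: tab wins if present on the first line.
.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) .stopf("empty file: %s", path)
  if (grepl("\t", first)) "\t" else ","
}

.read_delim <- function(path) {
  sep <- .detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", colClasses = "character")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

# Coerce a character column to numeric, reporting malformed cells by row.
.num_col <- function(x, name) {
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    .stopf("column '%s': malformed numeric value%s in row%s %s", name,
           if (length(bad) > 1L) "s" else "",
           if (length(bad) > 1L) "s" else "",
           paste(bad, collapse = ", "))
  out
}

## ---- Feature tables ---------------------------------------------------------

#' Construct a 4D feature table
#'
#' One row per detected ion with its four descriptors: m/z (Da), retention
#' time (min), collision cross section (A^2) and peak area. Polarity is
#' table-level metadata because processing is strictly per polarity.
#'
#' @param mz,rt,ccs,area numeric vectors of equal length; `mz > 0`, `rt >= 0`,
#'   `ccs > 0`, `area >= 0`.
#' @param polarity `"positive"` or `"negative"`.
#' @param spectrum_id optional character references into a spectrum store.
#' @param sample_id optional originating run identifier(s).
#' @return A `feature_table` data frame with a `polarity` attribute.
#' @export
feature_table <- function(mz, rt, ccs, area, polarity,
                          spectrum_id = NA_character_,
                          sample_id = NA_character_) {
  .check_polarity(polarity)
  df <- data.frame(mz = as.numeric(mz), rt = as.numeric(rt),
                   ccs = as.numeric(ccs), area = as.numeric(area),
                   spectrum_id = rep_len(as.character(spectrum_id), length(mz)),
                   sample_id = rep_len(as.character(sample_id), length(mz)),
                   stringsAsFactors = FALSE)
  validate_feature_table(df)
  attr(df, "polarity") <- polarity
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @rdname feature_table
#' @param x data frame to validate.
#' @export
validate_feature_table <- function(x) {
  for (col in c("mz", "rt", "ccs", "area"))
    if (!col %in% names(x)) .stopf("feature table lacks column '%s'", col)
  bad <- which(!is.finite(x$mz) | x$mz <= 0)
  if (length(bad)) .stopf("non-positive or missing mz in row %d", bad[1L])
  bad <- which(!is.finite(x$rt) | x$rt < 0)
  if (length(bad)) .stopf("negative or missing rt in row %d", bad[1L])
  bad <- which(!is.finite(x$ccs) | x$ccs <= 0)
  if (length(bad)) .stopf("non-positive or missing ccs in row %d", bad[1L])
  bad <- which(!is.finite(x$area) | x$area < 0)
  if (length(bad)) .stopf("negative or missing area in row %d", bad[1L])
  invisible(x)
}

#' Read / write a feature table
#'
#' Tab- or comma-separated text with header columns `mz`, `rt`, `ccs`, `area`
#' (case-insensitive) and optional `spectrum_id` / `sample_id`. Row order is
#' preserved; malformed numeric cells are reported with their row numbers and
#' nothing is silently dropped.
#'
#' @param path file path.
#' @param polarity `"positive"` or `"negative"` (file-level metadata).
#' @return [read_feature_table()]: a `feature_table`.
#' @export
read_feature_table <- function(path, polarity) {
  .check_polarity(polarity)
  raw <- .read_delim(path)
  names(raw) <- tolower(names(raw))
  for (col in c("mz", "rt", "ccs", "area"))
    if (!col %in% names(raw))
      .stopf("feature table '%s' is missing mandatory column '%s'", path, col)
  df <- data.frame(mz = .num_col(raw$mz, "mz"), rt = .num_col(raw$rt, "rt"),
                   ccs = .num_col(raw$ccs, "ccs"),
                   area = .num_col(raw$area, "area"),
                   spectrum_id = raw$spectrum_id %||% NA_character_,
                   sample_id = raw$sample_id %||% NA_character_,
                   stringsAsFactors = FALSE)
  validate_feature_table(df)
  attr(df, "polarity") <- polarity
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @rdname read_feature_table
#' @param x a `feature_table`.
#' @export
write_feature_table <- function(x, path) {
  validate_feature_table(x)
  .write_tsv(as.data.frame(x)[, c("mz", "rt", "ccs", "area", "spectrum_id",
                                  "sample_id")], path)
  invisible(path)
}

## ---- Spectra ----------------------------------------------------------------

#' Construct an MS/MS spectrum
#'
#' Peaks are sorted ascending on construction; duplicate m/z values are
#' aggregated by summing their intensities so the stored peak list is strictly
#' increasing in m/z.
#'
#' @param mz,intensity numeric peak vectors; at least one peak, intensities
#'   `>= 0`.
#' @param precursor_mz precursor m/z in Da (optional).
#' @param polarity optional polarity label.
#' @return An object of class `ms2_spectrum` with fields `mz`, `intensity`,
#'   `precursor_mz`, `polarity`.
#' @export
spectrum <- function(mz, intensity, precursor_mz = NA_real_, polarity = NA) {
  if (length(mz) == 0L) .stopf("spectrum must contain at least one peak")
  if (length(mz) != length(intensity))
    .stopf("mz and intensity lengths differ")
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    .stopf("non-finite spectrum values")
  if (any(intensity < 0)) .stopf("negative peak intensity")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(mz = mz, intensity = intensity,
                 precursor_mz = as.numeric(precursor_mz), polarity = polarity),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum: %d peaks, precursor %.4f>\n",
              length(x$mz), x$precursor_mz))
  invisible(x)
}

#' Read / write NIST-style MSP spectral libraries
#'
#' Each record starts with `Name:`, may carry `PrecursorMZ:` and ends with
#' `Num Peaks: n` followed by n `mz intensity` lines. A record whose declared
#' peak count disagrees with the listed peaks is a format error citing the
#' record name. Peaks are returned sorted ascending.
#'
#' @param path file path.
#' @return [read_msp()]: a named list of [spectrum()] objects keyed by record
#'   name.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  store <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^\\s*Name\\s*:", lines[i], ignore.case = TRUE)) {
      i <- i + 1L
      next
    }
    name <- trimws(sub("^\\s*Name\\s*:", "", lines[i], ignore.case = TRUE))
    precursor <- NA_real_
    i <- i + 1L
    npk <- NA_integer_
    while (i <= n && is.na(npk)) {
      if (grepl("^\\s*Num\\s*Peaks\\s*:", lines[i], ignore.case = TRUE)) {
        npk <- as.integer(trimws(sub(".*:", "", lines[i])))
      } else if (grepl("^\\s*Precursor[_ ]?MZ\\s*:", lines[i],
                       ignore.case = TRUE)) {
        precursor <- as.numeric(trimws(sub(".*:", "", lines[i])))
      }
      i <- i + 1L
    }
    if (is.na(npk)) .stopf("MSP record '%s' has no 'Num Peaks' line", name)
    peaks <- matrix(NA_real_, nrow = 0L, ncol = 2L)
    while (i <= n && nzchar(trimws(lines[i])) &&
           !grepl("^\\s*Name\\s*:", lines[i], ignore.case = TRUE)) {
      parts <- strsplit(trimws(lines[i]), "[\t ;]+")[[1L]]
      peaks <- rbind(peaks, as.numeric(parts[1:2]))
      i <- i + 1L
    }
    if (nrow(peaks) != npk)
      .stopf("MSP record '%s' declares %d peaks but lists %d", name, npk,
             nrow(peaks))
    store[[name]] <- spectrum(peaks[, 1L], peaks[, 2L],
                              precursor_mz = precursor)
  }
  store
}

#' @rdname read_msp
#' @param store a named list of spectra.
#' @export
write_msp <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (name in names(store)) {
    sp <- store[[name]]
    writeLines(sprintf("Name: %s", name), con)
    if (is.finite(sp$precursor_mz))
      writeLines(sprintf("PrecursorMZ: %.6f", sp$precursor_mz), con)
    writeLines(sprintf("Num Peaks: %d", length(sp$mz)), con)
    writeLines(sprintf("%.6f %.6f", sp$mz, sp$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read an MGF peak-list file (read-only convenience)
#'
#' `BEGIN IONS`/`END IONS` blocks keyed by `TITLE`, with `PEPMASS` taken as
#' the precursor m/z.
#'
#' @param path file path.
#' @return A named list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  store <- list()
  inside <- FALSE
  title <- NULL; precursor <- NA_real_; mzs <- c(); ints <- c()
  for (ln in lines) {
    t <- trimws(ln)
    if (toupper(t) == "BEGIN IONS") {
      inside <- TRUE; title <- NULL; precursor <- NA_real_
      mzs <- c(); ints <- c()
    } else if (toupper(t) == "END IONS") {
      if (is.null(title)) title <- sprintf("spectrum_%d", length(store) + 1L)
      store[[title]] <- spectrum(mzs, ints, precursor_mz = precursor)
      inside <- FALSE
    } else if (inside && grepl("^TITLE=", t, ignore.case = TRUE)) {
      title <- sub("^TITLE=", "", t, ignore.case = TRUE)
    } else if (inside && grepl("^PEPMASS=", t, ignore.case = TRUE)) {
      precursor <- as.numeric(strsplit(sub("^PEPMASS=", "", t,
                                           ignore.case = TRUE), "[\t ]+")[[1L]][1L])
    } else if (inside && grepl("^[0-9]", t)) {
      parts <- strsplit(t, "[\t ]+")[[1L]]
      mzs <- c(mzs, as.numeric(parts[1L]))
      ints <- c(ints, as.numeric(parts[2L]))
    }
  }
  store
}

## ---- Analyte lists ----------------------------------------------------------

ANALYTE_COLS <- c("name", "lipid_class", "adduct", "polarity", "neutral_mass",
                  "expected_mz", "expected_rt", "expected_ccs", "formula",
                  "spectrum_id", "is_istd")

#' Validate an analyte list (4D reference library)
#'
#' Checks the library invariants: positive expected coordinates, a single
#' polarity, and uniqueness of the (name, adduct, polarity) key.
#'
#' @param x data frame with the analyte-list columns.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_analyte_list <- function(x) {
  for (col in c("name", "adduct", "polarity", "expected_mz", "expected_rt",
                "expected_ccs"))
    if (!col %in% names(x)) .stopf("analyte list lacks column '%s'", col)
  if (nrow(x)) {
    if (length(unique(x$polarity)) > 1L)
      .stopf("analyte list mixes polarities: %s",
             paste(unique(x$polarity), collapse = ", "))
    .check_polarity(unique(x$polarity))
    if (any(!is.finite(x$expected_mz) | x$expected_mz <= 0))
      .stopf("non-positive expected_mz in analyte list")
    if (any(!is.finite(x$expected_rt) | x$expected_rt < 0))
      .stopf("negative expected_rt in analyte list")
    if (any(!is.finite(x$expected_ccs) | x$expected_ccs <= 0))
      .stopf("non-positive expected_ccs in analyte list")
    key <- paste(x$name, x$adduct, x$polarity, sep = "|")
    if (anyDuplicated(key))
      .stopf("duplicate (name, adduct, polarity) key(s): %s",
             paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  invisible(x)
}

#' Read / write a 4D analyte list
#'
#' Tabular text with the library columns (`name`, `lipid_class`, `adduct`,
#' `polarity`, `neutral_mass`, `expected_mz`, `expected_rt`, `expected_ccs`,
#' `formula`, `spectrum_id`, `is_istd`). One polarity per file; duplicate
#' (name, adduct, polarity) keys are rejected.
#'
#' @param path file path.
#' @return [read_analyte_list()]: a validated data frame.
#' @export
read_analyte_list <- function(path) {
  raw <- .read_delim(path)
  names(raw) <- tolower(names(raw))
  df <- data.frame(
    name = raw$name %||% .stopf("analyte list lacks column 'name'"),
    lipid_class = raw$lipid_class %||% NA_character_,
    adduct = raw$adduct %||% NA_character_,
    polarity = raw$polarity %||% NA_character_,
    neutral_mass = .num_col(raw$neutral_mass %||% NA_character_, "neutral_mass"),
    expected_mz = .num_col(raw$expected_mz %||% NA_character_, "expected_mz"),
    expected_rt = .num_col(raw$expected_rt %||% NA_character_, "expected_rt"),
    expected_ccs = .num_col(raw$expected_ccs %||% NA_character_, "expected_ccs"),
    formula = raw$formula %||% NA_character_,
    spectrum_id = raw$spectrum_id %||% NA_character_,
    is_istd = tolower(raw$is_istd %||% "false") %in% c("true", "1", "yes"),
    stringsAsFactors = FALSE)
  validate_analyte_list(df)
  df
}

#' @rdname read_analyte_list
#' @param x an analyte list data frame.
#' @export
write_analyte_list <- function(x, path) {
  validate_analyte_list(x)
  .write_tsv(x[, intersect(ANALYTE_COLS, names(x))], path)
  invisible(path)
}

## ---- Study designs ----------------------------------------------------------

#' Read / write a study design table
#'
#' Maps each sample to its individual, blood matrix, time point, dilution
#' volume (ul matrix on column) and batch role (`sample`, `blank`, `QC` or
#' `calibration_point_k`). Calibration points must carry a nominal
#' concentration.
#'
#' @param path file path.
#' @return [read_study_design()]: a validated data frame.
#' @export
read_study_design <- function(path) {
  raw <- .read_delim(path)
  names(raw) <- tolower(names(raw))
  df <- data.frame(
    sample_id = raw$sample_id %||% .stopf("study design lacks 'sample_id'"),
    individual = raw$individual %||% NA_character_,
    matrix = raw$matrix %||% NA_character_,
    time_point = raw$time_point %||% NA_character_,
    dilution_volume = .num_col(raw$dilution_volume %||% NA_character_,
                               "dilution_volume"),
    batch_role = raw$batch_role %||% "sample",
    nominal_conc = .num_col(raw$nominal_conc %||% NA_character_,
                            "nominal_conc"),
    stringsAsFactors = FALSE)
  validate_study_design(df)
  df
}

#' @rdname read_study_design
#' @param x a study design data frame.
#' @export
write_study_design <- function(x, path) {
  validate_study_design(x)
  .write_tsv(x, path)
  invisible(path)
}

#' @rdname read_study_design
#' @export
validate_study_design <- function(x) {
  if (!"sample_id" %in% names(x)) .stopf("study design lacks 'sample_id'")
  if (anyDuplicated(x$sample_id))
    .stopf("duplicate sample_id in study design: %s",
           paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  if ("batch_role" %in% names(x)) {
    cal <- grepl("^calibration_point", x$batch_role)
    if (any(cal) && "nominal_conc" %in% names(x) &&
        any(!is.finite(x$nominal_conc[cal])))
      .stopf("calibration points without nominal_conc: %s",
             paste(x$sample_id[cal & !is.finite(x$nominal_conc)],
                   collapse = ", "))
  }
  invisible(x)
}

## ---- Tolerances -------------------------------------------------------------

#' Per-dimension matching tolerances
#'
#' The tolerance box used throughout alignment, overlap matching, blank
#' subtraction and gap filling. Defaults are the platform's matching rules:
#' m/z agreement stricter than 0.002 Da, RT within 0.1 min, CCS within
#' 0.2 A^2. A ppm-based m/z tolerance may be supplied instead of the absolute
#' one; exactly one of the two is active.
#'
#' @param d_mz_abs absolute m/z tolerance in Da (exclusive bound).
#' @param d_rt RT tolerance in min (inclusive).
#' @param d_ccs CCS tolerance in A^2 (inclusive).
#' @param d_mz_ppm optional ppm m/z tolerance replacing `d_mz_abs`.
#' @return A `tolerance_set` list.
#' @export
tolerance_set <- function(d_mz_abs = 0.002, d_rt = 0.1, d_ccs = 0.2,
                          d_mz_ppm = NULL) {
  if (!is.null(d_mz_ppm)) {
    if (d_mz_ppm <= 0) .stopf("d_mz_ppm must be positive")
    d_mz_abs <- NULL
  } else if (d_mz_abs <= 0) .stopf("d_mz_abs must be positive")
  if (d_rt <= 0 || d_ccs <= 0) .stopf("tolerances must be strictly positive")
  structure(list(d_mz_abs = d_mz_abs, d_mz_ppm = d_mz_ppm, d_rt = d_rt,
                 d_ccs = d_ccs), class = "tolerance_set")
}

# Effective absolute m/z tolerance at a reference m/z.
.tol_mz <- function(tol, mz_ref) {
  if (!is.null(tol$d_mz_ppm)) tol$d_mz_ppm * 1e-6 * mz_ref else tol$d_mz_abs
}

# Box membership test: m/z strict (<), RT and CCS inclusive (<=).
.in_box <- function(mz, rt, ccs, ref_mz, ref_rt, ref_ccs, tol) {
  abs(mz - ref_mz) < .tol_mz(tol, ref_mz) &
    abs(rt - ref_rt) <= tol$d_rt &
    abs(ccs - ref_ccs) <= tol$d_ccs
}

# Normalized Chebyshev distance used for nearest-candidate tie resolution.
.cheb_dist <- function(mz, rt, ccs, ref_mz, ref_rt, ref_ccs, tol) {
  pmax(abs(mz - ref_mz) / .tol_mz(tol, ref_mz),
       abs(rt - ref_rt) / tol$d_rt,
       abs(ccs - ref_ccs) / tol$d_ccs)
}
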