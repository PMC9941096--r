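# Building the 4D reference library from replicate runs of lipid standards.
#
# Each purchased standard is screened in replicates (typically triplicates);
# the library entry stores the arithmetic mean of the replicate m/z, RT and
# CCS observations, and the MS/MS spectrum of one designated replicate.

#' Replicate observations of one lipid standard
#'
#' @param name analyte shorthand (e.g. `"PC 16:0_18:1"`).
#' @param adduct ion type label (e.g. `"[M-H]-"`).
#' @param polarity `"positive"` or `"negative"`.
#' @param mz,rt,ccs numeric replicate observations (equal lengths, >= 1).
#' @param spectra optional list of [spectrum()] objects, one per replicate.
#' @param reference_spectrum index of the replicate whose MS/MS is stored in
#'   the library; default `NULL` picks the replicate with the highest total
#'   MS/MS intensity (the choice among replicates is otherwise arbitrary).
#' @param lipid_class,neutral_mass,formula optional annotations carried into
#'   the entry.
#' @return A `standard_run_set` list.
#' @export
standard_run_set <- function(name, adduct, polarity, mz, rt, ccs,
                             spectra = NULL, reference_spectrum = NULL,
                             lipid_class = NA_character_,
                             neutral_mass = NA_real_,
                             formula = NA_character_) {
  .check_polarity(polarity)
  n <- length(mz)
  if (n < 1L) .stopf("standard run set needs at least one replicate")
  if (length(rt) != n || length(ccs) != n)
    .stopf("replicate vectors must share length")
  if (!is.null(spectra) && length(spectra) != n)
    .stopf("one spectrum per replicate expected")
  structure(list(name = name, adduct = adduct, polarity = polarity,
                 mz = as.numeric(mz), rt = as.numeric(rt),
                 ccs = as.numeric(ccs), spectra = spectra,
                 reference_spectrum = reference_spectrum,
                 lipid_class = lipid_class, neutral_mass = neutral_mass,
                 formula = formula),
            class = "standard_run_set")
}

#' Build a library entry from replicate standard runs
#'
#' Expected m/z, RT and CCS are the arithmetic means of the replicate
#' observations. The stored reference spectrum is taken from one replicate:
#' the designated one if set, otherwise the replicate with the highest total
#' MS/MS intensity.
#'
#' @param run_set a [standard_run_set()].
#' @return A list with `entry` (one analyte-list row) and `spectrum` (the
#'   chosen reference [spectrum()], or `NULL`).
#' @export
build_entry <- function(run_set) {
  if (!inherits(run_set, "standard_run_set"))
    .stopf("build_entry expects a standard_run_set")
  sp <- NULL
  spectrum_id <- NA_character_
  if (!is.null(run_set$spectra)) {
    idx <- run_set$reference_spectrum
    if (is.null(idx)) {
      totals <- vapply(run_set$spectra,
                       function(s) sum(s$intensity), numeric(1L))
      idx <- which.max(totals)
    }
    sp <- run_set$spectra[[idx]]
    spectrum_id <- sprintf("%s %s", run_set$name, run_set$adduct)
  }
  entry <- data.frame(
    name = run_set$name, lipid_class = run_set$lipid_class,
    adduct = run_set$adduct, polarity = run_set$polarity,
    neutral_mass = run_set$neutral_mass,
    expected_mz = mean(run_set$mz), expected_rt = mean(run_set$rt),
    expected_ccs = mean(run_set$ccs), formula = run_set$formula,
    spectrum_id = spectrum_id, is_istd = FALSE, stringsAsFactors = FALSE)
  list(entry = entry, spectrum = sp)
}

#' Merge curated entries into an existing library
#'
#' New entries are deduplicated against the library: an incoming entry whose
#' adduct matches and whose 4D coordinates fall inside an existing entry's
#' tolerance box *and* whose name matches is dropped (the existing entry is
#' kept). Entries whose coordinates collide with a differently named entry are
#' appended anyway but flagged in the merge report, mirroring manual curation
#' of isobars.
#'
#' @param library analyte-list data frame (may have zero rows).
#' @param new_entries analyte-list data frame of the same polarity.
#' @param tolerances a [tolerance_set()].
#' @return A list with `library` (merged data frame), `n_appended`,
#'   `n_deduplicated` and `collisions` (data frame of coordinate collisions
#'   between differently named entries).
#' @export
merge_curated <- function(library, new_entries, tolerances = tolerance_set()) {
  if (nrow(library) && nrow(new_entries) &&
      !identical(unique(library$polarity), unique(new_entries$polarity)))
    .stopf("cross-polarity merge: library is %s, new entries are %s",
           unique(library$polarity), unique(new_entries$polarity))
  collisions <- data.frame(existing = character(), incoming = character(),
                           stringsAsFactors = FALSE)
  keep <- logical(nrow(new_entries))
  merged <- library
  for (i in seq_len(nrow(new_entries))) {
    e <- new_entries[i, ]
    if (nrow(merged)) {
      inbox <- merged$adduct == e$adduct &
        .in_box(e$expected_mz, e$expected_rt, e$expected_ccs,
                merged$expected_mz, merged$expected_rt, merged$expected_ccs,
                tolerances)
      dup <- inbox & merged$name == e$name
      if (any(dup)) next  # existing entry kept
      clash <- which(inbox & merged$name != e$name)
      if (length(clash))
        collisions <- rbind(collisions,
                            data.frame(existing = merged$name[clash],
                                       incoming = rep(e$name, length(clash)),
                                       stringsAsFactors = FALSE))
    }
    keep[i] <- TRUE
    merged <- rbind(merged, e)
  }
  validate_analyte_list(merged)
  list(library = merged, n_appended = sum(keep),
       n_deduplicated = nrow(new_entries) - sum(keep), collisions = collisions)
}
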