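# Shared fixture builders. Everything is generated in code; no binary data.

# Small feature table at given coordinates.
ft <- function(mz, rt, ccs, area = rep(1e5, length(mz)),
               polarity = "negative", sample_id = NA_character_) {
  feature_table(mz, rt, ccs, area, polarity, sample_id = sample_id)
}

# n replicate runs of the same coordinate set (optionally jittered).
replicate_runs <- function(coords, n, jitter = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    ft(coords$mz + rnorm(nrow(coords), 0, jitter[1]),
       coords$rt + rnorm(nrow(coords), 0, jitter[2]),
       coords$ccs + rnorm(nrow(coords), 0, jitter[3]),
       area = coords$area %||% rep(1e5, nrow(coords)),
       sample_id = sprintf("S%02d", i))
  })
  names(out) <- sprintf("S%02d", seq_len(n))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal analyte-list row.
lib_entry <- function(name, mz, rt, ccs, adduct = "[M-H]-",
                      polarity = "negative", lipid_class = "PC",
                      spectrum_id = NA_character_, formula = NA_character_,
                      neutral_mass = mz + 1.007276, is_istd = FALSE) {
  data.frame(name = name, lipid_class = lipid_class, adduct = adduct,
             polarity = polarity, neutral_mass = neutral_mass,
             expected_mz = mz, expected_rt = rt, expected_ccs = ccs,
             formula = formula, spectrum_id = spectrum_id, is_istd = is_istd,
             stringsAsFactors = FALSE)
}

# Noise-free calibration points from a known power-law truth.
truth_points <- function(c1, c2, conc_is, conc_es = 5 * 2^(0:6)) {
  ratio <- conc_es / conc_is
  area_is <- rep(1e5, length(conc_es))
  calibration_points(conc_es, conc_is, area_is * c1 * ratio^(1 / c2), area_is)
}

# Balanced two-matrix paired design.
paired_design <- function(individuals, time_points, matrices) {
  g <- expand.grid(individual = individuals, time_point = time_points,
                   matrix = matrices, stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_%s", g$individual, g$matrix, g$time_point)
  g$dilution_volume <- NA_real_
  g$batch_role <- "sample"
  g$nominal_conc <- NA_real_
  g
}
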