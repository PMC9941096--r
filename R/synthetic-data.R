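# Seeded generators for every input the pipeline consumes: 4D libraries with
# class-wise CCS-m/z trends, replicate feature-table batches with background
# features and dropout, dilution ladders with flat artifact features,
# power-law calibration series, and a blood-matrix study with known matrix
# and time effects. Every generator is deterministic per config seed and
# exports its ground truth.

#' Simulation configuration
#'
#' Defaults encode the platform's stated experimental world: a 1:2 dilution
#' ladder from 2 to 0.0625 ul matrix on column measured in triplicate, a
#' 7-point calibration series spanning a 64-fold concentration range with a
#' power-law response, within-batch coordinate repeatability (0.5 ppm m/z,
#' 0.01 min RT, 0.05 A^2 CCS -- comfortably inside the matching tolerances,
#' as the platform's own 32-of-32 presence rule requires), 10 % log-normal
#' area noise, and a study of 4 individuals x 5 blood matrices x 3 time points in
#' which plasma and serum (and the two dried-blood-spot collections) are
#' near-identical, whole blood is distinct, and triglycerides carry elevated
#' multidien variation.
#'
#' @param seed integer seed fixing every random stream.
#' @param classes data frame of per-class coordinate structure (m/z range,
#'   RT window, CCS-vs-m/z linear trend and scatter).
#' @param n_per_class library entries per class.
#' @param noise list: `mz_ppm_sd`, `rt_sd` (min), `ccs_sd` (A^2), `area_cv`.
#' @param background_n background features per run.
#' @param dropout per-feature dropout probability.
#' @param dilution list: `volumes` (ul, strictly decreasing), `n_replicates`,
#'   `n_artifacts` (flat features planted in the ladder).
#' @param calibration list: truth `c1`, `c2`, `conc_is` (ng/mL), `conc_es`
#'   levels (ng/mL), `noise_cv`.
#' @param study list: `individuals`, `matrices`, `time_points`,
#'   `matrix_profile` (per matrix: reference matrix and log-SD offset),
#'   `n_lipids`, `variable_class`, `variable_class_cv`, `within_cv`,
#'   `individual_sd`.
#' @param polarity generated polarity.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    classes = data.frame(
      class = c("PC", "PE", "SM", "Cer", "TG"),
      mz_min = c(700, 650, 650, 500, 800),
      mz_max = c(850, 800, 850, 700, 950),
      rt_min = c(8, 9, 8, 10, 15),
      rt_max = c(14, 15, 14, 16, 19),
      ccs_intercept = c(110, 105, 115, 100, 120),
      ccs_slope = c(0.23, 0.23, 0.22, 0.25, 0.21),
      ccs_scatter = c(2, 2, 2, 2, 2),
      stringsAsFactors = FALSE),
    n_per_class = 10L,
    noise = list(mz_ppm_sd = 0.5, rt_sd = 0.01, ccs_sd = 0.05,
                 area_cv = 0.1),
    background_n = 200L,
    dropout = 0,
    dilution = list(volumes = c(2, 1, 0.5, 0.25, 0.125, 0.0625),
                    n_replicates = 3L, n_artifacts = 30L),
    calibration = list(c1 = 1.2, c2 = 1.1, conc_is = 100,
                       conc_es = 5 * 2^(0:6), noise_cv = 0.02),
    study = list(individuals = 4L,
                 matrices = c("plasma", "serum", "blood", "DBS_venous",
                              "DBS_finger"),
                 time_points = c("day0", "week1", "month1"),
                 matrix_profile = list(
                   plasma = list(ref = NA, sd = 0),
                   serum = list(ref = "plasma", sd = 0.05),
                   blood = list(ref = "plasma", sd = 0.5),
                   DBS_venous = list(ref = "plasma", sd = 0.4),
                   DBS_finger = list(ref = "DBS_venous", sd = 0.05)),
                 n_lipids = 100L, variable_class = "TG",
                 variable_class_cv = 0.25, within_cv = 0.1,
                 individual_sd = 0.15),
    polarity = "negative") {
  for (v in unlist(noise)) if (v < 0) .stopf("noise SDs must be >= 0")
  if (any(diff(dilution$volumes) >= 0))
    .stopf("dilution volumes must be strictly decreasing")
  if (dropout < 0 || dropout > 1) .stopf("dropout must lie in [0, 1]")
  structure(list(seed = as.integer(seed), classes = classes,
                 n_per_class = as.integer(n_per_class), noise = noise,
                 background_n = as.integer(background_n), dropout = dropout,
                 dilution = dilution, calibration = calibration,
                 study = study, polarity = polarity),
            class = "simulation_config")
}

.lognorm <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate a 4D reference library
#'
#' Entries are laid on per-class CCS-vs-m/z linear trends with Gaussian
#' scatter, RT uniform in the class window. One entry per class is marked as
#' the class internal standard. Each entry carries a synthetic reference
#' MS/MS spectrum. Identical coordinate pairs across entries are jittered
#' apart and logged.
#'
#' @param config a [simulation_config()].
#' @param n_per_class overrides `config$n_per_class`.
#' @return A list with `library` (analyte list), `spectra` (named spectrum
#'   store), `truth` (per-entry base areas and generating class parameters)
#'   and `jittered` (names regenerated to resolve coordinate collisions).
#' @export
gen_library <- function(config = simulation_config(),
                        n_per_class = config$n_per_class) {
  set.seed(config$seed)
  cls <- config$classes
  if (nrow(cls) < 1L) .stopf("need at least one class")
  rows <- list(); spectra <- list()
  for (i in seq_len(nrow(cls))) {
    mz <- sort(stats::runif(n_per_class, cls$mz_min[i], cls$mz_max[i]))
    rt <- stats::runif(n_per_class, cls$rt_min[i], cls$rt_max[i])
    ccs <- cls$ccs_intercept[i] + cls$ccs_slope[i] * mz +
      stats::rnorm(n_per_class, 0, cls$ccs_scatter[i])
    name <- sprintf("%s sim%02d", cls$class[i], seq_len(n_per_class))
    adduct <- if (config$polarity == "negative") "[M-H]-" else "[M+H]+"
    proton <- 1.007276
    rows[[i]] <- data.frame(
      name = name, lipid_class = cls$class[i], adduct = adduct,
      polarity = config$polarity,
      neutral_mass = if (config$polarity == "negative") mz + proton else
        mz - proton,
      expected_mz = mz, expected_rt = rt, expected_ccs = pmax(ccs, 50),
      formula = NA_character_, spectrum_id = name,
      is_istd = seq_len(n_per_class) == 1L, stringsAsFactors = FALSE)
    for (k in seq_len(n_per_class)) {
      npk <- sample(4:8, 1L)
      spectra[[name[k]]] <- spectrum(
        sort(stats::runif(npk, 100, mz[k] - 50)),
        stats::runif(npk, 10, 1000), precursor_mz = mz[k])
    }
  }
  lib <- do.call(rbind, rows)
  # resolve exact coordinate collisions by jitter (vanishingly rare)
  key <- paste(round(lib$expected_mz, 4), round(lib$expected_rt, 3),
               round(lib$expected_ccs, 2))
  jittered <- lib$name[duplicated(key)]
  while (anyDuplicated(key)) {
    d <- duplicated(key)
    lib$expected_mz[d] <- lib$expected_mz[d] + stats::runif(sum(d), 0.01, 0.05)
    key <- paste(round(lib$expected_mz, 4), round(lib$expected_rt, 3),
                 round(lib$expected_ccs, 2))
  }
  validate_analyte_list(lib)
  base_area <- stats::runif(nrow(lib), 1e4, 1e6)
  names(base_area) <- lib$name
  list(library = lib, spectra = spectra,
       truth = list(base_area = base_area, classes = cls), jittered = jittered)
}

# Jitter library coordinates by the configured measurement noise.
.observe <- function(lib, noise) {
  n <- nrow(lib)
  data.frame(
    mz = lib$expected_mz * (1 + stats::rnorm(n, 0, noise$mz_ppm_sd) * 1e-6),
    rt = pmax(0, lib$expected_rt + stats::rnorm(n, 0, noise$rt_sd)),
    ccs = lib$expected_ccs + stats::rnorm(n, 0, noise$ccs_sd))
}

.background_features <- function(n, lib, area_pool, polarity) {
  if (n == 0L)
    return(feature_table(numeric(0), numeric(0), numeric(0), numeric(0),
                         polarity))
  q <- stats::quantile(area_pool, c(0.05, 0.25))
  feature_table(
    mz = stats::runif(n, min(lib$expected_mz) - 50,
                      max(lib$expected_mz) + 50),
    rt = stats::runif(n, 0.5, max(lib$expected_rt) + 1),
    ccs = stats::runif(n, min(lib$expected_ccs) - 20,
                       max(lib$expected_ccs) + 20),
    area = stats::runif(n, q[[1L]], q[[2L]]), polarity = polarity)
}

#' Generate replicate feature-table runs from a library
#'
#' Each replicate holds the library features jittered by the measurement
#' noise model (subject to dropout) plus uniform background features whose
#' intensity matches the low quartile of the true features. The truth table
#' maps every emitted feature row to its source entry or `"background"`.
#'
#' @param lib_gen output of [gen_library()].
#' @param concentrations optional named abundance multipliers by entry name.
#' @param config a [simulation_config()].
#' @param n_replicates number of runs.
#' @param sample_prefix sample id prefix.
#' @return A list with `runs` (named list of feature tables) and `truth`
#'   (data frame: sample_id, run_row, source).
#' @export
gen_runs <- function(lib_gen, concentrations = NULL,
                     config = simulation_config(), n_replicates = 32L,
                     sample_prefix = "R") {
  set.seed(config$seed + 1L)
  lib <- lib_gen$library
  base <- lib_gen$truth$base_area
  conc <- rep(1, nrow(lib)); names(conc) <- lib$name
  if (!is.null(concentrations))
    conc[names(concentrations)] <- concentrations
  runs <- list(); truth <- list()
  for (r in seq_len(n_replicates)) {
    sid <- sprintf("%s%02d", sample_prefix, r)
    keep <- stats::runif(nrow(lib)) >= config$dropout
    obs <- .observe(lib[keep, , drop = FALSE], config$noise)
    area <- base[keep] * conc[keep] *
      .lognorm(sum(keep), config$noise$area_cv)
    ft <- feature_table(obs$mz, obs$rt, obs$ccs, area, config$polarity,
                        spectrum_id = lib$spectrum_id[keep], sample_id = sid)
    run <- ft
    bg <- .background_features(config$background_n, lib, base,
                               config$polarity)
    if (nrow(bg)) {
      bg$sample_id <- sid
      run <- rbind(ft, bg)
      attr(run, "polarity") <- config$polarity
      class(run) <- c("feature_table", "data.frame")
    }
    runs[[sid]] <- run
    truth[[sid]] <- data.frame(
      sample_id = sid, run_row = seq_len(nrow(run)),
      source = c(lib$name[keep], rep("background", nrow(bg))),
      stringsAsFactors = FALSE)
  }
  list(runs = runs, truth = do.call(rbind, truth))
}

#' Generate a dilution-ladder experiment
#'
#' True lipid areas scale proportionally with the matrix volume on column
#' (before noise); a planted set of artifact features stays flat across the
#' ladder. Defaults: 6 levels from 2 to 0.0625 ul in 1:2 steps, triplicates.
#'
#' @param lib_gen output of [gen_library()].
#' @param config a [simulation_config()].
#' @return A list with `runs`, `design` (sample_id, dilution_volume,
#'   batch_role) and `truth` (`true_names`, `artifact_coords`).
#' @export
gen_dilution_experiment <- function(lib_gen, config = simulation_config()) {
  set.seed(config$seed + 2L)
  lib <- lib_gen$library
  base <- lib_gen$truth$base_area
  vols <- config$dilution$volumes
  n_rep <- config$dilution$n_replicates
  n_art <- config$dilution$n_artifacts
  art <- .background_features(n_art, lib, base, config$polarity)
  runs <- list(); design <- list()
  for (li in seq_along(vols)) for (r in seq_len(n_rep)) {
    sid <- sprintf("D%02d_%d", li, r)
    obs <- .observe(lib, config$noise)
    area <- base * (vols[li] / max(vols)) *
      .lognorm(nrow(lib), config$noise$area_cv)
    ft <- feature_table(obs$mz, obs$rt, obs$ccs, area, config$polarity,
                        sample_id = sid)
    if (n_art > 0L) {
      a <- art
      a$mz <- a$mz * (1 + stats::rnorm(n_art, 0, config$noise$mz_ppm_sd) * 1e-6)
      a$rt <- pmax(0, a$rt + stats::rnorm(n_art, 0, config$noise$rt_sd))
      a$ccs <- a$ccs + stats::rnorm(n_art, 0, config$noise$ccs_sd)
      a$area <- a$area * .lognorm(n_art, config$noise$area_cv)
      a$sample_id <- sid
      ft <- rbind(ft, a)
      attr(ft, "polarity") <- config$polarity
      class(ft) <- c("feature_table", "data.frame")
    }
    runs[[sid]] <- ft
    design[[sid]] <- data.frame(sample_id = sid, individual = NA_character_,
                                matrix = "plasma", time_point = NA_character_,
                                dilution_volume = vols[li],
                                batch_role = "sample",
                                nominal_conc = NA_real_,
                                stringsAsFactors = FALSE)
  }
  list(runs = runs, design = do.call(rbind, design),
       truth = list(true_names = lib$name,
                    artifact_coords = as.data.frame(art)[, c("mz", "rt",
                                                             "ccs", "area")]))
}

#' Generate a calibration series
#'
#' Seven external-standard points spanning the configured concentration
#' range (>= 64-fold by default) with a power-law response
#' `areaRatio = c1 * concRatio^(1/c2)` under multiplicative log-normal
#' noise.
#'
#' @param config a [simulation_config()].
#' @param noise_cv overrides the configured calibration noise CV.
#' @return A list with `points` ([calibration_points()]) and `truth`
#'   (`c1`, `c2`, `conc_is`).
#' @export
gen_calibration <- function(config = simulation_config(),
                            noise_cv = config$calibration$noise_cv) {
  set.seed(config$seed + 3L)
  cal <- config$calibration
  conc_ratio <- cal$conc_es / cal$conc_is
  base_is <- 1e5
  area_is <- base_is * .lognorm(length(cal$conc_es), noise_cv)
  area_es <- base_is * cal$c1 * conc_ratio^(1 / cal$c2) *
    .lognorm(length(cal$conc_es), noise_cv)
  list(points = calibration_points(cal$conc_es, cal$conc_is, area_es,
                                   area_is),
       truth = list(c1 = cal$c1, c2 = cal$c2, conc_is = cal$conc_is))
}

#' Generate a blood-matrix study
#'
#' Produces a molar concentration matrix and study design for the configured
#' individuals x matrices x time points grid. Matrix lipidomes are derived
#' from a plasma profile by per-lipid log-normal offsets (serum and the
#' second dried-blood-spot collection nearly identical to their references,
#' whole blood strongly displaced), individuals carry their own log-normal
#' profile, and time points are stable except for the configured
#' high-variance class. The seven marker species needed by
#' [marker_ratios()] are always present.
#'
#' @param config a [simulation_config()].
#' @return A list with `conc` (samples x lipids, nmol/mL), `design`,
#'   `class_map` and `truth` (base concentrations and matrix profiles).
#' @export
gen_study <- function(config = simulation_config()) {
  set.seed(config$seed + 4L)
  st <- config$study
  if (st$individuals < 2L) .stopf("need at least 2 individuals")
  markers <- c("Cer d18:1_24:1" = "Cer", "Cer d18:1_24:0" = "Cer",
               "Cer d18:1_16:0" = "Cer", "Cer d18:1_18:0" = "Cer",
               "PC 38:5" = "PC", "PC 14:0_22:6" = "PC", "PC 16:0_16:0" = "PC")
  classes <- config$classes$class
  n_extra <- max(0L, st$n_lipids - length(markers))
  extra_class <- rep(classes, length.out = n_extra)
  lipids <- c(names(markers),
              sprintf("%s sim%03d", extra_class, seq_len(n_extra)))
  class_map <- c(unname(markers), extra_class)
  names(class_map) <- lipids
  n_lip <- length(lipids)
  base <- 10^stats::runif(n_lip, -2, 2)          # nmol/mL, 4 decades
  names(base) <- lipids

  profiles <- list()
  for (m in st$matrices) {
    mp <- st$matrix_profile[[m]] %||% list(ref = "plasma", sd = 0.3)
    ref <- if (is.na(mp$ref %||% NA)) base else {
      if (is.null(profiles[[mp$ref]]))
        .stopf("matrix_profile reference '%s' must precede '%s'", mp$ref, m)
      profiles[[mp$ref]]
    }
    profiles[[m]] <- ref * exp(stats::rnorm(n_lip, 0, mp$sd))
  }
  indiv_effect <- lapply(seq_len(st$individuals), function(i)
    exp(stats::rnorm(n_lip, 0, st$individual_sd)))

  rows <- list(); design <- list()
  variable <- class_map == st$variable_class
  for (i in seq_len(st$individuals))
    for (m in st$matrices)
      for (tp in st$time_points) {
        sid <- sprintf("I%d_%s_%s", i, m, tp)
        time_noise <- rep(1, n_lip)
        time_noise[variable] <- .lognorm(sum(variable), st$variable_class_cv)
        rows[[sid]] <- profiles[[m]] * indiv_effect[[i]] * time_noise *
          .lognorm(n_lip, st$within_cv)
        design[[sid]] <- data.frame(
          sample_id = sid, individual = sprintf("I%d", i), matrix = m,
          time_point = tp, dilution_volume = NA_real_, batch_role = "sample",
          nominal_conc = NA_real_, stringsAsFactors = FALSE)
      }
  conc <- do.call(rbind, rows)
  colnames(conc) <- lipids
  list(conc = conc, design = do.call(rbind, design), class_map = class_map,
       truth = list(base = base, profiles = profiles))
}
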