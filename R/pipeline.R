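# Pipeline orchestration: a declarative stage chain over a shared state with
# a machine-readable run manifest recording the selection funnel.

.PIPELINE_STAGES <- c("simulate", "align", "filter_presence", "subtract_blank",
                      "filter_dilution", "annotate", "quantify")

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           force = TRUE, digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a staged processing pipeline
#'
#' Executes the named stages in order over a shared state and emits exactly
#' one run manifest (tool version, config hash, seed, per-stage input/output
#' counts, timestamps). Unknown stage names are rejected before anything
#' executes; a stage failure aborts with a manifest recording the completed
#' prefix.
#'
#' Available stages: `simulate` (seeded synthetic batch: library, replicate
#' runs, blank, optional dilution ladder and calibration series), `align`,
#' `filter_presence`, `subtract_blank`, `filter_dilution` (dilution response
#' of the buckets overlapping the simulated ladder), `annotate`, `quantify`
#' (multi-point, against the class ISTD bucket, recursive values excluded).
#'
#' @param config list with `seed`, `stages` (character vector or list of
#'   `list(name=, params=)`), optional per-stage `params`, optional
#'   `out_dir` to write the manifest JSON.
#' @return A list with `state` (stage outputs) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stages <- lapply(config$stages, function(s)
    if (is.character(s)) list(name = s, params = list()) else
      list(name = s$name, params = s$params %||% list()))
  bad <- setdiff(vapply(stages, `[[`, character(1L), "name"),
                 .PIPELINE_STAGES)
  if (length(bad))
    .stopf("unknown stage name(s): %s (known: %s)",
           paste(bad, collapse = ", "),
           paste(.PIPELINE_STAGES, collapse = ", "))
  seed <- config$seed %||% 1L
  manifest <- list(
    tool = "lipid4d",
    version = as.character(utils::packageVersion("lipid4d")),
    config_hash = .config_hash(config[setdiff(names(config), "out_dir")]),
    seed = seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(), success = FALSE)
  state <- list(seed = seed)
  finish <- function() {
    manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  for (sg in stages) {
    res <- tryCatch(.run_stage(sg$name, state, sg$params),
                    error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[length(manifest$stages) + 1L]] <-
        list(name = sg$name, error = conditionMessage(res))
      finish()
      .stopf("stage '%s' failed: %s", sg$name, conditionMessage(res))
    }
    state <- res$state
    manifest$stages[[length(manifest$stages) + 1L]] <-
      c(list(name = sg$name), res$counts)
  }
  manifest$success <- TRUE
  finish()
  list(state = state, manifest = manifest)
}

.run_stage <- function(name, state, params) {
  switch(name,
    simulate = {
      cfg_args <- params$config %||% list()
      cfg <- do.call(simulation_config,
                     c(list(seed = state$seed), cfg_args))
      state$config <- cfg
      state$tolerances <- tolerance_set()
      lg <- gen_library(cfg, n_per_class = params$n_per_class %||%
                          cfg$n_per_class)
      state$library <- lg$library
      state$spectra <- lg$spectra
      state$lib_gen <- lg
      rr <- gen_runs(lg, config = cfg,
                     n_replicates = params$n_replicates %||% 8L)
      state$runs <- rr$runs
      state$runs_truth <- rr$truth
      # blank: re-draw background-like features so some buckets match it
      set.seed(cfg$seed + 9L)
      state$blank <- .background_features(params$blank_n %||% 30L,
                                          lg$library, lg$truth$base_area,
                                          cfg$polarity)
      if (isTRUE(params$with_dilution)) {
        dil <- gen_dilution_experiment(lg, cfg)
        state$dilution <- dil
        state$dilution_bt <- align_buckets(dil$runs, state$tolerances)
      }
      state$calibration <- gen_calibration(cfg)
      n_feat <- sum(vapply(state$runs, nrow, integer(1L)))
      list(state = state, counts = list(n_in = n_feat, n_out = n_feat))
    },
    align = {
      if (is.null(state$runs)) .stopf("no runs in state; run simulate first")
      n_feat <- sum(vapply(state$runs, nrow, integer(1L)))
      state$bt <- align_buckets(state$runs,
                                state$tolerances %||% tolerance_set())
      list(state = state,
           counts = list(n_in = n_feat, n_out = n_buckets(state$bt)))
    },
    filter_presence = {
      n_samples <- length(state$bt$samples)
      rule <- presence_rule(
        n_samples,
        params$t_seed %||% max(1L, ceiling(17 / 32 * n_samples)),
        params$t_final %||% n_samples)
      n_in <- n_buckets(state$bt)
      state$bt <- presence_filter(state$bt, rule)
      list(state = state,
           counts = list(n_in = n_in, n_out = n_buckets(state$bt)))
    },
    subtract_blank = {
      n_in <- n_buckets(state$bt)
      state$bt <- background_subtract(state$bt, state$blank,
                                      state$tolerances %||% tolerance_set())
      list(state = state,
           counts = list(n_in = n_in, n_out = n_buckets(state$bt)))
    },
    filter_dilution = {
      if (is.null(state$dilution_bt))
        .stopf("no dilution experiment in state; simulate with_dilution")
      n_in <- n_buckets(state$bt)
      dil <- dilution_response_filter(
        state$dilution_bt, state$dilution$design,
        do.call(dilution_filter_params, params$filter %||% list()))
      ok <- dil$kept$buckets
      a <- feature_table(state$bt$buckets$mz, state$bt$buckets$rt,
                         state$bt$buckets$ccs, rep(1, n_in),
                         state$bt$polarity)
      keep <- if (nrow(ok)) {
        b <- feature_table(ok$mz, ok$rt, ok$ccs, rep(1, nrow(ok)),
                           state$bt$polarity)
        sort(overlap_match(a, b,
                           state$tolerances %||% tolerance_set())$pairs$idx_a)
      } else integer(0)
      state$bt <- .bt_subset(state$bt, keep, "filter_dilution")
      list(state = state,
           counts = list(n_in = n_in, n_out = n_buckets(state$bt)))
    },
    annotate = {
      n_in <- n_buckets(state$bt)
      state$bt <- annotate_table(state$bt, state$library,
                                 do.call(score_bands, params$bands %||%
                                           list()),
                                 spectra = state$spectra)
      list(state = state,
           counts = list(n_in = n_in, n_out = nrow(state$bt$annotations)))
    },
    quantify = {
      ann <- state$bt$annotations
      if (is.null(ann)) .stopf("annotate before quantify")
      n_in <- nrow(ann)
      model <- fit_calibration(state$calibration$points)
      ctx <- quant_context()
      istd_names <- state$library$name[state$library$is_istd]
      istd_bucket <- ann$bucket_id[ann$name %in% istd_names][1L]
      if (is.na(istd_bucket)) .stopf("no ISTD bucket annotated")
      keep_ids <- ann$bucket_id
      idx <- match(keep_ids, state$bt$buckets$bucket_id)
      masses <- state$library$neutral_mass[match(ann$name,
                                                 state$library$name)]
      names(masses) <- keep_ids
      sub <- .bt_subset(state$bt, sort(idx), "quantify_subset")
      q <- quantify_bucket_table(sub, istd_bucket, model, ctx, masses)
      state$quant <- q
      state$calibration_model <- model
      quantified <- sum(rowSums(is.finite(q$C)) > 0)
      list(state = state,
           counts = list(n_in = n_in, n_out = quantified))
    },
    .stopf("unknown stage '%s'", name))
}
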