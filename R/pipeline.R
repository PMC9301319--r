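# End-to-end orchestration: synthesize (or load) stimuli and ratings,
# QC, successive-categories scaling, the perception-statistics
# battery, acoustic features, and fusion models, with per-stage file
# outputs and a JSON manifest under one master seed.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain. Exactly one data
#' source must be given: a synthetic design (the default) or paths to
#' existing ratings/metadata CSV files.
#'
#' @param design synthetic experiment design (see
#'   [build_stimulus_set()]); ignored when `ratings_path` is given.
#' @param n_raters simulated raters.
#' @param latent a [latent_percept_model()].
#' @param ratings_path,metadata_path optional CSV inputs replacing the
#'   synthetic source.
#' @param k_sd validity-filter multiplier.
#' @param clip scaling clip mode (`"proportion"` or `"drop"`).
#' @param alpha significance level for the statistics stage.
#' @param duration_s,sample_rate audio synthesis parameters.
#' @param window_s,hop_s feature framing parameters.
#' @param extract_audio_features run the (relatively slow) audio
#'   synthesis + feature + model stages?
#' @param model_kinds model kinds for the fusion-model stage.
#' @param folds cross-validation folds.
#' @param coef_threshold cutoff for the fusion equations.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = default_design(), n_raters = 32,
                            latent = latent_percept_model(),
                            ratings_path = NULL, metadata_path = NULL,
                            k_sd = 1.5, clip = "proportion", alpha = 0.05,
                            duration_s = 2, sample_rate = 44100,
                            window_s = 0.0232, hop_s = 0.0058,
                            extract_audio_features = TRUE,
                            model_kinds = c("linear_lasso", "random_forest",
                                            "mlp"),
                            folds = 4, coef_threshold = 4, seed = 1L) {
  if (!is.null(ratings_path) && is.null(metadata_path))
    stop("metadata_path is required when loading ratings from file")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys match the arguments of
#' [pipeline_config()]; `design` may be a nested culture/class count
#' mapping and `latent` a list of [latent_percept_model()] arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$design))
    raw$design <- lapply(raw$design, function(cu) unlist(cu))
  if (!is.null(raw$latent)) {
    la <- raw$latent
    if (!is.null(la$class_means))
      la$class_means <- do.call(rbind, la$class_means)
    raw$latent <- do.call(latent_percept_model, la)
  }
  do.call(pipeline_config, raw)
}

stage_seeds <- function(seed, n = 8) {
  with_preserved_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Run the full timbre-fusion analysis pipeline
#'
#' Executes, in order: stimulus-set construction, rating synthesis (or
#' CSV load), QC (alpha + validity filter), successive-categories
#' scaling of all four attributes, the statistics battery (category
#' frequencies, ANOVAs, SNK, correlations, preference map) and — when
#' audio stages are enabled — feature extraction and the grouped
#' fusion models. Each stage writes its tables under `out_dir`; a JSON
#' manifest records parameters, seeds and per-stage record counts.
#' Re-running with the same config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return list with all stage results (`metadata`, `ratings`, `qc`,
#'   `scales`, `stats`, `features`, `models`, `manifest`), invisibly
#'   written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("timbrefuse")),
                   seed = config$seed, stage_seeds = seeds,
                   parameters = list(k_sd = config$k_sd, clip = config$clip,
                                     alpha = config$alpha,
                                     folds = config$folds,
                                     coef_threshold = config$coef_threshold),
                   stages = list())
  fail <- function(stage, msg) stop("pipeline stage '", stage, "' failed: ",
                                    msg, call. = FALSE)

  # -- stage 1: stimuli + ratings ------------------------------------
  if (is.null(config$ratings_path)) {
    stim <- build_stimulus_set(config$design, seed = seeds[1],
                               duration_s = config$duration_s,
                               sample_rate = config$sample_rate)
    metadata <- stim$metadata
    ratings <- synth_ratings(config$latent, metadata,
                             n_raters = config$n_raters, seed = seeds[2])
  } else {
    if (!file.exists(config$ratings_path))
      fail("load", paste("ratings file not found:", config$ratings_path))
    if (!file.exists(config$metadata_path))
      fail("load", paste("metadata file not found:", config$metadata_path))
    stim <- NULL
    ratings <- utils::read.csv(config$ratings_path, stringsAsFactors = FALSE)
    metadata <- utils::read.csv(config$metadata_path,
                                stringsAsFactors = FALSE)
  }
  utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(ratings, file.path(out_dir, "ratings_raw.csv"),
                   row.names = FALSE)
  manifest$stages$stimuli <- list(n_stimuli = nrow(metadata),
                                  n_ratings = nrow(ratings))

  # -- stage 2: QC ---------------------------------------------------
  qc <- validity_filter(ratings, k_sd = config$k_sd)
  utils::write.csv(qc$ratings, file.path(out_dir, "ratings_clean.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(alpha = as.list(qc$report$alpha),
         n_removed = qc$report$n_removed, n_cells = qc$report$n_cells),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  manifest$stages$qc <- list(n_removed = qc$report$n_removed,
                             alpha = as.list(qc$report$alpha))

  # -- stage 3: scaling ----------------------------------------------
  sc <- fit_all_attributes(qc$ratings, clip = config$clip)
  utils::write.csv(sc$values, file.path(out_dir, "scales.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(sc$scales, function(s) unname(s$boundaries)),
                       file.path(out_dir, "boundaries.json"), digits = NA)
  manifest$stages$scaling <- list(n_stimuli = nrow(sc$values),
                                  n_attributes = length(sc$scales))

  # -- stage 4: statistics battery -----------------------------------
  meta_idx <- match(sc$values$stimulus_id, metadata$stimulus_id)
  env_cls <- metadata$envelope_class[meta_idx]
  culture <- metadata$culture[meta_idx]
  stats_out <- list()
  cat_cols <- paste0(TIMBRE_ATTRIBUTES, "_cat")
  stats_out$frequencies <- lapply(stats::setNames(cat_cols, TIMBRE_ATTRIBUTES),
                                  function(cc)
    category_frequencies(sc$values[[cc]], env_cls))
  both_factors <- length(unique(env_cls)) >= 2 &&
    length(unique(culture)) >= 2
  stats_out$anova <- lapply(stats::setNames(cat_cols, TIMBRE_ATTRIBUTES),
                            function(cc) list(
    one_way_envelope = one_way_anova(sc$values[[cc]], env_cls),
    two_way = if (both_factors)
      two_way_anova(sc$values[[cc]], env_cls, culture,
                    alpha = config$alpha),
    snk = snk_groups(sc$values[[cc]], env_cls, alpha = config$alpha)))
  corr_in <- sc$values[cat_cols]
  names(corr_in) <- TIMBRE_ATTRIBUTES
  stats_out$correlations <- attribute_correlations(corr_in)
  stats_out$mdpref <- mdpref_map(corr_in,
                                 data.frame(envelope_class = env_cls,
                                            culture = culture))
  utils::write.csv(
    data.frame(attribute = rownames(stats_out$correlations$r),
               stats_out$correlations$r),
    file.path(out_dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(stimulus_id = sc$values$stimulus_id, stats_out$mdpref$scores),
    file.path(out_dir, "mdpref_scores.csv"), row.names = FALSE)
  manifest$stages$statistics <- list(
    n_attributes = length(stats_out$anova),
    r_fusion_segregation =
      unname(stats_out$correlations$r["fusion", "segregation"]))

  features <- NULL
  models <- NULL
  if (config$extract_audio_features) {
    if (is.null(stim))
      fail("features", "audio stages need a synthetic stimulus set")
    # -- stage 5: acoustic features ----------------------------------
    features <- feature_table(stim, window_s = config$window_s,
                              hop_s = config$hop_s)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    manifest$stages$features <- list(n_stimuli = nrow(features),
                                     n_features = ncol(features) - 1L)
    # -- stage 6: fusion models --------------------------------------
    target <- stats::setNames(sc$values$fusion_cat, sc$values$stimulus_id)
    models <- run_grouped_models(features, target, metadata,
                                 kinds = config$model_kinds,
                                 k = config$folds,
                                 threshold = config$coef_threshold,
                                 seed = seeds[6])
    utils::write.csv(models$grid, file.path(out_dir, "model_grid.csv"),
                     row.names = FALSE)
    writeLines(vapply(models$equations, function(e) e$text, character(1)),
               file.path(out_dir, "fusion_equations.txt"))
    manifest$stages$models <- list(n_cells = nrow(models$grid))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metadata = metadata, ratings = ratings, qc = qc,
                 scales = sc, stats = stats_out, features = features,
                 models = models, manifest = manifest))
}
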