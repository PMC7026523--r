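# Pipeline orchestration: configuration validation and the end-to-end run
# (simulate -> [holograms -> reconstruct] -> features -> train -> score ->
# report) with a reproducible manifest.

config_defaults <- function() {
  list(
    seed = 1L,
    field_size = 1024L, pixel_pitch = 0.18, wavelength = 632,
    delta_n = 0.044, cells_per_field = 12L,
    lines = NULL,  # NULL -> default_line_profiles()
    use_holograms = FALSE, carrier = c(0.35, 0.15), noise_sd = 0,
    tilt_max = 0.02, quad_max = 1e-4,
    svm_C = 1, kernel_scale = 1, k_pcs = 6L, folds = 5L, repeats = 5L,
    n_trees = 200L, learn_rate = 0.1, test_n = 80L, outlier_sd = 5.6,
    min_area = 50L)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a JSON/YAML file path, a named list, or `NULL` (all defaults).
#' Defaults are injected for missing keys (632 nm, 0.18 um pitch, delta_n
#' 0.044, C = 1, 6 PCs, 5x5-fold CV, 200 learners, learning rate 0.1, 80
#' held-out cells per line, 5.6 SD outlier rule); unknown keys are rejected,
#' as are values violating the module invariants.
#'
#' @param config path, named list, or `NULL`.
#' @return normalized configuration of class `em_config`.
#' @export
validate_config <- function(config = NULL) {
  if (inherits(config, "em_config")) return(config)
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config) else
      jsonlite::fromJSON(config, simplifyVector = TRUE,
                         simplifyDataFrame = FALSE)
  }
  config <- config %||% list()
  if (!is.list(config)) stop("config must be a file path or a named list")
  def <- config_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(def, config)

  num_keys <- c("pixel_pitch", "wavelength", "delta_n", "noise_sd", "svm_C",
                "kernel_scale", "learn_rate", "outlier_sd", "tilt_max",
                "quad_max")
  int_keys <- c("seed", "field_size", "cells_per_field", "k_pcs", "folds",
                "repeats", "n_trees", "test_n", "min_area")
  bad <- c(
    num_keys[!vapply(cfg[num_keys], function(v)
      is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))],
    int_keys[!vapply(cfg[int_keys], function(v)
      is.numeric(v) && length(v) == 1 && is.finite(v) && v == round(v),
      logical(1))],
    if (!(is.numeric(cfg$carrier) && length(cfg$carrier) == 2)) "carrier",
    if (!is.logical(cfg$use_holograms)) "use_holograms")
  if (length(bad)) {
    stop(sprintf("config type mismatch for key(s): %s",
                 paste(unique(bad), collapse = ", ")))
  }
  if (cfg$delta_n <= 0) stop("delta_n must be > 0")
  if (cfg$pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  if (cfg$field_size < 64) stop("field_size must be >= 64")
  if (cfg$k_pcs < 1 || cfg$k_pcs > 17) stop("k_pcs must lie in [1, 17]")
  if (cfg$folds < 2) stop("folds must be >= 2")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$svm_C <= 0) stop("svm_C must be > 0")
  if (cfg$kernel_scale <= 0) stop("kernel_scale must be > 0")
  if (cfg$test_n < 0) stop("test_n must be >= 0")

  cfg$lines <- if (is.null(cfg$lines)) default_line_profiles() else {
    lapply(cfg$lines, function(ln) {
      if (inherits(ln, "line_profile")) return(ln)
      do.call(line_profile, ln)
    })
  }
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  structure(cfg, class = "em_config")
}

as_sim_config <- function(cfg) {
  sim_config(line_profiles = cfg$lines, field_size = cfg$field_size,
             pixel_pitch = cfg$pixel_pitch, wavelength = cfg$wavelength,
             delta_n = cfg$delta_n, cells_per_field = cfg$cells_per_field,
             seed = cfg$seed)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- cfg
  plain$lines <- lapply(plain$lines, unclass)
  jsonlite::write_json(plain, tmp, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# lines that are pure archetypes (fixed blend 0 or 1)
archetype_lines <- function(cfg) {
  is_arch <- vapply(cfg$lines, function(p)
    is.null(p$blend_beta) && p$blend_m %in% c(0, 1), logical(1))
  vapply(cfg$lines[is_arch], `[[`, character(1), "name")
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order: simulate the configured populations;
#' optionally render off-axis holograms with random tilt/quadratic
#' aberrations and reconstruct them back to phase; extract the per-cell
#' feature table; partition the archetype lines and train the EM model
#' bundle; transfer-score the held-out archetype cells and every
#' non-archetype cell; and assemble the evaluation report. The whole run is a
#' pure function of the configuration, and the returned manifest reconciles
#' the per-stage counts.
#'
#' @param config anything accepted by [validate_config()].
#' @param out_dir optional output directory; when given, the feature table,
#'   score table, model JSON, report summary and manifest are written there
#'   and checksummed in the manifest.
#' @param keep_fields keep the simulated fields in the returned object
#'   (memory-heavy for large runs).
#' @return object of class `em_run`: list with `manifest`, `features`,
#'   `model`, `scores`, `report`, `cv` and (optionally) `fields`.
#' @export
run_full <- function(config = NULL, out_dir = NULL, keep_fields = FALSE) {
  cfg <- validate_config(config)
  t0 <- Sys.time()

  sim <- simulate_dataset(as_sim_config(cfg))
  gen_counts <- table(sim$truth$line)

  if (cfg$use_holograms) {
    sim$fields <- lapply(seq_along(sim$fields), function(i) {
      f <- sim$fields[[i]]
      aseed <- derive_seed(cfg$seed, 5000L + i)
      ab <- with_seed(aseed, list(
        tilt = stats::runif(2, -cfg$tilt_max, cfg$tilt_max),
        quad = stats::runif(2, -cfg$quad_max, cfg$quad_max)))
      f <- render_hologram(f, carrier = cfg$carrier, tilt = ab$tilt,
                           quadratic = ab$quad, noise_sd = cfg$noise_sd,
                           seed = aseed)
      rec <- reconstruct_phase(f$hologram)
      f$phase <- rec$phase
      f$aberration_applied <- ab
      f$aberration_fit <- rec$model
      f
    })
  }

  features <- build_feature_table(sim$fields, min_area = cfg$min_area)

  arch <- archetype_lines(cfg)
  if (length(arch) < 2) {
    stop("pipeline needs at least two archetype lines (blend 0 and blend 1)")
  }
  arch_tab <- features[features$line %in% arch, , drop = FALSE]
  part <- partition_data(arch_tab, test_n = cfg$test_n,
                         seed = derive_seed(cfg$seed, 11))
  model <- em_train(part$train, k = cfg$k_pcs, C = cfg$svm_C,
                    kernel_scale = cfg$kernel_scale, n_trees = cfg$n_trees,
                    learn_rate = cfg$learn_rate,
                    seed = derive_seed(cfg$seed, 12))
  cv <- crossvalidate(
    pca_transform(model$pca, part$train), em_label(part$train$blend >= 0.5),
    trainer = function(x, y) train_linear_svm(x, y, C = cfg$svm_C,
                                              kernel_scale = cfg$kernel_scale),
    folds = cfg$folds, repeats = cfg$repeats,
    seed = derive_seed(cfg$seed, 13))

  unknown_tab <- features[!features$line %in% arch, , drop = FALSE]
  score_tab <- rbind(part$test, unknown_tab)
  scores <- transfer_score(model, score_tab)
  true_class <- ifelse(score_tab$line %in% arch,
                       ifelse(score_tab$blend >= 0.5, "M", "E"), NA)
  report <- evaluation_report(scores, true_class, outlier_sd = cfg$outlier_sd)

  outputs <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(features = file.path(out_dir, "features.csv"),
               scores = file.path(out_dir, "scores.csv"),
               model = file.path(out_dir, "model.json"))
    write_table_csv(features, paths["features"])
    write_table_csv(as.data.frame(scores), paths["scores"])
    em_model_save(model, paths["model"])
    summary_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(list(
      accuracy = lapply(report$performance, function(p)
        if (is.null(p)) NULL else p$accuracy),
      auc = lapply(report$performance, function(p)
        if (is.null(p) || is.null(p$roc)) NULL else p$roc$auc),
      excluded_ids = report$excluded_ids,
      cv_accuracy = cv$accuracy), summary_path, digits = NA,
      auto_unbox = TRUE)
    paths <- c(paths, report = summary_path)
    outputs <- lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  }

  manifest <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("emscore")),
    counts = list(
      generated = as.list(gen_counts),
      features = nrow(features),
      train = nrow(part$train), test = nrow(part$test),
      scored = nrow(scores), excluded = length(report$excluded_ids)),
    cv_accuracy = list(mean = cv$mean, sd = cv$sd),
    outputs = outputs)
  timestamps <- list(started = t0, finished = Sys.time())

  if (!is.null(out_dir)) {
    jsonlite::write_json(c(manifest, list(timestamps = lapply(timestamps, format))),
                         file.path(out_dir, "manifest.json"), digits = NA,
                         auto_unbox = TRUE, force = TRUE)
  }

  structure(list(manifest = manifest, timestamps = timestamps,
                 features = features, model = model, scores = scores,
                 report = report, cv = cv, partition = part,
                 fields = if (keep_fields) sim$fields else NULL),
            class = "em_run")
}

#' @export
print.em_run <- function(x, ...) {
  cat(sprintf("<em_run> %d cells featurized, %d scored; CV accuracy %.3f +/- %.3f\n",
              x$manifest$counts$features, x$manifest$counts$scored,
              x$manifest$cv_accuracy$mean, x$manifest$cv_accuracy$sd))
  invisible(x)
}
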