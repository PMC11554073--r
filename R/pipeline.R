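#' Default pipeline configuration
#'
#' Settings for a full synthetic-cohort run of every stage. The defaults are
#' deliberately small (a 60-patient cohort on a compact grid with 3 CV folds
#' and 2 repeats) so a complete run finishes in about a minute; the
#' reference protocol corresponds to `n_patients = 150`, `folds = 5`,
#' `repeats = 10`.
#'
#' @param ... Overrides of the default entries.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_patients = 60L,
    grid_shape = c(32L, 32L, 32L),
    folds = 3L, repeats = 2L,
    window = 24L,
    latent_dim = 48L,
    vae = list(hidden_width = 64L, pool = c(2L, 4L, 4L), epochs = 4L,
               batch_size = 16L, learning_rate = 3e-3, kl_weight = 1e-3),
    n_pretrain = 15L,
    nn = list(hidden_widths = c(32L, 16L), dropout = 0.2, epochs = 120L,
              batch_size = 32L, learning_rate = 1e-3),
    baselines = c("random_forest", "xgboost"),
    augment = FALSE,
    n_permutations = 20L,
    outcome = "ordering")
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Chains every stage on a synthetic cohort: simulate -> slice-window
#' selection and channel split -> VAE pretraining and latent extraction ->
#' clinical encoding and matrix assembly -> repeated cross-validation of the
#' clinical, MRI and multimodal neural networks (plus tuned tree-ensemble
#' baselines on the multimodal matrix) -> temporal-split test evaluation ->
#' grouped permutation importance -> baseline-characteristics table. All
#' outputs are plain text (CSV/JSON) under `out_dir`, listed in a run
#' manifest; reruns with the same config and seed are bit-identical except
#' for manifest timestamps.
#'
#' @param config A [pipeline_config()] (or a path to a YAML/JSON file with
#'   the same fields).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @return Invisibly, a list with the manifest and in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    cfg_file <- config
    config <- if (grepl("\\.ya?ml$", cfg_file)) yaml::read_yaml(cfg_file)
              else jsonlite::read_json(cfg_file, simplifyVector = TRUE)
    config <- do.call(pipeline_config, config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("kpsfusion")),
                   config_hash = config_hash(config), seed = seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  note <- function(stage, files) {
    manifest$stages[[stage]] <<- list(outputs = as.list(files))
    message(sprintf("[%s] done (%s)", stage,
                    paste(basename(files), collapse = ", ")))
  }

  stage <- "simulate"
  result <- tryCatch({
    model <- switch(config$outcome,
                    ordering = ordering_outcome_model(),
                    importance = importance_outcome_model(),
                    null = kps_outcome_model(),
                    stop("unknown outcome model tag: ", config$outcome))
    gen_cfg <- cohort_config(grid_shape = config$grid_shape)
    cohort <- simulate_cohort(config$n_patients, model, config = gen_cfg,
                              seed = seed)
    clin_csv <- file.path(out_dir, "clinical.csv")
    write_clinical_csv(cohort, clin_csv)
    note(stage, clin_csv)

    stage <- "pretrain_vae"
    shape <- c(config$window, config$grid_shape[2], config$grid_shape[3])
    v1 <- do.call(vae_config, c(list(latent_dim = config$latent_dim,
                                     input_channels = 2L, input_shape = shape,
                                     seed = seed + 2L), config$vae))
    v2 <- do.call(vae_config, c(list(latent_dim = config$latent_dim,
                                     input_channels = 1L, input_shape = shape,
                                     seed = seed + 3L), config$vae))
    vaes <- pretrain_cohort_vaes(config$n_pretrain, v1, v2,
                                 seed = seed + 104729L, config = gen_cfg)
    loss_csv <- file.path(out_dir, "vae_loss.csv")
    utils::write.csv(rbind(cbind(vae = "lesion", vaes$vae1$loss_history),
                           cbind(vae = "mask", vaes$vae2$loss_history)),
                     loss_csv, row.names = FALSE)
    note(stage, loss_csv)

    stage <- "extract_features"
    cohort <- extract_cohort_features(cohort, vaes$vae1, vaes$vae2,
                                      augment = isTRUE(config$augment))
    feat_csv <- file.path(out_dir, "mri_features.csv")
    utils::write.csv(data.frame(patient_id = rownames(cohort$mri),
                                cohort$mri, check.names = FALSE),
                     feat_csv, row.names = FALSE)
    note(stage, feat_csv)

    stage <- "evaluate_cv"
    nn_cfg <- do.call(nn_config, config$nn)
    builder <- nn_builder(nn_cfg)
    reports <- list()
    files <- character()
    for (mode in c("clinical", "mri", "multimodal")) {
      X <- build_matrix(cohort, mode = mode)
      rep_m <- repeated_cv(builder, X, folds = config$folds,
                           repeats = config$repeats, seed = seed + 31L)
      reports[[mode]] <- rep_m
      f <- file.path(out_dir, sprintf("cv_%s.csv", mode))
      utils::write.csv(rep_m$records, f, row.names = FALSE)
      roc <- mean_roc_curve(rep_m$fold_predictions)
      fr <- file.path(out_dir, sprintf("roc_%s.csv", mode))
      utils::write.csv(roc, fr, row.names = FALSE)
      files <- c(files, f, fr)
    }
    for (fam in config$baselines) {
      X <- build_matrix(cohort, mode = "multimodal")
      rep_b <- repeated_cv(baseline_builder(baseline_spec(fam)), X,
                           folds = config$folds, repeats = config$repeats,
                           seed = seed + 31L)
      f <- file.path(out_dir, sprintf("cv_baseline_%s.csv", fam))
      utils::write.csv(rep_b$records, f, row.names = FALSE)
      reports[[paste0("baseline_", fam)]] <- rep_b
      files <- c(files, f)
    }
    note(stage, files)

    stage <- "evaluate_test"
    split <- temporal_split(cohort)
    test_rows <- list()
    models <- list()
    for (mode in c("clinical", "mri", "multimodal")) {
      Xtr <- build_matrix(cohort, mode = mode, train_ids = split$train,
                          subset = split$train)
      Xte <- build_matrix(cohort, mode = mode, train_ids = split$train,
                          subset = split$test)
      cfg_m <- nn_cfg
      cfg_m$seed <- as.integer(seed + 71L)
      models[[mode]] <- train_nn(Xtr, config = cfg_m)
      m <- compute_metrics(Xte$label, predict_proba(models[[mode]], Xte))
      test_rows[[mode]] <- data.frame(mode = mode, auc = m$auc,
                                      accuracy = m$accuracy,
                                      sensitivity = m$sensitivity,
                                      specificity = m$specificity, f1 = m$f1)
    }
    test_csv <- file.path(out_dir, "test_metrics.csv")
    utils::write.csv(do.call(rbind, test_rows), test_csv, row.names = FALSE)
    note(stage, test_csv)

    stage <- "importance"
    Xte <- build_matrix(cohort, mode = "multimodal", train_ids = split$train,
                        subset = split$test)
    imp <- grouped_permutation_importance(models$multimodal, Xte,
                                          n_permutations = config$n_permutations,
                                          seed = seed + 13L)
    imp_csv <- file.path(out_dir, "importance.csv")
    utils::write.csv(imp, imp_csv, row.names = FALSE)
    note(stage, imp_csv)

    stage <- "table1"
    t1 <- build_table1(cohort$records)
    t1_csv <- file.path(out_dir, "table1.csv")
    write_table1(t1, t1_csv)
    note(stage, t1_csv)

    list(cohort_summary = list(n = nrow(cohort$records),
                               prevalence = mean(cohort$records$postop_kps_6mo < 70)),
         reports = reports, test_metrics = do.call(rbind, test_rows),
         importance = imp, split = split)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(result, list(manifest = manifest, out_dir = out_dir)))
}
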