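# End-to-end experiment runner: simulate -> screen -> fit -> evaluate ->
# project -> change, with every random step seeded deterministically from
# one master seed and all outputs written as plain-text files.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list; user configs
#' (lists or YAML files) are merged over it. The defaults are the study
#' conditions of the package's synthetic experiment: a 100 x 100
#' landscape spanning latitudes 0--70 N, a bell-shaped
#' suitability truth in the minimum temperature of the coldest month
#' (optimum 0 deg C, SD 6 deg C) and the dry-quarter precipitation
#' (optimum 195 mm, SD 110 mm), 500 sampled presence records, a 75/25
#' split with 10 replicates, and two emission-pathway presets combined as
#' two-member consensus forecasts.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(
      enabled = TRUE,
      n_rows = 100L, n_cols = 100L,
      x_ll = -35, y_ll = 0, cell_size = 0.7,
      autocorr_scale = 3, water_fraction = 0.35,
      n_presences = 500L, bias_human = FALSE
    ),
    inputs = list(predictors_dir = NULL, mask = NULL, occurrences = NULL),
    screening = list(
      enabled = TRUE, n_points = 1000L, threshold = 0.8,
      keep_priority = c("T_min", "Prec_dry", "T_max", "Prec_wet", "human_influence")
    ),
    model = list(
      classes = c("linear", "quadratic", "hinge"),
      n_hinge_knots = 20L, beta_multiplier = 1.0, tau = 0.5,
      tol = 1e-6, max_iter = 500L
    ),
    evaluation = list(
      train_fraction = 0.75, n_replicates = 10L,
      background_size = 2000L, n_null = 99L,
      null_mode = "target-group", null_max_iter = 200L
    ),
    scenarios = list(
      list(name = "strong", gcm_jitter = 0.25),
      list(name = "mild", gcm_jitter = 0.25)
    ),
    change = list(band_width = 1.0, dispersal = "full", regions = "halves")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  if (is.null(cfg$out_dir)) stop("config field missing: out_dir", call. = FALSE)
  if (is.null(cfg$seed)) stop("config field missing: seed", call. = FALSE)
  if (!isTRUE(cfg$simulate$enabled)) {
    for (f in c("predictors_dir", "mask", "occurrences")) {
      if (is.null(cfg$inputs[[f]])) {
        stop(sprintf("config field missing: inputs.%s (required when simulate is disabled)", f),
          call. = FALSE
        )
      }
    }
  }
  tf <- cfg$evaluation$train_fraction
  if (tf <= 0 || tf >= 1) stop("config field invalid: evaluation.train_fraction", call. = FALSE)
  invisible(cfg)
}

#' Run the full niche-modelling pipeline
#'
#' Chains landscape simulation (or file input), collinearity screening,
#' occurrence deduplication, background sampling, maximum-entropy model
#' fitting, cross-validation AUCs, the null-model significance test,
#' current and future suitability projection with per-scenario two-member
#' consensus, thresholding, range-change classification, turnover and
#' latitudinal profiles. Everything is reproducible bit-for-bit from the
#' master seed; outputs are plain-text grids, CSVs and a YAML manifest.
#'
#' @param config Nested list or path to a YAML file; merged over
#'   [default_config()].
#' @param out_dir Optional override of `config$out_dir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the fitted model, evaluation report,
#'   threshold, per-scenario change results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  seed_of <- function(stage) derive_seed(cfg$seed, stage)
  stage <- "setup"
  res <- try(
    {
      # ---- inputs -------------------------------------------------------
      stage <- "simulate/load"
      if (isTRUE(cfg$simulate$enabled)) {
        sim <- cfg$simulate
        land <- generate_landscape(
          n_rows = sim$n_rows, n_cols = sim$n_cols,
          x_ll = sim$x_ll, y_ll = sim$y_ll, cell_size = sim$cell_size,
          autocorr_scale = sim$autocorr_scale,
          water_fraction = sim$water_fraction,
          seed = seed_of("landscape")
        )
        truth <- truth_model()
        suit_true <- true_suitability(truth, land$predictors)
        occurrences <- sample_presences(
          suit_true, land$mask,
          n_target = sim$n_presences,
          bias = if (isTRUE(sim$bias_human)) land$predictors$human_influence,
          seed = seed_of("presences")
        )
        predictors <- land$predictors
        mask <- land$mask
        logf("simulated %dx%d landscape, %d presence records", sim$n_rows, sim$n_cols, nrow(occurrences))
      } else {
        stage <- "load inputs"
        pdir <- cfg$inputs$predictors_dir
        files <- list.files(pdir, pattern = "\\.asc$", full.names = TRUE)
        predictors <- lapply(files, read_ascii_grid)
        names(predictors) <- sub("\\.asc$", "", basename(files))
        mask <- read_ascii_grid(cfg$inputs$mask)
        predictors[[sub("\\.asc$", "", basename(cfg$inputs$mask))]] <- NULL
        occurrences <- read_occurrences(cfg$inputs$occurrences)
        logf("loaded %d predictor layers and %d occurrence records", length(predictors), nrow(occurrences))
      }

      # ---- screening ----------------------------------------------------
      stage <- "screening"
      if (isTRUE(cfg$screening$enabled)) {
        scr <- screen_predictors(
          predictors,
          n_points = cfg$screening$n_points,
          threshold = cfg$screening$threshold,
          keep_priority = cfg$screening$keep_priority,
          seed = seed_of("screening")
        )
        write_screening_report(scr, file.path(cfg$out_dir, "screening.csv"))
        model_vars <- scr$kept
        logf(
          "screening kept: %s (dropped: %s)", paste(scr$kept, collapse = ", "),
          if (length(scr$dropped)) paste(scr$dropped, collapse = ", ") else "none"
        )
      } else {
        scr <- NULL
        model_vars <- names(predictors)
      }
      mod_predictors <- predictors[model_vars]

      # ---- occurrences, background, partitions -------------------------
      stage <- "occurrences"
      template <- mod_predictors[[1L]]
      presences <- dedup_to_grid(occurrences, template)
      utils::write.csv(
        data.frame(
          row = presences$cells[, "row"], col = presences$cells[, "col"]
        ),
        file.path(cfg$out_dir, "presence_cells.csv"),
        row.names = FALSE
      )
      logf(
        "%d records -> %d unique cells (%d outside extent)",
        presences$n_raw, presences$n_unique, presences$n_outside
      )
      background <- sample_background(
        mask, mod_predictors,
        n = cfg$evaluation$background_size,
        seed = seed_of("background")
      )
      partitions <- split_train_test(
        presences,
        train_fraction = cfg$evaluation$train_fraction,
        n_replicates = cfg$evaluation$n_replicates,
        seed = seed_of("partitions")
      )
      write_partitions(
        presences, partitions, background,
        file.path(cfg$out_dir, "partitions.csv")
      )

      Xp <- extract_values(mod_predictors, presences$cells)
      Xb <- extract_values(mod_predictors, background$cells)

      fit_with <- function(Xtrain, max_iter = cfg$model$max_iter) {
        fit_maxent(
          Xtrain, Xb,
          classes = cfg$model$classes,
          n_hinge_knots = cfg$model$n_hinge_knots,
          beta_multiplier = cfg$model$beta_multiplier,
          tau = cfg$model$tau, tol = cfg$model$tol, max_iter = max_iter
        )
      }

      # ---- full model, threshold, importance ---------------------------
      stage <- "fit"
      full <- fit_with(Xp)
      write_maxent_model(full, file.path(cfg$out_dir, "model_full.yaml"))
      raw_current <- predict_raw(full, mod_predictors)
      suit_current <- predict_logistic(full, raw_current)
      train_suits <- predict_logistic(full, score_raw(full, Xp))
      thr <- threshold_10pct(train_suits)
      write_ascii_grid(suit_current, file.path(cfg$out_dir, "suitability_current.asc"))
      logf(
        "full model: gain %.4f, entropy %.4f; 10th-percentile threshold %.4f",
        full$training_gain, full$H, thr
      )
      imp <- variable_importance(
        Xp, Xb,
        classes = cfg$model$classes,
        n_hinge_knots = cfg$model$n_hinge_knots,
        beta_multiplier = cfg$model$beta_multiplier,
        tau = cfg$model$tau, tol = cfg$model$tol, max_iter = cfg$model$max_iter
      )
      utils::write.csv(imp$table, file.path(cfg$out_dir, "variable_importance.csv"),
        row.names = FALSE
      )

      # ---- cross-validation AUCs ---------------------------------------
      stage <- "evaluate"
      evalrep <- evaluate_replicates(partitions, function(train, test) {
        mdl <- fit_with(Xp[train, , drop = FALSE])
        sb <- score_raw(mdl, Xb)
        list(
          train_auc = auc(score_raw(mdl, Xp[train, , drop = FALSE]), sb),
          test_auc = auc(score_raw(mdl, Xp[test, , drop = FALSE]), sb)
        )
      })
      utils::write.csv(evalrep$replicates, file.path(cfg$out_dir, "cv_auc.csv"),
        row.names = FALSE
      )
      logf(
        "AUC train %.4f +/- %.4f, test %.4f +/- %.4f over %d replicates",
        evalrep$train_mean, evalrep$train_sd, evalrep$test_mean, evalrep$test_sd,
        cfg$evaluation$n_replicates
      )

      # ---- null-model test ---------------------------------------------
      stage <- "null models"
      actual_auc <- auc(score_raw(full, Xp), score_raw(full, Xb))
      null <- null_model_test(
        actual_auc,
        n_presences = presences$n_unique,
        pool = background$cells,
        fit_and_score = function(cells) {
          Xn <- extract_values(mod_predictors, cells)
          mdl <- fit_with(Xn, max_iter = cfg$evaluation$null_max_iter)
          auc(score_raw(mdl, Xn), score_raw(mdl, Xb))
        },
        n_null = cfg$evaluation$n_null,
        mode = cfg$evaluation$null_mode,
        seed = seed_of("null")
      )
      utils::write.csv(data.frame(null_auc = null$null_aucs),
        file.path(cfg$out_dir, "null_aucs.csv"),
        row.names = FALSE
      )
      logf(
        "null test (%s): actual AUC %.4f vs null median %.4f [%.4f, %.4f]; rank p %.3f; %s",
        null$mode, actual_auc, null$median, null$ci_lower, null$ci_upper, null$p_rank,
        if (null$significant) "significant" else "not significant"
      )

      # ---- projection and change ---------------------------------------
      stage <- "project/change"
      current_bin <- binarize(suit_current, thr)
      regions <- if (identical(cfg$change$regions, "halves")) {
        v <- matrix(1, template$n_rows, template$n_cols)
        v[, seq_len(template$n_cols %/% 2)] <- 2
        raster_grid(v, template$x_ll, template$y_ll, template$cell_size)
      }
      region_labels <- c("1" = "east", "2" = "west")
      scen_results <- list()
      for (sc in cfg$scenarios) {
        base <- scenario_preset(sc$name)
        jit <- sc$gcm_jitter %||% 0
        variants <- if (jit > 0) {
          list(
            scenario_delta(base$delta_t - jit, base$rho, name = paste0(sc$name, "_gcmA")),
            scenario_delta(base$delta_t + jit, base$rho, name = paste0(sc$name, "_gcmB"))
          )
        } else {
          list(base)
        }
        maps <- lapply(variants, function(d) {
          fut <- apply_scenario(mod_predictors, d)
          predict_logistic(full, predict_raw(full, fut))
        })
        cons <- consensus(maps)
        write_ascii_grid(cons, file.path(cfg$out_dir, sprintf("suitability_%s.asc", sc$name)))
        fut_bin <- binarize(cons, thr)
        chg <- classify_change(current_bin, fut_bin, dispersal = cfg$change$dispersal)
        write_ascii_grid(chg$map, file.path(cfg$out_dir, sprintf("change_%s.asc", sc$name)))
        prof <- latitudinal_profile(chg$map, band_width = cfg$change$band_width)
        utils::write.csv(prof$bands,
          file.path(cfg$out_dir, sprintf("lat_profile_%s.csv", sc$name)),
          row.names = FALSE
        )
        regsum <- if (!is.null(regions)) {
          rs <- regional_summary(chg$map, regions, labels = region_labels)
          utils::write.csv(rs, file.path(cfg$out_dir, sprintf("regional_%s.csv", sc$name)),
            row.names = FALSE
          )
          rs
        }
        s <- chg$summary
        logf(
          "scenario %s: CR %d, retained %d, gain %d, loss %d, turnover %.1f%%; gain centroid %.2fN vs loss %.2fN",
          sc$name, s$CR, s$R, s$G, s$L, s$T,
          prof$centroids[["gain"]], prof$centroids[["loss"]]
        )
        scen_results[[sc$name]] <- list(
          consensus = cons, change = chg, profile = prof, regional = regsum
        )
      }
      writeLines(
        c(
          "change map category codes:",
          sprintf("  %d = %s", CHANGE_CODES, names(CHANGE_CODES))
        ),
        file.path(cfg$out_dir, "change_codes.txt")
      )

      # ---- manifest -----------------------------------------------------
      stage <- "manifest"
      manifest <- list(
        package = "nichecast",
        version = as.character(utils::packageVersion("nichecast")),
        master_seed = cfg$seed,
        stage_seeds = list(
          landscape = seed_of("landscape"), presences = seed_of("presences"),
          screening = seed_of("screening"), background = seed_of("background"),
          partitions = seed_of("partitions"), null = seed_of("null")
        ),
        config = cfg,
        outputs = list.files(cfg$out_dir)
      )
      yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

      list(
        config = cfg, model = full, threshold = thr,
        evaluation = evalrep, null = null, actual_auc = actual_auc,
        importance = imp$table, screening = scr,
        presences = presences, background = background,
        suitability_current = suit_current, current_binary = current_bin,
        scenarios = scen_results, manifest = manifest
      )
    },
    silent = TRUE
  )
  if (inherits(res, "try-error")) {
    writeLines(
      c(sprintf("FAILED at stage: %s", stage), attr(res, "condition")$message),
      file.path(cfg$out_dir, "PARTIAL_RESULTS")
    )
    stop(sprintf(
      "pipeline failed at stage '%s': %s",
      stage, conditionMessage(attr(res, "condition"))
    ), call. = FALSE)
  }
  invisible(res)
}
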