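#' Pipeline configuration
#'
#' Builds (and validates) the configuration consumed by [run_pipeline()].
#' Unknown keys are rejected by name. A configuration can also be read from
#' a YAML file with [read_pipeline_config()].
#'
#' @param n_patients Synthetic cohort size (default 120).
#' @param pira_fraction Injected PIRA fraction for the clinical arm.
#' @param image_size Phantom dimensions `c(H, W, Z)` (default 64 x 64 x 12).
#' @param n_slices Central axial slices per patient.
#' @param lesion_lambda,lesion_max,lesion_radius Lesion-count distribution
#'   and blob radius for the phantom arm.
#' @param hazard Named list overriding [hazard_model_params()] fields.
#' @param train Named list overriding [dsn_config()] fields.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 120L, pira_fraction = 0.22,
                            image_size = c(64, 64, 12), n_slices = 6L,
                            lesion_lambda = 4, lesion_max = 12L,
                            lesion_radius = 2.5,
                            hazard = list(), train = list()) {
  hp <- hazard_model_params()
  for (k in names(hazard)) {
    if (!k %in% names(hp))
      stop_pirasurv(sprintf("unknown hazard config key '%s'", k),
                    "pirasurv_config")
    hp[[k]] <- hazard[[k]]
  }
  tc <- dsn_config(initial_lr = 1e-3, max_epochs = 20L)
  for (k in names(train)) {
    if (!k %in% names(tc))
      stop_pirasurv(sprintf("unknown train config key '%s'", k),
                    "pirasurv_config")
    tc[[k]] <- train[[k]]
  }
  structure(list(n_patients = as.integer(n_patients),
                 pira_fraction = pira_fraction,
                 image_size = as.integer(image_size),
                 n_slices = as.integer(n_slices),
                 lesion_lambda = lesion_lambda,
                 lesion_max = as.integer(lesion_max),
                 lesion_radius = lesion_radius,
                 hazard = hp, train = tc),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys must be arguments of [pipeline_config()]; unknown keys
#' raise an error naming the key.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "...")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop_pirasurv(sprintf("unknown config key(s): %s",
                          paste(bad, collapse = ", ")), "pirasurv_config")
  do.call(pipeline_config, y)
}

# one global seed fans out to per-stage seeds through fixed small offsets,
# so stages are individually reproducible and mutually decoupled
.stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, label = 2L, train = 3L, evaluate = 4L,
              threshold = 5L, cox = 6L, explain = 7L, report = 8L)
  (seed + 101L * stages[[stage]]) %% .Machine$integer.max
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes, in canonical order, the requested stages of: `simulate`
#' (clinical tables + imaging cohort), `label` (PIRA labelling of the
#' clinical CSVs), `train` (survival network on a train split), `evaluate`
#' (time-dependent concordance and integrated Brier score on the test
#' split), `threshold` (best-accuracy threshold of the first-interval
#' risk), `cox` (benchmark augmentation with the scaled first-interval
#' risk), `explain` (region relevance table over a phantom parcellation)
#' and `report` (collated summary). Each stage writes its artifact plus a
#' manifest (config hash, seed, timing) under `out_dir`; identical
#' config + seed reproduce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param seed Global integer seed, fanned out per stage.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run (default: all).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = tempfile("pira_pipeline_"),
                         stages = c("simulate", "label", "train", "evaluate",
                                    "threshold", "cox", "explain", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "label", "train", "evaluate", "threshold",
                  "cox", "explain", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop_pirasurv(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
                  "pirasurv_config")
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(rapply(unclass(config), unclass, how = "replace")),
                       cfg_file, auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_file))

  state <- list()
  manifest <- list()
  need <- function(what, producer) {
    if (is.null(state[[what]]))
      stop_pirasurv(sprintf(
        "missing upstream artifact '%s': run the '%s' stage first",
        what, producer), "pirasurv_missing_artifact")
  }
  log_stage <- function(stage, elapsed, files) {
    manifest[[stage]] <<- list(seed = .stage_seed(seed, stage),
                               config_md5 = cfg_hash,
                               elapsed_s = round(elapsed, 3), files = files)
  }

  for (stage in stages) {
    t0 <- proc.time()[3]
    files <- character()
    switch(stage,
      simulate = {
        clin <- simulate_clinical_cohort(config$n_patients,
                                         config$pira_fraction,
                                         seed = .stage_seed(seed, stage))
        files <- write_clinical_tables(clin$records,
                                       file.path(out_dir, "clinical"))
        img <- simulate_imaging_cohort(
          config$n_patients, config$hazard,
          phantom_params(image_size = config$image_size,
                         lesion_radius = config$lesion_radius),
          n_slices = config$n_slices,
          lesion_lambda = config$lesion_lambda,
          lesion_max = config$lesion_max,
          seed = .stage_seed(seed, stage) + 1L)
        state$clinical <- clin; state$imaging <- img
      },
      label = {
        need("clinical", "simulate")
        labels <- label_cohort(state$clinical$records)
        f <- file.path(out_dir, "labels.csv")
        write_labels_csv(labels, f)
        files <- f
        state$labels <- labels
      },
      train = {
        need("imaging", "simulate")
        img <- state$imaging
        n <- nrow(img$labels)
        set.seed(.stage_seed(seed, stage))
        test <- sort(sample.int(n, max(2L, round(n / 3))))
        trn <- setdiff(seq_len(n), test)
        fit <- pira_dsn(img$stacks[trn], img$labels[trn, ],
                        config = config$train)
        Fte <- predict(fit, img$stacks[test], type = "cumrisk")
        state$fit <- fit; state$test <- test; state$cumrisk_test <- Fte
        pred <- data.frame(patient = rep(test, each = ncol(Fte)),
                           interval = rep(seq_len(ncol(Fte)), length(test)),
                           F = as.vector(t(Fte)),
                           S = 1 - as.vector(t(Fte)))
        f <- file.path(out_dir, "predictions.csv")
        write.csv(pred, f, row.names = FALSE)
        files <- f
      },
      evaluate = {
        need("cumrisk_test", "train")
        lab <- state$imaging$labels[state$test, ]
        ctd <- td_cindex(state$cumrisk_test, lab$interval, lab$event)
        ibs <- integrated_brier(1 - state$cumrisk_test, lab$interval,
                                lab$event)
        state$metrics <- list(
          c_td = ctd, ibs_mean = ibs$mean, ibs_sd = ibs$sd,
          n_test = length(state$test),
          noninformative_bound =
            noninformative_brier_bound(mean(lab$event)))
        f <- file.path(out_dir, "metrics.json")
        jsonlite::write_json(state$metrics, f, auto_unbox = TRUE, digits = NA)
        files <- f
      },
      threshold = {
        need("cumrisk_test", "train")
        lab <- state$imaging$labels[state$test, ]
        thr <- best_accuracy_threshold(state$cumrisk_test[, 1L], lab$event,
                                       interval = 1L)
        state$threshold <- thr
        f <- file.path(out_dir, "threshold.json")
        jsonlite::write_json(list(threshold = thr$threshold,
                                  interval = thr$interval_used,
                                  accuracy = thr$accuracy),
                             f, auto_unbox = TRUE, digits = NA)
        files <- f
      },
      cox = {
        need("cumrisk_test", "train")
        lab <- state$imaging$labels[state$test, ]
        covs <- state$imaging$covariates[state$test, "ventricle_scale",
                                         drop = FALSE]
        base <- fit_cox(covs, lab$interval, lab$event)
        aug <- augment_with_dl(base, state$cumrisk_test[, 1L])
        state$cox <- aug
        f <- file.path(out_dir, "cox.json")
        jsonlite::write_json(list(base_c = aug$base_c, new_c = aug$new_c,
                                  dl_hr = aug$dl_hr, dl_p = aug$dl_p,
                                  significant = aug$significant),
                             f, auto_unbox = TRUE, digits = NA)
        files <- f
      },
      explain = {
        need("fit", "train")
        atlas <- phantom_region_atlas(config$image_size[1:2])
        test <- state$test
        maps <- lapply(test[seq_len(min(10L, length(test)))], function(i) {
          s <- state$imaging$stacks[[i]]
          mid <- ceiling(dim(s)[4] / 2)
          rel <- attribute(state$fit, s[, , , mid])
          normalize_binarize(rel[, , 2L]) # FLAIR channel
        })
        tab <- population_region_table(maps, atlas)
        f <- file.path(out_dir, "region_relevance.csv")
        write.csv(tab, f, row.names = FALSE)
        files <- f
        state$regions <- tab
      },
      report = {
        rep <- list(stages_run = names(manifest),
                    metrics = state$metrics,
                    threshold = if (!is.null(state$threshold))
                      state$threshold$threshold,
                    cox_delta_c = if (!is.null(state$cox))
                      state$cox$delta_c)
        f <- file.path(out_dir, "report.json")
        jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA,
                             force = TRUE)
        files <- f
      })
    log_stage(stage, proc.time()[3] - t0, files)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(state)
}

#' Phantom parcellation for in-plane relevance aggregation
#'
#' A 2D integer atlas matching the phantom geometry: 1 = ventricular zone,
#' 2 = periventricular ring (where lesions are placed), 3 = peripheral
#' brain, 0 = background. Useful for exercising the relevance aggregation
#' without an anatomical parcellation; it is synthetic, not an anatomical
#' atlas.
#'
#' @param hw Height/width `c(H, W)`.
#' @return An `(H, W)` integer matrix.
#' @export
phantom_region_atlas <- function(hw = c(64, 64)) {
  xs <- seq(-1, 1, length.out = hw[1])
  ys <- seq(-1, 1, length.out = hw[2])
  r2 <- outer(xs^2, ys^2, `+`)
  ell <- function(cx, ax, ay) outer((xs - cx)^2 / ax^2, ys^2 / ay^2, `+`) <= 1
  brain <- outer(xs^2 / 0.85^2, ys^2 / 0.95^2, `+`) <= 1
  vent <- ell(-0.2, 0.17, 0.45) | ell(0.2, 0.17, 0.45)
  ring <- brain & r2 <= 0.55 & !vent
  atlas <- matrix(0L, hw[1], hw[2])
  atlas[brain] <- 3L
  atlas[ring] <- 2L
  atlas[vent & brain] <- 1L
  atlas
}
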