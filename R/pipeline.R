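#' Run the full SPAD estimation pipeline
#'
#' Orchestrates simulate -> calibrate/extract -> select -> train/evaluate
#' -> invert -> compare from a single configuration, writing every
#' artefact (CSV tables, images, a manifest and a log) under one run
#' directory. Re-running with an identical configuration and seed
#' reproduces all numeric artefacts.
#'
#' The configuration is a nested list (or a YAML file of one) with
#' optional blocks:
#' \describe{
#'   \item{seed}{global seed (default 1).}
#'   \item{simulate}{arguments of [sim_config()]; or `input_csv` naming a
#'     dataset CSV to load instead.}
#'   \item{selection}{`methods`: subset of `c("ca", "scars", "iriv")`
#'     (default `"ca"`), plus per-method blocks `ca`, `scars`, `iriv`
#'     passed to the respective configs.}
#'   \item{models}{`methods`: subset of
#'     `c("plsr", "xgboost", "rfr", "gbdt")` (default `"plsr"`), and
#'     `cv_folds` (default 10).}
#'   \item{inversion}{`enabled` flag (default `FALSE`); when enabled, three
#'     synthetic leaves (one per tier) are generated, calibrated, and
#'     mapped with the best model; `nrow`, `ncol`, `limits` optional.}
#' }
#' Stages not configured are skipped; `simulate` always runs (it provides
#' the dataset).
#'
#' @param config nested list, or path to a YAML file.
#' @param out_dir run directory; default a timestamped directory under
#'   `tempdir()`.
#' @return Invisibly, a list with the run directory, the dataset, the
#'   selections, the CV reports and (if enabled) the inversion maps.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(),
                         format(Sys.time(), "spadspec_run_%Y%m%d_%H%M%S"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }

  stage <- "simulate"
  result <- tryCatch({
    # --- simulate / load -------------------------------------------------
    if (!is.null(cfg$simulate$input_csv)) {
      ds <- read_dataset_csv(cfg$simulate$input_csv)
      log_line(stage, "loaded ", nrow(ds$X), " samples from ",
               cfg$simulate$input_csv)
      sim_cfg <- NULL
    } else {
      sim_args <- cfg$simulate
      sim_args$input_csv <- NULL
      sim_args$seed <- seed
      sim_cfg <- do.call(sim_config, sim_args %||% list())
      ds <- generate_dataset(sim_cfg)
      log_line(stage, "generated ", nrow(ds$X), " samples x ",
               ncol(ds$X), " bands, seed ", seed)
    }
    write_dataset_csv(ds, file.path(out_dir, "dataset.csv"))

    # --- select ----------------------------------------------------------
    stage <- "select"
    methods <- cfg$selection$methods
    if (is.null(methods)) methods <- "ca"
    selections <- list()
    for (m in methods) {
      sel <- switch(m,
        ca = do.call(run_ca, c(list(ds = ds), cfg$selection$ca)),
        scars = run_scars(ds, do.call(scars_config,
          utils::modifyList(list(seed = seed), cfg$selection$scars %||% list()))),
        iriv = run_iriv(ds, do.call(iriv_config,
          utils::modifyList(list(seed = seed), cfg$selection$iriv %||% list()))),
        stop("unknown selection method: ", m))
      selections[[m]] <- sel
      write_selection_csv(sel, file.path(out_dir,
                                         paste0("selection_", m, ".csv")),
                          wavelengths = ds$wavelengths)
      log_line(stage, m, " selected ", length(sel$indices), " / ",
               sel$n_bands_total, " bands")
    }

    # --- train / evaluate ------------------------------------------------
    stage <- "evaluate"
    model_methods <- cfg$models$methods
    if (is.null(model_methods)) model_methods <- "plsr"
    cv_k <- cfg$models$cv_folds %||% 10L
    reports <- list()
    for (sname in names(selections)) {
      for (mm in model_methods) {
        spec <- model_spec(mm, seed = seed)
        rep <- cross_validate(ds, bands = selections[[sname]],
                              spec = spec, k = cv_k, seed = seed)
        key <- paste(sname, mm, sep = "_")
        reports[[key]] <- rep
        write_cv_csv(rep, file.path(out_dir, paste0("cv_", key, ".csv")),
                     file.path(out_dir, paste0("predictions_", key, ".csv")))
        log_line(stage, key, sprintf(": Rcv2 = %.3f, RMSEcv = %.3f",
                                     rep$aggregate$R2, rep$aggregate$RMSE))
      }
    }

    # --- invert ----------------------------------------------------------
    stage <- "invert"
    maps <- NULL
    if (isTRUE(cfg$inversion$enabled)) {
      if (is.null(sim_cfg))
        stop("inversion stage needs the simulate stage (known ground truth)")
      best <- names(reports)[which.max(vapply(reports, function(r)
        r$aggregate$R2, numeric(1)))]
      parts <- strsplit(best, "_")[[1]]
      best_sel <- selections[[parts[1]]]
      best_spec <- model_spec(parts[2], seed = seed)
      model <- fit_model(ds, best_spec, bands = best_sel)
      log_line(stage, "best model: ", best)

      nr <- cfg$inversion$nrow %||% 40L
      nc <- cfg$inversion$ncol %||% 60L
      tiers <- c(lower = sim_cfg$position_means[["lower"]],
                 middle = sim_cfg$position_means[["middle"]],
                 upper = sim_cfg$position_means[["upper"]])
      maps <- list()
      for (tier in names(tiers)) {
        scene <- synthetic_leaf(nr, nc, tiers[[tier]])
        tier_cfg <- sim_cfg
        tier_cfg$seed <- seed + match(tier, names(tiers))
        cubes <- generate_hypercube(scene$spad_field, scene$leaf_mask,
                                    tier_cfg)
        refl <- calibrate(cubes$raw, cubes$white, cubes$dark)
        maps[[tier]] <- predict_map(refl, model)
        render_map(maps[[tier]],
                   file.path(out_dir, paste0("map_", tier, ".png")),
                   limits = cfg$inversion$limits %||% c(0, 100))
      }
      stats <- map_stats(maps, model_name = best)
      write.csv(stats, file.path(out_dir, "map_stats.csv"),
                row.names = FALSE)
      log_line(stage, "tier map means: ",
               paste(sprintf("%s=%.1f", stats$leaf, stats$mean),
                     collapse = ", "))
    }

    # --- compare ---------------------------------------------------------
    stage <- "compare"
    overlap <- NULL
    if (length(selections) >= 2) {
      overlap <- compare_selections(selections)
      write.csv(overlap$table, file.path(out_dir, "selection_overlap.csv"),
                row.names = FALSE)
      log_line(stage, "common bands: ", length(overlap$common))
    }

    list(out_dir = out_dir, dataset = ds, selections = selections,
         reports = reports, maps = maps, overlap = overlap)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    seed = seed,
    config = cfg,
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("spadspec")),
    artefacts = sort(setdiff(list.files(out_dir), "manifest.json")),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

# md5 of the canonical (sorted-key) serialisation of the config
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
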