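#' Load a fixture bundle from a directory
#'
#' Reads the directory layout written by [write_bundle()]: PNG image sets,
#' 0/255 mask PNGs and `manifest.json`.
#'
#' @param dir Bundle directory.
#' @return A `fixture_bundle` (without generating latents).
#' @export
load_bundle <- function(dir) {
  if (!dir.exists(dir)) stopf("bundle directory '%s' does not exist", dir,
                              class = "anomrecon_config_error")
  read_set <- function(sub) {
    d <- file.path(dir, sub)
    if (!dir.exists(d)) return(NULL)
    files <- sort(list.files(d, pattern = "\\.png$", full.names = TRUE))
    stats::setNames(lapply(files, function(f) load_png(f)$pixels),
                    tools::file_path_sans_ext(basename(files)))
  }
  set_dirs <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  anom_names <- sub("^anomaly_", "", grep("^anomaly_", set_dirs, value = TRUE))
  sets <- masks <- stats::setNames(vector("list", length(anom_names)),
                                   anom_names)
  for (nm in anom_names) {
    sets[[nm]] <- read_set(paste0("anomaly_", nm))
    mdir <- file.path(dir, "masks", nm)
    if (dir.exists(mdir)) {
      files <- sort(list.files(mdir, pattern = "\\.png$", full.names = TRUE))
      masks[[nm]] <- lapply(files, read_mask_png)
    } else masks[nm] <- list(NULL)
  }
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  structure(list(baseline_train = read_set("baseline_train"),
                 baseline_test = read_set("baseline_test"),
                 latents = NULL, anomaly_sets = sets, anomaly_masks = masks,
                 manifest = manifest),
            class = "fixture_bundle")
}

#' Pipeline run configuration
#'
#' @param backend A backend object, or the path to a phantom backend JSON
#'   config.
#' @param bundle A `fixture_bundle`, or the path of a bundle directory.
#' @param out_dir Output directory for reports.
#' @param metric Reconstruction score: `"wd"` or `"mse"`.
#' @param mask_mode `"full"` or `"body"` (scores restricted to
#'   [extract_body_mask()] of the original).
#' @param steps Projection steps.
#' @param seed Projection seed for the detection arm.
#' @param localize_d Patch side for localization; `NULL` skips localization.
#' @param localize_seeds Projection seeds for the localization arm.
#' @param eval_repeats Subsampling repetitions for AUROC.
#' @param eval_seed Seed of the AUROC subsampling.
#' @return A `run_config` list.
#' @export
run_config <- function(backend, bundle, out_dir, metric = c("wd", "mse"),
                       mask_mode = c("full", "body"), steps = 200, seed = 0,
                       localize_d = NULL, localize_seeds = 0:4,
                       eval_repeats = 50, eval_seed = 0) {
  structure(list(backend = backend, bundle = bundle, out_dir = out_dir,
                 metric = match.arg(metric), mask_mode = match.arg(mask_mode),
                 steps = as.integer(steps), seed = as.integer(seed),
                 localize_d = localize_d,
                 localize_seeds = as.integer(localize_seeds),
                 eval_repeats = as.integer(eval_repeats),
                 eval_seed = as.integer(eval_seed)),
            class = "run_config")
}

#' Run the full anomaly-detection pipeline
#'
#' Orchestrates the two workflows end to end on a fixture bundle:
#' reconstruct every baseline-test and anomaly image ([project()]), score
#' reconstructions ([mse_score()]/[wd_score()], optionally body-masked),
#' localize local anomalies (top patch across seeds), and evaluate detection
#' ([subsampled_auroc()] per anomaly set). Writes `scores.csv`,
#' `localization.csv` (when enabled), `evaluation.json` and `run_manifest.json`
#' into `out_dir`; all outputs are regenerable bitwise from the manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the score table, localization table and
#'   evaluation results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  backend <- config$backend
  if (is.character(backend)) backend <- phantom_backend_from_config(backend)
  bundle <- config$bundle
  if (is.character(bundle)) bundle <- load_bundle(bundle)
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg <- projection_config(steps = config$steps, seed = config$seed)
  score_one_set <- function(images, set_name) {
    vals <- vapply(seq_along(images), function(i) {
      fit <- project(backend, images[[i]], cfg)
      mask <- if (config$mask_mode == "body")
        extract_body_mask(images[[i]]) else NULL
      score_metric(config$metric)(images[[i]], fitted(fit), mask = mask)
    }, numeric(1))
    ids <- names(images)
    if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(images))
    data.frame(set = set_name, image_id = ids, metric = config$metric,
               mask_mode = config$mask_mode, value = vals,
               stringsAsFactors = FALSE)
  }

  scores <- rbind(
    score_one_set(bundle$baseline_test, "baseline_test"),
    do.call(rbind, lapply(names(bundle$anomaly_sets), function(nm)
      score_one_set(bundle$anomaly_sets[[nm]], nm)))
  )
  utils::write.csv(scores, file.path(config$out_dir, "scores.csv"),
                   row.names = FALSE)

  loc_tab <- NULL
  if (!is.null(config$localize_d)) {
    local_sets <- names(bundle$anomaly_masks)[
      !vapply(bundle$anomaly_masks, is.null, logical(1))]
    loc_tab <- do.call(rbind, lapply(local_sets, function(nm) {
      res <- localization_proportion(
        bundle$anomaly_sets[[nm]], backend, bundle$anomaly_masks[[nm]],
        d = config$localize_d, metric = config$metric,
        seeds = config$localize_seeds, steps = config$steps)
      data.frame(set = nm, d = res$d, metric = res$metric,
                 seed = res$seeds, proportion = res$proportions,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(loc_tab, file.path(config$out_dir, "localization.csv"),
                     row.names = FALSE)
  }

  base_scores <- scores$value[scores$set == "baseline_test"]
  evaluation <- lapply(names(bundle$anomaly_sets), function(nm) {
    res <- subsampled_auroc(base_scores,
                            scores$value[scores$set == nm],
                            repeats = config$eval_repeats,
                            seed = config$eval_seed)
    list(set = nm, mean_auroc = res$mean_auroc, sd_auroc = res$sd_auroc,
         repeats = res$repeats, subsample_size = res$subsample_size)
  })
  names(evaluation) <- names(bundle$anomaly_sets)
  jsonlite::write_json(evaluation,
                       file.path(config$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(config = unclass(config)[setdiff(names(config),
                                                    c("backend", "bundle"))],
                   backend = backend_descriptor(backend),
                   bundle_manifest = bundle$manifest,
                   package_version = as.character(
                     utils::packageVersion("anomrecon")))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scores = scores, localization = loc_tab,
                 evaluation = evaluation))
}
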