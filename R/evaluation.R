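#' Area under the ROC curve for anomaly scores
#'
#' The probability that a randomly chosen anomaly score exceeds a randomly
#' chosen baseline score, with ties counted one half (the Mann-Whitney
#' formulation, computed from ranks). Anomalous is the positive class:
#' reconstruction scores should be high for anomalous images.
#'
#' @param baseline_scores,anomaly_scores Non-empty numeric vectors.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(baseline_scores, anomaly_scores) {
  if (length(baseline_scores) == 0 || length(anomaly_scores) == 0)
    stopf("both score vectors must be non-empty",
          class = "anomrecon_insufficient_data")
  na <- length(anomaly_scores)
  nb <- length(baseline_scores)
  r <- rank(c(anomaly_scores, baseline_scores))
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
}

#' Subsampled AUROC with variability estimate
#'
#' Addresses baseline/anomaly class imbalance by repeatedly drawing a
#' without-replacement baseline subsample of the anomaly-set size and
#' computing the AUROC against the full anomaly set; reports the mean and
#' sample SD across repeats.
#'
#' @inheritParams auroc
#' @param repeats Number of subsampling repetitions.
#' @param seed Integer seed; identical seeds give identical results.
#' @return List (class `auroc_result`) with `mean_auroc`, `sd_auroc`,
#'   `aurocs`, `repeats`, `subsample_size`.
#' @export
subsampled_auroc <- function(baseline_scores, anomaly_scores, repeats = 50,
                             seed = 0) {
  na <- length(anomaly_scores)
  nb <- length(baseline_scores)
  if (na < 1) stopf("anomaly score vector must be non-empty",
                    class = "anomrecon_insufficient_data")
  if (nb < na)
    stopf("baseline set (%d) smaller than anomaly set (%d): cannot subsample without replacement",
          nb, na, class = "anomrecon_config_error")
  aucs <- with_seed(seed, vapply(seq_len(repeats), function(r) {
    auroc(baseline_scores[sample.int(nb, na)], anomaly_scores)
  }, numeric(1)))
  structure(list(mean_auroc = mean(aucs),
                 sd_auroc = if (repeats > 1) stats::sd(aucs) else 0,
                 aurocs = aucs, repeats = repeats, subsample_size = na),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("<auroc_result> mean %.3f (+/- %.3f) over %d subsamples of size %d\n",
              x$mean_auroc, x$sd_auroc, x$repeats, x$subsample_size))
  invisible(x)
}

#' Top-patch localization proportion across projection seeds
#'
#' The localization arm of the pipeline: for each projection seed, every
#' target image is reconstructed, its patch grid scored, and the top-scoring
#' patch counted as a hit when it overlaps the ground-truth anomaly mask by
#' at least `min_overlap` pixels. Reports the mean and sample SD of the hit
#' proportion across seeds.
#'
#' @param targets List of grayscale matrices.
#' @param backend A backend object.
#' @param anomaly_masks List of logical masks aligned with `targets`.
#' @param d Patch side in pixels.
#' @param stride Patch stride (default `d`).
#' @param metric `"mse"` or `"wd"`.
#' @param seeds Integer vector of projection seeds (default 0:4).
#' @param steps Projection steps per reconstruction.
#' @param min_overlap Minimum overlapping mask pixels for a hit.
#' @param config Optional [projection_config()] template; `steps` and the
#'   per-run seed override its fields.
#' @return List (class `localization_result`) with `mean_proportion`,
#'   `sd_proportion`, `proportions`, `d`, `metric`, `seeds`.
#' @export
localization_proportion <- function(targets, backend, anomaly_masks, d,
                                    stride = d, metric = c("wd", "mse"),
                                    seeds = 0:4, steps = 200,
                                    min_overlap = 1,
                                    config = NULL) {
  metric <- match.arg(metric)
  if (length(seeds) == 0) stopf("`seeds` must be non-empty")
  if (length(targets) != length(anomaly_masks))
    stopf("`targets` and `anomaly_masks` lengths differ",
          class = "anomrecon_contract_error")
  for (i in seq_along(targets)) check_mask(anomaly_masks[[i]], targets[[i]])
  if (is.null(config)) config <- projection_config(steps = steps)
  props <- vapply(seeds, function(sd) {
    cfg <- config
    cfg$seed <- as.integer(sd)
    cfg$steps <- as.integer(steps)
    hits <- vapply(seq_along(targets), function(i) {
      fit <- project(backend, targets[[i]], cfg)
      grid <- patch_scores(targets[[i]], fitted(fit), d = d, stride = stride,
                           metric = metric)
      tp <- top_patch(grid)
      patch_mask <- anomaly_masks[[i]][tp$row0 + seq_len(d),
                                       tp$col0 + seq_len(d)]
      sum(patch_mask) >= min_overlap
    }, logical(1))
    mean(hits)
  }, numeric(1))
  structure(list(mean_proportion = mean(props),
                 sd_proportion = if (length(props) > 1) stats::sd(props) else 0,
                 proportions = props, d = as.integer(d), metric = metric,
                 seeds = as.integer(seeds)),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("<localization_result> d=%d %s: %.2f (+/- %.2f) over seeds %s\n",
              x$d, x$metric, x$mean_proportion, x$sd_proportion,
              paste(x$seeds, collapse = ",")))
  invisible(x)
}

# ---- summary aggregations over published-style result tables --------------

#' Mean percent reduction of generated vs manipulated Frechet distances
#'
#' For each row of a context table (one dataset/metric/manipulation
#' combination), computes the percent reduction
#' `(1 - generated_fd / manipulated_fd) * 100` and returns the mean across
#' rows. Rows where the generated FD exceeds the manipulated FD contribute
#' negative reductions.
#'
#' @param fd_table Data frame with numeric columns `generated_fd` and
#'   `manipulated_fd` (all `manipulated_fd` > 0).
#' @return Mean percent reduction (scalar).
#' @export
summarize_fd_reduction <- function(fd_table) {
  g <- fd_table$generated_fd
  m <- fd_table$manipulated_fd
  if (any(m == 0)) stopf("manipulated_fd contains zero: reduction undefined")
  mean((1 - g / m) * 100)
}

#' Relative AUROC improvement from masked scoring
#'
#' Per-row relative change `(auroc_masked - auroc_full) / auroc_full * 100`,
#' summarized by its mean and sample SD (denominator n - 1).
#'
#' @param paired_aurocs Data frame with numeric columns `auroc_full` (> 0)
#'   and `auroc_masked`.
#' @return List with `mean_percent` and `sd_percent` (0 with a warning for a
#'   single row).
#' @export
summarize_improvement <- function(paired_aurocs) {
  f <- paired_aurocs$auroc_full
  m <- paired_aurocs$auroc_masked
  if (any(f == 0)) stopf("auroc_full contains zero: relative change undefined")
  rel <- (m - f) / f * 100
  sdp <- if (length(rel) > 1) stats::sd(rel) else {
    warnf("single row: SD undefined, reporting 0")
    0
  }
  list(mean_percent = mean(rel), sd_percent = sdp)
}

#' Mean and SD of a set of AUROCs
#'
#' @param aurocs Non-empty numeric vector.
#' @return List with `mean`, `sd_sample` (n - 1) and `sd_population` (n);
#'   both SD conventions are reported since published summaries do not always
#'   state theirs.
#' @export
summarize_dataset_mean <- function(aurocs) {
  if (length(aurocs) == 0) stopf("`aurocs` must be non-empty")
  n <- length(aurocs)
  sds <- if (n > 1) stats::sd(aurocs) else 0
  list(mean = mean(aurocs), sd_sample = sds,
       sd_population = sds * sqrt((n - 1) / n))
}

#' Bundled reference result tables
#'
#' Plain-CSV copies of the aggregate result tables from a published
#' application of this methodology (StyleGAN2 models of abdominal CT and
#' chest radiographs), shipped so the summary aggregations can be exercised
#' on real reported numbers: `fd_context` (Frechet distances for
#' baseline-halves / generated / noise / blur conditions), `auroc_full`
#' (whole-image detection AUROCs), `auroc_body` (body-masked detection
#' AUROCs, CT only), and `localization` (top-patch hit proportions by metric
#' and patch size).
#'
#' @param name Table name.
#' @return A data.frame.
#' @export
reference_table <- function(name = c("fd_context", "auroc_full",
                                     "auroc_body", "localization")) {
  name <- match.arg(name)
  path <- system.file("extdata", "reference_tables",
                      paste0(name, ".csv"), package = "anomrecon")
  if (!nzchar(path)) stopf("reference table '%s' not found", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
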