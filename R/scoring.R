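#' Mean squared error between two images
#'
#' Mean of squared intensity differences over the included pixels, on the
#' \[0, 255\] scale. Sensitive to spatial arrangement (contrast with
#' [wd_score()]).
#'
#' @param a,b Numeric matrices of identical shape, values in \[0, 255\].
#' @param mask Optional logical matrix restricting scoring (e.g. a body mask
#'   from [extract_body_mask()]); must be non-empty.
#' @return Non-negative scalar (intensity units squared).
#' @export
mse_score <- function(a, b, mask = NULL) {
  check_gray(a, "a"); check_gray(b, "b")
  check_same_shape(a, b)
  if (!is.null(mask)) {
    check_mask(mask, a)
    if (!any(mask)) stopf("empty mask: no pixels to score",
                          class = "anomrecon_degenerate_region")
    return(mean((a[mask] - b[mask])^2))
  }
  mean((a - b)^2)
}

#' 1-D Wasserstein distance between two images' intensity distributions
#'
#' The Wasserstein-1 distance between the empirical distributions of the
#' included pixel intensities of `a` and `b` — the integral of the absolute
#' difference of their quantile functions. Because it only sees the intensity
#' multisets, it is invariant to any spatial rearrangement of pixels, the
#' property that motivates its use as a reconstruction score. When the two
#' pixel counts are equal it reduces to the mean absolute difference of the
#' sorted intensity sequences.
#'
#' @inheritParams mse_score
#' @return Non-negative scalar in intensity units (at most 255).
#' @export
wd_score <- function(a, b, mask = NULL) {
  check_gray(a, "a"); check_gray(b, "b")
  check_same_shape(a, b)
  if (!is.null(mask)) {
    check_mask(mask, a)
    if (!any(mask)) stopf("empty mask: no pixels to score",
                          class = "anomrecon_degenerate_region")
    va <- a[mask]; vb <- b[mask]
  } else {
    va <- as.numeric(a); vb <- as.numeric(b)
  }
  wasserstein1 <- function(x, y) {
    # quantile-function formulation; supports unequal sample sizes
    allv <- sort(c(x, y))
    if (length(allv) < 2) return(abs(x - y))
    deltas <- diff(allv)
    cdf_x <- stats::ecdf(x)(allv[-length(allv)])
    cdf_y <- stats::ecdf(y)(allv[-length(allv)])
    sum(abs(cdf_x - cdf_y) * deltas)
  }
  wasserstein1(va, vb)
}

score_metric <- function(metric = c("mse", "wd")) {
  metric <- match.arg(metric)
  if (metric == "mse") mse_score else wd_score
}

#' Per-patch reconstruction errors
#'
#' Scores every `d` x `d` patch on a stride lattice with the chosen metric
#' restricted to the patch, producing a grid used for anomaly localization.
#' When a mask is supplied, only patches with at least `min_mask_frac` of
#' their pixels inside the mask are scored (others are `NA`), and the metric
#' is evaluated on the masked pixels of the patch.
#'
#' @inheritParams mse_score
#' @param d Patch side in pixels (<= both image sides).
#' @param stride Lattice stride in pixels; default `d` (non-overlapping
#'   tiling).
#' @param metric `"mse"` or `"wd"`.
#' @param min_mask_frac Minimum fraction of in-mask pixels for a patch to be
#'   scored when `mask` is given.
#' @return A `patch_grid`: list with `scores` (matrix, one cell per patch
#'   position), `row0`/`col0` (0-based patch origins), `d`, `stride`,
#'   `metric`.
#' @export
patch_scores <- function(a, b, d, stride = d, metric = c("mse", "wd"),
                         mask = NULL, min_mask_frac = 0.5) {
  metric <- match.arg(metric)
  check_gray(a, "a"); check_gray(b, "b")
  check_same_shape(a, b)
  if (d > nrow(a) || d > ncol(a))
    stopf("patch size d=%d exceeds image dimensions %dx%d", d, nrow(a),
          ncol(a), class = "anomrecon_config_error")
  if (stride < 1) stopf("`stride` must be >= 1")
  if (!is.null(mask)) check_mask(mask, a)
  fn <- score_metric(metric)
  row0 <- seq(0L, nrow(a) - d, by = stride)
  col0 <- seq(0L, ncol(a) - d, by = stride)
  scores <- matrix(NA_real_, length(row0), length(col0))
  for (i in seq_along(row0)) {
    rs <- row0[i] + seq_len(d)
    for (j in seq_along(col0)) {
      cs <- col0[j] + seq_len(d)
      if (is.null(mask)) {
        scores[i, j] <- fn(a[rs, cs, drop = FALSE], b[rs, cs, drop = FALSE])
      } else {
        mk <- mask[rs, cs, drop = FALSE]
        if (mean(mk) >= min_mask_frac)
          scores[i, j] <- fn(a[rs, cs, drop = FALSE],
                             b[rs, cs, drop = FALSE], mask = mk)
      }
    }
  }
  structure(list(scores = scores, row0 = row0, col0 = col0, d = as.integer(d),
                 stride = as.integer(stride), metric = metric),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d x %d patches (d=%d, stride=%d, metric=%s), max score %.4g\n",
              nrow(x$scores), ncol(x$scores), x$d, x$stride, x$metric,
              suppressWarnings(max(x$scores, na.rm = TRUE))))
  invisible(x)
}

#' Location of the highest-error patch
#'
#' Ties are broken deterministically: smallest patch row origin, then
#' smallest column origin.
#'
#' @param grid A `patch_grid` from [patch_scores()].
#' @return List with `row0`, `col0` (0-based top-left corner) and `d`.
#' @export
top_patch <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  sc <- grid$scores
  if (all(is.na(sc))) stopf("patch grid has no scored patches")
  mx <- max(sc, na.rm = TRUE)
  hits <- which(sc == mx, arr.ind = TRUE)
  # column-major order within equal rows: sort by row origin then col origin
  ord <- order(grid$row0[hits[, 1]], grid$col0[hits[, 2]])
  i <- hits[ord[1], 1]; j <- hits[ord[1], 2]
  list(row0 = grid$row0[i], col0 = grid$col0[j], d = grid$d,
       score = sc[i, j])
}

#' Score a set of reconstructions
#'
#' Convenience wrapper producing the long score table used by the evaluation
#' stage: one row per image.
#'
#' @param originals,reconstructions Named lists of images (matching names).
#' @param metric `"mse"` or `"wd"`.
#' @param masks Optional named list of logical masks (`mask_mode = "body"`).
#' @return A data.frame with columns `image_id`, `metric`, `mask_mode`,
#'   `value`.
#' @export
score_set <- function(originals, reconstructions, metric = c("mse", "wd"),
                      masks = NULL) {
  metric <- match.arg(metric)
  ids <- names(originals)
  if (is.null(ids)) ids <- as.character(seq_along(originals))
  fn <- score_metric(metric)
  vals <- vapply(seq_along(originals), function(i) {
    m <- if (is.null(masks)) NULL else masks[[i]]
    fn(originals[[i]], reconstructions[[i]], mask = m)
  }, numeric(1))
  data.frame(image_id = ids, metric = metric,
             mask_mode = if (is.null(masks)) "full" else "body",
             value = vals, stringsAsFactors = FALSE)
}
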