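#' Generate a seeded baseline image set
#'
#' Draws `n` latents from the backend prior and decodes them. These images
#' are, by construction, inside the backend's expressible family (each
#' carries its generating latent as a certificate).
#'
#' @param backend A backend object.
#' @param n Number of images (>= 1).
#' @param seed Integer seed.
#' @return List with `images` (list of matrices) and `latents` (list of
#'   latent vectors).
#' @export
generate_baseline_set <- function(backend, n, seed = 0) {
  stopifnot(n >= 1)
  img_seeds <- with_seed(seed, sample.int(2147483646L, n))
  latents <- lapply(img_seeds, function(s) latent_prior_sample(backend, s))
  images <- lapply(latents, function(z) decode(backend, z))
  list(images = images, latents = latents)
}

# Distance from each pixel centre to a segment (x0,y0)-(x1,y1), all in
# 0-based pixel coordinates (x = column, y = row).
segment_distance <- function(rows, cols, x0, y0, x1, y1) {
  xg <- matrix(rep(seq_len(cols) - 1, each = rows), rows, cols)
  yg <- matrix(rep(seq_len(rows) - 1, times = cols), rows, cols)
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) matrix(0, rows, cols) else
    clamp(((xg - x0) * vx + (yg - y0) * vy) / len2, 0, 1)
  sqrt((xg - (x0 + t * vx))^2 + (yg - (y0 + t * vy))^2)
}

#' Insert a synthetic needle into an image
#'
#' Draws a bright line segment (with optional fainter artifact streaks
#' extending beyond its tips, mimicking metal streak artifacts) at a seeded
#' random position and angle inside the body region. The returned mask marks
#' the needle pixels — and the artifact pixels when `artifact = TRUE`,
#' matching the convention that a strong needle artifact counts as the
#' needle for localization purposes.
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param seed Integer seed (placement is deterministic given the seed).
#' @param length Needle length in pixels.
#' @param thickness Needle thickness in pixels.
#' @param intensity Needle intensity.
#' @param artifact Add artifact streaks (included in the mask).
#' @param artifact_intensity Streak intensity.
#' @param body_mask Optional precomputed body mask; derived with
#'   [extract_body_mask()] when `NULL`.
#' @return List with `image` and `mask` (logical).
#' @export
inject_needle <- function(img, seed = 0, length = 18, thickness = 2,
                          intensity = 255, artifact = TRUE,
                          artifact_intensity = 190, body_mask = NULL) {
  check_gray(img)
  if (is.null(body_mask)) body_mask <- extract_body_mask(img)
  if (!any(body_mask))
    stopf("body region too small to place a needle",
          class = "anomrecon_placement_error")
  cand <- which(body_mask, arr.ind = TRUE)
  placement <- with_seed(seed, {
    ok <- NULL
    for (try in seq_len(200)) {
      ctr <- cand[sample.int(nrow(cand), 1), ]
      ang <- stats::runif(1, 0, pi)
      x0 <- (ctr[2] - 1) - cos(ang) * length / 2
      y0 <- (ctr[1] - 1) - sin(ang) * length / 2
      x1 <- (ctr[2] - 1) + cos(ang) * length / 2
      y1 <- (ctr[1] - 1) + sin(ang) * length / 2
      ends <- rbind(c(y0, x0), c(y1, x1))
      rr <- round(ends[, 1]) + 1; cc <- round(ends[, 2]) + 1
      inside <- all(rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)) &&
        all(body_mask[cbind(rr, cc)])
      if (inside) { ok <- c(x0, y0, x1, y1); break }
    }
    ok
  })
  if (is.null(placement))
    stopf("body region too small to place a needle of length %d", length,
          class = "anomrecon_placement_error")
  x0 <- placement[1]; y0 <- placement[2]
  x1 <- placement[3]; y1 <- placement[4]
  dseg <- segment_distance(nrow(img), ncol(img), x0, y0, x1, y1)
  needle <- dseg <= thickness / 2
  out <- img
  out[needle] <- intensity
  mask <- needle
  if (artifact) {
    # collinear streaks past both tips, half the needle length each
    ux <- (x1 - x0) / length; uy <- (y1 - y0) / length
    ext <- length / 2
    for (side in list(c(x0, y0, x0 - ux * ext, y0 - uy * ext),
                      c(x1, y1, x1 + ux * ext, y1 + uy * ext))) {
      dstr <- segment_distance(nrow(img), ncol(img),
                               side[1], side[2], side[3], side[4])
      streak <- dstr <= 0.5 & body_mask & !needle
      out[streak] <- artifact_intensity
      mask <- mask | streak
    }
  }
  list(image = clamp(out, 0, 255), mask = mask)
}

#' Insert a peripheral fluid rim into an image
#'
#' Inserts a crescent-shaped band of the given intensity along part of the
#' inner body boundary, emulating free fluid (ascites-like) collecting at
#' the body periphery. The band is the in-body margin of width `width`
#' restricted to a seeded random angular sector.
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param seed Integer seed (sector placement).
#' @param width Band width in pixels; 0 returns the image unchanged with an
#'   empty mask.
#' @param intensity Fluid intensity (fluid is darker than soft tissue on a
#'   soft-tissue window).
#' @param arc Angular extent of the crescent in radians.
#' @param body_mask Optional precomputed body mask.
#' @return List with `image` and `mask` (logical).
#' @export
inject_fluid_rim <- function(img, seed = 0, width = 4, intensity = 35,
                             arc = 2 * pi / 3, body_mask = NULL) {
  check_gray(img)
  if (width == 0)
    return(list(image = img, mask = matrix(FALSE, nrow(img), ncol(img))))
  if (is.null(body_mask)) body_mask <- extract_body_mask(img)
  if (!any(body_mask))
    stopf("no body region to attach a fluid rim to",
          class = "anomrecon_placement_error")
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(width)) + 1L, "disc")
  inner <- matrix(as.integer(EBImage::erode(EBImage::Image(body_mask * 1),
                                            brush)) > 0,
                  nrow(img), ncol(img))
  band <- body_mask & !inner
  idx <- which(body_mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]) - 1; cx <- mean(idx[, 2]) - 1
  theta0 <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  xg <- matrix(rep(seq_len(ncol(img)) - 1, each = nrow(img)),
               nrow(img), ncol(img))
  yg <- matrix(rep(seq_len(nrow(img)) - 1, times = ncol(img)),
               nrow(img), ncol(img))
  ang <- atan2(yg - cy, xg - cx)
  dtheta <- abs(((ang - theta0 + pi) %% (2 * pi)) - pi)
  rim <- band & (dtheta <= arc / 2)
  out <- img
  out[rim] <- intensity
  list(image = clamp(out, 0, 255), mask = rim)
}

#' Apply a global image transform
#'
#' Whole-image manipulations emulating out-of-scope submissions to an
#' imaging repository: grayscale inversion, edge filtering, blanking, or
#' added Gaussian noise.
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param kind `"invert"`, `"edge_filter"`, `"blank"`, or `"noise"`.
#' @param value Constant intensity for `"blank"`.
#' @param noise_sd Noise SD for `"noise"`.
#' @param seed Integer seed for `"noise"`.
#' @return Transformed image in \[0, 255\].
#' @export
apply_global_transform <- function(img, kind = c("invert", "edge_filter",
                                                 "blank", "noise"),
                                   value = 0, noise_sd = 25, seed = 0) {
  kind <- match.arg(kind)
  check_gray(img)
  switch(kind,
    invert = 255 - img,
    edge_filter = {
      gx <- (img[, c(2:ncol(img), ncol(img))] -
               img[, c(1, 1:(ncol(img) - 1))]) / 2
      gy <- (img[c(2:nrow(img), nrow(img)), ] -
               img[c(1, 1:(nrow(img) - 1)), ]) / 2
      gm <- sqrt(gx^2 + gy^2)
      if (max(gm) == 0) gm else gm / max(gm) * 255
    },
    blank = matrix(value, nrow(img), ncol(img)),
    noise = add_gaussian_noise(img, sd = noise_sd, seed = seed)
  )
}

#' Benchmark configuration for [make_benchmark()]
#'
#' @param n_train,n_test Baseline training/test set sizes.
#' @param anomaly_sets Named list; each entry is a list with `n`, `type`
#'   (`"needle"`, `"rim"`, or a global transform kind), and optional
#'   injection `params`.
#' @param seed Master seed; every stage seed is derived from it, so the
#'   manifest regenerates the bundle bitwise.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_train = 40, n_test = 40,
                             anomaly_sets = list(
                               needle = list(n = 40, type = "needle"),
                               rim = list(n = 40, type = "rim"),
                               inverted = list(n = 40, type = "invert")),
                             seed = 0) {
  structure(list(n_train = n_train, n_test = n_test,
                 anomaly_sets = anomaly_sets, seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Assemble a synthetic benchmark bundle
#'
#' Builds a complete, seeded study-in-a-box: baseline training and test sets
#' drawn from the backend prior, plus named anomaly sets derived from fresh
#' baseline draws by local insertion (needle, fluid rim — each with a
#' ground-truth mask) or a global transform (no mask). A manifest of derived
#' seeds and parameters makes regeneration bitwise reproducible.
#'
#' @param backend A backend object.
#' @param config A [benchmark_config()].
#' @return A `fixture_bundle`: list with `baseline_train`, `baseline_test`,
#'   `latents` (test-set generating latents), `anomaly_sets`,
#'   `anomaly_masks` (NULL entries for global sets) and `manifest`.
#' @export
make_benchmark <- function(backend, config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  n_stage <- 2 + length(config$anomaly_sets)
  stage_seeds <- with_seed(config$seed, sample.int(2147483646L, n_stage))
  train <- generate_baseline_set(backend, config$n_train, stage_seeds[1])
  test <- generate_baseline_set(backend, config$n_test, stage_seeds[2])
  sets <- masks <- stats::setNames(vector("list",
                                          length(config$anomaly_sets)),
                                   names(config$anomaly_sets))
  for (k in seq_along(config$anomaly_sets)) {
    spec <- config$anomaly_sets[[k]]
    sseed <- stage_seeds[2 + k]
    base <- generate_baseline_set(backend, spec$n, sseed)
    inj_seeds <- with_seed(sseed, sample.int(2147483646L, spec$n))
    params <- spec$params
    if (spec$type == "needle") {
      res <- lapply(seq_len(spec$n), function(i)
        do.call(inject_needle, c(list(img = base$images[[i]],
                                      seed = inj_seeds[i]), params)))
      sets[[k]] <- lapply(res, `[[`, "image")
      masks[[k]] <- lapply(res, `[[`, "mask")
    } else if (spec$type == "rim") {
      res <- lapply(seq_len(spec$n), function(i)
        do.call(inject_fluid_rim, c(list(img = base$images[[i]],
                                         seed = inj_seeds[i]), params)))
      sets[[k]] <- lapply(res, `[[`, "image")
      masks[[k]] <- lapply(res, `[[`, "mask")
    } else {
      sets[[k]] <- lapply(seq_len(spec$n), function(i)
        do.call(apply_global_transform,
                c(list(img = base$images[[i]], kind = spec$type,
                       seed = inj_seeds[i]), params)))
      masks[k] <- list(NULL)
    }
  }
  desc <- backend_descriptor(backend)
  manifest <- list(backend = desc, config = unclass(config),
                   stage_seeds = stage_seeds,
                   package_version = as.character(utils::packageVersion("anomrecon")))
  structure(list(baseline_train = train$images, baseline_test = test$images,
                 latents = test$latents, anomaly_sets = sets,
                 anomaly_masks = masks, manifest = manifest),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d train / %d test baseline images\n",
              length(x$baseline_train), length(x$baseline_test)))
  for (nm in names(x$anomaly_sets))
    cat(sprintf("  anomaly '%s': %d images%s\n", nm,
                length(x$anomaly_sets[[nm]]),
                if (is.null(x$anomaly_masks[[nm]])) "" else " (masked)"))
  invisible(x)
}

#' Write a fixture bundle to a directory
#'
#' Layout: `baseline_train/`, `baseline_test/`, `anomaly_<name>/` as 8-bit
#' PNG, `masks/<name>/` as 0/255 PNG, `manifest.json`.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  write_set <- function(images, sub) {
    d <- file.path(dir, sub)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(images))
      write_gray_png(images[[i]], file.path(d, sprintf("img_%03d.png", i)))
  }
  write_set(bundle$baseline_train, "baseline_train")
  write_set(bundle$baseline_test, "baseline_test")
  for (nm in names(bundle$anomaly_sets)) {
    write_set(bundle$anomaly_sets[[nm]], paste0("anomaly_", nm))
    if (!is.null(bundle$anomaly_masks[[nm]])) {
      d <- file.path(dir, "masks", nm)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(bundle$anomaly_masks[[nm]]))
        write_mask_png(bundle$anomaly_masks[[nm]][[i]],
                       file.path(d, sprintf("img_%03d.png", i)))
    }
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
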