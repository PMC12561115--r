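#' Feature extractor contract and the radiomics-lite reference extractor
#'
#' A feature extractor is a function `function(img) -> numeric vector` of
#' fixed length, deterministic in the image, together with a declared feature
#' count. [radiomics_lite_extractor()] is the bundled deterministic reference:
#' 17 first-order and gradient features defined directly on \[0, 255\]
#' intensities — mean, SD, skewness, excess kurtosis, 256-bin histogram
#' entropy (bits), the nine deciles (10%..90%, type-7 quantiles), foreground
#' fraction (pixels above 10% of the scale), and gradient-magnitude mean and
#' SD (central differences). Pretrained-network extractors can be plugged in
#' through the same contract.
#'
#' @return A function with attributes `n_features` and `name`.
#' @export
radiomics_lite_extractor <- function() {
  f <- function(img) {
    check_gray(img)
    v <- as.numeric(img)
    n <- length(v)
    m <- mean(v)
    s <- stats::sd(v)
    cent <- v - m
    skew <- if (s > 0) mean(cent^3) / s^3 else 0
    kurt <- if (s > 0) mean(cent^4) / s^4 - 3 else 0
    counts <- tabulate(pmin(pmax(floor(v), 0), 255) + 1L, nbins = 256L)
    p <- counts[counts > 0] / n
    entropy <- -sum(p * log2(p))
    deciles <- stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1),
                               names = FALSE)
    fg <- mean(v > 25.5)
    gx <- (img[, c(2:ncol(img), ncol(img))] -
             img[, c(1, 1:(ncol(img) - 1))]) / 2
    gy <- (img[c(2:nrow(img), nrow(img)), ] -
             img[c(1, 1:(nrow(img) - 1)), ]) / 2
    gm <- sqrt(gx^2 + gy^2)
    c(mean = m, sd = s, skewness = skew, kurtosis = kurt,
      entropy = entropy,
      stats::setNames(deciles, paste0("q", seq(10, 90, 10))),
      fg_fraction = fg, grad_mean = mean(gm), grad_sd = stats::sd(gm))
  }
  attr(f, "n_features") <- 17L
  attr(f, "name") <- "radiomics_lite"
  f
}

#' Extract a feature matrix from a set of images
#'
#' @param images List of grayscale matrices (>= 2).
#' @param extractor A feature extractor (default [radiomics_lite_extractor()]).
#' @return Numeric matrix, one row per image.
#' @export
extract_features <- function(images, extractor = radiomics_lite_extractor()) {
  if (length(images) < 2)
    stopf("need at least 2 images to characterize a feature distribution")
  rows <- lapply(images, extractor)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1)
    stopf("extractor returned inconsistent feature lengths (%s)",
          paste(unique(lens), collapse = ", "),
          class = "anomrecon_contract_error")
  feats <- do.call(rbind, rows)
  if (any(!is.finite(feats))) stopf("extractor produced non-finite features")
  feats
}

#' Gaussian moments of a feature distribution
#'
#' Sample mean and sample covariance (denominator n - 1) of the feature rows;
#' the covariance is symmetrized by averaging with its transpose.
#'
#' @param features Numeric matrix, one row per image (>= 2 rows).
#' @return A `feature_moments` object: list with `mu`, `sigma`, `n`.
#' @export
moments <- function(features) {
  if (!is.matrix(features) || nrow(features) < 2)
    stopf("need at least 2 feature rows to estimate moments",
          class = "anomrecon_insufficient_sample")
  mu <- colMeans(features)
  sigma <- stats::cov(features)
  sigma <- (sigma + t(sigma)) / 2
  structure(list(mu = mu, sigma = sigma, n = nrow(features)),
            class = "feature_moments")
}

#' @export
print.feature_moments <- function(x, ...) {
  cat(sprintf("<feature_moments> %d features, n = %d\n", length(x$mu), x$n))
  invisible(x)
}

# Symmetric PSD square root via eigendecomposition, eigenvalues clamped at 0.
psd_sqrt <- function(S, tol = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (any(e$values < -tol))
    stopf("matrix is not positive semi-definite (min eigenvalue %.3g)",
          min(e$values), class = "anomrecon_numerical_error")
  lam <- pmax(e$values, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' Frechet distance between two Gaussian feature distributions
#'
#' The squared Frechet distance
#' \deqn{d^2 = |\mu_1 - \mu_2|^2 + \mathrm{tr}\left(\Sigma_1 + \Sigma_2 -
#'   2 (\Sigma_1 \Sigma_2)^{1/2}\right)}
#' between Gaussians with moments `m1` and `m2`. The matrix square root is
#' computed by eigendecomposition of the symmetrized product
#' \eqn{\Sigma_1^{1/2} \Sigma_2 \Sigma_1^{1/2}}; eigenvalues above -1e-8 are
#' clamped to zero and the result is clamped at 0. This is the common scalar
#' underlying FID/FSD/FRD-style fidelity metrics, which differ only in the
#' feature extractor.
#'
#' @param m1,m2 `feature_moments` of matching dimension.
#' @return Non-negative scalar (the squared distance, as conventionally
#'   reported).
#' @export
frechet_distance <- function(m1, m2) {
  stopifnot(inherits(m1, "feature_moments"), inherits(m2, "feature_moments"))
  if (length(m1$mu) != length(m2$mu))
    stopf("moment dimensions differ (%d vs %d)", length(m1$mu),
          length(m2$mu), class = "anomrecon_contract_error")
  s1h <- psd_sqrt(m1$sigma)
  M <- s1h %*% m2$sigma %*% s1h
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  tr_sqrt <- sum(sqrt(pmax(e$values, 0)))
  d2 <- sum((m1$mu - m2$mu)^2) + sum(diag(m1$sigma)) + sum(diag(m2$sigma)) -
    2 * tr_sqrt
  max(d2, 0)
}

#' Add Gaussian pixel noise to an image
#' @param img Numeric matrix in \[0, 255\].
#' @param sd Noise SD in intensity units.
#' @param seed Integer seed.
#' @return Noisy image clamped to \[0, 255\].
#' @export
add_gaussian_noise <- function(img, sd, seed = 0) {
  check_gray(img)
  if (sd == 0) return(img)
  with_seed(seed, clamp(img + stats::rnorm(length(img), sd = sd), 0, 255))
}

#' Gaussian-blur an image
#' @param img Numeric matrix in \[0, 255\].
#' @param sd Blur SD in pixels.
#' @return Blurred image in \[0, 255\].
#' @export
gaussian_blur <- function(img, sd) {
  check_gray(img)
  if (sd == 0) return(img)
  out <- EBImage::gblur(EBImage::Image(img / 255), sigma = sd)
  clamp(matrix(as.numeric(out), nrow(img), ncol(img)) * 255, 0, 255)
}

#' Contextualized Frechet-distance protocol
#'
#' Puts a Frechet distance in context the way generative-fidelity studies do:
#' repeatedly split a dataset into random halves and measure FD between the
#' halves, optionally after applying a uniform manipulation (Gaussian pixel
#' noise or blur) to every image of one half, or substituting a
#' generated-image sample for one half. Baseline-halves FDs give the
#' same-distribution floor; noise/blur FDs give the scale of an obvious
#' corruption; generated FDs in between indicate good generative fidelity.
#'
#' @param images List of grayscale matrices (>= 4).
#' @param extractor Feature extractor.
#' @param condition `"baseline_halves"`, `"noise"`, `"blur"`, or
#'   `"generated"`.
#' @param noise_sd Pixel-noise SD (intensity units) for `"noise"`.
#' @param blur_sd Blur SD (pixels) for `"blur"`.
#' @param generated_images For `"generated"`: list of generated images; each
#'   repeat compares a seeded random subsample of them (of half-dataset size)
#'   against the full real set.
#' @param repeats Number of halving/generation repetitions (>= 1).
#' @param seed Integer seed; identical seeds give identical results.
#' @return List (class `fd_protocol_result`) with `condition`, `mean_fd`,
#'   `sd_fd`, `fds`, `repeats` and the manipulation parameters.
#' @export
contextual_fd_protocol <- function(images,
                                   extractor = radiomics_lite_extractor(),
                                   condition = c("baseline_halves", "noise",
                                                 "blur", "generated"),
                                   noise_sd = 25, blur_sd = 2,
                                   generated_images = NULL,
                                   repeats = 5, seed = 0) {
  condition <- match.arg(condition)
  if (repeats < 1) stopf("`repeats` must be >= 1",
                         class = "anomrecon_config_error")
  n <- length(images)
  if (n < 4) stopf("need at least 4 images for the halving protocol")
  if (condition == "generated" && length(generated_images) < 2)
    stopf("condition 'generated' requires `generated_images`")
  half <- n %/% 2
  # per-repeat derived seeds keep the halving stream identical across
  # conditions, so e.g. noise_sd = 0 reproduces baseline_halves exactly
  rep_seeds <- with_seed(seed, matrix(sample.int(2147483646L, 2L * repeats),
                                      nrow = 2L))
  fds <- vapply(seq_len(repeats), function(r) {
    idx <- with_seed(rep_seeds[1, r], sample.int(n, half))
    if (condition == "generated") {
      g_idx <- with_seed(rep_seeds[2, r],
                         sample.int(length(generated_images),
                                    min(half, length(generated_images))))
      set1 <- images
      set2 <- generated_images[g_idx]
    } else {
      set1 <- images[idx]
      set2 <- images[-idx]
      if (condition == "noise") {
        set2 <- lapply(seq_along(set2), function(i)
          add_gaussian_noise(set2[[i]], sd = noise_sd,
                             seed = (rep_seeds[2, r] + i) %% 2147483647))
      } else if (condition == "blur") {
        set2 <- lapply(set2, gaussian_blur, sd = blur_sd)
      }
    }
    frechet_distance(moments(extract_features(set1, extractor)),
                     moments(extract_features(set2, extractor)))
  }, numeric(1))
  structure(list(condition = condition, mean_fd = mean(fds),
                 sd_fd = if (repeats > 1) stats::sd(fds) else 0,
                 fds = fds, repeats = repeats,
                 params = list(noise_sd = noise_sd, blur_sd = blur_sd),
                 extractor = attr(extractor, "name")),
            class = "fd_protocol_result")
}

#' @export
print.fd_protocol_result <- function(x, ...) {
  cat(sprintf("<fd_protocol_result> %s: FD %.4g (+/- %.4g) over %d repeats\n",
              x$condition, x$mean_fd, x$sd_fd, x$repeats))
  invisible(x)
}
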