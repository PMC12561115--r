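#' Generative backend contract
#'
#' A backend maps a fixed-length latent vector to a grayscale image via
#' [decode()]. Any object can serve as a backend by providing S3 methods for
#' [decode()], [backend_descriptor()], [latent_prior_sample()] and (for
#' gradient-based projection) [decode_gradient()]; non-differentiable backends
#' can rely on the central finite-difference fallback built into the default
#' [decode_gradient()] method. The reference implementation is the analytic
#' phantom renderer of [phantom_backend()].
#'
#' @param backend A backend object.
#' @return `backend_descriptor()` returns a list with `latent_dim`,
#'   `out_rows`, `out_cols`, `differentiable` and `name`.
#' @name backend-contract
NULL

#' @rdname backend-contract
#' @export
backend_descriptor <- function(backend) UseMethod("backend_descriptor")

#' Decode a latent vector into an image
#'
#' Deterministic: equal latents give identical images. Output is clamped to
#' \[0, 255\] and always has the backend's declared output shape.
#'
#' @param backend A backend object.
#' @param latent Numeric vector of length `backend_descriptor(backend)$latent_dim`.
#' @return Numeric matrix (grayscale image) in \[0, 255\].
#' @export
decode <- function(backend, latent) UseMethod("decode")

#' Draw a latent vector from the backend's prior
#'
#' @inheritParams decode
#' @param seed Integer seed; the same seed always yields the same draw.
#' @return Numeric latent vector inside the backend's declared plausible
#'   region (for the phantom backend, the unit box).
#' @export
latent_prior_sample <- function(backend, seed) UseMethod("latent_prior_sample")

#' Coordinate-wise mean of prior draws
#'
#' Mirrors the average-latent starting point used by generator projectors.
#'
#' @inheritParams latent_prior_sample
#' @param n_samples Number of prior draws to average (>= 1).
#' @return Numeric latent vector.
#' @export
mean_latent <- function(backend, n_samples = 500, seed = 0) {
  UseMethod("mean_latent")
}

#' Backpropagate an image-space loss gradient to the latent
#'
#' Given dLoss/dImage evaluated at `decode(backend, latent)`, returns
#' dLoss/dLatent. Backends that declare `differentiable = TRUE` supply an
#' analytic method; otherwise a central finite-difference fallback over
#' [decode()] is used (or a capability error is raised when disabled).
#'
#' @inheritParams decode
#' @param loss_gradient_at_image Numeric matrix, same shape as the decoded
#'   image.
#' @param fd_fallback Allow the finite-difference fallback for
#'   non-differentiable backends.
#' @param fd_step Central-difference step in latent units.
#' @return Numeric vector of length `latent_dim`.
#' @export
decode_gradient <- function(backend, latent, loss_gradient_at_image,
                            fd_fallback = TRUE, fd_step = 1e-4) {
  UseMethod("decode_gradient")
}

#' @export
decode_gradient.default <- function(backend, latent, loss_gradient_at_image,
                                    fd_fallback = TRUE, fd_step = 1e-4) {
  if (!isTRUE(fd_fallback))
    stopf("backend '%s' is not differentiable and the finite-difference fallback is disabled",
          backend_descriptor(backend)$name, class = "anomrecon_capability_error")
  fd_decode_gradient(backend, latent, loss_gradient_at_image, fd_step)
}

fd_decode_gradient <- function(backend, latent, G, h) {
  vapply(seq_along(latent), function(j) {
    zp <- latent; zp[j] <- zp[j] + h
    zm <- latent; zm[j] <- zm[j] - h
    sum(G * (decode(backend, zp) - decode(backend, zm))) / (2 * h)
  }, numeric(1))
}

check_latent <- function(backend, latent) {
  d <- backend_descriptor(backend)$latent_dim
  if (!is.numeric(latent) || length(latent) != d)
    stopf("latent has length %d but backend '%s' declares latent_dim %d",
          length(latent), backend_descriptor(backend)$name, d,
          class = "anomrecon_contract_error")
  if (any(!is.finite(latent)))
    stopf("latent contains non-finite values",
          class = "anomrecon_contract_error")
  invisible(latent)
}

# ---- phantom backend ------------------------------------------------------

# Default parameter boxes, as fractions of image width (x-quantities: cx, a),
# height (y-quantities: cy, b) or intensity units (I). One body ellipse and
# three "organs" at fixed anatomical stations (bright liver-like left organ,
# dark fluid-filled right organ, bright bone-like lower organ) so the latent
# parametrization is identifiable.
phantom_default_boxes <- function() {
  list(
    body  = list(cx = c(0.47, 0.53), cy = c(0.47, 0.53),
                 a = c(0.36, 0.44), b = c(0.30, 0.38), I = c(90, 130)),
    liver = list(cx = c(0.28, 0.40), cy = c(0.34, 0.46),
                 a = c(0.10, 0.16), b = c(0.08, 0.14), I = c(150, 190)),
    bowel = list(cx = c(0.60, 0.72), cy = c(0.38, 0.50),
                 a = c(0.06, 0.11), b = c(0.06, 0.11), I = c(50, 80)),
    spine = list(cx = c(0.46, 0.54), cy = c(0.66, 0.76),
                 a = c(0.05, 0.09), b = c(0.05, 0.09), I = c(200, 240))
  )
}

#' Differentiable parametric phantom backend
#'
#' An analytic renderer standing in for a trained generative model. Each
#' latent coordinate lies in \[0, 1\] and maps affinely onto a parameter box;
#' the parameters describe a soft-edged body ellipse plus `K` organ ellipses
#' (centres, semi-axes, intensities). The rendered image is
#' \deqn{I(p) = \mathrm{clamp}\left(bg + \sum_e (I_e - I_{below(e)})\,
#'   \sigma\!\left(\frac{1 - q_e(p)}{s}\right),\ 0,\ 255\right)}
#' where \eqn{q_e} is the ellipse quadratic form at pixel \eqn{p}, \eqn{\sigma}
#' the logistic function and \eqn{s} the edge softness. Ellipses are
#' composited body-first, so each organ's amplitude is relative to the body
#' intensity.
#'
#' The essential property for anomaly detection is that the family can express
#' baseline anatomy (any in-prior latent) but cannot express inserted content
#' such as needles, fluid rims, or global intensity transforms.
#'
#' @param rows,cols Output image size in pixels.
#' @param boxes Named list of per-ellipse parameter boxes (see
#'   `phantom_default_boxes` in the package source); fractions of image size
#'   for geometry, \[0, 255\] units for intensities. First entry is the body.
#' @param softness Edge softness `s` of the logistic profile, in units of the
#'   ellipse quadratic form (larger = blurrier edges).
#' @param background Background intensity outside the body.
#' @param name Backend name used in reports.
#' @return An object of class `phantom_backend`.
#' @examples
#' be <- phantom_backend(rows = 32, cols = 32)
#' z <- latent_prior_sample(be, seed = 1)
#' img <- decode(be, z)
#' range(img)
#' @export
phantom_backend <- function(rows = 64, cols = 64,
                            boxes = phantom_default_boxes(),
                            softness = 0.08, background = 0,
                            name = "phantom") {
  stopifnot(rows >= 1, cols >= 1, softness > 0)
  scale_of <- c(cx = cols, cy = rows, a = cols, b = rows, I = 1)
  lo <- hi <- numeric(0)
  pnames <- character(0)
  for (ell in names(boxes)) {
    bx <- boxes[[ell]]
    for (p in c("cx", "cy", "a", "b", "I")) {
      lo <- c(lo, bx[[p]][1] * scale_of[[p]])
      hi <- c(hi, bx[[p]][2] * scale_of[[p]])
      pnames <- c(pnames, paste0(ell, ".", p))
    }
  }
  names(lo) <- names(hi) <- pnames
  structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    latent_dim = length(lo), lo = lo, hi = hi,
    ellipses = names(boxes), boxes = boxes,
    softness = softness, background = background,
    differentiable = TRUE, name = name,
    # pixel-centre coordinates, 0-based, x = column, y = row
    xg = matrix(rep(seq_len(cols) - 1, each = rows), rows, cols),
    yg = matrix(rep(seq_len(rows) - 1, times = cols), rows, cols)
  ), class = "phantom_backend")
}

#' @export
backend_descriptor.phantom_backend <- function(backend) {
  list(latent_dim = backend$latent_dim, out_rows = backend$rows,
       out_cols = backend$cols, differentiable = backend$differentiable,
       name = backend$name)
}

#' @export
print.phantom_backend <- function(x, ...) {
  cat(sprintf("<phantom_backend '%s'> %d x %d, latent_dim %d (%d ellipses), softness %.3g\n",
              x$name, x$rows, x$cols, x$latent_dim, length(x$ellipses),
              x$softness))
  invisible(x)
}

#' Map a normalized latent to physical phantom parameters
#'
#' @param backend A `phantom_backend`.
#' @param latent Normalized latent vector (unit box = prior support).
#' @return Named numeric vector of physical parameters (pixel units for
#'   geometry, intensity units for `I`). Semi-axes are floored at 0.5 px.
#' @export
phantom_params <- function(backend, latent) {
  check_latent(backend, latent)
  phys <- backend$lo + latent * (backend$hi - backend$lo)
  ax <- grepl("\\.(a|b)$", names(phys))
  phys[ax] <- pmax(phys[ax], 0.5)
  phys
}

#' Latent whose box-mapped parameters equal `params`
#'
#' Inverse of [phantom_params()] (for parameters inside the boxes).
#'
#' @param backend A `phantom_backend`.
#' @param params Named physical parameter vector in the layout of
#'   [phantom_params()].
#' @return Normalized latent vector.
#' @export
phantom_latent_from_params <- function(backend, params) {
  if (length(params) != backend$latent_dim)
    stopf("expected %d parameters", backend$latent_dim)
  (params - backend$lo) / (backend$hi - backend$lo)
}

# Shared render pass. Returns the clamped image plus, when `context = TRUE`,
# the per-ellipse terms needed for the analytic gradient.
phantom_render <- function(backend, latent, context = FALSE) {
  phys <- phantom_params(backend, latent)
  s <- backend$softness
  K <- length(backend$ellipses)
  img <- matrix(backend$background, backend$rows, backend$cols)
  ctx <- if (context) vector("list", K)
  for (k in seq_len(K)) {
    p <- phys[(k - 1) * 5 + 1:5]
    dx <- backend$xg - p[1]
    dy <- backend$yg - p[2]
    q <- (dx / p[3])^2 + (dy / p[4])^2
    Tk <- 1 / (1 + exp(-(1 - q) / s))
    below <- if (k == 1) backend$background else phys[5] # body intensity
    A <- p[5] - below
    img <- img + A * Tk
    if (context)
      ctx[[k]] <- list(p = p, dx = dx, dy = dy, T = Tk,
                       Tp = Tk * (1 - Tk), A = A)
  }
  pre <- img
  img <- clamp(img, 0, 255)
  if (context) list(img = img, pre = pre, ctx = ctx, phys = phys) else img
}

#' @export
decode.phantom_backend <- function(backend, latent) {
  check_latent(backend, latent)
  phantom_render(backend, latent)
}

#' @export
latent_prior_sample.phantom_backend <- function(backend, seed) {
  with_seed(seed, stats::runif(backend$latent_dim))
}

#' @export
mean_latent.phantom_backend <- function(backend, n_samples = 500, seed = 0) {
  stopifnot(n_samples >= 1)
  d <- backend$latent_dim
  draws <- with_seed(seed, matrix(stats::runif(n_samples * d), nrow = d))
  rowMeans(draws)
}

#' @export
decode_gradient.phantom_backend <- function(backend, latent,
                                            loss_gradient_at_image,
                                            fd_fallback = TRUE,
                                            fd_step = 1e-4) {
  check_latent(backend, latent)
  G <- loss_gradient_at_image
  check_same_shape(G, matrix(0, backend$rows, backend$cols),
                   c("loss_gradient_at_image", "image"))
  rend <- phantom_render(backend, latent, context = TRUE)
  # clamp: zero gradient where the pre-clamp image saturates
  Geff <- G * (rend$pre > 0 & rend$pre < 255)
  s <- backend$softness
  K <- length(backend$ellipses)
  g_phys <- numeric(backend$latent_dim)
  # compositing: d img / d I_body picks up -T_k from every organ amplitude
  for (k in seq_len(K)) {
    e <- rend$ctx[[k]]
    a <- e$p[3]; b <- e$p[4]
    common <- Geff * e$Tp * e$A / s
    i0 <- (k - 1) * 5
    g_phys[i0 + 1] <- sum(common * 2 * e$dx / a^2)
    g_phys[i0 + 2] <- sum(common * 2 * e$dy / b^2)
    g_phys[i0 + 3] <- sum(common * 2 * e$dx^2 / a^3)
    g_phys[i0 + 4] <- sum(common * 2 * e$dy^2 / b^3)
    g_phys[i0 + 5] <- sum(Geff * e$T)
    if (k > 1) g_phys[5] <- g_phys[5] - sum(Geff * e$T)
  }
  # semi-axis floor: clamped parameters do not respond to the latent
  phys_raw <- backend$lo + latent * (backend$hi - backend$lo)
  ax <- grepl("\\.(a|b)$", names(phys_raw))
  g_phys[ax & phys_raw < 0.5] <- 0
  unname(g_phys * (backend$hi - backend$lo))
}

# ---- backend configuration files ------------------------------------------

#' Read or write a phantom backend configuration
#'
#' The backend is fully described by a small JSON file (image size, softness,
#' background, and the per-ellipse parameter boxes); no weight files are
#' involved. `write_phantom_config()` round-trips with
#' `phantom_backend_from_config()`.
#'
#' @param path JSON file path.
#' @param backend A `phantom_backend`.
#' @return `phantom_backend_from_config()` returns a `phantom_backend`;
#'   `write_phantom_config()` returns `path` invisibly.
#' @export
phantom_backend_from_config <- function(path) {
  if (!file.exists(path))
    stopf("backend config '%s' does not exist", path,
          class = "anomrecon_config_error")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  boxes <- lapply(cfg$boxes, function(bx) lapply(bx, as.numeric))
  phantom_backend(rows = cfg$rows, cols = cfg$cols, boxes = boxes,
                  softness = cfg$softness, background = cfg$background,
                  name = if (is.null(cfg$name)) "phantom" else cfg$name)
}

#' @rdname phantom_backend_from_config
#' @export
write_phantom_config <- function(backend, path) {
  stopifnot(inherits(backend, "phantom_backend"))
  cfg <- list(rows = backend$rows, cols = backend$cols,
              softness = backend$softness, background = backend$background,
              name = backend$name, boxes = backend$boxes)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
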