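#' Projection (latent optimization) configuration
#'
#' Settings for reconstructing an image by gradient descent over a backend's
#' latent space.
#'
#' @param steps Number of gradient steps (>= 1).
#' @param seed Integer seed controlling the initialization jitter.
#' @param init `"mean_latent"` (average of `init_samples` prior draws, the
#'   usual projector start) or `"prior_sample"` (a single prior draw).
#' @param step_size Base learning rate, in units of the (preconditioned)
#'   Newton step; 1 takes full per-coordinate Gauss-Newton steps.
#' @param step_schedule `"cosine_ramp"` (linear warm-up over the first 5% of
#'   steps, then cosine decay to zero) or `"constant"`.
#' @param loss Image-space loss; `"pixel_mse"` (mean squared error on the
#'   \[0, 255\] scale) is the reference choice.
#' @param init_jitter_sd SD of the Gaussian jitter added to the
#'   initialization, in latent units.
#' @param init_samples Prior draws averaged for the `"mean_latent"` start.
#' @param precond_refresh Recompute the Gauss-Newton diagonal preconditioner
#'   every this many steps (see [project()]).
#' @param precond_damping Additive damping of the preconditioner
#'   (Levenberg-Marquardt style), guarding against flat coordinates.
#' @param precond_fd_step Central-difference step (latent units) used to
#'   probe the backend's per-coordinate sensitivity.
#' @return A `projection_config` list.
#' @export
projection_config <- function(steps = 1000, seed = 0,
                              init = c("mean_latent", "prior_sample"),
                              step_size = 1,
                              step_schedule = c("cosine_ramp", "constant"),
                              loss = "pixel_mse",
                              init_jitter_sd = 0.05,
                              init_samples = 500,
                              precond_refresh = 25,
                              precond_damping = 1e-4,
                              precond_fd_step = 1e-3) {
  init <- match.arg(init)
  step_schedule <- match.arg(step_schedule)
  loss <- match.arg(loss)
  if (steps < 1) stopf("`steps` must be >= 1")
  if (step_size <= 0) stopf("`step_size` must be > 0")
  if (init_jitter_sd < 0) stopf("`init_jitter_sd` must be >= 0")
  structure(list(steps = as.integer(steps), seed = as.integer(seed),
                 init = init, step_size = step_size,
                 step_schedule = step_schedule, loss = loss,
                 init_jitter_sd = init_jitter_sd,
                 init_samples = as.integer(init_samples),
                 precond_refresh = as.integer(precond_refresh),
                 precond_damping = precond_damping,
                 precond_fd_step = precond_fd_step),
            class = "projection_config")
}

schedule_lr <- function(cfg, t) {
  if (cfg$step_schedule == "constant") return(cfg$step_size)
  warm <- max(1, ceiling(0.05 * cfg$steps))
  ramp <- min(1, t / warm)
  decay <- 0.5 * (1 + cos(pi * (t - 1) / cfg$steps))
  cfg$step_size * ramp * decay
}

#' Reconstruct an image by latent optimization
#'
#' Fits a latent vector to a target image by gradient descent on the
#' pixel-space loss, backpropagated through the backend's [decode()]. This is
#' the reconstruction step of reconstruction-based anomaly detection: content
#' the backend can express is recovered with low error, while content outside
#' its family (the anomalies) cannot be reproduced and leaves a high residual.
#'
#' Latent coordinates can differ by orders of magnitude in how strongly they
#' move the image, which makes a single scalar learning rate either unstable
#' or hopelessly slow. The descent is therefore preconditioned by the
#' Gauss-Newton diagonal of the MSE loss, estimated backend-agnostically by
#' central finite differences of [decode()] and refreshed every
#' `precond_refresh` steps; the update is
#' `z <- z - lr_t * g / (diag_GN + damping)`. This uses only the current
#' point (no momentum or gradient history), so the trajectory remains a
#' deterministic function of the initialization.
#'
#' The returned fit is the best latent over all visited steps (robust to
#' late-step oscillation), together with its decoded reconstruction and the
#' full loss trace. Identical `(backend, target, config)` — including the
#' seed — give bitwise-identical results.
#'
#' @param backend A backend object (see [backend-contract]).
#' @param target Numeric matrix in \[0, 255\] matching the backend's output
#'   shape.
#' @param config A [projection_config()].
#' @return An object of class `projection` with elements `latent`,
#'   `reconstruction`, `loss_trace`, `best_step` and `config`. Methods:
#'   `print`, `summary`, `coef` (the latent), `fitted` (the reconstruction),
#'   `residuals` (target minus reconstruction), `plot`.
#' @examples
#' be <- phantom_backend(rows = 32, cols = 32)
#' tgt <- decode(be, latent_prior_sample(be, seed = 7))
#' fit <- project(be, tgt, projection_config(steps = 50, seed = 0))
#' fit
#' @export
project <- function(backend, target, config = projection_config()) {
  desc <- backend_descriptor(backend)
  check_gray(target, "target")
  if (nrow(target) != desc$out_rows || ncol(target) != desc$out_cols)
    stopf("target shape (%dx%d) does not match backend output (%dx%d)",
          nrow(target), ncol(target), desc$out_rows, desc$out_cols,
          class = "anomrecon_contract_error")
  stopifnot(inherits(config, "projection_config"))

  z <- with_seed(config$seed, {
    z0 <- if (config$init == "mean_latent")
      mean_latent(backend, config$init_samples, seed = config$seed)
    else latent_prior_sample(backend, config$seed)
    z0 + stats::rnorm(desc$latent_dim, sd = config$init_jitter_sd)
  })

  npix <- desc$out_rows * desc$out_cols
  d <- desc$latent_dim
  trace <- numeric(config$steps)
  best_loss <- Inf
  best_z <- z
  best_step <- 1L
  img <- decode(backend, z)
  h <- config$precond_fd_step
  prec <- NULL
  for (t in seq_len(config$steps)) {
    if (is.null(prec) || (t - 1L) %% config$precond_refresh == 0L) {
      prec <- vapply(seq_len(d), function(j) {
        zp <- z; zp[j] <- zp[j] + h
        zm <- z; zm[j] <- zm[j] - h
        J <- (decode(backend, zp) - decode(backend, zm)) / (2 * h)
        2 * sum(J^2) / npix
      }, numeric(1)) + config$precond_damping
    }
    G <- 2 * (img - target) / npix
    g <- decode_gradient(backend, z, G)
    z <- z - schedule_lr(config, t) * g / prec
    img <- decode(backend, z)
    loss_t <- mean((img - target)^2)
    if (!is.finite(loss_t))
      stopf("optimization diverged: non-finite loss at step %d", t,
            class = "anomrecon_divergence_error")
    trace[t] <- loss_t
    if (loss_t < best_loss) {
      best_loss <- loss_t; best_z <- z; best_step <- t
    }
  }

  structure(list(latent = best_z,
                 reconstruction = decode(backend, best_z),
                 loss_trace = trace, best_step = best_step,
                 config = config, target = target,
                 backend_name = desc$name),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("<projection> backend '%s', %d steps (best at step %d)\n",
              x$backend_name, length(x$loss_trace), x$best_step))
  cat(sprintf("  final MSE %.4g, best MSE %.4g\n",
              x$loss_trace[length(x$loss_trace)],
              x$loss_trace[x$best_step]))
  invisible(x)
}

#' @export
summary.projection <- function(object, ...) {
  res <- residuals(object)
  out <- list(backend = object$backend_name,
              steps = length(object$loss_trace),
              best_step = object$best_step,
              best_mse = object$loss_trace[object$best_step],
              final_mse = object$loss_trace[length(object$loss_trace)],
              residual_range = range(res),
              latent = object$latent)
  class(out) <- "summary.projection"
  out
}

#' @export
print.summary.projection <- function(x, ...) {
  cat(sprintf("Latent projection against backend '%s'\n", x$backend))
  cat(sprintf("  steps: %d, best step: %d\n", x$steps, x$best_step))
  cat(sprintf("  best MSE: %.6g   final MSE: %.6g\n", x$best_mse, x$final_mse))
  cat(sprintf("  residual range: [%.4g, %.4g]\n",
              x$residual_range[1], x$residual_range[2]))
  cat(sprintf("  latent (%d coordinates): %s ...\n", length(x$latent),
              paste(sprintf("%.3f", utils::head(x$latent, 5)), collapse = " ")))
  invisible(x)
}

#' @export
coef.projection <- function(object, ...) object$latent

#' @export
fitted.projection <- function(object, ...) object$reconstruction

#' @export
residuals.projection <- function(object, ...) {
  object$target - object$reconstruction
}

#' @export
plot.projection <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  show_img <- function(m, main) {
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256,
                    start = 0, end = 1), zlim = c(0, 255), axes = FALSE,
                    main = main, asp = nrow(m) / ncol(m))
  }
  show_img(x$target, "target")
  show_img(x$reconstruction, "reconstruction")
  graphics::plot(x$loss_trace, type = "l", log = "y", xlab = "step",
                 ylab = "MSE", main = "loss trace")
  graphics::abline(v = x$best_step, lty = 2)
  invisible(x)
}
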