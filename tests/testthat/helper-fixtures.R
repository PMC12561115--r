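# Shared fixture builders. Everything is generated in code at test time.

# Small, fast phantom for unit tests; the default 64x64 phantom is reserved
# for the end-to-end run.
tiny_backend <- function(rows = 32, cols = 32) {
  phantom_backend(rows = rows, cols = cols)
}

# Analytic ellipse raster, independent of the phantom renderer: hard-edged
# indicator, used as an oracle for mask-area checks.
ellipse_image <- function(rows, cols, cy, cx, b, a, intensity = 120,
                          background = 0) {
  yg <- matrix(rep(seq_len(rows) - 1, times = cols), rows, cols)
  xg <- matrix(rep(seq_len(cols) - 1, each = rows), rows, cols)
  inside <- ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1
  out <- matrix(background, rows, cols)
  out[inside] <- intensity
  out
}

random_gray <- function(rows, cols, seed) {
  withr::with_seed(seed, matrix(runif(rows * cols, 0, 255), rows, cols))
}

# A minimal non-differentiable backend wrapping decode() of another backend,
# exercising the finite-difference fallback and the capability error.
opaque_backend <- function(inner) {
  structure(list(inner = inner), class = "opaque_backend")
}
backend_descriptor.opaque_backend <- function(backend) {
  d <- backend_descriptor(backend$inner)
  d$differentiable <- FALSE
  d$name <- "opaque"
  d
}
decode.opaque_backend <- function(backend, latent) {
  decode(backend$inner, latent)
}
latent_prior_sample.opaque_backend <- function(backend, seed) {
  latent_prior_sample(backend$inner, seed)
}
registerS3method("backend_descriptor", "opaque_backend",
                 backend_descriptor.opaque_backend,
                 envir = asNamespace("anomrecon"))
registerS3method("decode", "opaque_backend", decode.opaque_backend,
                 envir = asNamespace("anomrecon"))
registerS3method("latent_prior_sample", "opaque_backend",
                 latent_prior_sample.opaque_backend,
                 envir = asNamespace("anomrecon"))
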