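# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "anomrecon_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# Seeded evaluation that never disturbs the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

check_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stopf("`%s` must be a numeric matrix", arg)
  if (any(!is.finite(img)))
    stopf("`%s` contains non-finite values", arg)
  invisible(img)
}

check_same_shape <- function(a, b, what = c("a", "b")) {
  if (!identical(dim(a), dim(b)))
    stopf("`%s` (%dx%d) and `%s` (%dx%d) must have identical dimensions",
          what[1], nrow(a), ncol(a), what[2], nrow(b), ncol(b))
  invisible(NULL)
}

check_mask <- function(mask, img) {
  if (!is.matrix(mask) || !is.logical(mask))
    stopf("`mask` must be a logical matrix")
  if (!identical(dim(mask), dim(img)))
    stopf("`mask` shape (%dx%d) does not match image (%dx%d)",
          nrow(mask), ncol(mask), nrow(img), ncol(img))
  invisible(mask)
}
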