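#' Read a grayscale image from PNG or DICOM
#'
#' Reads a single-frame 2-D grayscale image. For DICOM input the rescale
#' slope/intercept are applied so pixel values are returned in modality units
#' (e.g. Hounsfield units for CT), and the photometric interpretation
#' (MONOCHROME1/MONOCHROME2) is recorded. PNG pixels are returned on the
#' \[0, 255\] scale with photometric `"unknown"`.
#'
#' @param path Path to the image file.
#' @param format `"png"`, `"dicom"`, or `"auto"` (decide from the file
#'   extension, falling back to content sniffing).
#' @return A `raw_image` object: a list with `pixels` (numeric matrix, rows x
#'   cols), and `photometric` (one of `"monochrome1"`, `"monochrome2"`,
#'   `"unknown"`).
#' @seealso [apply_window()], [rescale_linear()]
#' @export
load_image <- function(path, format = c("auto", "png", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stopf("cannot read image: file '%s' does not exist", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("dcm", "dicom")) "dicom"
      else if (ext == "png") "png"
      else if (is_dicom_file(path)) "dicom" else "png"
  }
  switch(format,
    png = load_png(path),
    dicom = load_dicom(path)
  )
}

#' Construct a raw image
#'
#' @param pixels Numeric matrix in modality units.
#' @param photometric `"monochrome1"`, `"monochrome2"`, or `"unknown"`.
#' @return A `raw_image` object.
#' @export
raw_image <- function(pixels, photometric = "unknown") {
  check_gray(pixels, "pixels")
  structure(list(pixels = pixels, photometric = photometric),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image> %d x %d, photometric %s, range [%.6g, %.6g]\n",
              nrow(x$pixels), ncol(x$pixels), x$photometric,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

load_png <- function(path) {
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) stopf("cannot read PNG '%s': %s",
                                            path, conditionMessage(e)))
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    chans <- lapply(seq_len(min(nc, 3L)), function(k) arr[, , k])
    same <- all(vapply(chans[-1], function(ch)
      isTRUE(all.equal(ch, chans[[1]], tolerance = 0)), logical(1)))
    if (!same)
      stopf("color PNG '%s' is unsupported; expected 8-bit grayscale", path)
    arr <- chans[[1]]
  }
  raw_image(arr * 255, photometric = "unknown")
}

# ---- minimal DICOM reader -------------------------------------------------
# Single-frame grayscale, little-endian transfer syntaxes only (explicit or
# implicit VR). Honors Rows/Columns, BitsAllocated, PixelRepresentation,
# RescaleSlope/RescaleIntercept and PhotometricInterpretation. No installed R
# package parses DICOM, hence this purpose-built reader.

is_dicom_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}

.vr_short <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO","LT",
               "PN","SH","SL","SS","ST","TM","UI","UL","US")
.vr_long <- c("OB","OW","OF","SQ","UT","UN")

dcm_u16 <- function(bytes, off) {
  as.integer(bytes[off + 1]) + 256L * as.integer(bytes[off + 2])
}
dcm_u32 <- function(bytes, off) {
  sum(as.numeric(bytes[off + 1:4]) * c(1, 256, 65536, 16777216))
}

load_dicom <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  off <- 0
  if (length(bytes) >= 132 && rawToChar(bytes[129:132]) == "DICM") off <- 132
  n <- length(bytes)
  tags <- new.env(parent = emptyenv())

  while (off + 8 <= n) {
    group <- dcm_u16(bytes, off)
    elem <- dcm_u16(bytes, off + 2)
    vr <- rawToChar(bytes[off + 5:6])
    explicit <- group == 2L || vr %in% c(.vr_short, .vr_long)
    if (explicit && vr %in% .vr_long) {
      len <- dcm_u32(bytes, off + 8); hdr <- 12L
    } else if (explicit && vr %in% .vr_short) {
      len <- dcm_u16(bytes, off + 6); hdr <- 8L
    } else {
      vr <- NA_character_; len <- dcm_u32(bytes, off + 4); hdr <- 8L
    }
    if (len == 4294967295)
      stopf("DICOM '%s': undefined-length element (%04x,%04x) unsupported",
            path, group, elem)
    val_off <- off + hdr
    if (val_off + len > n)
      stopf("DICOM '%s': truncated element (%04x,%04x)", path, group, elem)
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% c("0028,0002", "0028,0004", "0028,0008", "0028,0010",
                   "0028,0011", "0028,0100", "0028,0103", "0028,1052",
                   "0028,1053", "7fe0,0010"))
      assign(key, bytes[val_off + seq_len(len)], envir = tags)
    off <- val_off + len
    if (key == "7fe0,0010") break
  }

  get_str <- function(key, default = NULL) {
    if (!exists(key, envir = tags)) return(default)
    trimws(rawToChar(get(key, envir = tags)))
  }
  get_u16 <- function(key, default = NULL) {
    if (!exists(key, envir = tags)) return(default)
    v <- get(key, envir = tags)
    readBin(v, "integer", length(v) %/% 2L, size = 2L,
            signed = FALSE, endian = "little")[1]
  }
  get_num <- function(key, default) {
    s <- get_str(key)
    if (is.null(s) || !nzchar(s)) default else as.numeric(strsplit(s, "\\\\")[[1]][1])
  }

  rows <- get_u16("0028,0010"); cols <- get_u16("0028,0011")
  if (is.null(rows) || is.null(cols))
    stopf("DICOM '%s': missing Rows/Columns", path)
  spp <- get_u16("0028,0002", 1L)
  if (spp != 1L)
    stopf("DICOM '%s': color images (SamplesPerPixel=%d) unsupported", path, spp)
  nframes <- get_num("0028,0008", 1)
  if (!is.na(nframes) && nframes > 1)
    stopf("DICOM '%s': multi-frame images (%d frames) unsupported", path, nframes)
  bits <- get_u16("0028,0100", 16L)
  signed <- identical(get_u16("0028,0103", 0L), 1L)
  if (!exists("7fe0,0010", envir = tags))
    stopf("DICOM '%s': missing PixelData", path)
  pd <- get("7fe0,0010", envir = tags)
  npix <- rows * cols
  stored <- if (bits == 8L) {
    readBin(pd, "integer", npix, size = 1L, signed = signed)
  } else if (bits == 16L) {
    if (signed) readBin(pd, "integer", npix, size = 2L, signed = TRUE,
                        endian = "little")
    else readBin(pd, "integer", npix, size = 2L, signed = FALSE,
                 endian = "little")
  } else stopf("DICOM '%s': BitsAllocated=%d unsupported", path, bits)
  if (length(stored) < npix)
    stopf("DICOM '%s': PixelData shorter than Rows x Columns", path)

  slope <- get_num("0028,1053", 1)
  intercept <- get_num("0028,1052", 0)
  photo <- switch(get_str("0028,0004", ""),
                  MONOCHROME1 = "monochrome1",
                  MONOCHROME2 = "monochrome2",
                  "unknown")
  # DICOM pixel order is row-major (left-to-right, top-to-bottom)
  px <- matrix(stored * slope + intercept, nrow = rows, ncol = cols,
               byrow = TRUE)
  raw_image(px, photometric = photo)
}

# ---- intensity mapping ----------------------------------------------------

#' Apply a CT display window
#'
#' Maps modality-unit pixels (e.g. Hounsfield units) through a linear display
#' window onto the \[0, 255\] grayscale range: values at or below
#' `level - width/2` map to 0, values at or above `level + width/2` map to
#' 255, with linear interpolation in between. The defaults are the abdominal
#' soft-tissue (liver) window of level 50 HU and width 350 HU.
#'
#' Values are kept real; quantization to 8-bit happens only when writing with
#' [write_gray_png()].
#'
#' @param raw A `raw_image` or numeric matrix in modality units.
#' @param level Window centre.
#' @param width Window width (> 0).
#' @return Numeric matrix with values in \[0, 255\].
#' @export
apply_window <- function(raw, level = 50, width = 350) {
  px <- if (inherits(raw, "raw_image")) raw$pixels else raw
  check_gray(px, "raw")
  if (!is.numeric(width) || width <= 0) stopf("window `width` must be > 0")
  clamp((px - (level - width / 2)) / width * 255, 0, 255)
}

#' Linearly rescale an image to \[0, 255\]
#'
#' Min-max rescaling used for radiograph-style images: the minimum pixel maps
#' to 0, the maximum to 255. MONOCHROME1 images (high values displayed dark)
#' are inverted first so anatomy polarity matches MONOCHROME2.
#'
#' @param raw A `raw_image` or numeric matrix.
#' @return Numeric matrix with values in \[0, 255\]. A constant input returns
#'   all zeros with a warning (degenerate range).
#' @export
rescale_linear <- function(raw) {
  photo <- if (inherits(raw, "raw_image")) raw$photometric else "unknown"
  px <- if (inherits(raw, "raw_image")) raw$pixels else raw
  check_gray(px, "raw")
  if (identical(photo, "monochrome1")) px <- -px
  rng <- range(px)
  if (rng[1] == rng[2]) {
    warnf("constant image: degenerate intensity range, returning all zeros")
    return(matrix(0, nrow(px), ncol(px)))
  }
  (px - rng[1]) / (rng[2] - rng[1]) * 255
}

# ---- resampling -----------------------------------------------------------

# Interpolation weight matrix mapping `n_in` samples to `n_out`, pixel-centre
# convention: output index i samples input coordinate (i + 0.5) * n_in/n_out
# - 0.5, clamped at the borders.
interp_matrix <- function(n_in, n_out, method) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  W <- matrix(0, n_out, n_in)
  if (method == "bilinear") {
    for (i in seq_len(n_out)) {
      s <- clamp(src[i], 0, n_in - 1)
      lo <- floor(s); f <- s - lo
      j <- lo + 1
      W[i, j] <- W[i, j] + (1 - f)
      if (f > 0) W[i, j + 1] <- W[i, j + 1] + f
    }
  } else { # bicubic, Keys kernel a = -0.5
    ker <- function(t) {
      t <- abs(t)
      ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
             ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
    }
    for (i in seq_len(n_out)) {
      s <- src[i]
      base <- floor(s)
      for (k in (-1):2) {
        j <- clamp(base + k, 0, n_in - 1) + 1
        W[i, j] <- W[i, j] + ker(s - (base + k))
      }
    }
  }
  W
}

#' Resize a grayscale image
#'
#' Separable bilinear or bicubic (Keys, a = -0.5) resampling with the
#' pixel-centre coordinate convention and clamped borders. Output values are
#' clamped to \[0, 255\].
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param target_rows,target_cols Output dimensions (>= 1).
#' @param method `"bilinear"` or `"bicubic"`.
#' @return Numeric matrix of dimension `target_rows` x `target_cols`.
#' @export
resize_gray <- function(img, target_rows, target_cols,
                        method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  check_gray(img)
  if (target_rows < 1 || target_cols < 1) stopf("resize targets must be >= 1")
  if (target_rows == nrow(img) && target_cols == ncol(img) &&
      method == "bilinear")
    return(img)
  Wr <- interp_matrix(nrow(img), target_rows, method)
  Wc <- interp_matrix(ncol(img), target_cols, method)
  clamp(Wr %*% img %*% t(Wc), 0, 255)
}

# ---- body masking ---------------------------------------------------------

#' Extract a body mask
#'
#' Segments the patient's body (anatomy) from the background: threshold
#' (Otsu's method when `threshold` is `NULL`), morphological closing with a
#' disc brush, keep the largest connected foreground component, and fill
#' interior holes. All steps are configurable; the recipe is a pragmatic
#' default since reconstruction scoring only needs a region that covers the
#' anatomy and excludes air/table background.
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param threshold Foreground threshold on the \[0, 255\] scale; `NULL` for
#'   Otsu.
#' @param closing_radius Disc radius (pixels) of the morphological closing;
#'   0 disables closing.
#' @param fill_holes Fill interior holes of the retained component.
#' @return Logical matrix of the same shape (TRUE = body). All-background
#'   input yields an empty mask with a warning.
#' @export
extract_body_mask <- function(img, threshold = NULL, closing_radius = 5,
                              fill_holes = TRUE) {
  check_gray(img)
  if (is.null(threshold)) {
    u <- clamp(img / 255, 0, 1)
    threshold <- 255 * EBImage::otsu(EBImage::Image(u), range = c(0, 1))
  }
  fg <- img > threshold
  if (!any(fg)) {
    warnf("no pixel exceeds the foreground threshold; returning empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  m <- EBImage::Image(fg * 1)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    m <- EBImage::closing(m, brush)
  }
  lab <- EBImage::bwlabel(m)
  labv <- as.integer(lab)
  labv <- labv[labv > 0]
  if (length(labv) == 0) {
    warnf("closing removed all foreground; returning empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  keep <- as.integer(names(which.max(table(labv))))
  comp <- EBImage::Image((lab == keep) * 1)
  if (fill_holes) comp <- EBImage::fillHull(comp)
  matrix(as.integer(comp) > 0, nrow(img), ncol(img))
}

# ---- PNG output -----------------------------------------------------------

#' Write a grayscale image as 8-bit PNG
#'
#' Quantizes with round-half-up (the only place quantization happens in the
#' pipeline) and clamps to \[0, 255\].
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  check_gray(img)
  q <- clamp(round_half_up(img), 0, 255)
  png::writePNG(q / 255, path)
  invisible(path)
}

#' Write a binary mask as PNG (0/255)
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!is.logical(mask)) stopf("`mask` must be logical")
  png::writePNG((mask * 1), path)
  invisible(path)
}

#' Read a mask PNG written by [write_mask_png()]
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  load_png(path)$pixels > 127
}
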