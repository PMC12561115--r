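test_that("CT windowing maps the window edges, centre and midpoints linearly", {
  img <- matrix(c(-125, 225, 50, -300, 500, 137.5), 2, 3)
  w <- apply_window(img, level = 50, width = 350)
  expect_equal(w[1, 1], 0)
  expect_equal(w[2, 1], 255)
  expect_equal(w[1, 2], 127.5)
  expect_equal(w[2, 2], 0)    # below lower edge clamps
  expect_equal(w[1, 3], 255)  # above upper edge clamps
  expect_equal(w[2, 3], (137.5 + 125) / 350 * 255)
  expect_error(apply_window(img, 50, 0), "width")
})

test_that("windowing is monotone and acts as identity in window units", {
  x <- sort(runif(100, -500, 500))
  w <- apply_window(matrix(x, 1), level = 0, width = 400)
  expect_true(all(diff(as.numeric(w)) >= 0))
  # an already-windowed [0,255] image re-windowed with the identity window
  g <- random_gray(8, 8, seed = 1)
  expect_equal(apply_window(g, level = 127.5, width = 255), g)
})

test_that("linear rescaling attains the full range and inverts MONOCHROME1", {
  expect_equal(rescale_linear(matrix(c(0, 100), 1)), matrix(c(0, 255), 1))
  expect_equal(rescale_linear(matrix(c(-5, 0, 5), 1)),
               matrix(c(0, 127.5, 255), 1))
  m1 <- raw_image(matrix(c(0, 100), 1), photometric = "monochrome1")
  expect_equal(rescale_linear(m1), matrix(c(255, 0), 1))
  for (seed in 1:5) {
    r <- rescale_linear(random_gray(6, 7, seed))
    expect_equal(min(r), 0)
    expect_equal(max(r), 255)
  }
  expect_warning(out <- rescale_linear(matrix(7, 3, 3)), "constant")
  expect_equal(out, matrix(0, 3, 3))
})

test_that("PNG round trip preserves 8-bit images and quantizes half-up", {
  path <- withr::local_tempfile(fileext = ".png")
  img <- matrix(sample(0:255, 48, replace = TRUE), 6, 8)
  write_gray_png(img, path)
  expect_equal(load_image(path, "png")$pixels, img)
  # 127.5 rounds up to 128 only at write time
  write_gray_png(matrix(127.5, 2, 2), path)
  expect_equal(load_image(path)$pixels, matrix(128, 2, 2))
  expect_error(load_image(file.path(tempdir(), "nope.png")), "does not exist")
})

test_that("DICOM reading applies rescale slope/intercept in both VR modes", {
  stored <- matrix(c(1024L, 100L, 0L, 2048L, 512L, 1L), 2, 3)
  for (explicit in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".dcm")
    write_test_dicom(path, stored, slope = 1, intercept = -1024,
                     explicit = explicit)
    r <- load_image(path, "dicom")
    expect_s3_class(r, "raw_image")
    expect_equal(r$pixels, stored - 1024)
    expect_equal(r$photometric, "monochrome2")
  }
})

test_that("DICOM reading handles 8-bit data, MONOCHROME1 and rejects multi-frame", {
  path <- withr::local_tempfile(fileext = ".dcm")
  stored <- matrix(0:11, 3, 4)
  write_test_dicom(path, stored, bits = 8, photometric = "MONOCHROME1")
  r <- load_image(path, "dicom")
  expect_equal(r$pixels, stored)
  expect_equal(r$photometric, "monochrome1")
  write_test_dicom(path, stored, n_frames = 2)
  expect_error(load_image(path, "dicom"), "multi-frame")
})

test_that("format auto-detection distinguishes PNG from DICOM content", {
  dcm <- withr::local_tempfile(fileext = ".bin")
  write_test_dicom(dcm, matrix(5L, 2, 2))
  expect_equal(load_image(dcm)$pixels, matrix(5, 2, 2))
  png_path <- withr::local_tempfile(fileext = ".png")
  write_gray_png(matrix(9, 2, 2), png_path)
  expect_equal(load_image(png_path)$pixels, matrix(9, 2, 2))
})

test_that("resizing preserves constants, identities, and the checkerboard average", {
  const <- matrix(42, 5, 7)
  expect_equal(resize_gray(const, 3, 2), matrix(42, 3, 2))
  expect_equal(resize_gray(const, 9, 11, "bicubic"), matrix(42, 9, 11),
               tolerance = 1e-12)
  img <- random_gray(6, 6, seed = 2)
  expect_identical(resize_gray(img, 6, 6), img)
  cb <- 255 * outer(0:3, 0:3, function(r, c) (r + c) %% 2)
  expect_equal(resize_gray(cb, 2, 2), matrix(127.5, 2, 2))
})

test_that("bilinear resizing agrees with an independent reference resampler", {
  img <- random_gray(16, 12, seed = 3)
  ours <- resize_gray(img, 8, 6)
  ref <- matrix(as.numeric(EBImage::resize(EBImage::Image(img / 255),
                                           w = 8, h = 6,
                                           filter = "bilinear")), 8, 6) * 255
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("body mask area matches the analytic ellipse area", {
  img <- ellipse_image(64, 64, cy = 32, cx = 32, b = 20, a = 24)
  mask <- extract_body_mask(img)
  analytic <- pi * 24 * 20
  expect_lt(abs(sum(mask) - analytic) / analytic, 0.05)
})

test_that("body mask keeps the largest component and fills holes", {
  img <- ellipse_image(64, 64, cy = 32, cx = 28, b = 18, a = 20)
  img[30:34, 30:34] <- 0                 # interior hole -> filled
  img[3, 60] <- 255                      # detached bright speck -> dropped
  mask <- extract_body_mask(img)
  expect_true(all(mask[30:34, 30:34]))
  expect_false(mask[3, 60])
})

test_that("body mask is invariant to zero padding", {
  img <- ellipse_image(48, 48, cy = 24, cx = 24, b = 14, a = 16)
  mask <- extract_body_mask(img)
  padded <- matrix(0, 68, 68)
  padded[11:58, 11:58] <- img
  mask_pad <- extract_body_mask(padded)
  expect_equal(mask_pad[11:58, 11:58], mask)
  expect_warning(empty <- extract_body_mask(matrix(0, 16, 16)), "empty mask")
  expect_false(any(empty))
})

test_that("mask PNGs round-trip as 0/255", {
  path <- withr::local_tempfile(fileext = ".png")
  mask <- matrix(c(TRUE, FALSE), 4, 4)
  write_mask_png(mask, path)
  expect_equal(read_mask_png(path), mask)
})
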