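test_that("baseline sets are seeded, distinct and carry latent certificates", {
  be <- tiny_backend()
  s1 <- generate_baseline_set(be, 5, seed = 10)
  s2 <- generate_baseline_set(be, 5, seed = 10)
  expect_identical(s1$images, s2$images)
  for (i in 1:5)
    expect_identical(decode(be, s1$latents[[i]]), s1$images[[i]])
  many <- generate_baseline_set(be, 50, seed = 11)$images
  dists <- combn(10, 2, function(ij)
    max(abs(many[[ij[1]]] - many[[ij[2]]])))
  expect_true(all(dists > 0))
})

test_that("needle injection is local, seeded and marks its own pixels", {
  be <- tiny_backend()
  img <- generate_baseline_set(be, 1, seed = 12)$images[[1]]
  res <- inject_needle(img, seed = 3, length = 10, thickness = 2)
  expect_true(any(res$mask))
  expect_equal(res$image[!res$mask], img[!res$mask])
  expect_true(any(res$image[res$mask] != img[res$mask]))
  res2 <- inject_needle(img, seed = 3, length = 10, thickness = 2)
  expect_identical(res2, res)
  res3 <- inject_needle(img, seed = 4, length = 10, thickness = 2)
  expect_false(identical(res3$mask, res$mask))
})

test_that("a zero-contrast needle changes nothing but still has a mask", {
  img <- ellipse_image(32, 32, cy = 16, cx = 16, b = 12, a = 13,
                       intensity = 120)
  res <- inject_needle(img, seed = 5, length = 8, thickness = 2,
                       intensity = 120, artifact = FALSE)
  expect_true(any(res$mask))
  expect_equal(res$image, img)
})

test_that("needle placement fails gracefully when the body is too small", {
  img <- ellipse_image(32, 32, cy = 16, cx = 16, b = 2, a = 2,
                       intensity = 120)
  expect_error(inject_needle(img, seed = 1, length = 30),
               class = "anomrecon_placement_error")
})

test_that("fluid rims form a peripheral band of the configured intensity", {
  be <- tiny_backend()
  img <- generate_baseline_set(be, 1, seed = 13)$images[[1]]
  res <- inject_fluid_rim(img, seed = 2, width = 3, intensity = 35)
  expect_true(any(res$mask))
  expect_true(all(res$image[res$mask] == 35))
  expect_equal(res$image[!res$mask], img[!res$mask])
  # rim pixels sit at the body periphery: none deep inside the body
  body <- extract_body_mask(img)
  inner <- matrix(as.integer(EBImage::erode(
    EBImage::Image(body * 1), EBImage::makeBrush(11, "disc"))) > 0,
    nrow(img), ncol(img))
  expect_false(any(res$mask & inner))
  zero <- inject_fluid_rim(img, seed = 2, width = 0)
  expect_false(any(zero$mask))
  expect_identical(zero$image, img)
  expect_identical(inject_fluid_rim(img, seed = 2, width = 3),
                   inject_fluid_rim(img, seed = 2, width = 3))
})

test_that("global transforms behave as involutions, constants and filters", {
  img <- random_gray(16, 16, 14)
  expect_equal(apply_global_transform(apply_global_transform(img, "invert"),
                                      "invert"), img)
  blank <- apply_global_transform(img, "blank", value = 40)
  expect_equal(sd(blank), 0)
  expect_equal(blank[1, 1], 40)
  expect_equal(apply_global_transform(matrix(99, 8, 8), "edge_filter"),
               matrix(0, 8, 8))
  edge <- apply_global_transform(img, "edge_filter")
  expect_equal(max(edge), 255)
  n1 <- apply_global_transform(img, "noise", noise_sd = 10, seed = 3)
  expect_identical(n1, apply_global_transform(img, "noise", noise_sd = 10,
                                              seed = 3))
  expect_error(apply_global_transform(img, "swirl"))
})

test_that("benchmark bundles have configured counts and regenerate bitwise", {
  be <- tiny_backend()
  cfg <- benchmark_config(n_train = 4, n_test = 3,
                          anomaly_sets = list(
                            needle = list(n = 2, type = "needle",
                                          params = list(length = 8)),
                            inverted = list(n = 2, type = "invert")),
                          seed = 99)
  b1 <- make_benchmark(be, cfg)
  expect_length(b1$baseline_train, 4)
  expect_length(b1$baseline_test, 3)
  expect_length(b1$anomaly_sets$needle, 2)
  expect_length(b1$anomaly_masks$needle, 2)
  expect_null(b1$anomaly_masks$inverted)
  expect_true(all(vapply(b1$anomaly_masks$needle, any, logical(1))))
  b2 <- make_benchmark(be, cfg)
  expect_identical(b1$baseline_train, b2$baseline_train)
  expect_identical(b1$anomaly_sets, b2$anomaly_sets)
  only_base <- make_benchmark(be, benchmark_config(n_train = 2, n_test = 2,
                                                   anomaly_sets = list(),
                                                   seed = 1))
  expect_length(only_base$anomaly_sets, 0)
})

test_that("bundles round-trip through the directory layout", {
  be <- tiny_backend()
  cfg <- benchmark_config(n_train = 2, n_test = 2,
                          anomaly_sets = list(
                            needle = list(n = 2, type = "needle",
                                          params = list(length = 8))),
                          seed = 5)
  bundle <- make_benchmark(be, cfg)
  dir <- withr::local_tempdir()
  write_bundle(bundle, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  loaded <- load_bundle(dir)
  expect_length(loaded$baseline_test, 2)
  expect_length(loaded$anomaly_sets$needle, 2)
  expect_identical(loaded$anomaly_masks$needle, bundle$anomaly_masks$needle)
  # PNG quantization: loaded images within rounding of the originals
  expect_lt(max(abs(loaded$baseline_test[[1]] - bundle$baseline_test[[1]])),
            0.5 + 1e-9)
})

test_that("needle content is outside the backend's expressible family", {
  be <- tiny_backend()
  base <- generate_baseline_set(be, 10, seed = 17)
  cfg <- projection_config(steps = 100, seed = 0)
  rms <- vapply(1:10, function(i) {
    inj <- inject_needle(base$images[[i]], seed = 500 + i, length = 10,
                         thickness = 2)
    fit <- project(be, inj$image, cfg)
    sqrt(mean((fitted(fit)[inj$mask] - inj$image[inj$mask])^2))
  }, numeric(1))
  expect_true(all(rms >= 10))
})
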