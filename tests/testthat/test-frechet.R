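test_that("the radiomics-lite extractor is deterministic with closed-form edge cases", {
  ext <- radiomics_lite_extractor()
  img <- random_gray(16, 16, 81)
  expect_identical(ext(img), ext(img))
  expect_length(ext(img), attr(ext, "n_features"))
  expect_true(all(is.finite(ext(img))))
  const <- matrix(128, 16, 16)
  f <- ext(const)
  expect_equal(unname(f["sd"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["grad_mean"]), 0)
  rows <- extract_features(list(img, img, const))
  expect_equal(rows[1, ], rows[2, ])
  calls <- new.env(); calls$n <- 0
  bad <- function(img) {
    calls$n <- calls$n + 1
    runif(1 + calls$n) # length grows with every call
  }
  expect_error(extract_features(list(img, img), bad),
               class = "anomrecon_contract_error")
  expect_error(extract_features(list(img)), "at least 2")
})

test_that("moments compute sample mean and covariance with n-1 denominator", {
  f <- rbind(c(0, 0), c(2, 2))
  m <- moments(f)
  expect_equal(unname(m$mu), c(1, 1))
  expect_equal(unname(m$sigma), matrix(2, 2, 2))
  expect_equal(m$n, 2)
  same <- matrix(3, 4, 5)
  expect_equal(moments(same)$sigma, matrix(0, 5, 5), ignore_attr = TRUE)
  shuffled <- f[c(2, 1), ]
  expect_equal(moments(shuffled)$mu, m$mu)
  expect_equal(moments(shuffled)$sigma, m$sigma)
  expect_error(moments(f[1, , drop = FALSE]),
               class = "anomrecon_insufficient_sample")
})

fm <- function(mu, sigma) moments_from(mu, sigma)
moments_from <- function(mu, sigma) {
  structure(list(mu = mu, sigma = as.matrix(sigma), n = NA_integer_),
            class = "feature_moments")
}

test_that("frechet distance matches the 1-D closed form", {
  expect_equal(frechet_distance(fm(0, matrix(1)), fm(0, matrix(1))), 0)
  # mu 0 vs 3, var 1 vs 4: 9 + (1-2)^2 = 10
  expect_equal(frechet_distance(fm(0, matrix(1)), fm(3, matrix(4))), 10)
  for (s in 1:20) {
    v <- withr::with_seed(s, c(rnorm(2), runif(2, 0.1, 5)))
    closed <- (v[1] - v[2])^2 + (sqrt(v[3]) - sqrt(v[4]))^2
    expect_equal(frechet_distance(fm(v[1], matrix(v[3])),
                                  fm(v[2], matrix(v[4]))),
                 closed, tolerance = 1e-6)
  }
})

test_that("frechet distance matches the commuting-diagonal closed form", {
  for (s in 1:20) {
    p <- withr::with_seed(s, list(mu1 = rnorm(4), mu2 = rnorm(4),
                                  l1 = runif(4, 0.1, 4),
                                  l2 = runif(4, 0.1, 4)))
    closed <- sum((p$mu1 - p$mu2)^2) + sum((sqrt(p$l1) - sqrt(p$l2))^2)
    got <- frechet_distance(fm(p$mu1, diag(p$l1)), fm(p$mu2, diag(p$l2)))
    expect_equal(got, closed, tolerance = 1e-6)
  }
})

test_that("frechet distance agrees with an independent matrix square root", {
  for (s in 1:10) {
    dat <- withr::with_seed(s, list(a = matrix(rnorm(40), 20, 2),
                                    b = matrix(rnorm(40, 1), 20, 2)))
    m1 <- moments(dat$a); m2 <- moments(dat$b)
    got <- frechet_distance(m1, m2)
    covmean <- pracma::sqrtm(m1$sigma %*% m2$sigma)$B
    oracle <- sum((m1$mu - m2$mu)^2) +
      sum(diag(m1$sigma + m2$sigma - 2 * Re(covmean)))
    expect_equal(got, oracle, tolerance = 1e-6)
    expect_equal(frechet_distance(m2, m1), got, tolerance = 1e-10)
    expect_gte(got, 0)
  }
  m <- moments(matrix(rnorm(60), 20, 3))
  expect_equal(frechet_distance(m, m), 0, tolerance = 1e-8)
  expect_error(frechet_distance(m, fm(rnorm(2), diag(2))),
               class = "anomrecon_contract_error")
})

test_that("the halving protocol is seeded and null under no manipulation", {
  be <- tiny_backend()
  imgs <- generate_baseline_set(be, 10, seed = 91)$images
  base <- contextual_fd_protocol(imgs, repeats = 3, seed = 11)
  base2 <- contextual_fd_protocol(imgs, repeats = 3, seed = 11)
  expect_identical(base$fds, base2$fds)
  noise0 <- contextual_fd_protocol(imgs, condition = "noise", noise_sd = 0,
                                   repeats = 3, seed = 11)
  expect_equal(noise0$mean_fd, base$mean_fd)
  expect_error(contextual_fd_protocol(imgs, repeats = 0),
               class = "anomrecon_config_error")
})

test_that("identical halves give zero distance; noise inflates it", {
  same <- replicate(8, matrix(100, 8, 8), simplify = FALSE)
  res <- contextual_fd_protocol(same, repeats = 2, seed = 1)
  expect_equal(res$mean_fd, 0, tolerance = 1e-8)
  be <- tiny_backend()
  imgs <- generate_baseline_set(be, 12, seed = 92)$images
  base <- contextual_fd_protocol(imgs, repeats = 3, seed = 7)
  noisy <- contextual_fd_protocol(imgs, condition = "noise", noise_sd = 50,
                                  repeats = 3, seed = 7)
  expect_gt(noisy$mean_fd, base$mean_fd)
})

test_that("noise and blur helpers stay in range and are seeded", {
  img <- random_gray(12, 12, 95)
  n1 <- add_gaussian_noise(img, sd = 20, seed = 4)
  expect_identical(n1, add_gaussian_noise(img, sd = 20, seed = 4))
  expect_true(all(n1 >= 0 & n1 <= 255))
  expect_identical(add_gaussian_noise(img, sd = 0, seed = 4), img)
  b1 <- gaussian_blur(img, sd = 1.5)
  expect_true(all(b1 >= 0 & b1 <= 255))
  expect_lt(sd(b1), sd(img)) # smoothing shrinks dispersion
})
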