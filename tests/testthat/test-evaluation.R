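test_that("auroc matches closed-form cases and exhaustive pair enumeration", {
  expect_equal(auroc(c(1, 2), c(3, 4)), 1.0)
  expect_equal(auroc(rep(5, 4), rep(5, 3)), 0.5)
  expect_equal(auroc(c(1, 3), c(2, 4)), 0.75)
  pair_oracle <- function(b, a) {
    cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
    mean(cmp)
  }
  for (nb in 1:6) for (na in 1:6) {
    for (rep in 1:3) {
      v <- withr::with_seed(nb * 100 + na * 10 + rep,
                            sample(1:6, nb + na, replace = TRUE))
      b <- v[seq_len(nb)]; a <- v[-seq_len(nb)]
      expect_equal(auroc(b, a), pair_oracle(b, a))
    }
  }
  expect_error(auroc(numeric(0), 1), class = "anomrecon_insufficient_data")
})

test_that("auroc complements when the roles are swapped", {
  for (s in 1:10) {
    v <- withr::with_seed(s, list(b = sample(1:10, 5, TRUE),
                                  a = sample(1:10, 7, TRUE)))
    expect_equal(auroc(v$b, v$a) + auroc(v$a, v$b), 1)
  }
})

test_that("subsampled auroc is calibrated, separates, and is seeded", {
  null_scores <- withr::with_seed(1, list(b = rnorm(400), a = rnorm(80)))
  res <- subsampled_auroc(null_scores$b, null_scores$a, repeats = 50, seed = 2)
  expect_lt(abs(res$mean_auroc - 0.5), 0.1)
  expect_equal(res$subsample_size, 80)
  sep <- subsampled_auroc(1:100, 201:240, repeats = 20, seed = 3)
  expect_equal(sep$mean_auroc, 1.0)
  expect_equal(sep$sd_auroc, 0.0)
  r1 <- subsampled_auroc(null_scores$b, null_scores$a, repeats = 10, seed = 9)
  r2 <- subsampled_auroc(null_scores$b, null_scores$a, repeats = 10, seed = 9)
  expect_identical(r1$aurocs, r2$aurocs)
  expect_error(subsampled_auroc(1:3, 1:5), class = "anomrecon_config_error")
})

test_that("subsampled auroc converges to the full-sample auroc", {
  scores <- withr::with_seed(4, list(b = rnorm(300), a = rnorm(60, 0.8)))
  full <- auroc(scores$b, scores$a)
  res <- subsampled_auroc(scores$b, scores$a, repeats = 500, seed = 5)
  expect_lt(abs(res$mean_auroc - full), 0.02)
})

test_that("localization hits everything with full masks and nothing with empty ones", {
  be <- tiny_backend()
  targets <- generate_baseline_set(be, 2, seed = 55)$images
  full_masks <- lapply(targets, function(t) matrix(TRUE, nrow(t), ncol(t)))
  empty_masks <- lapply(targets, function(t) matrix(FALSE, nrow(t), ncol(t)))
  res_full <- localization_proportion(targets, be, full_masks, d = 8,
                                      seeds = 0:1, steps = 5)
  expect_equal(res_full$mean_proportion, 1.0)
  expect_equal(res_full$sd_proportion, 0.0)
  res_empty <- localization_proportion(targets, be, empty_masks, d = 8,
                                       seeds = 0:1, steps = 5)
  expect_equal(res_empty$mean_proportion, 0.0)
  expect_error(
    localization_proportion(targets, be, full_masks[1], d = 8, seeds = 0),
    class = "anomrecon_contract_error")
})

test_that("fd-reduction summary handles trivial and degenerate tables", {
  expect_equal(summarize_fd_reduction(
    data.frame(generated_fd = c(2, 3), manipulated_fd = c(2, 3))), 0)
  expect_equal(summarize_fd_reduction(
    data.frame(generated_fd = 1, manipulated_fd = 4)), 75)
  expect_error(summarize_fd_reduction(
    data.frame(generated_fd = 1, manipulated_fd = 0)), "zero")
})

test_that("improvement summary computes relative changes with sample SD", {
  same <- data.frame(auroc_full = c(0.5, 0.7), auroc_masked = c(0.5, 0.7))
  res <- summarize_improvement(same)
  expect_equal(res$mean_percent, 0)
  expect_equal(res$sd_percent, 0)
  expect_warning(single <- summarize_improvement(
    data.frame(auroc_full = 0.5, auroc_masked = 1.0)), "SD undefined")
  expect_equal(single$mean_percent, 100)
  expect_equal(single$sd_percent, 0)
  expect_error(summarize_improvement(
    data.frame(auroc_full = 0, auroc_masked = 1)), "zero")
})

test_that("dataset mean summary reports both SD conventions", {
  res <- summarize_dataset_mean(rep(0.7, 5))
  expect_equal(res$mean, 0.7)
  expect_equal(res$sd_sample, 0)
  x <- c(0.2, 0.4, 0.9)
  res2 <- summarize_dataset_mean(x)
  expect_equal(res2$mean, mean(x))
  expect_equal(res2$sd_sample, sd(x))
  expect_equal(res2$sd_population, sqrt(mean((x - mean(x))^2)))
})

test_that("bundled reference tables load with their expected shapes", {
  fd <- reference_table("fd_context")
  expect_equal(nrow(fd), 6)
  expect_true(all(c("generated_fd", "noise_fd", "blur_fd") %in% names(fd)))
  full <- reference_table("auroc_full")
  expect_equal(nrow(full), 12)
  body <- reference_table("auroc_body")
  expect_equal(nrow(body), 6)
  loc <- reference_table("localization")
  expect_equal(nrow(loc), 12)
})
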