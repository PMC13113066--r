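test_that("scan_configs enumerates the 16 distinct factor combinations", {
  g <- scan_configs()
  expect_equal(nrow(g), 16)
  expect_equal(nrow(unique(g)), 16)
  expect_setequal(unique(g$region), c("full", "cropped"))
  expect_setequal(unique(g$angle), c("horizontal", "vertical"))
  expect_setequal(unique(g$augmentation), c("morphological", "comprehensive"))
  expect_setequal(unique(g$model), c("medium", "small"))
})

test_that("run_grid produces n_runs x 16 deterministic rows and resumes", {
  # a cheap synthetic evaluator keeps this a pure grid-machinery test
  fake_eval <- function(dataset, config, split = NULL, seed = 1, ...) {
    set.seed(seed %% 1e6 + sum(utf8ToInt(paste(unlist(config), collapse = ""))))
    tibble::tibble(region = config$region, angle = config$angle,
                   augmentation = config$augmentation, model = config$model,
                   seed = seed, precision = runif(1), recall = runif(1),
                   f1 = runif(1))
  }
  r1 <- run_grid(list(), n_runs = 3, base_seed = 5, evaluator = fake_eval)
  expect_equal(nrow(r1), 48)
  expect_equal(nrow(unique(r1[, c("region", "angle", "augmentation", "model")])), 16)
  r2 <- run_grid(list(), n_runs = 3, base_seed = 5, evaluator = fake_eval)
  expect_identical(r1, r2)
  # resuming from a partial table reuses its rows
  partial <- r1[r1$run < 3, ]
  r3 <- run_grid(list(), n_runs = 3, base_seed = 5, evaluator = fake_eval,
                 previous = partial)
  expect_identical(r3, r1)
  expect_error(run_grid(list(), n_runs = 0, evaluator = fake_eval), "at least 1")
})

test_that("a planted cropped recall penalty is recovered by the grid means", {
  res <- simulate_run_results(
    n_runs = 10, effects = list(recall = c(region = -0.2)),
    baseline = c(precision = 0.8, recall = 0.85, f1 = 0.82),
    noise_sd = 0.02, seed = 4)
  gap <- mean(res$recall[res$region == "full"]) -
    mean(res$recall[res$region == "cropped"])
  expect_lt(abs(gap - 0.2), 0.05)
})

test_that("ANOVA F statistics equal the brute-force mean decomposition", {
  # 2-factor toy grid, 2 reps: hand-checkable two-way ANOVA arithmetic
  d2 <- expand.grid(region = c("full", "cropped"),
                    angle = c("horizontal", "vertical"), rep = 1:2,
                    stringsAsFactors = FALSE)
  d2$augmentation <- "morphological"
  d2$model <- "medium"
  d2$recall <- c(0.9, 0.7, 0.95, 0.8, 0.88, 0.72, 0.97, 0.78)
  # the factorial fit needs all four factors present; compare region/angle
  # F values against the brute-force oracle computed on the same data
  oracle <- oracle_anova_f(d2, "recall", c("region", "angle"))
  fit <- lm(recall ~ region + angle, data = d2)
  a <- anova(fit)
  expect_equal(unname(a[c("region", "angle"), "F value"]), unname(oracle),
               tolerance = 1e-8)

  # full 4-factor balanced grid, 3 reps, random response
  res <- simulate_run_results(
    n_runs = 3,
    effects = list(recall = c(region = -0.1, angle = 0.05,
                              augmentation = 0.02, model = -0.01)),
    noise_sd = 0.03, seed = 11)
  rep4 <- fit_main_effects(res, "recall")
  oracle4 <- oracle_anova_f(as.data.frame(res), "recall",
                            c("region", "angle", "augmentation", "model"))
  got <- setNames(rep4$anova$statistic, rep4$anova$term)
  expect_equal(unname(got[names(oracle4)]), unname(oracle4), tolerance = 1e-8)
  # SS additivity on the balanced design
  y <- res$recall
  expect_equal(sum(rep4$anova$sum_sq) + rep4$residual_ss,
               sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("all-equal responses give zero F statistics and zero coefficients", {
  res <- simulate_run_results(n_runs = 2, effects = list(),
                              baseline = c(precision = 0.8, recall = 0.8,
                                           f1 = 0.8),
                              noise_sd = 0, seed = 1)
  rep0 <- suppressWarnings(fit_main_effects(res, "recall"))  # perfect fit
  expect_true(all(rep0$anova$statistic == 0))
  expect_true(all(abs(rep0$coefficients$estimate[-1]) < 1e-10))
  expect_equal(unname(rep0$coefficients$estimate[1]), 0.8, tolerance = 1e-10)
})

test_that("planted effects come out with the right sign and significance", {
  res <- simulate_run_results(
    n_runs = 10,
    effects = list(recall = c(region = -0.2),
                   precision = c(augmentation = -0.05)),
    noise_sd = 0.02, seed = 21)
  rec <- fit_main_effects(res, "recall")
  co <- rec$coefficients
  expect_lt(co$estimate[co$term == "regioncropped"], 0)
  expect_lt(rec$anova$p_value[rec$anova$term == "region"], 0.05)
  pre <- fit_main_effects(res, "precision")
  cop <- pre$coefficients
  expect_lt(cop$estimate[cop$term == "augmentationcomprehensive"], 0)
  # confidence intervals contain their estimates
  expect_true(all(co$ci_low <= co$estimate & co$estimate <= co$ci_high))
})

test_that("two-way model adds six interaction tests and respects null interactions", {
  # additive truth: interaction p-values are null, so significant calls
  # appear at the nominal 5% rate (binomial bound over 20 x 6 tests)
  n_sig <- vapply(1:20, function(r) {
    res <- simulate_run_results(
      n_runs = 10,
      effects = list(recall = c(region = -0.1, angle = 0.05)),
      noise_sd = 0.01, seed = 500 + r)
    rep2 <- fit_two_way(res, "recall")
    inter <- rep2$anova[grepl(":", rep2$anova$term), ]
    expect_equal(nrow(inter), 6)
    sum(inter$p_value < 0.05)
  }, integer(1))
  n_tests <- 20 * 6
  expect_lte(sum(n_sig), 0.05 * n_tests + 3 * sqrt(n_tests * 0.05 * 0.95))

  # a planted angle x augmentation interaction has the largest interaction F
  res <- simulate_run_results(
    n_runs = 10,
    effects = list(recall = c(region = -0.1, "angle:augmentation" = 0.15)),
    noise_sd = 0.02, seed = 77)
  rep2 <- fit_two_way(res, "recall")
  inter <- rep2$anova[grepl(":", rep2$anova$term), ]
  expect_equal(inter$term[which.max(inter$statistic)], "angle:augmentation")
  # main-effect rows are retained
  expect_true(all(c("region", "angle", "augmentation", "model") %in%
                    rep2$anova$term))
})

test_that("interactions with a factor the response ignores have zero SS", {
  # noiseless response depending on region only: every term not involving
  # region has exactly zero SS and reports F = 0, not 0/0
  res <- simulate_run_results(
    n_runs = 2, effects = list(recall = c(region = -0.1)),
    noise_sd = 0, seed = 31)
  rep2 <- suppressWarnings(fit_two_way(res, "recall"))  # perfect fit
  a <- rep2$anova
  inert <- !grepl("region", a$term)
  expect_true(all(a$sum_sq[inert] < 1e-12))
  expect_true(all(a$statistic[inert] == 0))
  expect_true(all(a$sum_sq >= 0))
})

test_that("type II table agrees with its reference implementation", {
  res <- simulate_run_results(
    n_runs = 3,
    effects = list(recall = c(region = -0.1, "angle:augmentation" = 0.07)),
    noise_sd = 0.03, seed = 41)
  rep2 <- fit_two_way(res, "recall")
  ref <- car::Anova(rep2$fit, type = 2)
  terms_idx <- setdiff(rownames(ref), "Residuals")
  got <- setNames(rep2$anova$sum_sq, rep2$anova$term)
  expect_equal(unname(got[terms_idx]), ref[terms_idx, "Sum Sq"],
               tolerance = 1e-10)
})

test_that("rank-deficient designs fail with the missing cells named", {
  res <- simulate_run_results(n_runs = 2, seed = 3)
  broken <- res[res$region == "full", ]
  expect_error(fit_main_effects(broken, "recall"), "region=cropped")
  broken2 <- res[!(res$region == "full" & res$angle == "vertical"), ]
  expect_error(fit_two_way(broken2, "recall"), "missing cells")
})

test_that("durbin_watson matches direct arithmetic and its reference implementation", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_error(durbin_watson(rep(0, 5)), "all-zero")
  expect_error(durbin_watson(1), "at least 2")
  # near 2 for independent residuals
  set.seed(8)
  expect_lt(abs(durbin_watson(rnorm(10000)) - 2), 0.1)
  # agrees with lmtest::dwtest on a real regression
  skip_if_not_installed("lmtest")
  set.seed(9)
  d <- data.frame(x = rnorm(50))
  d$y <- 1 + 2 * d$x + rnorm(50)
  fit <- lm(y ~ x, data = d)
  expect_equal(durbin_watson(residuals(fit)),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)
})

test_that("condition_number detects orthogonality and collinearity", {
  expect_equal(condition_number(diag(4)), 1)
  # balanced +-1-coded 2^4 main-effects design with intercept
  g <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1), d = c(-1, 1))
  x <- cbind(1, as.matrix(g))
  expect_equal(condition_number(x), 1, tolerance = 1e-10)
  expect_error(condition_number(cbind(1:4, 1:4)), "rank deficient")
})

test_that("reports carry consistent diagnostics and print cleanly", {
  res <- simulate_run_results(n_runs = 5,
                              effects = list(recall = c(region = -0.1)),
                              noise_sd = 0.02, seed = 13)
  rep1 <- fit_main_effects(res, "recall")
  expect_s3_class(rep1, "scan_lm_report")
  expect_true(rep1$durbin_watson > 0 && rep1$durbin_watson < 4)
  expect_gt(rep1$condition_number, 1)
  expect_equal(rep1$n, 80)
  out <- capture.output(print(rep1))
  expect_true(any(grepl("Durbin-Watson", out)))
  expect_true(any(grepl("regioncropped", out)))
})
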