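test_that("simulate_population draws the declared class mix and count ranges", {
  pop <- simulate_population(107, prevalence = 25 / 107, seed = 1)
  expect_equal(nrow(pop), 107)
  n_up <- sum(pop$true_class == "underperforming")
  # binomial around 25: stay within 3 SDs
  expect_lt(abs(n_up - 25), 3 * sqrt(107 * (25 / 107) * (82 / 107)) + 1e-9)
  expect_true(all(pop$n_collections >= 2 & pop$n_collections <= 49))
  tot <- pop$n_images_horizontal + pop$n_images_vertical
  expect_true(all(tot >= 9 & tot <= 17))
  expect_true(all(pop$bad_rate >= 0 & pop$bad_rate <= 1))
  # underperforming profiles have strictly higher bad + trash rates
  up <- pop$true_class == "underperforming"
  expect_gt(min(pop$bad_rate[up] + pop$trash_rate[up]),
            max(pop$bad_rate[!up] + pop$trash_rate[!up]))
  expect_error(simulate_population(0), "positive")
})

test_that("degenerate prevalence values give single-class populations", {
  expect_true(all(simulate_population(2, prevalence = 0, seed = 1)$true_class ==
                    "high_quality"))
  expect_true(all(simulate_population(5, prevalence = 1, seed = 1)$true_class ==
                    "underperforming"))
})

test_that("underperforming fraction concentrates at the requested prevalence", {
  pop <- simulate_population(1000, prevalence = 0.25, seed = 7)
  frac <- mean(pop$true_class == "underperforming")
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
})

test_that("population medians match the study shape on large simulations", {
  pop <- simulate_population(2000, seed = 21)
  expect_equal(median(pop$n_collections), 30, tolerance = 1)
  expect_lte(abs(median(pop$n_images_horizontal + pop$n_images_vertical) - 12), 1)
})

test_that("semen histories respect count, spacing and criteria guarantees", {
  pop <- simulate_population(5, seed = 2)
  p <- pop[1, ]
  p$n_collections <- 30L
  h <- simulate_semen_history(p, seed = 9)
  expect_equal(nrow(h), 30)
  gaps <- diff(h$day)
  expect_true(all(gaps >= 5 & gaps <= 14))
  expect_lte(max(h$day) - min(h$day), 30 * 14)
  expect_gte(min(h$day), 200)
  # bad_rate = trash_rate = 0 means every record passes all three criteria
  p0 <- p
  p0$bad_rate <- 0
  p0$trash_rate <- 0
  h0 <- simulate_semen_history(p0, seed = 10)
  expect_true(all(h0$total_sperm_count >= 20e9))
  expect_true(all(h0$motility > 70 & h0$motility <= 100))
  expect_true(all(h0$morphology > 70 & h0$morphology <= 100))
  expect_false(any(h0$trash_flag))
})

test_that("per-record bad fraction matches its binomial target", {
  pop <- simulate_population(1, seed = 3)
  p <- pop[1, ]
  p$n_collections <- 40L
  p$bad_rate <- 0.5
  p$trash_rate <- 0
  fracs <- vapply(1:200, function(s) {
    h <- simulate_semen_history(p, seed = s)
    mean(classify_collection(h)$status == "bad")
  }, numeric(1))
  se <- sqrt(0.5 * 0.5 / (200 * 40))
  expect_lt(abs(mean(fracs) - 0.5), 3 * se)
})

test_that("records and images are bit-identical across repeated seeds", {
  pop1 <- simulate_population(6, seed = 5)
  pop2 <- simulate_population(6, seed = 5)
  expect_identical(pop1, pop2)
  expect_identical(simulate_semen_history(pop1[2, ], seed = 8),
                   simulate_semen_history(pop2[2, ], seed = 8))
  im1 <- render_image(pop1[1, ], "vertical", seed = 4)
  im2 <- render_image(pop2[1, ], "vertical", seed = 4)
  expect_identical(im1$pixels, im2$pixels)
  expect_false(identical(im1$pixels,
                         render_image(pop1[1, ], "vertical", seed = 5)$pixels))
})

test_that("rendered images satisfy the structural invariants", {
  pop <- simulate_population(4, seed = 6)
  for (angle in c("horizontal", "vertical")) {
    im <- render_image(pop[1, ], angle, seed = 3)
    expect_true(all(im$pixels >= 0 & im$pixels <= 255))
    expect_equal(dim(im$pixels), c(96, 96))
  }
  # vertical: the maximum row-mean lies inside the declared band rows
  imv <- render_image(pop[2, ], "vertical", seed = 11)
  expect_true(which.max(rowMeans(imv$pixels)) %in% imv$structure$rows)
  # horizontal: a compact bright blob at the declared center
  imh <- render_image(pop[2, ], "horizontal", seed = 12)
  expect_equal(unname(bright_centroid(imh$pixels, 140)),
               imh$structure$center, tolerance = 2)
  expect_error(render_image(pop[1, ], "vertical", size = 16), "at least 32")
})

test_that("echogenicity shift moves the central-region mean by its stated amount", {
  p20 <- list(boar_id = "x", echogenicity_shift = 20)
  p0 <- list(boar_id = "x", echogenicity_shift = 0)
  cm <- function(p, s) mean(crop_region(render_image(p, "vertical", seed = s))$pixels)
  d <- mean(vapply(1:100, function(s) cm(p20, s), numeric(1))) -
    mean(vapply(101:200, function(s) cm(p0, s), numeric(1)))
  expect_lt(abs(d - 20), 5)
})

test_that("with no echogenicity shift the central means carry no class signal", {
  # 20 replicates of a two-sample t-test on central means, one image per
  # profile so images are independent; expect >= 90% non-significant
  nonsig <- vapply(1:20, function(r) {
    a <- vapply(1:25, function(i) {
      mean(crop_region(render_image(list(boar_id = "a", echogenicity_shift = 0),
                                    "vertical", seed = r * 1000 + i))$pixels)
    }, numeric(1))
    b <- vapply(26:50, function(i) {
      mean(crop_region(render_image(list(boar_id = "b", echogenicity_shift = 0),
                                    "vertical", seed = r * 1000 + i))$pixels)
    }, numeric(1))
    stats::t.test(a, b)$p.value >= 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.9)
})

test_that("write_dataset produces the expected files and round-trips exactly", {
  pop <- simulate_population(3, seed = 4)
  pop$n_images_horizontal <- 4L
  pop$n_images_vertical <- 8L
  rec <- simulate_records(pop, seed = 5)
  imgs <- render_images(pop, size = 48, seed = 6)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(pop, rec, imgs, dir)
  expect_equal(nrow(manifest), 36)
  expect_equal(length(list.files(dir, pattern = "\\.png$")), 36)
  expect_true(all(c("records.csv", "manifest.csv") %in% list.files(dir)))
  back <- read_dataset(dir)
  expect_equal(nrow(back$records), nrow(rec))
  for (i in c(1, 10, 36)) {
    orig <- imgs[[i]]
    match_row <- which(manifest$boar_id == orig$boar_id &
                         manifest$angle == orig$angle)[
                           sum(manifest$boar_id[1:i] == orig$boar_id &
                                 manifest$angle[1:i] == orig$angle)]
    expect_equal(back$images[[match_row]]$pixels, orig$pixels,
                 ignore_attr = TRUE)
  }
  expect_error(write_dataset(pop, rec[0, ], imgs, dir), "at least one")
  bad_imgs <- imgs
  bad_imgs[[1]]$boar_id <- "ZZZZ"
  expect_error(write_dataset(pop, rec, bad_imgs, dir), "not present")
})

test_that("planted classes are recovered by the labeling rule on simulated boars", {
  pop <- simulate_population(200, seed = 31)
  rec <- simulate_records(pop, seed = 32)
  labs <- label_dataset(rec)
  agree <- mean(labs$label[match(pop$boar_id, labs$boar_id)] == pop$true_class)
  expect_gte(agree, 0.95)
})

test_that("experiment configs load from YAML with sensible defaults", {
  cfg <- load_experiment_config(
    system.file("extdata", "experiment.yaml", package = "boarscan"))
  expect_equal(cfg$n_boars, 60)
  expect_equal(cfg$threshold, 0.3)
  expect_s3_class(cfg$pipeline, "aug_pipeline")
  expect_equal(cfg$pipeline$group, "comprehensive")
  expect_equal(cfg$params$shift_high, 6)
  expect_error(load_experiment_config("no/such/file.yaml"), "not found")
})
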