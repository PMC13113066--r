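#' The 2x2x2x2 configuration grid
#'
#' All 16 combinations of the four study factors. Level 0 (the reference
#' level of the treatment coding) is listed first for each factor: full
#' image, horizontal view, morphological augmentation, medium model.
#'
#' @return tibble with 16 rows and columns `region`, `angle`, `augmentation`,
#'   `model`.
#' @export
scan_configs <- function() {
  g <- expand.grid(model = c("medium", "small"),
                   augmentation = c("morphological", "comprehensive"),
                   angle = c("horizontal", "vertical"),
                   region = c("full", "cropped"),
                   stringsAsFactors = FALSE)
  tibble::as_tibble(g[, c("region", "angle", "augmentation", "model")])
}

#' Run the full factor grid over repeated seeds
#'
#' Evaluates all 16 configurations for `n_runs` independent runs. Each run
#' re-draws the By-ID split; within a run the augmentation stream depends
#' only on the preprocessing factors (region, angle, augmentation group), so
#' the two capacity tiers of a configuration see identical augmented images
#' and augmented features are computed once per preprocessing arm.
#'
#' @param dataset a [simulate_dataset()] object.
#' @param n_runs number of independent runs (>= 1).
#' @param base_seed integer; run `r` uses the deterministic child seed of
#'   `(base_seed, r)`.
#' @param evaluator function with the signature of [evaluate_config()];
#'   replace it to plug in an external classifier or a response simulator.
#' @param previous optional earlier result table; (config, run) rows already
#'   present are carried over instead of recomputed, making long grids
#'   resumable.
#' @param threshold aggregation threshold.
#' @param lambda ridge penalty for the baseline classifier.
#' @return tibble of `n_runs * 16` rows: factor columns, `run`, `seed`,
#'   `precision`, `recall`, `f1` (plus confusion counts from the default
#'   evaluator).
#' @export
run_grid <- function(dataset, n_runs = 10, base_seed = 1,
                     evaluator = evaluate_config, previous = NULL,
                     threshold = 0.3, lambda = 0.01) {
  if (n_runs < 1) stop("`n_runs` must be at least 1")
  configs <- scan_configs()
  rows <- list()
  cache <- new.env(parent = emptyenv())
  labels <- NULL
  for (r in seq_len(n_runs)) {
    run_seed <- child_seed(base_seed, 101L, r)
    split <- NULL
    for (i in seq_len(nrow(configs))) {
      cfg <- configs[i, ]
      if (!is.null(previous)) {
        hit <- previous[previous$run == r & previous$region == cfg$region &
                        previous$angle == cfg$angle &
                        previous$augmentation == cfg$augmentation &
                        previous$model == cfg$model, , drop = FALSE]
        if (nrow(hit) == 1) {
          rows[[length(rows) + 1L]] <- hit
          next
        }
      }
      if (is.null(split) && identical(evaluator, evaluate_config)) {
        if (is.null(labels)) labels <- label_dataset(dataset$records)
        split <- by_id_kfold(labels$boar_id, k = 5, seed = run_seed)
      }
      aug_seed <- child_seed(run_seed, 3L,
                             match(cfg$region, c("full", "cropped")),
                             match(cfg$angle, c("horizontal", "vertical")),
                             match(cfg$augmentation,
                                   c("morphological", "comprehensive")))
      res <- evaluator(dataset, cfg, split = split, seed = run_seed,
                       threshold = threshold, aug_seed = aug_seed,
                       lambda = lambda, cache = cache, labels = labels)
      res$run <- r
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  tibble::as_tibble(out)
}

#' Simulate a run-result table with planted factor effects
#'
#' Generates the 16-configuration grid over `n_runs` runs directly from a
#' linear model on the treatment-coded factors, without touching images.
#' Used to test the grid-to-ANOVA chain against known truth (e.g. a planted
#' cropped-region recall penalty).
#'
#' @param n_runs runs per configuration.
#' @param effects named list per metric (`precision`, `recall`, `f1`), each a
#'   named numeric vector of level-1 effects: `region` (cropped), `angle`
#'   (vertical), `augmentation` (comprehensive), `model` (small), and
#'   optionally interactions named like `"region:angle"`.
#' @param baseline named numeric vector of metric intercepts.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @return tibble shaped like a [run_grid()] result (clamped to `[0, 1]`).
#' @export
simulate_run_results <- function(n_runs = 10,
                                 effects = list(recall = c(region = -0.2)),
                                 baseline = c(precision = 0.8, recall = 0.85,
                                              f1 = 0.82),
                                 noise_sd = 0.02, seed = 1) {
  configs <- scan_configs()
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
      cbind(configs, run = r)
    }))
    lev1 <- cbind(region = as.numeric(out$region == "cropped"),
                  angle = as.numeric(out$angle == "vertical"),
                  augmentation = as.numeric(out$augmentation == "comprehensive"),
                  model = as.numeric(out$model == "small"))
    for (metric in c("precision", "recall", "f1")) {
      mu <- rep(baseline[[metric]], nrow(out))
      eff <- effects[[metric]]
      for (nm in names(eff)) {
        parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
        term <- rep(1, nrow(out))
        for (p in parts) term <- term * lev1[, p]
        mu <- mu + eff[[nm]] * term
      }
      out[[metric]] <- pmin(1, pmax(0, mu + rnorm(nrow(out), 0, noise_sd)))
    }
    out$seed <- seed
    tibble::as_tibble(out)
  })
}
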