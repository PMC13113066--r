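#' Aggregate image probabilities into one decision per boar
#'
#' Decision-level (aggregated) inference: the positive-class probabilities of
#' all test images of a boar are averaged and compared against a fixed
#' threshold (default 0.3; the boundary uses `>=`, so a mean of exactly 0.3
#' is predicted high-quality).
#'
#' @param probabilities numeric vector of image-level probabilities in
#'   `[0, 1]`.
#' @param boar_ids character vector aligned with `probabilities`.
#' @param threshold decision threshold (default 0.3).
#' @return tibble with one row per boar: `boar_id`, `mean_probability`,
#'   `predicted_label`, `n_images`.
#' @export
aggregate_predictions <- function(probabilities, boar_ids, threshold = 0.3) {
  if (length(probabilities) == 0) {
    stop("`probabilities` must contain at least one value")
  }
  if (length(probabilities) != length(boar_ids)) {
    stop("`probabilities` and `boar_ids` must be aligned")
  }
  if (any(is.na(probabilities)) || any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  ids <- sort(unique(as.character(boar_ids)))
  mp <- unname(vapply(ids, function(id) mean(probabilities[boar_ids == id]),
                      numeric(1)))
  n <- unname(vapply(ids, function(id) sum(boar_ids == id), integer(1)))
  tibble::tibble(
    boar_id = ids,
    mean_probability = mp,
    predicted_label = ifelse(mp >= threshold, "high_quality", "underperforming"),
    n_images = n
  )
}

#' Precision, recall and F1 at the boar level
#'
#' High-quality boars are the positive class. `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, `F1 = 2 * precision * recall /
#' (precision + recall)`; all three are 0 when their denominator is 0 (in
#' particular F1 = 0 when TP = 0).
#'
#' @param predictions tibble from [aggregate_predictions()] (columns
#'   `boar_id`, `predicted_label`).
#' @param truth tibble with columns `boar_id` and `label` (or `true_class`).
#' @return object of class `boar_metrics`: list with `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`.
#' @export
score_predictions <- function(predictions, truth) {
  lab_col <- if ("label" %in% names(truth)) "label" else "true_class"
  if (!all(predictions$boar_id %in% truth$boar_id)) {
    stop("`truth` is missing some predicted boar ids")
  }
  y <- truth[[lab_col]][match(predictions$boar_id, truth$boar_id)]
  pos_true <- y == "high_quality"
  pos_pred <- predictions$predicted_label == "high_quality"
  tp <- sum(pos_true & pos_pred)
  fp <- sum(!pos_true & pos_pred)
  fn <- sum(pos_true & !pos_pred)
  tn <- sum(!pos_true & !pos_pred)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (tp > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
                 recall = recall, f1 = f1),
            class = "boar_metrics")
}

#' @exportS3Method base::print
print.boar_metrics <- function(x, ...) {
  cat(sprintf("<boar_metrics> TP %d FP %d FN %d TN %d | precision %.4f recall %.4f F1 %.4f\n",
              x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1))
  invisible(x)
}

# internal: features for all images of one angle/region, optionally augmented.
# cached per (angle, region, aug-group, aug_seed) so both capacity tiers and
# all folds of one configuration see identical augmented copies.
prep_features <- function(dataset, angle, region, augmentation = NULL,
                          aug_seed = 1, cache = NULL) {
  key <- paste(angle, region, augmentation %||% "clean",
               if (is.null(augmentation)) "" else aug_seed, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  sel <- vapply(dataset$images, function(im) im$angle == angle, logical(1))
  if (!any(sel)) stop("dataset contains no images at angle: ", angle)
  imgs <- dataset$images[sel]
  if (region == "cropped") imgs <- lapply(imgs, crop_region)
  if (!is.null(augmentation)) {
    # training sees the originals plus one augmented copy of each image, so
    # the feature distribution stays anchored to the evaluation images
    pipeline <- build_pipeline(augmentation)
    aug <- with_seed(child_seed(aug_seed, 37L), {
      lapply(imgs, augment_core, pipeline = pipeline)
    })
    imgs <- c(imgs, aug)
  }
  out <- list(
    boar_id = vapply(imgs, function(im) im$boar_id, character(1)),
    x = feature_matrix(imgs)
  )
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Evaluate one scanning configuration
#'
#' Runs the full pipeline for one cell of the factor grid: filters images by
#' probe angle, crops if the region factor says so, trains the configured
#' capacity tier on augmented training images within each By-ID fold,
#' predicts the clean test images, pools test boars across the k folds (each
#' boar is tested exactly once), aggregates image probabilities per boar at
#' the decision threshold, and scores against the rule-derived boar labels.
#'
#' @param dataset a [simulate_dataset()] object (or any list with `records`
#'   and `images` in the same shape).
#' @param config one-row data frame or list with `region`
#'   (`"full"`/`"cropped"`), `angle` (`"horizontal"`/`"vertical"`),
#'   `augmentation` (`"morphological"`/`"comprehensive"`) and `model`
#'   (`"medium"`/`"small"`).
#' @param split optional [by_id_kfold()] assignment; derived from `seed` when
#'   omitted.
#' @param seed integer seed (drives the split and, by default, augmentation).
#' @param threshold aggregation threshold (default 0.3).
#' @param aug_seed seed for the augmentation draws; defaults to `seed`.
#'   Shared across model tiers by [run_grid()].
#' @param lambda ridge penalty passed to [classifier_spec()].
#' @param cache optional environment used to reuse augmented features across
#'   configurations.
#' @param labels optional precomputed [label_dataset()] table (derived from
#'   `dataset$records` when omitted).
#' @return one-row tibble: the four factor columns, `seed`, `precision`,
#'   `recall`, `f1` plus confusion counts.
#' @export
evaluate_config <- function(dataset, config, split = NULL, seed = 1,
                            threshold = 0.3, aug_seed = seed, lambda = 0.01,
                            cache = NULL, labels = NULL) {
  config <- as.list(config)
  if (is.null(labels)) labels <- label_dataset(dataset$records)
  if (is.null(split)) {
    split <- by_id_kfold(labels$boar_id, k = 5, seed = seed)
  }
  train_feats <- prep_features(dataset, config$angle, config$region,
                               augmentation = config$augmentation,
                               aug_seed = aug_seed, cache = cache)
  test_feats <- prep_features(dataset, config$angle, config$region,
                              cache = cache)
  spec <- classifier_spec(config$model, lambda = lambda, seed = seed)
  k <- attr(split, "k")
  probs <- list()
  ids <- list()
  for (f in seq_len(k) - 1L) {
    roles <- fold_roles(split, f)
    tr <- train_feats$boar_id %in% roles$train
    te <- test_feats$boar_id %in% roles$test
    y <- labels$label[match(train_feats$boar_id[tr], labels$boar_id)]
    model <- train_on_features(spec, train_feats$x[tr, , drop = FALSE], y)
    probs[[f + 1L]] <- predict_proba(model, test_feats$x[te, , drop = FALSE])
    ids[[f + 1L]] <- test_feats$boar_id[te]
  }
  agg <- aggregate_predictions(unlist(probs), unlist(ids), threshold)
  m <- score_predictions(agg, labels)
  tibble::tibble(region = config$region, angle = config$angle,
                 augmentation = config$augmentation, model = config$model,
                 seed = seed, precision = m$precision, recall = m$recall,
                 f1 = m$f1, tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn)
}
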