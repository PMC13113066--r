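#' Subject-level (By-ID) k-fold split
#'
#' Partitions boar ids into k folds so that all images of one boar fall into
#' exactly one fold. For fold configuration `f`, fold `f` is the test set,
#' the next fold is the validation set, and the remaining folds train -- so a
#' boar never appears in more than one role within a configuration and every
#' boar is tested exactly once across the k configurations.
#'
#' @param boar_ids character vector of distinct animal identifiers.
#' @param k number of folds (default 5, the 80/20 split).
#' @param seed integer seed.
#' @return object of class `split_assignment`: tibble with columns `boar_id`
#'   and `fold` (0-based fold index).
#' @export
by_id_kfold <- function(boar_ids, k = 5, seed = 1) {
  boar_ids <- unique(as.character(boar_ids))
  if (k < 2) stop("`k` must be at least 2")
  if (length(boar_ids) < k) stop("need at least `k` distinct boar ids")
  with_seed(seed, {
    shuffled <- sample(boar_ids)
    fold <- rep(seq_len(k) - 1L, length.out = length(shuffled))
    out <- tibble::tibble(boar_id = shuffled, fold = fold)
    out <- out[order(out$boar_id), ]
    class(out) <- c("split_assignment", class(out))
    attr(out, "k") <- as.integer(k)
    out
  })
}

#' Train/validation/test ids for one fold configuration
#'
#' @param split a [by_id_kfold()] assignment.
#' @param fold 0-based test fold index.
#' @return list with character vectors `train`, `validation`, `test`.
#' @export
fold_roles <- function(split, fold) {
  k <- attr(split, "k")
  if (fold < 0 || fold >= k) stop("`fold` must lie in [0, k-1]")
  test <- split$boar_id[split$fold == fold]
  validation <- split$boar_id[split$fold == (fold + 1) %% k]
  train <- split$boar_id[!split$fold %in% c(fold, (fold + 1) %% k)]
  list(train = train, validation = validation, test = test)
}

#' Feature names in extraction order
#' @return character vector of the 14 feature names.
#' @export
feature_names <- function() {
  c("mean", "variance", paste0("q", seq(10, 90, 10)),
    "central_mean", "gradient_energy", "row_profile_max")
}

#' Extract a fixed-length feature vector from an image
#'
#' Features, in order: intensity mean; variance; the nine deciles q10--q90 of
#' the pixel histogram; the central-region mean (the tubule window, see
#' [central_region()]); gradient energy (mean squared forward difference over
#' both axes); and the row-profile maximum (maximum over rows of the row mean
#' intensity -- a band detector). This summary stands behind the pluggable
#' classifier contract in place of a learned representation.
#'
#' @param image a [usg_image()] or pixel matrix.
#' @return named numeric vector of length 14.
#' @export
extract_features <- function(image) {
  px <- as_pixels(image)
  rows <- central_region(nrow(px))
  cols <- central_region(ncol(px))
  # compiled single pass for 8-bit integer images; generic path otherwise
  out <- cpp_features(px, rows[1], rows[length(rows)], cols[1],
                      cols[length(cols)])
  if (is.null(out)) {
    v <- as.numeric(px)
    n <- length(v)
    s <- sort(v)
    deciles <- s[pmax(1L, ceiling(n * seq(0.1, 0.9, 0.1)))]
    m <- sum(v) / n
    dx <- px[, -1, drop = FALSE] - px[, -ncol(px), drop = FALSE]
    dy <- px[-1, , drop = FALSE] - px[-nrow(px), , drop = FALSE]
    grad <- (sum(dx^2) + sum(dy^2)) / (length(dx) + length(dy))
    out <- c(m, sum((v - m)^2) / n, deciles, central_mean(px),
             grad, max(rowMeans(px)))
  }
  names(out) <- feature_names()
  out
}

#' Feature matrix for a list of images
#'
#' @param images list of images.
#' @return numeric matrix, one row per image, columns per [feature_names()].
#' @export
feature_matrix <- function(images) {
  t(vapply(images, extract_features, numeric(14)))
}

#' Classifier specification
#'
#' Two capacity tiers stand in for the small/medium network contrast: the
#' `small` tier uses histogram features only (mean, variance, deciles; 11
#' parameters), the `medium` tier uses the full 14-feature set plus all
#' pairwise interactions among the eight core features (mean, variance, q10,
#' q50, q90, central mean, gradient energy, row-profile max; 42 parameters),
#' so the medium tier strictly dominates the small tier in capacity. Both are
#' ridge-regularized logistic models fit by iterative likelihood maximization
#' with class-balanced weights.
#'
#' @param capacity `"small"` or `"medium"`.
#' @param lambda ridge penalty (default 0.01).
#' @param seed integer seed carried along with the specification (the fit
#'   itself is deterministic).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(capacity = c("small", "medium"), lambda = 0.01,
                            seed = 1) {
  capacity <- match.arg(capacity)
  structure(list(capacity = capacity, lambda = lambda, seed = seed),
            class = "classifier_spec")
}

# internal: expand a base feature matrix according to the capacity tier
tier_features <- function(x, capacity) {
  fn <- feature_names()
  if (capacity == "small") {
    return(x[, c("mean", "variance", paste0("q", seq(10, 90, 10))),
             drop = FALSE])
  }
  core <- c("mean", "variance", "q10", "q50", "q90", "central_mean",
            "gradient_energy", "row_profile_max")
  pairs <- utils::combn(core, 2)
  inter <- matrix(0, nrow(x), ncol(pairs))
  colnames(inter) <- paste(pairs[1, ], pairs[2, ], sep = ":")
  for (j in seq_len(ncol(pairs))) {
    inter[, j] <- x[, pairs[1, j]] * x[, pairs[2, j]]
  }
  cbind(x[, fn, drop = FALSE], inter)
}

# internal: fit from a precomputed base feature matrix
train_on_features <- function(spec, x, labels) {
  y <- as.integer(labels == "high_quality")
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class; cannot fit a classifier")
  }
  xt <- tier_features(x, spec$capacity)
  w <- ifelse(y == 1, 0.5 / mean(y == 1), 0.5 / mean(y == 0))
  fit <- glmnet::glmnet(xt, y, family = "binomial", alpha = 0,
                        lambda = spec$lambda, weights = w, standardize = TRUE)
  structure(list(spec = spec, fit = fit, features = colnames(xt)),
            class = "boar_classifier")
}

#' Train the baseline image classifier
#'
#' Extracts features from (optionally augmented) training images and fits a
#' class-weighted ridge logistic regression. The positive class is
#' `high_quality`. Any external classifier honoring the same
#' train/[predict_proba()] contract can replace this baseline in
#' [evaluate_config()] and [run_grid()].
#'
#' @param spec a [classifier_spec()].
#' @param images list of training images.
#' @param labels character vector (`"high_quality"` / `"underperforming"`),
#'   one per image.
#' @param pipeline optional [build_pipeline()]; when supplied, one augmented
#'   copy of each training image is appended to the originals (evaluation
#'   images are never augmented).
#' @param seed integer seed for the augmentation draws.
#' @return object of class `boar_classifier`.
#' @export
train_classifier <- function(spec, images, labels, pipeline = NULL, seed = 1) {
  stopifnot(length(images) == length(labels))
  if (!is.null(pipeline)) {
    aug <- with_seed(child_seed(seed, 29L), {
      lapply(images, augment_core, pipeline = pipeline)
    })
    images <- c(images, aug)
    labels <- c(labels, labels)
  }
  train_on_features(spec, feature_matrix(images), labels)
}

#' @exportS3Method base::print
print.boar_classifier <- function(x, ...) {
  cat(sprintf("<boar_classifier> %s tier, %d features, lambda = %g\n",
              x$spec$capacity, length(x$features), x$spec$lambda))
  invisible(x)
}

#' Save / load a trained classifier as JSON
#'
#' The on-disk format is a plain JSON object with the capacity tier, the
#' ridge penalty, the intercept and the named coefficient vector in feature
#' order, so external tools can inspect or re-implement the decision
#' function.
#'
#' @param model a trained [train_classifier()] model.
#' @param path output (input) JSON path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns a `boar_classifier` usable with [predict_proba()].
#' @export
save_classifier <- function(model, path) {
  if (!inherits(model, "boar_classifier")) stop("`model` must be a boar_classifier")
  beta <- as.numeric(coef(model$fit))
  obj <- list(capacity = model$spec$capacity, lambda = model$spec$lambda,
              intercept = beta[1],
              coefficients = as.list(setNames(beta[-1], model$features)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(spec = classifier_spec(obj$capacity, lambda = obj$lambda),
                 fit = NULL, intercept = obj$intercept,
                 weights = unlist(obj$coefficients),
                 features = names(obj$coefficients)),
            class = "boar_classifier")
}

#' Positive-class probability for images
#'
#' @param model a trained [train_classifier()] model.
#' @param images a single image or list of images (or a precomputed base
#'   feature matrix).
#' @return numeric vector of probabilities in `[0, 1]` that each image comes
#'   from a high-quality boar; monotone in the model's linear score
#'   (logistic link: score 0 maps to 0.5).
#' @export
predict_proba <- function(model, images) {
  if (!inherits(model, "boar_classifier")) {
    stop("`model` must be a trained boar_classifier")
  }
  is_feature_matrix <- is.matrix(images) && !is.null(colnames(images)) &&
    all(feature_names() %in% colnames(images))
  x <- if (is_feature_matrix) images
       else if (inherits(images, "usg_image") || is.matrix(images)) {
         feature_matrix(list(images))
       } else feature_matrix(images)
  xt <- tier_features(x, model$spec$capacity)
  if (!is.null(model$fit)) {
    return(as.numeric(predict(model$fit, newx = xt, type = "response")))
  }
  score <- model$intercept + drop(xt[, model$features, drop = FALSE] %*%
                                    model$weights)
  1 / (1 + exp(-score))
}
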