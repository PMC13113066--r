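#' Crop an image to its central region
#'
#' Keeps the central `fraction` of each dimension -- the seminiferous-tubule
#' region -- excluding the simulated bright band/blob, which the generator
#' places outside this window. Mirrors the "cropped section" arm of the
#' region factor.
#'
#' @param image a [usg_image()] with `region == "full"`.
#' @param fraction fraction of each dimension retained (default 0.5).
#' @return a cropped [usg_image()] (`region = "cropped"`).
#' @export
crop_region <- function(image, fraction = 0.5) {
  if (!inherits(image, "usg_image")) stop("`image` must be a usg_image")
  if (image$region == "cropped") stop("image is already cropped")
  px <- image$pixels
  out <- px[central_region(nrow(px), fraction),
            central_region(ncol(px), fraction), drop = FALSE]
  usg_image(out, boar_id = image$boar_id, angle = image$angle,
            region = "cropped", structure = NULL)
}

# ---- geometric machinery -------------------------------------------------

mat_translate <- function(tx, ty) matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3, 3)
mat_scale <- function(sx, sy = sx) diag(c(sx, sy, 1))
mat_rotate <- function(degrees) {
  th <- degrees * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# conjugate a transform so it acts about the image center
about_center <- function(m, h, w) {
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  mat_translate(cx, cy) %*% m %*% mat_translate(-cx, -cy)
}

# homography (forward) mapping src (x, y) points onto dst points; 4 pairs
homography_from_points <- function(src, dst) {
  a <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; X <- dst[i, 1]; Y <- dst[i, 2]
    a[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -x * X, -y * X)
    a[2 * i, ]     <- c(0, 0, 0, x, y, 1, -x * Y, -y * Y)
    b[2 * i - 1] <- X
    b[2 * i] <- Y
  }
  h <- solve(a, b)
  matrix(c(h[1], h[4], h[7], h[2], h[5], h[8], h[3], h[6], 1), 3, 3)
}

# inverse-map warp with bilinear interpolation and edge-clamped coordinates
# (replicates border pixels, which keeps the intensity mean approximately
# unchanged on stationary textures). `forward` maps input (x, y, 1) to
# output; the per-pixel resampling loop is compiled (src/warp.cpp).
warp_pixels <- function(px, forward) {
  cpp_warp(px, solve(forward))
}

# clamp to the 8-bit range in place; faster than pmin/pmax on large images
clamp255 <- function(px) {
  px[px < 0] <- 0
  px[px > 255] <- 255
  px
}

# forward 3x3 matrix for one morphological operator; draws any unspecified
# parameters from the current RNG stream
morph_matrix <- function(op, h, w, params = list(), magnitudes = list()) {
  mag <- utils::modifyList(list(rotation = 15, perspective = 0.2,
                                zoom_max = 1.5, affine_rotation = 10,
                                affine_translate = 5, affine_scale = 0.1,
                                affine_shear = 0.1), magnitudes)
  switch(op,
    hflip = about_center(mat_scale(-1, 1), h, w),
    vflip = about_center(mat_scale(1, -1), h, w),
    rotation = {
      deg <- params$degrees %||% runif(1, -mag$rotation, mag$rotation)
      about_center(mat_rotate(deg), h, w)
    },
    zoom_out = {
      s <- params$scale %||% runif(1, 1, mag$zoom_max)
      about_center(mat_scale(1 / s), h, w)
    },
    affine = {
      deg <- params$degrees %||% runif(1, -mag$affine_rotation, mag$affine_rotation)
      tx <- params$tx %||% runif(1, -mag$affine_translate, mag$affine_translate)
      ty <- params$ty %||% runif(1, -mag$affine_translate, mag$affine_translate)
      sc <- params$scale %||% runif(1, 1 - mag$affine_scale, 1 + mag$affine_scale)
      sh <- params$shear %||% runif(1, -mag$affine_shear, mag$affine_shear)
      shear <- matrix(c(1, 0, 0, sh, 1, 0, 0, 0, 1), 3, 3)
      about_center(mat_translate(tx, ty) %*% mat_rotate(deg) %*%
                     shear %*% mat_scale(sc), h, w)
    },
    perspective = {
      d <- params$distortion %||% mag$perspective
      src <- rbind(c(1, 1), c(w, 1), c(w, h), c(1, h))
      jit <- matrix(runif(8, 0, d), 4, 2) * cbind(c(w, -w, -w, w) / 2,
                                                  c(h, h, -h, -h) / 2)
      homography_from_points(src, src + jit)
    },
    stop("unknown morphological operator: ", op)
  )
}

# ---- brightness operators ------------------------------------------------

brightness_apply <- function(px, op, params = list(), magnitudes = list()) {
  mag <- utils::modifyList(list(jitter_min = 0.6, jitter_max = 1.4,
                                solarize_threshold = 128, posterize_bits = 4),
                           magnitudes)
  out <- switch(op,
    jitter = {
      b <- params$brightness %||% runif(1, mag$jitter_min, mag$jitter_max)
      cf <- params$contrast %||% runif(1, mag$jitter_min, mag$jitter_max)
      v <- px * b
      (v - mean(v)) * cf + mean(v)
    },
    solarize = {
      thr <- params$threshold %||% mag$solarize_threshold
      {
        out <- px
        hi <- px >= thr
        out[hi] <- 255 - px[hi]
        out
      }
    },
    autocontrast = {
      lo <- min(px); hi <- max(px)
      if (hi > lo) (px - lo) * (255 / (hi - lo)) else px
    },
    posterize = {
      bits <- params$bits %||% mag$posterize_bits
      step <- 2^(8 - bits)
      floor(round(px) / step) * step
    },
    equalize = equalize_pixels(px),
    invert = 255 - px,
    stop("unknown brightness operator: ", op)
  )
  if (op == "jitter") out <- clamp255(out)  # the only op that can leave range
  out <- round(out)
  if (!is.matrix(out)) out <- matrix(out, nrow(px), ncol(px))
  out
}

# classic 8-bit histogram equalization:
# lut(v) = round(255 * (cdf(v) - cdf_min) / (n - cdf_min))
equalize_pixels <- function(px) {
  v <- as.integer(round(px))
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(v)
  if (n == cdf_min) return(matrix(as.numeric(v), nrow(px), ncol(px)))
  lut <- round(255 * (cdf - cdf_min) / (n - cdf_min))
  matrix(as.numeric(lut[v + 1L]), nrow(px), ncol(px))
}

morphological_ops <- c("perspective", "rotation", "hflip", "vflip",
                       "zoom_out", "affine")
brightness_ops <- c("jitter", "solarize", "autocontrast", "posterize",
                    "equalize", "invert")

# internal: rebuild a usg_image with new pixels
with_pixels <- function(image, px) {
  if (inherits(image, "usg_image")) {
    image$pixels <- px
    image
  } else {
    px
  }
}

#' Apply one randomly chosen morphological (geometric) operator
#'
#' Operators: perspective, rotation, horizontal flip, vertical flip, zoom out,
#' random affine. Output dimensions are preserved; out-of-frame samples are
#' edge-replicated, so the intensity histogram is approximately unchanged
#' (exactly unchanged for flips).
#'
#' @param image a [usg_image()] or bare pixel matrix.
#' @param seed integer seed.
#' @param op force a specific operator instead of a random choice.
#' @param params fixed operator parameters (e.g. `list(degrees = 15)` for
#'   `op = "rotation"`); unspecified parameters are drawn randomly.
#' @param magnitudes magnitude overrides, see [build_pipeline()].
#' @return the transformed image (same class as the input).
#' @export
apply_morphological <- function(image, seed = 1, op = NULL, params = list(),
                                magnitudes = list()) {
  px <- as_pixels(image)
  with_seed(seed, {
    if (is.null(op)) op <- sample(morphological_ops, 1)
    m <- morph_matrix(op, nrow(px), ncol(px), params, magnitudes)
    out <- round(clamp255(warp_pixels(px, m)))
    with_pixels(image, out)
  })
}

#' Apply one randomly chosen brightness operator
#'
#' Operators: color jitter (brightness/contrast scaling -- on grayscale these
#' are the only components of color jitter), solarize, autocontrast,
#' posterize, equalize, invert.
#'
#' @inheritParams apply_morphological
#' @export
apply_brightness <- function(image, seed = 1, op = NULL, params = list(),
                             magnitudes = list()) {
  px <- as_pixels(image)
  with_seed(seed, {
    if (is.null(op)) op <- sample(brightness_ops, 1)
    with_pixels(image, brightness_apply(px, op, params, magnitudes))
  })
}

#' Build an augmentation pipeline
#'
#' The `morphological` group applies only geometric operators; the
#' `comprehensive` group additionally applies brightness operators, which is
#' the mechanism that perturbs the echogenicity signal. Each operator fires
#' independently with its group probability; all geometric operators that fire
#' are composed into a single homography so one interpolation pass is used
#' per image.
#'
#' @param group `"morphological"` or `"comprehensive"`.
#' @param p_morphological,p_brightness per-operator firing probabilities
#'   (default 0.5).
#' @param magnitudes named list of magnitude overrides: `rotation` (max
#'   degrees, default 15), `perspective` (max distortion fraction, 0.2),
#'   `zoom_max` (1.5), `affine_rotation` (10), `affine_translate` (5 px),
#'   `affine_scale` (0.1), `affine_shear` (0.1), `jitter_min`/`jitter_max`
#'   (brightness/contrast factor range, 0.6--1.4), `solarize_threshold` (128),
#'   `posterize_bits` (4).
#' @return object of class `aug_pipeline`.
#' @export
build_pipeline <- function(group = c("morphological", "comprehensive"),
                           p_morphological = 0.5, p_brightness = 0.5,
                           magnitudes = list()) {
  if (is.character(group) && length(group) == 1 &&
      !group %in% c("morphological", "comprehensive")) {
    stop("unknown augmentation group: ", group)
  }
  group <- match.arg(group)
  structure(list(group = group,
                 p_morphological = p_morphological,
                 p_brightness = p_brightness,
                 magnitudes = magnitudes),
            class = "aug_pipeline")
}

#' @exportS3Method base::print
print.aug_pipeline <- function(x, ...) {
  cat(sprintf("<aug_pipeline> %s (p_morph = %g%s)\n", x$group,
              x$p_morphological,
              if (x$group == "comprehensive")
                sprintf(", p_bright = %g", x$p_brightness) else ""))
  invisible(x)
}

#' Augment one image with a pipeline
#'
#' Geometric operators fire first (composed into one warp), then -- for the
#' comprehensive group -- brightness operators fire in a fixed order. With a
#' fixed seed the output is bit-identical across calls. Augmentation is a
#' training-time operation; evaluation images are never augmented.
#'
#' @param image a [usg_image()] or pixel matrix.
#' @param pipeline an [build_pipeline()] object.
#' @param seed integer seed.
#' @return the augmented image.
#' @export
augment_image <- function(image, pipeline, seed = 1) {
  if (!inherits(pipeline, "aug_pipeline")) stop("`pipeline` must be an aug_pipeline")
  with_seed(seed, augment_core(image, pipeline))
}

# unseeded augmentation core, drawing from the current RNG stream; used by
# augment_image and by the batch path in prep_features
augment_core <- function(image, pipeline) {
  px <- as_pixels(image)
  h <- nrow(px); w <- ncol(px)
  fire_m <- runif(length(morphological_ops)) < pipeline$p_morphological
  m <- diag(3)
  any_geom <- FALSE
  for (i in seq_along(morphological_ops)) {
    if (fire_m[i]) {
      m <- morph_matrix(morphological_ops[i], h, w,
                        magnitudes = pipeline$magnitudes) %*% m
      any_geom <- TRUE
    }
  }
  if (any_geom) px <- warp_pixels(px, m)   # bilinear output stays in range
  if (pipeline$group == "comprehensive") {
    fire_b <- runif(length(brightness_ops)) < pipeline$p_brightness
    for (i in seq_along(brightness_ops)) {
      if (fire_b[i]) {
        px <- brightness_apply(px, brightness_ops[i],
                               magnitudes = pipeline$magnitudes)
      }
    }
  }
  with_pixels(image, round(px))
}
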