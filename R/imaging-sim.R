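#' Ultrasound-like image objects
#'
#' A `usg_image` is a list with fields `pixels` (H x W numeric matrix of 8-bit
#' intensities in `[0, 255]`), `boar_id`, `angle` (`"horizontal"` or
#' `"vertical"`), `region` (`"full"` or `"cropped"`) and `structure`, a small
#' list describing where the simulated bright anatomy was planted
#' (`type = "band"` with `rows`, or `type = "blob"` with `center` and
#' `radius`; `NULL` after cropping).
#'
#' @param pixels numeric matrix with values in `[0, 255]`.
#' @param boar_id animal identifier.
#' @param angle probe orientation.
#' @param region `"full"` or `"cropped"`.
#' @param structure optional bright-structure descriptor.
#' @return object of class `usg_image`.
#' @export
usg_image <- function(pixels, boar_id = NA_character_,
                      angle = c("horizontal", "vertical"),
                      region = c("full", "cropped"), structure = NULL) {
  angle <- match.arg(angle)
  region <- match.arg(region)
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels <= 255))
  structure(list(pixels = pixels, boar_id = boar_id, angle = angle,
                 region = region, structure = structure),
            class = "usg_image")
}

#' @exportS3Method base::print
print.usg_image <- function(x, ...) {
  cat(sprintf("<usg_image> boar %s, %s view, %s, %dx%d, mean intensity %.1f\n",
              x$boar_id, x$angle, x$region, nrow(x$pixels), ncol(x$pixels),
              mean(x$pixels)))
  invisible(x)
}

# internal: accept a usg_image or a bare matrix
as_pixels <- function(image) {
  if (inherits(image, "usg_image")) image$pixels else as.matrix(image)
}

#' Index range of the central (tubule) region
#'
#' The central region is the middle `fraction` of each dimension; it is the
#' crop window of [crop_region()] and the region whose mean intensity carries
#' the echogenicity shift in [render_image()].
#'
#' @param n dimension length in pixels.
#' @param fraction fraction of the dimension retained (default 0.5).
#' @return integer index vector.
#' @export
central_region <- function(n, fraction = 0.5) {
  half <- floor(n * fraction / 2)
  mid <- floor(n / 2)
  seq.int(mid - half + 1L, mid + half)
}

# internal: mean intensity of the central region of a pixel matrix
central_mean <- function(px, fraction = 0.5) {
  mean(px[central_region(nrow(px), fraction), central_region(ncol(px), fraction)])
}

#' Render one B-mode-like testis image
#'
#' Produces an 8-bit grayscale image with multiplicative speckle texture
#' (exponentially distributed echo intensity, log-compressed -- the standard
#' B-mode caricature), a bright structure mimicking the rete testis (a
#' horizontal high-intensity band spanning the image in the vertical view; a
#' compact bright blob in the horizontal view; both placed outside the central
#' crop window), and a darker central seminiferous-tubule region whose mean
#' intensity is shifted by the boar's `echogenicity_shift`. The bright
#' structure's intensity is shifted by `band_gain * echogenicity_shift`, so
#' part of the class signal lives in anatomy that cropping removes. The whole
#' image is offset by the boar's class-independent `baseline_offset` plus a
#' small per-image jitter.
#'
#' @param profile one-row profile (needs `boar_id`, `echogenicity_shift`;
#'   `baseline_offset` optional, default 0).
#' @param angle `"horizontal"` or `"vertical"`.
#' @param size image side length in pixels (>= 32).
#' @param seed integer seed; identical seeds give bit-identical images.
#' @param band_gain multiplier applied to `echogenicity_shift` for the bright
#'   structure (default 2.5).
#' @param base_level,structure_level mean background / bright-structure
#'   intensity before shifts.
#' @param speckle_scale intensity scale of the log-compressed speckle.
#' @return a [usg_image()].
#' @export
render_image <- function(profile, angle = c("horizontal", "vertical"),
                         size = 96, seed = 1, band_gain = 2.5,
                         base_level = 62, structure_level = 150,
                         speckle_scale = 16) {
  angle <- match.arg(angle)
  if (size < 32) stop("`size` must be at least 32 pixels")
  profile <- as.list(profile)
  shift <- profile$echogenicity_shift %||% 0
  baseline <- profile$baseline_offset %||% 0
  with_seed(seed, {
    # log-compressed exponential speckle, centered so base_level is the mean
    e <- matrix(stats::rexp(size * size), size, size)
    speck <- log1p(2 * e)
    speck <- (speck - 0.92291) * speckle_scale  # E[log(1 + 2X)], X ~ Exp(1)
    px <- base_level + speck

    if (angle == "vertical") {
      # longitudinal section: darker central tubule window carrying the class
      # shift, surrounded by tunica/epididymis-level background, plus the
      # bright rete-testis band above the crop window
      rows <- central_region(size)
      cols <- central_region(size)
      px[rows, cols] <- px[rows, cols] - 7 + shift
      band_rows <- seq.int(max(1L, round(size * 0.08)), round(size * 0.20))
      px[band_rows, ] <- structure_level + band_gain * shift +
        speck[band_rows, ] * 0.8
      struct <- list(type = "band", rows = band_rows)
    } else {
      # transverse section: the field is dominated by tubule parenchyma, so
      # the whole image carries the class shift; the rete testis appears
      # only as a small bright point (with rete-level signal, like the band)
      px <- px - 7 + shift
      ctr <- c(round(size * 0.14), round(size * 0.5))
      radius <- max(4, round(size * 0.055))
      d2 <- outer(seq_len(size) - ctr[1], seq_len(size) - ctr[2],
                  function(a, b) a^2 + b^2)
      blob <- d2 <= radius^2
      px[blob] <- structure_level + band_gain * shift + speck[blob] * 0.8
      struct <- list(type = "blob", center = ctr, radius = radius)
    }

    # per-boar baseline plus per-image acquisition jitter; longitudinal scans
    # are taken one testis at a time with repeated probe repositioning, so
    # their per-image gain varies more (they are also more numerous, so the
    # jitter averages out at the boar level), while the few transverse scans
    # come from one stable probe placement across both testes
    px <- px + baseline + rnorm(1, 0, if (angle == "vertical") 12 else 3)
    px[px < 0] <- 0
    px[px > 255] <- 255
    px <- round(px)
    usg_image(px, boar_id = profile$boar_id %||% NA_character_,
              angle = angle, region = "full", structure = struct)
  })
}

#' Render all images for a population
#'
#' @param profiles profile table from [simulate_population()].
#' @param size image side length.
#' @param seed integer seed; each image gets a deterministic child seed.
#' @return list of [usg_image()] objects, `n_images_horizontal +
#'   n_images_vertical` per boar.
#' @export
render_images <- function(profiles, size = 96, seed = 1) {
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    nh <- p$n_images_horizontal
    nv <- p$n_images_vertical
    angles <- c(rep("horizontal", nh), rep("vertical", nv))
    for (k in seq_along(angles)) {
      out[[length(out) + 1L]] <-
        render_image(p, angle = angles[k], size = size,
                     seed = child_seed(seed, 13L, i, k))
    }
  }
  out
}

#' Simulate a complete dataset
#'
#' Convenience wrapper generating a population, its semen records and its
#' images in one deterministic step.
#'
#' @inheritParams simulate_population
#' @param image_size image side length in pixels.
#' @return object of class `boar_dataset`: list with `profiles`, `records`,
#'   `images`.
#' @export
simulate_dataset <- function(n_boars = 107, prevalence = 25 / 107, seed = 1,
                             image_size = 96,
                             params = generator_defaults(prevalence = prevalence)) {
  profiles <- simulate_population(n_boars, prevalence, seed = child_seed(seed, 1L),
                                  params = params)
  records <- simulate_records(profiles, seed = child_seed(seed, 2L))
  images <- render_images(profiles, size = image_size, seed = child_seed(seed, 3L))
  structure(list(profiles = profiles, records = records, images = images),
            class = "boar_dataset")
}

#' @exportS3Method base::print
print.boar_dataset <- function(x, ...) {
  cat(sprintf(paste0("<boar_dataset> %d boars (%d underperforming), ",
                     "%d semen records, %d images\n"),
              nrow(x$profiles),
              sum(x$profiles$true_class == "underperforming"),
              nrow(x$records), length(x$images)))
  invisible(x)
}

#' Write a dataset to disk
#'
#' Writes PNG images named `<boar_id>_<angle>_<k>.png`, the semen records as
#' `records.csv`, and a `manifest.csv` linking boar ids to image files and
#' true classes. The files round-trip losslessly through [read_dataset()].
#'
#' @param profiles,records,images components as produced by
#'   [simulate_dataset()] (consistent `boar_id`s required).
#' @param out_dir output directory (created if missing).
#' @return the manifest tibble, invisibly.
#' @export
write_dataset <- function(profiles, records, images, out_dir) {
  if (nrow(records) == 0) stop("`records` must contain at least one row")
  if (length(images) == 0) stop("`images` must contain at least one image")
  img_ids <- vapply(images, function(im) im$boar_id, character(1))
  known <- profiles$boar_id
  bad <- setdiff(unique(c(img_ids, records$boar_id)), known)
  if (length(bad) > 0) {
    stop("boar ids not present in `profiles`: ", paste(bad, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counter <- new.env(parent = emptyenv())
  rows <- lapply(images, function(im) {
    key <- paste(im$boar_id, im$angle, sep = "_")
    k <- (get0(key, envir = counter, ifnotfound = 0L)) + 1L
    assign(key, k, envir = counter)
    file <- sprintf("%s_%s_%02d.png", im$boar_id, im$angle, k)
    png::writePNG(im$pixels / 255, file.path(out_dir, file))
    tibble::tibble(boar_id = im$boar_id, angle = im$angle, k = k, file = file)
  })
  manifest <- do.call(rbind, rows)
  manifest$true_class <- profiles$true_class[match(manifest$boar_id, known)]
  write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `records` (tibble), `manifest` (tibble) and `images`
#'   (list of [usg_image()]; `structure` metadata is not persisted).
#' @export
read_dataset <- function(dir) {
  manifest <- tibble::as_tibble(read.csv(file.path(dir, "manifest.csv"),
                                         stringsAsFactors = FALSE))
  records <- tibble::as_tibble(read.csv(file.path(dir, "records.csv"),
                                        stringsAsFactors = FALSE))
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    px <- png::readPNG(file.path(dir, manifest$file[i]))
    if (length(dim(px)) == 3) px <- px[, , 1]
    usg_image(round(px * 255), boar_id = manifest$boar_id[i],
              angle = manifest$angle[i], region = "full")
  })
  list(records = records, manifest = manifest, images = images)
}
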