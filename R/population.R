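#' Default generator parameters
#'
#' Parameters controlling the synthetic boar population and semen-record
#' generator. Defaults emulate the study conditions: 107 boars with 2--49
#' collections each (median 30) at 5--14 day intervals starting around 200
#' days of age, 9--17 images per boar (median 12) split between horizontal and
#' vertical probe orientations, and roughly a quarter of boars
#' underperforming.
#'
#' Semen-metric distributions are truncated normals: passing records draw
#' total sperm count from N(60e9, 15e9) truncated at >= 20e9 and motility /
#' morphology from N(85, 5) truncated to (70, 100]; failing metrics draw
#' below their thresholds. Per collection, an underperforming boar fails >= 2
#' criteria with probability `bad_rate` and is technician-flagged trash with
#' probability `trash_rate`; records failing exactly one criterion
#' (intermediate) occur at half the bad rate.
#'
#' The image class signal is carried by echogenicity: high-quality boars get a
#' positive mean-intensity shift (default +6) and underperforming boars the
#' negative (default -6), applied to the central tubule region and, amplified
#' by `band_gain`, to the bright rete-testis structure. A per-boar baseline
#' intensity offset (`baseline_sd`, class-independent) models inter-animal
#' echogenicity variability and keeps classification non-trivial.
#'
#' @param prevalence probability that a boar is underperforming.
#' @param collections_mean,collections_sd mean/SD of the truncated-normal draw
#'   for collections per boar (rounded, truncated to `[2, 49]`).
#' @param shift_high,shift_under class means of the echogenicity shift
#'   (intensity units on the 0--255 scale).
#' @param shift_sd per-boar SD around the class shift mean.
#' @param baseline_sd SD of the class-independent per-boar intensity offset.
#' @param hq_bad_rate,hq_trash_rate per-collection bad / trash probabilities
#'   for high-quality boars.
#' @param up_bad_rate,up_trash_rate the same for underperforming boars.
#' @return named list of generator parameters.
#' @export
generator_defaults <- function(prevalence = 25 / 107,
                               collections_mean = 30, collections_sd = 9,
                               shift_high = 6, shift_under = -6, shift_sd = 1.5,
                               baseline_sd = 6,
                               hq_bad_rate = 0.01, hq_trash_rate = 0.005,
                               up_bad_rate = 0.30, up_trash_rate = 0.10) {
  list(prevalence = prevalence,
       collections_mean = collections_mean, collections_sd = collections_sd,
       shift_high = shift_high, shift_under = shift_under, shift_sd = shift_sd,
       baseline_sd = baseline_sd,
       hq_bad_rate = hq_bad_rate, hq_trash_rate = hq_trash_rate,
       up_bad_rate = up_bad_rate, up_trash_rate = up_trash_rate)
}

#' Simulate a boar population
#'
#' Draws boar profiles: the true quality class, the number of semen
#' collections, image counts per probe orientation, per-collection bad/trash
#' probabilities, and the echogenicity parameters used by [render_image()].
#'
#' Collections per boar are a rounded truncated normal on `[2, 49]` with
#' median 30. Total images per boar are `9 + Binomial(8, 3/8)` (range 9--17,
#' median 12), of which 4--5 are horizontal (the transverse view images both
#' testes at once, so fewer are needed) and the rest vertical.
#'
#' @param n_boars number of boars (>= 2 for a usable population; >= 1 accepted).
#' @param prevalence probability a boar is underperforming, in `[0, 1)` or 1.
#' @param seed integer seed; identical seeds give identical populations.
#' @param params generator parameters, see [generator_defaults()].
#' @return tibble with one row per boar: `boar_id`, `true_class`
#'   (`"high_quality"` / `"underperforming"`), `n_collections`,
#'   `n_images_horizontal`, `n_images_vertical`, `echogenicity_shift`,
#'   `baseline_offset`, `bad_rate`, `trash_rate`.
#' @export
simulate_population <- function(n_boars = 107,
                                prevalence = 25 / 107,
                                seed = 1,
                                params = generator_defaults(prevalence = prevalence)) {
  if (!is.numeric(n_boars) || length(n_boars) != 1 || n_boars < 1) {
    stop("`n_boars` must be a positive integer")
  }
  if (prevalence < 0 || prevalence > 1) stop("`prevalence` must lie in [0, 1]")
  n_boars <- as.integer(n_boars)
  with_seed(seed, {
    under <- rbinom(n_boars, 1, prevalence) == 1
    n_coll <- pmin(49L, pmax(2L, as.integer(round(
      rtruncnorm(n_boars, params$collections_mean, params$collections_sd, 2, 49)
    ))))
    n_total_img <- 9L + rbinom(n_boars, 8, 3 / 8)
    n_h <- sample(4:5, n_boars, replace = TRUE)
    n_v <- n_total_img - n_h
    shift <- ifelse(under, params$shift_under, params$shift_high) +
      rnorm(n_boars, 0, params$shift_sd)
    baseline <- rnorm(n_boars, 0, params$baseline_sd)
    tibble::tibble(
      boar_id = sprintf("B%04d", seq_len(n_boars)),
      true_class = ifelse(under, "underperforming", "high_quality"),
      n_collections = n_coll,
      n_images_horizontal = as.integer(n_h),
      n_images_vertical = as.integer(n_v),
      echogenicity_shift = shift,
      baseline_offset = baseline,
      bad_rate = ifelse(under, params$up_bad_rate, params$hq_bad_rate),
      trash_rate = ifelse(under, params$up_trash_rate, params$hq_trash_rate)
    )
  })
}

# internal: draw the three metrics for one record given which criteria fail.
# fail is logical length 3: c(count, motility, morphology)
draw_metrics <- function(fail) {
  count <- if (fail[1]) rtruncnorm(1, 12e9, 5e9, 0, 20e9 - 1) else
    rtruncnorm(1, 60e9, 15e9, 20e9, Inf)
  motility <- if (fail[2]) rtruncnorm(1, 55, 10, 0, 70) else
    rtruncnorm(1, 85, 5, 70 + 1e-9, 100)
  morphology <- if (fail[3]) rtruncnorm(1, 55, 10, 0, 70) else
    rtruncnorm(1, 85, 5, 70 + 1e-9, 100)
  c(count, motility, morphology)
}

#' Simulate the semen-collection history of one boar
#'
#' Generates `n_collections` records at intervals drawn uniformly from
#' 5--14 days, starting around 200 days of age. Each record fails at least two
#' quality criteria (a bad collection) with probability `bad_rate`, fails
#' exactly one (intermediate) with probability `bad_rate / 2`, and is
#' technician-flagged as trash, independently, with probability `trash_rate`.
#' With `bad_rate = 0` and `trash_rate = 0` every record passes all three
#' criteria.
#'
#' @param profile a one-row profile as returned by [simulate_population()]
#'   (fields `boar_id`, `n_collections`, `bad_rate`, `trash_rate`).
#' @param seed integer seed.
#' @return tibble with columns `boar_id`, `day`, `total_sperm_count`,
#'   `motility`, `morphology`, `trash_flag`.
#' @export
simulate_semen_history <- function(profile, seed = 1) {
  profile <- as.list(profile)
  n <- as.integer(profile$n_collections)
  if (is.na(n) || n < 1) stop("profile must have a positive `n_collections`")
  with_seed(seed, {
    gaps <- sample(5:14, n - 1, replace = TRUE)
    days <- 200L + sample(0:13, 1) + c(0L, cumsum(gaps))
    kind <- sample(c("bad", "intermediate", "good"), n, replace = TRUE,
                   prob = c(profile$bad_rate, profile$bad_rate / 2,
                            max(0, 1 - 1.5 * profile$bad_rate)))
    trash <- runif(n) < profile$trash_rate
    metrics <- t(vapply(kind, function(k) {
      fail <- switch(k,
        good = c(FALSE, FALSE, FALSE),
        intermediate = sample(c(TRUE, FALSE, FALSE)),
        bad = {
          n_fail <- sample(2:3, 1, prob = c(0.7, 0.3))
          sample(c(rep(TRUE, n_fail), rep(FALSE, 3 - n_fail)))
        })
      draw_metrics(fail)
    }, numeric(3)))
    tibble::tibble(
      boar_id = profile$boar_id,
      day = days,
      total_sperm_count = metrics[, 1],
      motility = metrics[, 2],
      morphology = metrics[, 3],
      trash_flag = trash
    )
  })
}

#' Simulate semen histories for a whole population
#'
#' @param profiles profile table from [simulate_population()].
#' @param seed integer seed; each boar gets a deterministic child seed.
#' @return tibble of records, one block per boar, ordered by `boar_id`.
#' @export
simulate_records <- function(profiles, seed = 1) {
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    simulate_semen_history(profiles[i, ], seed = child_seed(seed, 7L, i))
  })
  do.call(rbind, out)
}
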