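#' Load an experiment configuration from YAML
#'
#' An experiment config collects the tunables of a full study in one file:
#' generator settings (`n_boars`, `prevalence`, `image_size`, plus any
#' [generator_defaults()] override under `generator:`), the augmentation
#' block (`augmentation:` with `group`, `p_morphological`, `p_brightness`
#' and magnitude overrides), and the evaluation block (`threshold`,
#' `lambda`, `n_runs`, `base_seed`).
#'
#' @param path path to a YAML file.
#' @return a list with elements `n_boars`, `prevalence`, `image_size`,
#'   `params` (full generator parameter list), `pipeline` (an
#'   [build_pipeline()] object), `threshold`, `lambda`, `n_runs`,
#'   `base_seed`.
#' @examples
#' cfg <- load_experiment_config(
#'   system.file("extdata", "experiment.yaml", package = "boarscan"))
#' cfg$pipeline
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  gen <- raw$generator %||% list()
  params <- do.call(generator_defaults, gen)
  aug <- raw$augmentation %||% list()
  pipeline <- build_pipeline(
    group = aug$group %||% "morphological",
    p_morphological = aug$p_morphological %||% 0.5,
    p_brightness = aug$p_brightness %||% 0.5,
    magnitudes = aug$magnitudes %||% list()
  )
  list(
    n_boars = raw$n_boars %||% 107L,
    prevalence = raw$prevalence %||% params$prevalence,
    image_size = raw$image_size %||% 96L,
    params = params,
    pipeline = pipeline,
    threshold = raw$threshold %||% 0.3,
    lambda = raw$lambda %||% 0.01,
    n_runs = raw$n_runs %||% 10L,
    base_seed = raw$base_seed %||% 1L
  )
}
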