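#' Number of semen-quality criteria met by a collection
#'
#' The three criteria are: total sperm count >= 20e9 (boundary inclusive),
#' motility > 70% and morphology > 70% (boundaries exclusive).
#'
#' @param total_sperm_count sperm per collection (absolute count).
#' @param motility,morphology percentages in `[0, 100]`.
#' @return integer vector of counts in 0--3.
#' @export
good_count <- function(total_sperm_count, motility, morphology) {
  if (any(is.na(total_sperm_count)) || any(is.na(motility)) ||
      any(is.na(morphology))) {
    stop("semen metrics must not be missing")
  }
  if (any(motility < 0 | motility > 100) || any(morphology < 0 | morphology > 100) ||
      any(total_sperm_count < 0)) {
    stop("semen metrics out of range")
  }
  as.integer((total_sperm_count >= 20e9) + (motility > 70) + (morphology > 70))
}

#' Classify semen collections
#'
#' A technician trash flag overrides the metrics. Otherwise a collection is
#' `good` when all three criteria are met, `bad` when at most one is met, and
#' `intermediate` when exactly two are met. Intermediate collections are
#' neither good nor low-quality; they count only in the denominator of the
#' boar-level rule.
#'
#' @param records data frame with columns `total_sperm_count`, `motility`,
#'   `morphology`, `trash_flag`.
#' @return the input with added columns `good_count` (integer) and `status`
#'   (`"good"`, `"intermediate"`, `"bad"`, `"trash"`).
#' @export
classify_collection <- function(records) {
  needed <- c("total_sperm_count", "motility", "morphology", "trash_flag")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  gc <- good_count(records$total_sperm_count, records$motility,
                   records$morphology)
  status <- ifelse(records$trash_flag, "trash",
            ifelse(gc == 3L, "good",
            ifelse(gc <= 1L, "bad", "intermediate")))
  records$good_count <- gc
  records$status <- status
  records
}

#' Label one boar from its collection statuses
#'
#' Two-step rule: a boar is underperforming iff it has more than one
#' low-quality collection (bad or trash) **and** low-quality collections make
#' up at least 10% of its total collections (boundary inclusive: exactly 10%
#' is underperforming). Trash-flagged records count both as low-quality and
#' in the denominator.
#'
#' @param statuses character vector of per-collection statuses
#'   (`"good"`, `"intermediate"`, `"bad"`, `"trash"`).
#' @return one-row tibble: `label`, `n_total`, `n_low_quality`,
#'   `low_quality_fraction`.
#' @export
label_boar <- function(statuses) {
  if (length(statuses) == 0) stop("`statuses` must contain at least one element")
  bad_set <- c("good", "intermediate", "bad", "trash")
  if (!all(statuses %in% bad_set)) {
    stop("unknown status values: ",
         paste(setdiff(unique(statuses), bad_set), collapse = ", "))
  }
  n_total <- length(statuses)
  n_low <- sum(statuses %in% c("bad", "trash"))
  frac <- n_low / n_total
  label <- if (n_low > 1 && frac >= 0.10) "underperforming" else "high_quality"
  tibble::tibble(label = label, n_total = n_total, n_low_quality = n_low,
                 low_quality_fraction = frac)
}

#' Label every boar in a record table
#'
#' Applies [classify_collection()] and [label_boar()] per boar.
#'
#' @param records data frame of semen records (or a path to a CSV file with
#'   the same columns), requiring `boar_id`, `total_sperm_count`, `motility`,
#'   `morphology`, `trash_flag`.
#' @return tibble with one row per `boar_id` (sorted): `boar_id`, `label`,
#'   `n_total`, `n_low_quality`, `low_quality_fraction`.
#' @export
label_dataset <- function(records) {
  if (is.character(records) && length(records) == 1) {
    records <- read.csv(records, stringsAsFactors = FALSE)
    records$trash_flag <- as.logical(records$trash_flag)
  }
  if (!"boar_id" %in% names(records)) stop("records are missing columns: boar_id")
  classified <- classify_collection(records)
  ids <- sort(unique(classified$boar_id))
  out <- lapply(ids, function(id) {
    res <- label_boar(classified$status[classified$boar_id == id])
    cbind(tibble::tibble(boar_id = id), res)
  })
  tibble::as_tibble(do.call(rbind, out))
}
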