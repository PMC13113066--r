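#' Durbin-Watson statistic
#'
#' First-order residual autocorrelation diagnostic: the sum of squared
#' successive residual differences divided by the residual sum of squares.
#' Values near 2 indicate no first-order autocorrelation; the statistic lies
#' in `[0, 4]`. Residuals are taken in the order they were fitted (the data
#' are not time-ordered, so higher-order autocorrelation is not assessed).
#'
#' @param residuals numeric vector of at least 2 residuals, not all zero.
#' @return the statistic.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need at least 2 residuals")
  ssr <- sum(residuals^2)
  if (ssr == 0) stop("Durbin-Watson is undefined for all-zero residuals")
  sum(diff(residuals)^2) / ssr
}

#' Condition number of a design matrix
#'
#' Ratio of the largest to the smallest singular value of the column-scaled
#' (unit Euclidean norm) design matrix. Values near 1 indicate an orthogonal
#' design; large values flag multicollinearity.
#'
#' @param x numeric design matrix, full column rank.
#' @return the condition number.
#' @export
condition_number <- function(x) {
  x <- as.matrix(x)
  norms <- sqrt(colSums(x^2))
  if (any(norms == 0)) stop("design matrix has a zero column")
  d <- svd(scale(x, center = FALSE, scale = norms), nu = 0, nv = 0)$d
  if (min(d) < max(d) * 1e-10) stop("design matrix is rank deficient")
  max(d) / min(d)
}

# internal: results table -> data frame of treatment-coded factors + metric
factorize_results <- function(results, metric) {
  metric <- match.arg(metric, c("precision", "recall", "f1"))
  needed <- c("region", "angle", "augmentation", "model", metric)
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols) > 0) {
    stop("results are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  d <- data.frame(
    region = factor(results$region, levels = c("full", "cropped")),
    angle = factor(results$angle, levels = c("horizontal", "vertical")),
    augmentation = factor(results$augmentation,
                          levels = c("morphological", "comprehensive")),
    model = factor(results$model, levels = c("medium", "small")),
    y = results[[metric]]
  )
  if (anyNA(d)) stop("results contain unknown factor levels or missing values")
  d
}

# internal: fail with the missing cells named when the design is not estimable
check_cells <- function(d, interactions) {
  for (f in c("region", "angle", "augmentation", "model")) {
    present <- unique(as.character(d[[f]]))
    absent <- setdiff(levels(d[[f]]), present)
    if (length(absent) > 0) {
      stop("design is not estimable; missing cells: ",
           paste0(f, "=", absent, collapse = ", "))
    }
  }
  if (interactions) {
    facs <- c("region", "angle", "augmentation", "model")
    pairs <- utils::combn(facs, 2)
    for (j in seq_len(ncol(pairs))) {
      tab <- table(d[[pairs[1, j]]], d[[pairs[2, j]]])
      if (any(tab == 0)) {
        empty <- which(tab == 0, arr.ind = TRUE)
        cells <- paste0(pairs[1, j], "=", rownames(tab)[empty[, 1]], "/",
                        pairs[2, j], "=", colnames(tab)[empty[, 2]])
        stop("design is not estimable; missing cells: ",
             paste(cells, collapse = ", "))
      }
    }
  }
}

# internal: marginal (Type II) ANOVA by nested residual-sum-of-squares
# comparisons. For each term, the reduced model drops the term and every
# higher-order term containing it (marginality). Equivalent to car::Anova
# type 2 on estimable designs, but also defined when the residual SS is 0:
# a term with zero SS reports F = 0 (not 0/0), a term with positive SS over
# a saturated fit reports an infinite F.
type2_anova <- function(fit, d) {
  trms <- attr(stats::terms(fit), "term.labels")
  rss <- sum(stats::residuals(fit)^2)
  rdf <- stats::df.residual(fit)
  rows <- lapply(trms, function(t) {
    t_vars <- strsplit(t, ":", fixed = TRUE)[[1]]
    contains_t <- vapply(trms, function(u) {
      all(t_vars %in% strsplit(u, ":", fixed = TRUE)[[1]])
    }, logical(1))
    keep <- trms[!contains_t]
    red <- lm(if (length(keep) == 0) y ~ 1 else
                stats::reformulate(keep, response = "y"), data = d)
    ext <- lm(stats::reformulate(c(keep, t), response = "y"), data = d)
    ss <- sum(stats::residuals(red)^2) - sum(stats::residuals(ext)^2)
    df <- stats::df.residual(red) - stats::df.residual(ext)
    data.frame(term = t, sum_sq = max(ss, 0), df = df)
  })
  a <- do.call(rbind, rows)
  fstat <- numeric(nrow(a))
  pval <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (a$sum_sq[i] < 1e-12) {
      fstat[i] <- 0
      pval[i] <- 1
    } else if (rss < 1e-12) {
      fstat[i] <- Inf
      pval[i] <- 0
    } else {
      fstat[i] <- (a$sum_sq[i] / a$df[i]) / (rss / rdf)
      pval[i] <- pf(fstat[i], a$df[i], rdf, lower.tail = FALSE)
    }
  }
  tibble::tibble(term = a$term, sum_sq = a$sum_sq, df = a$df,
                 statistic = fstat, p_value = pval,
                 significant = pval < 0.05)
}

# internal: shared fitting path for the main-effects / two-way models
fit_factorial <- function(results, metric, interactions) {
  d <- factorize_results(results, metric)
  check_cells(d, interactions)
  form <- if (interactions) {
    y ~ (region + angle + augmentation + model)^2
  } else {
    y ~ region + angle + augmentation + model
  }
  fit <- lm(form, data = d)
  if (any(is.na(coef(fit)))) {
    stop("design is not estimable; model matrix is rank deficient")
  }
  n <- nrow(d)
  p <- length(coef(fit))
  if (n - p < 1) stop("need at least 2 observations per cell for error df")
  anova_tbl <- type2_anova(fit, d)
  rss <- sum(stats::residuals(fit)^2)
  rdf <- stats::df.residual(fit)

  cf <- summary(fit)$coefficients
  ci <- confint(fit)
  coef_tbl <- tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                             std_error = cf[, 2], statistic = cf[, 3],
                             p_value = cf[, 4], ci_low = ci[, 1],
                             ci_high = ci[, 2])

  structure(list(metric = metric,
                 model = if (interactions) "two_way" else "main_effects",
                 n = n, fit = fit, anova = anova_tbl,
                 coefficients = coef_tbl,
                 residual_ss = rss, residual_df = rdf,
                 durbin_watson = if (rss < 1e-12) NA_real_ else
                   durbin_watson(stats::residuals(fit)),
                 condition_number = condition_number(model.matrix(fit))),
            class = "scan_lm_report")
}

#' Main-effects linear model over the factor grid
#'
#' Fits `y = mu + Region + Angle + Augmentation + Model + error` by ordinary
#' least squares with treatment coding (reference levels: full, horizontal,
#' morphological, medium), so level-1 coefficients read as the effect of
#' cropping, the vertical view, comprehensive augmentation and the small
#' tier. ANOVA F-tests use marginal (Type II) sums of squares, which coincide
#' with the sequential decomposition on the balanced grid; terms with zero
#' sum of squares report F = 0.
#'
#' @param results a [run_grid()] (or [simulate_run_results()]) table.
#' @param metric `"precision"`, `"recall"` or `"f1"`.
#' @return object of class `scan_lm_report`: ANOVA table, coefficient table
#'   with 95% confidence intervals, residual SS/df, Durbin-Watson statistic
#'   and design condition number.
#' @export
fit_main_effects <- function(results, metric = c("precision", "recall", "f1")) {
  fit_factorial(results, match.arg(metric), interactions = FALSE)
}

#' Two-way-interaction linear model over the factor grid
#'
#' Expands the main-effects model with all six pairwise interaction terms;
#' main-effect rows are retained.
#'
#' @inheritParams fit_main_effects
#' @export
fit_two_way <- function(results, metric = c("precision", "recall", "f1")) {
  fit_factorial(results, match.arg(metric), interactions = TRUE)
}

#' @exportS3Method base::print
print.scan_lm_report <- function(x, digits = 4, ...) {
  cat(sprintf("Factorial %s model for %s (n = %d)\n\n",
              gsub("_", "-", x$model), x$metric, x$n))
  cat("ANOVA (Type II):\n")
  a <- as.data.frame(x$anova)
  a$sum_sq <- signif(a$sum_sq, digits)
  a$statistic <- signif(a$statistic, digits)
  a$p_value <- format.pval(a$p_value, digits = 3)
  a$significant <- ifelse(a$significant, "*", "")
  print(a, row.names = FALSE)
  cat(sprintf("Residual: SS = %s on %d df\n\n",
              signif(x$residual_ss, digits), x$residual_df))
  cat("OLS coefficients:\n")
  b <- as.data.frame(x$coefficients)
  for (cc in c("estimate", "std_error", "statistic", "ci_low", "ci_high")) {
    b[[cc]] <- signif(b[[cc]], digits)
  }
  b$p_value <- format.pval(b$p_value, digits = 3)
  print(b, row.names = FALSE)
  cat(sprintf("\nDurbin-Watson = %.3f; condition number = %.2f\n",
              x$durbin_watson, x$condition_number))
  invisible(x)
}
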