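# Independent oracles used across test files.

# Literal two-step labeling rule, written directly from the definitions:
# underperforming iff more than one low-quality collection AND low-quality
# collections are at least 10% of the total.
oracle_label <- function(n_low, n_total) {
  if (n_low > 1 && n_low / n_total >= 0.10) "underperforming" else "high_quality"
}

# Build a status vector with a given composition.
status_vector <- function(n_bad = 0, n_trash = 0, n_good = 0, n_intermediate = 0) {
  c(rep("bad", n_bad), rep("trash", n_trash), rep("good", n_good),
    rep("intermediate", n_intermediate))
}

# Brute-force balanced-ANOVA decomposition: factor sums of squares from
# group means, residual as total minus the factor sums (main-effects model).
# Returns per-factor F statistics computed from first principles.
oracle_anova_f <- function(d, response, factors) {
  y <- d[[response]]
  grand <- mean(y)
  ss_tot <- sum((y - grand)^2)
  ss <- numeric(length(factors))
  df <- numeric(length(factors))
  for (i in seq_along(factors)) {
    f <- as.factor(d[[factors[i]]])
    means <- tapply(y, f, mean)
    counts <- tapply(y, f, length)
    ss[i] <- sum(counts * (means[levels(f)] - grand)^2)
    df[i] <- nlevels(f) - 1
  }
  ss_res <- ss_tot - sum(ss)
  df_res <- length(y) - 1 - sum(df)
  fstat <- ifelse(ss < 1e-12, 0, (ss / df) / (ss_res / df_res))
  stats::setNames(fstat, factors)
}

# A deterministic flat test image with a bright square blob, as a plain
# pixel matrix.
blob_image <- function(size = 64, value = 40, blob_value = 220,
                       blob_center = c(16, 16), blob_half = 3) {
  px <- matrix(value, size, size)
  r <- seq(blob_center[1] - blob_half, blob_center[1] + blob_half)
  c <- seq(blob_center[2] - blob_half, blob_center[2] + blob_half)
  px[r, c] <- blob_value
  px
}

# Intensity centroid of the bright pixels of a matrix.
bright_centroid <- function(px, threshold = 128) {
  idx <- which(px > threshold, arr.ind = TRUE)
  colMeans(idx)
}

# One speckle-like random test image.
speckle_image <- function(size = 48, seed = 1) {
  set.seed(seed)
  matrix(round(pmin(pmax(62 + (log1p(2 * rexp(size * size)) - 0.92) * 16, 0),
                    255)), size, size)
}
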