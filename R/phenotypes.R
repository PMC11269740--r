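# Trait derivation and the Rensch's-rule test.
#
# SSD is the log2 ratio of average adult male to average adult female body
# mass (positive = males larger); body mass is log10-transformed for
# normality; relative brain size is the residual of a log-log OLS fit of
# brain mass on body mass. Rensch's rule (SSD increasing with size) is
# diagnosed by a major-axis slope of log male on log female mass above 1.

#' Sexual size dimorphism
#'
#' `ssd = log2(male_mass / female_mass)`; positive values mean males are
#' larger. Vectorized.
#'
#' @param male_mass,female_mass Positive masses in grams.
#' @return Numeric SSD values.
#' @export
compute_ssd <- function(male_mass, female_mass) {
  if (any(!is.finite(male_mass)) || any(!is.finite(female_mass)) ||
      any(male_mass <= 0) || any(female_mass <= 0)) {
    ssd_error("masses must be finite and positive", "ssd_domain_error")
  }
  log2(male_mass / female_mass)
}

#' Relative brain size
#'
#' Residuals of an ordinary least-squares fit of log10(brain mass) on
#' log10(body mass): the component of brain size not explained by body-size
#' allometry. Residuals sum to zero and are invariant to rescaling body
#' mass by a constant (the shift is absorbed by the intercept).
#'
#' @param brain_mass,body_mass Positive masses; `NA`s allowed and returned
#'   as `NA` residuals.
#' @return Residual vector aligned with the input.
#' @export
relative_brain_size <- function(brain_mass, body_mass) {
  stopifnot(length(brain_mass) == length(body_mass))
  complete <- !is.na(brain_mass) & !is.na(body_mass)
  if (any(brain_mass[complete] <= 0) || any(body_mass[complete] <= 0)) {
    ssd_error("masses must be positive", "ssd_domain_error")
  }
  if (sum(complete) < 3) {
    ssd_error("relative brain size needs at least 3 species with both measures",
              "ssd_domain_error")
  }
  x <- log10(body_mass[complete])
  y <- log10(brain_mass[complete])
  if (stats::var(x) == 0) {
    ssd_error("zero variance in body mass", "ssd_domain_error")
  }
  res <- rep(NA_real_, length(brain_mass))
  res[complete] <- stats::residuals(stats::lm(y ~ x))
  res
}

#' Derive the full trait table from raw masses
#'
#' Adds `ssd`, `mean_mass`, `log10_mass` and, when `brain_mass` is present
#' with at least 3 complete cases, `rel_brain` to a raw trait table.
#'
#' @param traits Data frame with `species`, `male_mass`, `female_mass` and
#'   optionally `brain_mass`.
#' @return The augmented data frame.
#' @export
augment_traits <- function(traits) {
  required <- c("species", "male_mass", "female_mass")
  missing <- setdiff(required, names(traits))
  if (length(missing) > 0) {
    ssd_error(sprintf("traits table lacks columns: %s",
                      paste(missing, collapse = ", ")), "ssd_schema_error")
  }
  traits$species <- normalize_species(traits$species)
  traits$ssd <- compute_ssd(traits$male_mass, traits$female_mass)
  traits$mean_mass <- (traits$male_mass + traits$female_mass) / 2
  traits$log10_mass <- log10(traits$mean_mass)
  if ("brain_mass" %in% names(traits) &&
      sum(!is.na(traits$brain_mass) & !is.na(traits$mean_mass)) >= 3) {
    traits$rel_brain <- relative_brain_size(traits$brain_mass, traits$mean_mass)
  }
  traits
}

#' Major-axis regression
#'
#' Fits the first principal axis of the bivariate sample: with sample
#' variances `s_xx`, `s_yy` and covariance `s_xy`, the slope is
#' `(s_yy - s_xx + sqrt((s_yy - s_xx)^2 + 4 s_xy^2)) / (2 s_xy)` (the
#' leading-eigenvector direction of the covariance matrix), treating both
#' variables symmetrically. The slope-vs-hypothesis test follows the
#' standard rotation construction for major-axis slopes: under H0 the
#' residual axis `u = y - b0 x` and fitted axis `v = x + b0 y` are
#' uncorrelated, so `F = r_uv^2 (n-2) / (1 - r_uv^2)` is referred to
#' F(1, n-2).
#'
#' @param x,y Numeric vectors of equal length >= 3 with positive variance.
#' @param slope_null Hypothesized slope for `p_slope_vs_h0` (default 1,
#'   isometry).
#' @return A list of class `"ma_result"`: `slope`, `intercept`, `r`
#'   (Pearson correlation), `n`, `p_slope_vs_1`, `p_assoc`, `degenerate`.
#' @export
major_axis_regression <- function(x, y, slope_null = 1) {
  stopifnot(length(x) == length(y))
  complete <- !is.na(x) & !is.na(y)
  x <- x[complete]; y <- y[complete]
  n <- length(x)
  if (n < 3) {
    ssd_error("major-axis regression needs at least 3 points", "ssd_domain_error")
  }
  s_xx <- stats::var(x); s_yy <- stats::var(y); s_xy <- stats::cov(x, y)
  if (s_xx == 0 || s_yy == 0) {
    ssd_error("zero variance in x or y", "ssd_domain_error")
  }
  degenerate <- FALSE
  if (s_xy == 0) {
    if (s_xx == s_yy) {         # circular cloud: no major axis
      slope <- NA_real_
      degenerate <- TRUE
    } else {
      slope <- if (s_yy > s_xx) Inf else 0
    }
  } else {
    slope <- (s_yy - s_xx + sqrt((s_yy - s_xx)^2 + 4 * s_xy^2)) / (2 * s_xy)
  }
  intercept <- if (is.finite(slope)) mean(y) - slope * mean(x) else NA_real_
  r <- s_xy / sqrt(s_xx * s_yy)
  u <- y - slope_null * x       # residual axis under H0
  v <- x + slope_null * y       # fitted axis under H0
  if (stats::var(u) == 0 || stats::var(v) == 0) {
    p_slope <- 1                # data lie exactly on the hypothesized axis
  } else {
    r_uv <- stats::cor(u, v)
    Fstat <- r_uv^2 * (n - 2) / (1 - r_uv^2)
    p_slope <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  }
  p_assoc <- stats::cor.test(x, y)$p.value
  structure(
    list(slope = slope, intercept = intercept, r = r, n = n,
         p_slope_vs_1 = p_slope, p_assoc = p_assoc, slope_null = slope_null,
         degenerate = degenerate),
    class = "ma_result"
  )
}

#' @export
print.ma_result <- function(x, ...) {
  cat(sprintf(
    "Major-axis regression (n = %d)\n  slope = %.4f  intercept = %.4f  r = %.4f\n  H0 slope = %g: p = %.4g   H0 r = 0: p = %.4g\n",
    x$n, x$slope, x$intercept, x$r, x$slope_null, x$p_slope_vs_1, x$p_assoc))
  invisible(x)
}

#' Test Rensch's rule
#'
#' Major-axis regression of log10 male mass on log10 female mass with a
#' test of the slope against 1 (hyperallometry, slope > 1, indicates
#' Rensch's rule), plus the correlation between SSD and log10 mean body
#' mass (`r_assoc`) as a direct measure of the allometric SSD-size
#' association.
#'
#' @param traits Trait table; augmented via [augment_traits()] if the
#'   derived columns are absent.
#' @param config An [analysis_config()] (controls the `r_assoc`
#'   correlation estimator).
#' @return An `"ma_result"` with extra fields `r_assoc` and `p_assoc_ssd`.
#' @export
test_rensch <- function(traits, config = analysis_config()) {
  if (!all(c("ssd", "log10_mass") %in% names(traits))) {
    traits <- augment_traits(traits)
  }
  complete <- !is.na(traits$male_mass) & !is.na(traits$female_mass)
  traits <- traits[complete, ]
  ma <- major_axis_regression(log10(traits$female_mass),
                              log10(traits$male_mass))
  assoc <- stats::cor.test(traits$ssd, traits$log10_mass,
                           method = config$r_assoc_method, exact = FALSE)
  ma$r_assoc <- unname(assoc$estimate)
  ma$p_assoc_ssd <- assoc$p.value
  ssd_log("info", sprintf(
    "Rensch test on %d species: MA slope = %.3f (p vs 1 = %.3g), r_assoc = %.3f",
    ma$n, ma$slope, ma$p_slope_vs_1, ma$r_assoc))
  ma
}
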