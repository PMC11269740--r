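#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline. Defaults encode the
#' screening conditions used throughout: gene families must be present in at
#' least 80% of species, reach at least 3 genes in at least one species, and
#' vary across species; significance is controlled at FDR 0.05 by
#' Benjamini-Hochberg; effect sizes above |r| = 0.3 earn a secondary
#' "strong" label; resampling procedures draw 10,000 replicates; GO terms
#' annotated to fewer than 50 families are pooled into an excluded
#' "small_GO" category.
#'
#' @param prevalence_threshold Fraction of species in which a family must
#'   have a positive count (default 0.80).
#' @param min_max_count Minimum of the per-family maximum count (default 3).
#' @param effect_r_threshold Absolute effect size above which a significant
#'   family is additionally labelled "strong" (default 0.3).
#' @param alpha Significance level for adjusted p-values (default 0.05).
#' @param n_resamples Number of randomization / bootstrap replicates
#'   (default 10000).
#' @param random_seed Integer seed recorded into the config; `NULL` leaves
#'   seeding to the caller.
#' @param brain_label Tissue identifier treated as the brain in the
#'   expression-rank analysis (default `"brain"`).
#' @param small_go_min GO terms annotated to fewer than this many families
#'   are pooled into "small_GO" and excluded from testing (default 50).
#' @param use_raw_p If `TRUE`, expansion/contraction calls gate on raw
#'   rather than BH-adjusted p-values.
#' @param r_assoc_method Correlation estimator for the SSD-vs-body-mass
#'   association reported by [test_rensch()].
#' @param enrichment_alternative `"greater"` tests enrichment only (upper
#'   tail of Z); `"two.sided"` also captures depletion.
#' @return A list of class `"ssd_config"`.
#' @export
analysis_config <- function(prevalence_threshold = 0.80,
                            min_max_count = 3L,
                            effect_r_threshold = 0.3,
                            alpha = 0.05,
                            n_resamples = 10000L,
                            random_seed = NULL,
                            brain_label = "brain",
                            small_go_min = 50L,
                            use_raw_p = FALSE,
                            r_assoc_method = c("pearson", "spearman"),
                            enrichment_alternative = c("greater", "two.sided")) {
  r_assoc_method <- match.arg(r_assoc_method)
  enrichment_alternative <- match.arg(enrichment_alternative)
  if (!is.numeric(prevalence_threshold) || prevalence_threshold <= 0 ||
      prevalence_threshold > 1) {
    ssd_error("prevalence_threshold must lie in (0, 1]", "ssd_config_error")
  }
  if (!is_count(min_max_count) || min_max_count < 0) {
    ssd_error("min_max_count must be a nonnegative integer", "ssd_config_error")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    ssd_error("alpha must lie in (0, 1)", "ssd_config_error")
  }
  if (!is_count(n_resamples) || n_resamples < 1) {
    ssd_error("n_resamples must be a positive integer", "ssd_config_error")
  }
  if (!is_count(small_go_min) || small_go_min < 1) {
    ssd_error("small_go_min must be a positive integer", "ssd_config_error")
  }
  if (!is.null(random_seed) && !is_count(random_seed)) {
    ssd_error("random_seed must be an integer or NULL", "ssd_config_error")
  }
  structure(
    list(
      prevalence_threshold = prevalence_threshold,
      min_max_count = as.integer(min_max_count),
      effect_r_threshold = effect_r_threshold,
      alpha = alpha,
      n_resamples = as.integer(n_resamples),
      random_seed = if (is.null(random_seed)) NULL else as.integer(random_seed),
      brain_label = brain_label,
      small_go_min = as.integer(small_go_min),
      use_raw_p = isTRUE(use_raw_p),
      r_assoc_method = r_assoc_method,
      enrichment_alternative = enrichment_alternative
    ),
    class = "ssd_config"
  )
}

#' Read a pipeline configuration file
#'
#' The config file is a flat `key: value` YAML document whose keys are the
#' arguments of [analysis_config()]; unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param path Path to the YAML config file.
#' @return An `"ssd_config"` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    ssd_error(sprintf("config file not found: %s", path), "ssd_io_error")
  }
  values <- yaml::read_yaml(path)
  if (is.null(values)) values <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0) {
    ssd_error(
      sprintf("unknown config keys: %s (expected among: %s)",
              paste(unknown, collapse = ", "), paste(known, collapse = ", ")),
      "ssd_config_error"
    )
  }
  do.call(analysis_config, values)
}

#' @export
print.ssd_config <- function(x, ...) {
  cat("ssdscreen analysis configuration\n")
  for (k in names(x)) {
    cat(sprintf("  %-22s %s\n", k, if (is.null(x[[k]])) "NULL" else format(x[[k]])))
  }
  invisible(x)
}
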