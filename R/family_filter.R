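#' Filter a gene-family count matrix
#'
#' Applies the three inclusion rules of the screen: a family must (i) have
#' a positive count in at least `ceiling(prevalence_threshold * n_species)`
#' species (removing lineage-specific families), (ii) reach at least
#' `min_max_count` genes in at least one species (avoiding
#' presence/absence comparisons), and (iii) vary across species (a
#' regression cannot explain variance that does not exist). The report
#' records, for every input family, its prevalence, maximum count,
#' variance, and which rules it failed; filtering is idempotent.
#'
#' @param counts Integer matrix, families in rows, species in columns.
#' @param config An [analysis_config()].
#' @return A list with `counts` (the retained submatrix) and `report` (a
#'   data frame covering every input family with columns `family`,
#'   `prevalence`, `max_count`, `variance`, `passed`, `failed_rules`).
#'   An empty result is returned with a warning, not an error.
#' @export
filter_families <- function(counts, config = analysis_config()) {
  if (!is.matrix(counts) || nrow(counts) == 0 || ncol(counts) == 0) {
    ssd_error("counts must be a nonempty families x species matrix",
              "ssd_validation_error")
  }
  n_sp <- ncol(counts)
  need <- ceiling(config$prevalence_threshold * n_sp)
  prevalence <- rowMeans(counts > 0)
  n_present <- rowSums(counts > 0)
  max_count <- apply(counts, 1, max)
  variance <- apply(counts, 1, stats::var)
  fail_prev <- n_present < need
  fail_max <- max_count < config$min_max_count
  fail_var <- variance == 0
  failed <- mapply(function(p, m, v) {
    paste(c(if (p) "prevalence", if (m) "max_count", if (v) "variance"),
          collapse = ";")
  }, fail_prev, fail_max, fail_var)
  passed <- !(fail_prev | fail_max | fail_var)
  report <- data.frame(
    family = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    prevalence = prevalence, max_count = max_count, variance = variance,
    passed = passed, failed_rules = failed,
    stringsAsFactors = FALSE, row.names = NULL
  )
  kept <- counts[passed, , drop = FALSE]
  ssd_log("info", sprintf(
    "family filter: %d/%d families retained (need count>0 in >=%d of %d species, max count >=%d, variance >0)",
    nrow(kept), nrow(counts), need, n_sp, config$min_max_count))
  if (nrow(kept) == 0) {
    warning("no gene families pass the filters; returning an empty matrix")
  }
  list(counts = kept, report = report)
}
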