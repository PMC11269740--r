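# GO-term enrichment of focal gene-family sets against equally sized
# random draws from the background, with Z scores computed from the
# randomized null's mean and standard deviation.

#' Collapse gene-level GO annotations to the family level
#'
#' A term is linked to a family whenever the term is assigned to any gene
#' belonging to that family, in any species; membership is a set, so
#' multiple carrier genes yield a single edge. Genes annotated with GO
#' terms but absent from the membership map are skipped with a logged
#' count.
#'
#' @param gene_go Data frame with columns `gene`, `term`.
#' @param membership Data frame with columns `gene`, `family`.
#' @return A data frame of unique (`term`, `family`) edges with a
#'   `testable` flag (all `TRUE`; [pool_small_terms()] may clear it).
#' @export
map_go_to_families <- function(gene_go, membership) {
  stopifnot(all(c("gene", "term") %in% names(gene_go)),
            all(c("gene", "family") %in% names(membership)))
  known <- gene_go$gene %in% membership$gene
  if (!any(known)) {
    ssd_error("no annotated gene appears in the membership map",
              "ssd_validation_error")
  }
  n_skip <- length(unique(gene_go$gene[!known]))
  if (n_skip > 0) {
    ssd_log("info", sprintf(
      "map_go_to_families: %d annotated genes missing from the membership map were skipped",
      n_skip))
  }
  merged <- merge(gene_go[known, c("gene", "term")],
                  membership[, c("gene", "family")], by = "gene")
  edges <- unique(merged[, c("term", "family")])
  edges <- edges[order(edges$term, edges$family), ]
  rownames(edges) <- NULL
  edges$testable <- TRUE
  edges
}

#' Pool rare GO terms into an excluded "small_GO" category
#'
#' Terms annotated to fewer than `config$small_go_min` families are merged
#' into a single pseudo-term `"small_GO"` that stays in the map (its
#' term-family edge count is conserved) but is flagged not testable, so it
#' never enters the randomization test or the BH correction. The strict
#' inequality means a term with exactly `small_go_min` families is
#' retained.
#'
#' @param map A family-term edge table from [map_go_to_families()].
#' @param config An [analysis_config()].
#' @return The edge table with small terms relabelled `"small_GO"` and
#'   `testable = FALSE`.
#' @export
pool_small_terms <- function(map, config = analysis_config()) {
  if (nrow(map) == 0) {
    ssd_error("empty family-term map", "ssd_validation_error")
  }
  sizes <- tapply(map$family, map$term, function(f) length(unique(f)))
  small <- names(sizes)[sizes < config$small_go_min]
  is_small <- map$term %in% small
  map$term[is_small] <- "small_GO"
  map$testable[is_small] <- FALSE
  ssd_log("info", sprintf(
    "small-GO pooling: %d of %d terms pooled (fewer than %d families)",
    length(small), length(sizes), config$small_go_min))
  if (all(!map$testable)) {
    warning("all GO terms fall below the small-GO threshold; nothing is testable")
  }
  map
}

#' Randomization test of GO-term enrichment
#'
#' Compares, for each testable term, the number of focal families carrying
#' the term against its distribution over `config$n_resamples` samples of
#' size `|focal|` drawn uniformly without replacement from the background.
#' `Z = (x_obs - null_mean) / null_sd`; p is the upper normal tail of Z
#' (enrichment; set `enrichment_alternative = "two.sided"` in the config
#' for depletion scans), BH-adjusted across testable terms. Terms whose
#' null is degenerate (`null_sd = 0`) fall back to the add-one empirical
#' tail probability and are flagged.
#'
#' @param focal Character vector of focal families, a strict subset of
#'   `background`.
#' @param background Character vector: the selection universe (the families
#'   that entered the screen).
#' @param map Family-term edge table ([map_go_to_families()], optionally
#'   after [pool_small_terms()]).
#' @param config An [analysis_config()]; `n_resamples` must be >= 100.
#' @param seed Integer seed (default `config$random_seed`).
#' @return A data frame per testable term: `term`, `n_families` (in
#'   background), `x_obs`, `null_mean`, `null_sd`, `Z`, `p_raw`, `p_adj`,
#'   `degenerate`.
#' @export
randomization_enrichment <- function(focal, background, map,
                                     config = analysis_config(),
                                     seed = config$random_seed) {
  focal <- unique(focal)
  background <- unique(background)
  if (length(focal) < 1 || !all(focal %in% background)) {
    ssd_error("focal must be a nonempty subset of background",
              "ssd_validation_error")
  }
  if (length(focal) == length(background)) {
    ssd_error(
      "focal equals background: every draw is the background itself; provide a strict subset",
      "ssd_validation_error"
    )
  }
  if (config$n_resamples < 100) {
    ssd_error("n_resamples must be at least 100", "ssd_validation_error")
  }
  map <- map[map$testable & map$family %in% background, , drop = FALSE]
  terms <- sort(unique(map$term))
  if (length(terms) == 0) {
    ssd_error("no testable term has background families", "ssd_validation_error")
  }
  # terms x background incidence
  M <- matrix(0, nrow = length(terms), ncol = length(background),
              dimnames = list(terms, background))
  M[cbind(match(map$term, terms), match(map$family, background))] <- 1
  x_obs <- as.integer(M[, focal, drop = FALSE] %*% rep(1, length(focal)))
  f <- length(focal)
  B <- config$n_resamples
  ssd_log("info", sprintf(
    "enrichment: %d focal vs %d background families, %d terms, %d resamples, seed = %s",
    f, length(background), length(terms), B, format(seed %||% "NULL")))
  null_counts <- with_seed(seed, {
    S <- matrix(0, nrow = length(background), ncol = B)
    for (b in seq_len(B)) {
      S[sample.int(length(background), f), b] <- 1
    }
    M %*% S
  })
  null_mean <- rowMeans(null_counts)
  null_sd <- apply(null_counts, 1, stats::sd)
  degenerate <- null_sd == 0
  Z <- ifelse(degenerate, NA_real_, (x_obs - null_mean) / null_sd)
  p_raw <- ifelse(
    degenerate,
    (1 + rowSums(null_counts >= x_obs)) / (1 + B),
    if (config$enrichment_alternative == "greater") {
      stats::pnorm(Z, lower.tail = FALSE)
    } else {
      2 * stats::pnorm(-abs(Z))
    }
  )
  res <- data.frame(
    term = terms, n_families = as.integer(rowSums(M)), x_obs = x_obs,
    null_mean = null_mean, null_sd = null_sd, Z = Z, p_raw = p_raw,
    p_adj = bh_adjust(p_raw), degenerate = degenerate,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res
}
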