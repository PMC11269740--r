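# Brain-expression statistics: tissue rank of brain expression with a
# bootstrap null, temporal trajectory slopes across brain structure
# groups, and female-to-male fold-change testing.

#' Brain structure groups
#'
#' Region codes mapped to the three broad brain structures used for
#' temporal trajectories: cortex, subcortex and cerebellum.
#'
#' @return Named list of character vectors of region codes.
#' @export
brain_structure_groups <- function() {
  list(
    cortex = c("Ocx", "M1C-S1C", "STC", "MFC", "DFC", "OFC", "ITC", "HIP",
               "VFC", "PCx", "TCx", "A1C", "V1C", "M1C", "IPC", "S1C"),
    subcortex = c("AMY", "MGE", "MD", "CGE", "DTH", "STR"),
    cerebellum = c("URL", "CB", "CBC")
  )
}

# average replicate rows sharing (gene, tissue [, stage, sex]) before any
# statistic
average_replicates <- function(expr, by = c("gene", "tissue")) {
  by <- intersect(by, names(expr))
  stats::aggregate(expr["value"], expr[by], mean)
}

#' Brain expression rank
#'
#' For each gene, the number of non-brain tissues whose (replicate-
#' averaged) expression is strictly greater than the brain's; 0 means the
#' brain is the top tissue, `T - 1` the bottom. Lower mean rank over a
#' gene set indicates brain-biased expression. The rank depends only on
#' the ordering of values, so it is invariant under any strictly
#' increasing transform.
#'
#' @param expr Expression table (`gene`, `tissue`, `value`; extra columns
#'   are averaged over).
#' @param genes Gene set to average over; genes without a brain
#'   measurement are excluded with a logged count.
#' @param brain_label Tissue identifier of the brain.
#' @return A list of class `"rank_result"`: `mean_rank`, `per_gene`
#'   (named ranks), `n_tissues`, `n_genes`.
#' @export
brain_rank <- function(expr, genes, brain_label = "brain") {
  if (!brain_label %in% expr$tissue) {
    ssd_error(sprintf("brain tissue '%s' absent from the table", brain_label),
              "ssd_validation_error")
  }
  avg <- average_replicates(expr)
  ranks <- gene_ranks(avg, brain_label)
  usable <- intersect(genes, names(ranks))
  n_missing <- length(setdiff(genes, usable))
  if (n_missing > 0) {
    ssd_log("info", sprintf(
      "brain_rank: %d genes without a brain measurement excluded", n_missing))
  }
  if (length(usable) == 0) {
    ssd_error("no usable gene has a brain measurement", "ssd_validation_error")
  }
  structure(
    list(mean_rank = mean(ranks[usable]), per_gene = ranks[usable],
         n_tissues = length(unique(avg$tissue)), n_genes = length(usable)),
    class = "rank_result"
  )
}

# per-gene rank = #{non-brain tissues with value strictly > brain value};
# only genes with a brain value are returned
gene_ranks <- function(avg, brain_label) {
  brain <- avg[avg$tissue == brain_label, c("gene", "value")]
  other <- avg[avg$tissue != brain_label, c("gene", "value")]
  other <- other[other$gene %in% brain$gene, ]
  bval <- stats::setNames(brain$value, brain$gene)
  higher <- tapply(other$value > bval[other$gene], other$gene, sum)
  out <- stats::setNames(as.numeric(higher), names(higher))
  out[names(bval)[names(bval) %in% names(out)]]
}

#' Bootstrap significance of a gene set's brain rank
#'
#' Draws `config$n_resamples` gene sets of the same size with replacement
#' from all genes with a brain measurement, computes each set's mean rank,
#' and returns the add-one lower-tail probability
#' `p_boot = (1 + #{bootstrap mean <= observed}) / (1 + n_resamples)`:
#' the chance that a random gene set is at least as brain-biased (low
#' rank) as the observed one. The add-one estimator keeps p strictly
#' positive.
#'
#' @param expr Expression table.
#' @param genes Focal gene set.
#' @param config An [analysis_config()] (`brain_label`, `n_resamples`).
#' @param seed Integer seed (default `config$random_seed`).
#' @return A `"rank_result"` with `mean_rank`, `boot_means`, `p_boot`,
#'   `n_tissues`, `n_genes`, `n_background`.
#' @export
bootstrap_rank_p <- function(expr, genes, config = analysis_config(),
                             seed = config$random_seed) {
  avg <- average_replicates(expr)
  ranks <- gene_ranks(avg, config$brain_label)
  if (length(ranks) < 2) {
    ssd_error("background needs at least 2 genes with a brain measurement",
              "ssd_validation_error")
  }
  usable <- intersect(genes, names(ranks))
  if (length(usable) == 0) {
    ssd_error("no focal gene has a brain measurement", "ssd_validation_error")
  }
  obs <- mean(ranks[usable])
  B <- config$n_resamples
  boot_means <- with_seed(seed, {
    draws <- matrix(sample(ranks, length(usable) * B, replace = TRUE),
                    ncol = B)
    colMeans(draws)
  })
  p_boot <- (1 + sum(boot_means <= obs)) / (1 + B)
  ssd_log("info", sprintf(
    "bootstrap_rank_p: mean rank %.3f over %d genes (background %d, %d tissues), p_boot = %.4g",
    obs, length(usable), length(ranks), length(unique(avg$tissue)), p_boot))
  structure(
    list(mean_rank = obs, per_gene = ranks[usable], boot_means = boot_means,
         p_boot = p_boot, n_tissues = length(unique(avg$tissue)),
         n_genes = length(usable), n_background = length(ranks)),
    class = "rank_result"
  )
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf("Brain expression rank: mean %.3f over %d genes (%d tissues)\n",
              x$mean_rank, x$n_genes, x$n_tissues))
  if (!is.null(x$p_boot)) {
    cat(sprintf("  bootstrap p (lower tail, %d resamples): %.4g\n",
                length(x$boot_means), x$p_boot))
  }
  invisible(x)
}

#' Temporal expression trajectory of a brain structure group
#'
#' Per developmental stage, expression is log2(x + 1)-transformed,
#' averaged over the group's regions per gene, then over genes; the slope
#' is the ordinary least-squares slope of the stage means against the
#' stage axis (numeric age when `use_age = TRUE` and an `age` column is
#' present, otherwise ordinal stage position). Stages with no region of
#' the group are skipped with a log entry.
#'
#' @param expr Expression table with region codes in `tissue`.
#' @param genes Gene set.
#' @param group One of `"cortex"`, `"subcortex"`, `"cerebellum"`.
#' @param region_groups Region-code mapping (default
#'   [brain_structure_groups()]).
#' @param stages Ordered character vector of stage labels; default the
#'   order of appearance (or ascending `age` when present).
#' @param use_age Use numeric age as the regression axis.
#' @return A list: `slope`, `stage_means` (data frame `stage`, `axis`,
#'   `mean_expr`, `n_genes`), `group`.
#' @export
temporal_trajectory <- function(expr, genes, group = c("cortex", "subcortex",
                                                       "cerebellum"),
                                region_groups = brain_structure_groups(),
                                stages = NULL, use_age = FALSE) {
  group <- match.arg(group)
  regions <- region_groups[[group]]
  sub <- expr[expr$gene %in% genes & expr$tissue %in% regions, ]
  if (nrow(sub) == 0) {
    ssd_error(sprintf("no data for group '%s'", group), "ssd_validation_error")
  }
  if (is.null(stages)) {
    stages <- if ("age" %in% names(expr) && !anyNA(expr$age)) {
      unique(expr$stage[order(expr$age)])
    } else {
      unique(expr$stage)
    }
  }
  skipped <- setdiff(stages, unique(sub$stage))
  if (length(skipped) > 0) {
    ssd_log("info", sprintf("temporal_trajectory(%s): stages without data skipped: %s",
                            group, paste(skipped, collapse = ", ")))
    stages <- setdiff(stages, skipped)
  }
  if (length(stages) < 3) {
    ssd_error("need at least 3 stages with data", "ssd_validation_error")
  }
  sub$log_value <- log2(sub$value + 1)
  # per stage: mean over regions within gene, then over genes
  per_gene <- stats::aggregate(log_value ~ gene + stage, data = sub, FUN = mean)
  per_stage <- stats::aggregate(log_value ~ stage, data = per_gene, FUN = mean)
  n_genes <- stats::aggregate(gene ~ stage, data = per_gene,
                              FUN = function(g) length(unique(g)))
  per_stage <- per_stage[match(stages, per_stage$stage), ]
  axis <- if (use_age && "age" %in% names(sub)) {
    sub$age[match(stages, sub$stage)]
  } else {
    seq_along(stages)
  }
  fit <- stats::lm(per_stage$log_value ~ axis)
  slope <- unname(stats::coef(fit)[2])
  list(
    slope = slope,
    stage_means = data.frame(
      stage = stages, axis = axis, mean_expr = per_stage$log_value,
      n_genes = n_genes$gene[match(stages, n_genes$stage)],
      stringsAsFactors = FALSE
    ),
    group = group
  )
}

#' Sex-biased expression fold change
#'
#' For each gene and each (region, stage) pair of the requested phase with
#' both sexes measured, computes `log2((female mean + 1)/(male mean + 1))`
#' (the +1 mirroring the log2(x + 1) transform, so zero expression is
#' well-defined), then tests the per-gene fold-change vector against 0
#' with a two-sided one-sample Wilcoxon signed-rank test
#' (`stats::wilcox.test`: exact for few pairs, normal approximation with
#' continuity correction otherwise) and BH-adjusts across genes within
#' the phase. Genes whose fold changes are all exactly zero get p = 1 by
#' convention and are flagged.
#'
#' @param expr Expression table with columns `gene`, `tissue`, `stage`,
#'   `sex`, `value` and a `phase` column (`"prenatal"`/`"adult"`).
#' @param genes Gene set to test.
#' @param phase `"prenatal"` or `"adult"`; the two phases never share
#'   samples.
#' @param config An [analysis_config()].
#' @return A data frame per usable gene: `gene`, `n_pairs`,
#'   `median_log2fc`, `p_wilcoxon`, `p_adj`, `all_zero`; the per-gene
#'   fold-change vectors are in `attr(, "log2fc")`.
#' @export
sexbias_foldchange <- function(expr, genes, phase = c("prenatal", "adult"),
                               config = analysis_config()) {
  phase <- match.arg(phase)
  if (!"phase" %in% names(expr)) {
    ssd_error("expression table needs a 'phase' column (prenatal/adult)",
              "ssd_schema_error")
  }
  sub <- expr[expr$phase == phase & expr$gene %in% genes &
                expr$sex %in% c("female", "male"), ]
  if (nrow(sub) == 0) {
    ssd_error(sprintf("no %s-phase data for the requested genes", phase),
              "ssd_validation_error")
  }
  avg <- average_replicates(sub, by = c("gene", "tissue", "stage", "sex"))
  wide <- stats::reshape(avg, direction = "wide",
                         idvar = c("gene", "tissue", "stage"),
                         timevar = "sex")
  if (!all(c("value.female", "value.male") %in% names(wide))) {
    ssd_error("need both sexes measured in the requested phase",
              "ssd_validation_error")
  }
  wide <- wide[!is.na(wide$value.female) & !is.na(wide$value.male), ]
  wide$log2fc <- log2((wide$value.female + 1) / (wide$value.male + 1))
  fc_by_gene <- split(wide$log2fc, wide$gene)
  skipped <- setdiff(genes, names(fc_by_gene))
  if (length(skipped) > 0) {
    ssd_log("info", sprintf(
      "sexbias_foldchange(%s): %d genes without a matched sex pair skipped",
      phase, length(skipped)))
  }
  rows <- lapply(names(fc_by_gene), function(g) {
    fc <- fc_by_gene[[g]]
    all_zero <- all(fc == 0)
    p <- if (all_zero) 1 else
      suppressWarnings(stats::wilcox.test(fc, mu = 0)$p.value)
    data.frame(gene = g, n_pairs = length(fc),
               median_log2fc = stats::median(fc), p_wilcoxon = p,
               all_zero = all_zero, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p_wilcoxon)
  res <- res[, c("gene", "n_pairs", "median_log2fc", "p_wilcoxon", "p_adj",
                 "all_zero")]
  attr(res, "log2fc") <- fc_by_gene
  res
}
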