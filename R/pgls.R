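# The statistical core: Brownian phylogenetic covariance, per-family
# generalized least squares, correlation-scale effect sizes, FDR control
# and expansion/contraction classification.

#' Brownian-motion phylogenetic covariance matrix
#'
#' Under Brownian trait evolution the covariance of two tips equals the
#' depth (root-to-node path length) of their most recent common ancestor;
#' the diagonal holds root-to-tip depths. Species absent from `species`
#' are pruned before computing, and the result is ordered as requested.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param species Ordered tip labels to keep; default all tips in tree
#'   order.
#' @return A symmetric positive-semidefinite matrix with `species` as row
#'   and column names.
#' @export
phylo_covariance <- function(tree, species = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  validate_tree(tree)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0) {
    ssd_error(sprintf("species not in tree: %s", paste(missing, collapse = ", ")),
              "ssd_tree_error")
  }
  if (length(species) < 2) {
    ssd_error("need at least 2 species", "ssd_domain_error")
  }
  pruned <- ape::keep.tip(tree, species)
  C <- ape::vcv.phylo(pruned)
  C[species, species]
}

#' Generalized least squares fit with phylogenetic covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * C)`, by Cholesky whitening:
#' with `C = R'R`, the transformed problem `R'^-1 y = R'^-1 X beta + z` is
#' ordinary least squares. The returned quantities satisfy the generalized
#' normal equations `beta = (X'C^-1 X)^-1 X'C^-1 y`,
#' `sigma2 = e'C^-1 e / (n - k)`, `se_j = sqrt(sigma2 [(X'C^-1X)^-1]_jj)`,
#' `t = beta / se`, two-sided p from t with `n - k` degrees of freedom.
#' A perfect fit (`sigma2` numerically 0) is flagged degenerate with
#' undefined t rather than dividing by zero.
#'
#' @param y Response vector (one value per species).
#' @param X Design matrix including the intercept column.
#' @param C Phylogenetic covariance matrix, positive definite.
#' @return A list of class `"pgls_fit"`: `beta`, `se`, `t`, `df`,
#'   `sigma2`, `p_raw`, `degenerate`.
#' @export
pgls_fit <- function(y, X, C) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n || nrow(C) != n || ncol(C) != n) {
    ssd_error("dimensions of y, X and C disagree", "ssd_domain_error")
  }
  if (n <= k) {
    ssd_error("need more species than predictors", "ssd_domain_error")
  }
  R <- tryCatch(chol(C), error = function(e)
    ssd_error("C is not positive definite", "ssd_domain_error"))
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-12) {
    ssd_error("design matrix is rank-deficient after whitening",
              "ssd_domain_error")
  }
  XtX_inv <- solve(XtX)
  beta <- drop(XtX_inv %*% crossprod(Xw, yw))
  resid <- yw - drop(Xw %*% beta)
  df <- n - k
  rss <- sum(resid^2)
  sigma2 <- rss / df
  degenerate <- sigma2 <= .Machine$double.eps * max(1, sum(yw^2))
  if (degenerate) {
    se <- t_stat <- p_raw <- rep(NA_real_, k)
  } else {
    se <- sqrt(sigma2 * diag(XtX_inv))
    t_stat <- beta / se
    p_raw <- 2 * stats::pt(-abs(t_stat), df)
  }
  names(beta) <- colnames(X)
  structure(
    list(beta = beta, se = stats::setNames(se, colnames(X)),
         t = stats::setNames(t_stat, colnames(X)), df = df, sigma2 = sigma2,
         p_raw = stats::setNames(p_raw, colnames(X)), degenerate = degenerate),
    class = "pgls_fit"
  )
}

#' Correlation-scale effect size from a t statistic
#'
#' `r = t / sqrt(t^2 + df)`: a strictly increasing, sign-preserving map of
#' t onto (-1, 1), comparable across families with equal degrees of
#' freedom.
#'
#' @param t t statistic(s).
#' @param df Residual degrees of freedom, at least 1.
#' @return Effect size(s) in (-1, 1).
#' @export
effect_size_r <- function(t, df) {
  if (any(df < 1)) {
    ssd_error("df must be >= 1", "ssd_domain_error")
  }
  t / sqrt(t^2 + df)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; a validating wrapper around
#' `stats::p.adjust(method = "BH")` returning values in input order.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    ssd_error("p-values must lie in [0, 1]", "ssd_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

# intersect tree tips, trait species and count columns; log what is dropped
align_species <- function(counts, traits, tree, required_cols) {
  traits$species <- normalize_species(traits$species)
  colnames(counts) <- normalize_species(colnames(counts))
  complete <- rep(TRUE, nrow(traits))
  for (col in required_cols) complete <- complete & !is.na(traits[[col]])
  usable <- traits$species[complete]
  common <- intersect(intersect(tree$tip.label, usable), colnames(counts))
  dropped <- setdiff(unique(c(tree$tip.label, traits$species, colnames(counts))),
                     common)
  if (length(dropped) > 0) {
    ssd_log("info", sprintf(
      "species alignment: %d retained, %d dropped (%s%s)",
      length(common), length(dropped),
      paste(utils::head(dropped, 5), collapse = ", "),
      if (length(dropped) > 5) ", ..." else ""))
  }
  if (length(common) < 3) {
    ssd_error("fewer than 3 species shared by tree, traits and counts",
              "ssd_domain_error")
  }
  common
}

#' Screen gene families for trait associations by PGLS
#'
#' Fits, for every family, the two-predictor model
#' `family size ~ predictor1 + predictor2` under a Brownian-motion error
#' covariance, then converts t statistics to effect sizes
#' (`r = t/sqrt(t^2+df)`), adjusts p-values across families separately per
#' predictor (Benjamini-Hochberg) and classifies each family per
#' predictor: `expanding` when significant with `r > 0`, `contracting`
#' when significant with `r < 0`, `ns` otherwise. Significant families
#' with `|r|` above `config$effect_r_threshold` additionally carry the
#' `strong` flag. Species are aligned by exact name intersection of tree,
#' traits and counts before fitting; species missing a predictor value
#' are dropped for the whole screen.
#'
#' @param counts Filtered integer matrix, families x species.
#' @param traits Trait table (raw or augmented; augmented on the fly).
#' @param tree An [ape::phylo] with branch lengths.
#' @param predictors Ordered pair from `ssd`, `log10_mass`, `rel_brain`
#'   (default `c("ssd", "log10_mass")`).
#' @param config An [analysis_config()].
#' @return A data frame (one row per family x predictor, intercept rows
#'   excluded) with columns `family`, `term`, `beta`, `se`, `t`, `df`,
#'   `p_raw`, `p_adj`, `r`, `call`, `strong`, `degenerate`, plus
#'   attributes `species` (those analysed) and `n_species`.
#' @export
screen_families <- function(counts, traits, tree,
                            predictors = c("ssd", "log10_mass"),
                            config = analysis_config()) {
  stopifnot(length(predictors) == 2)
  ok <- c("ssd", "log10_mass", "rel_brain")
  if (!all(predictors %in% ok)) {
    ssd_error(sprintf("predictors must be two of {%s}", paste(ok, collapse = ", ")),
              "ssd_domain_error")
  }
  if (!all(predictors %in% names(traits))) {
    traits <- augment_traits(traits)
  }
  if (!all(predictors %in% names(traits))) {
    ssd_error(sprintf("trait table cannot supply predictors: %s",
                      paste(setdiff(predictors, names(traits)), collapse = ", ")),
              "ssd_schema_error")
  }
  if (nrow(counts) == 0) {
    warning("no families to screen; returning an empty table")
    return(data.frame(family = character(0), term = character(0),
                      beta = numeric(0), se = numeric(0), t = numeric(0),
                      df = integer(0), p_raw = numeric(0), p_adj = numeric(0),
                      r = numeric(0), call = character(0), strong = logical(0),
                      degenerate = logical(0)))
  }
  species <- align_species(counts, traits, tree, predictors)
  traits <- traits[match(species, traits$species), ]
  Y <- t(counts[, species, drop = FALSE])   # species x families
  C <- phylo_covariance(tree, species)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(traits[, predictors, drop = FALSE]))
  n <- length(species)
  k <- ncol(X)
  df <- n - k
  ssd_log("info", sprintf(
    "PGLS screen: %d families, %d species, predictors = %s",
    ncol(Y), n, paste(predictors, collapse = " + ")))

  # whiten once, then solve all families in one least-squares pass
  R <- chol(C)
  Yw <- backsolve(R, Y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  colnames(Xw) <- colnames(X)
  XtX_inv <- solve(crossprod(Xw))
  beta <- XtX_inv %*% crossprod(Xw, Yw)          # k x m
  resid <- Yw - Xw %*% beta
  rss <- colSums(resid^2)
  sigma2 <- rss / df
  degenerate <- sigma2 <= .Machine$double.eps * pmax(1, colSums(Yw^2))
  se <- sqrt(outer(diag(XtX_inv), sigma2))       # k x m
  t_stat <- beta / se
  t_stat[, degenerate] <- NA_real_
  p_raw <- 2 * stats::pt(-abs(t_stat), df)

  fams <- colnames(Y)
  res <- do.call(rbind, lapply(predictors, function(pred) {
    pr <- p_raw[pred, ]
    pa <- bh_adjust(pr)
    r <- effect_size_r(t_stat[pred, ], df)
    gate <- if (config$use_raw_p) pr else pa
    call <- ifelse(is.na(gate) | gate >= config$alpha, "ns",
                   ifelse(r > 0, "expanding", "contracting"))
    data.frame(
      family = fams, term = pred, beta = beta[pred, ], se = se[pred, ],
      t = t_stat[pred, ], df = df, p_raw = pr, p_adj = pa, r = r,
      call = call,
      strong = call != "ns" & abs(r) > config$effect_r_threshold,
      degenerate = degenerate,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  n_deg <- sum(degenerate)
  if (n_deg > 0) {
    ssd_log("warn", sprintf("%d families had degenerate (perfect) fits", n_deg))
  }
  for (pred in predictors) {
    sub <- res[res$term == pred, ]
    ssd_log("info", sprintf(
      "  %s: %d expanding, %d contracting (alpha = %g on %s p)",
      pred, sum(sub$call == "expanding"), sum(sub$call == "contracting"),
      config$alpha, if (config$use_raw_p) "raw" else "BH-adjusted"))
  }
  attr(res, "species") <- species
  attr(res, "n_species") <- n
  res
}

#' Extract a focal family set from a screen result
#'
#' @param result A [screen_families()] table.
#' @param direction `"expanding"` or `"contracting"`.
#' @param term Predictor whose calls are used (default `"ssd"`).
#' @return Character vector of family identifiers.
#' @export
called_families <- function(result, direction = c("expanding", "contracting"),
                            term = "ssd") {
  direction <- match.arg(direction)
  sub <- result[result$term == term & result$call == direction, ]
  sub$family
}
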