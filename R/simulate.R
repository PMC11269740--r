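# Synthetic-data generators. Every generator is deterministic under a fixed
# seed and returns ground truth alongside the data so downstream stages can
# be validated by parameter recovery rather than by external data sets.

#' Simulate an ultrametric phylogeny
#'
#' Pure-birth (Yule) tree with unit birth rate, rescaled so the root-to-tip
#' depth is exactly 1; tips are relabelled `sp1..spN`. This is the stand-in
#' for a time-calibrated mammal phylogeny: the analyses depend on the tree
#' only through its Brownian covariance, for which an ultrametric branching
#' process is the structurally faithful minimal model.
#'
#' @param n_tips Number of tips (at least 2).
#' @param seed Integer seed; the same `(n_tips, seed)` always yields the
#'   identical tree.
#' @return An [ape::phylo] object with `n_tips` tips and root depth 1.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (!is_count(n_tips) || n_tips < 2) {
    ssd_error("n_tips must be an integer >= 2", "ssd_sim_error")
  }
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("sp", seq_len(n_tips))
  tree
}

# lower Cholesky factor of a 2x2 correlation-scaled covariance, valid for
# |rho| = 1 as well
chol2_lower <- function(s1, s2, rho) {
  matrix(c(s1, 0, rho * s2, s2 * sqrt(max(0, 1 - rho^2))),
         nrow = 2, byrow = TRUE)
}

# simulate k correlated Brownian traits along the tree edges; returns a
# tips x k matrix. root: numeric root states; L: lower Cholesky of the
# per-unit-time covariance.
brownian_traits <- function(tree, root, L) {
  k <- length(root)
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  vals <- matrix(NA_real_, nrow = n_node, ncol = k)
  root_id <- n_tip + 1L
  vals[root_id, ] <- root
  z <- matrix(stats::rnorm(k * nrow(tree$edge)), nrow = k)
  incr <- t(L %*% z) * sqrt(tree$edge.length)
  for (e in seq_len(nrow(tree$edge))) {
    vals[tree$edge[e, 2], ] <- vals[tree$edge[e, 1], ] + incr[e, ]
  }
  out <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate correlated SSD and body-mass traits on a tree
#'
#' Sexual size dimorphism (log2 male/female mass ratio) and log10 mean body
#' mass evolve as correlated Brownian motion: increments on a branch of
#' length l are bivariate normal with covariance l * Sigma, where Sigma has
#' standard deviations `sigma_ssd`, `sigma_bm` and correlation `rho`. Male
#' and female masses are back-derived by inverting the defining identities
#' ssd = log2(M/F) and mean = (M+F)/2, so [compute_ssd()] reproduces the
#' simulated SSD exactly. Optionally simulates brain mass as an allometric
#' power law of body mass plus an independent Brownian deviation.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param sigma_ssd,sigma_bm Brownian standard deviations per unit branch
#'   length for SSD and log10 body mass (defaults 0.4 and 1.2, giving
#'   tip-level spreads comparable to mammalian SSD and body-mass ranges on
#'   a depth-1 tree).
#' @param rho Correlation of the two diffusions, in `[-1, 1]` (default 0.4,
#'   a positive SSD-mass coupling of the kind Rensch's rule describes).
#' @param root_ssd,root_log10_mass Root states (defaults 0.3 and 3.5).
#' @param include_brain If `TRUE`, adds `brain_mass` via
#'   `log10(brain) = brain_intercept + brain_exponent * log10(body) + dev`,
#'   `dev` a Brownian deviation with SD `sigma_brain`.
#' @param brain_exponent,brain_intercept,sigma_brain Allometry parameters
#'   (defaults 0.75, -1.3, 0.1).
#' @param seed Integer seed.
#' @return A trait data frame with columns `species`, `male_mass`,
#'   `female_mass`, `mean_mass`, `ssd`, `log10_mass` (and `brain_mass` when
#'   requested).
#' @export
simulate_traits <- function(tree, sigma_ssd = 0.4, sigma_bm = 1.2, rho = 0.4,
                            root_ssd = 0.3, root_log10_mass = 3.5,
                            include_brain = FALSE, brain_exponent = 0.75,
                            brain_intercept = -1.3, sigma_brain = 0.1,
                            seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    ssd_error("tree has no branch lengths", "ssd_tree_error")
  }
  if (abs(rho) > 1 || sigma_ssd < 0 || sigma_bm < 0) {
    ssd_error("require |rho| <= 1 and nonnegative sigmas", "ssd_sim_error")
  }
  with_seed(seed, {
    L <- chol2_lower(sigma_ssd, sigma_bm, rho)
    tips <- brownian_traits(tree, c(root_ssd, root_log10_mass), L)
    ssd <- tips[, 1]
    log10_mass <- tips[, 2]
    mean_mass <- 10^log10_mass
    ratio <- 2^ssd  # male/female
    female <- 2 * mean_mass / (1 + ratio)
    male <- female * ratio
    traits <- data.frame(
      species = rownames(tips), male_mass = male, female_mass = female,
      mean_mass = mean_mass, ssd = ssd, log10_mass = log10_mass,
      stringsAsFactors = FALSE, row.names = NULL
    )
    if (include_brain) {
      dev <- brownian_traits(tree, 0, matrix(sigma_brain))[, 1]
      traits$brain_mass <-
        10^(brain_intercept + brain_exponent * log10_mass + dev)
    }
    traits
  })
}

#' Simulate a gene-family count matrix with planted trait effects
#'
#' For an associated family j the latent size of species i is
#' `a_j + b_j * SSD_i + u_i`, with `u ~ MVN(0, noise_sigma^2 * C)` and `C`
#' the Brownian covariance of the tree, so residuals carry exactly the
#' phylogenetic structure the PGLS screen assumes. Counts are the latent
#' values rounded and clipped at zero; baselines `a_j` are drawn so the
#' latent mean is Unif(4, 12), keeping mean counts at 3 or more. Effects
#' `b_j` are `+/- effect_scale` with random sign for a fraction
#' `frac_assoc` of families and 0 otherwise; the truth table records every
#' `b_j`.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param traits Trait table covering every tip (column `ssd`).
#' @param n_families Number of families to simulate.
#' @param frac_assoc Fraction of families with a nonzero SSD effect.
#' @param effect_scale Magnitude of the planted effect per SSD unit.
#' @param noise_sigma Brownian residual standard deviation (default 1).
#' @param model `"gaussian"` (rounded latent, matching the fitted model) or
#'   `"poisson"` (counts Poisson with the latent as mean, for robustness
#'   checks).
#' @param seed Integer seed.
#' @return A list with `counts` (integer matrix, families x species) and
#'   `truth` (data frame `family`, `b`, `associated`).
#' @export
simulate_family_counts <- function(tree, traits, n_families = 1000,
                                   frac_assoc = 0.1, effect_scale = 2,
                                   noise_sigma = 1,
                                   model = c("gaussian", "poisson"),
                                   seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"))
  if (frac_assoc < 0 || frac_assoc > 1) {
    ssd_error("frac_assoc must lie in [0, 1]", "ssd_sim_error")
  }
  missing <- setdiff(tree$tip.label, traits$species)
  if (length(missing) > 0) {
    ssd_error(sprintf("traits missing for tips: %s",
                      paste(utils::head(missing, 5), collapse = ", ")),
              "ssd_sim_error")
  }
  sp <- tree$tip.label
  ssd <- traits$ssd[match(sp, traits$species)]
  n_sp <- length(sp)
  C <- phylo_covariance(tree, sp)
  Lc <- t(chol(C))
  with_seed(seed, {
    n_assoc <- round(frac_assoc * n_families)
    fam <- sprintf("OG%05d", seq_len(n_families))
    b <- numeric(n_families)
    if (n_assoc > 0) {
      idx <- sample.int(n_families, n_assoc)
      b[idx] <- sample(c(-1, 1), n_assoc, replace = TRUE) * effect_scale
    }
    target_mean <- stats::runif(n_families, 4, 12)
    a <- target_mean - b * mean(ssd)
    u <- noise_sigma * (Lc %*% matrix(stats::rnorm(n_sp * n_families), n_sp))
    latent <- matrix(a, n_sp, n_families, byrow = TRUE) + outer(ssd, b) + u
    counts <- if (model == "gaussian") {
      pmax(round(latent), 0)
    } else {
      matrix(stats::rpois(length(latent), pmax(latent, 0.1)), n_sp)
    }
    counts <- t(counts)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(fam, sp)
    list(counts = counts,
         truth = data.frame(family = fam, b = b, associated = b != 0,
                            stringsAsFactors = FALSE))
  })
}

#' Calibrate a planted effect size for the PGLS screen
#'
#' Returns the SSD coefficient `b` whose true correlation-scale effect size
#' equals `target_r` under the screen's own generalized least squares
#' geometry: the expected t statistic for coefficient `b` with residual SD
#' `noise_sigma` is `b / (noise_sigma * sqrt([(X' C^-1 X)^-1]_jj))`, and
#' `r = t / sqrt(t^2 + df)` is inverted at the target.
#'
#' @param tree,traits Tree and trait table as in [simulate_family_counts()].
#' @param target_r Desired absolute effect size in (0, 1).
#' @param noise_sigma Residual SD the counts will be simulated with.
#' @param predictors Predictor pair the screen will use.
#' @return The positive effect magnitude `b`.
#' @export
calibrate_effect_scale <- function(tree, traits, target_r = 0.5,
                                   noise_sigma = 1,
                                   predictors = c("ssd", "log10_mass")) {
  stopifnot(target_r > 0, target_r < 1)
  sp <- intersect(tree$tip.label, traits$species)
  traits <- traits[match(sp, traits$species), ]
  C <- phylo_covariance(tree, sp)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(traits[, predictors, drop = FALSE]))
  n <- length(sp)
  df <- n - ncol(X)
  t_target <- target_r * sqrt(df / (1 - target_r^2))
  R <- chol(C)
  Xw <- backsolve(R, X, transpose = TRUE)
  colnames(Xw) <- colnames(X)
  XtX_inv <- solve(crossprod(Xw))
  se_unit <- sqrt(XtX_inv[predictors[1], predictors[1]])
  t_target * noise_sigma * se_unit
}

#' Simulate gene-level GO annotations with one planted enriched term
#'
#' Background terms are assigned to families uniformly at random; one
#' planted term draws `round(focal_overlap * planted_term_size)` of its
#' member families from the designated focal set and the remainder from
#' outside it. Families carry `genes_per_family` genes and each term-family
#' link is realized through one or more member genes, so the gene-to-family
#' collapse of [map_go_to_families()] is exercised end to end.
#'
#' @param families Character vector of family identifiers.
#' @param n_terms Number of background terms.
#' @param planted_term_size Number of families carrying the planted term.
#' @param focal Character vector of focal family identifiers.
#' @param focal_overlap Fraction of the planted term's families drawn from
#'   the focal set.
#' @param term_size_range Range of background term sizes (families).
#' @param genes_per_family Genes per family (default 3).
#' @param seed Integer seed.
#' @return A list with `gene_go` (data frame gene, term), `membership`
#'   (data frame gene, family) and `truth` (list with `planted_term`,
#'   `planted_families`, and per-term `planted` flags).
#' @export
simulate_go_annotations <- function(families, n_terms = 30,
                                    planted_term_size = 30, focal = NULL,
                                    focal_overlap = 1,
                                    term_size_range = c(60, 120),
                                    genes_per_family = 3, seed = NULL) {
  if (planted_term_size > length(families)) {
    ssd_error("planted_term_size exceeds the number of families", "ssd_sim_error")
  }
  focal <- focal %||% character(0)
  if (!all(focal %in% families)) {
    ssd_error("focal families must be a subset of `families`", "ssd_sim_error")
  }
  n_focal_members <- round(focal_overlap * planted_term_size)
  if (n_focal_members > length(focal)) {
    ssd_error("focal_overlap demands more focal families than exist", "ssd_sim_error")
  }
  non_focal <- setdiff(families, focal)
  if (planted_term_size - n_focal_members > length(non_focal)) {
    ssd_error("not enough non-focal families for the planted term", "ssd_sim_error")
  }
  with_seed(seed, {
    membership <- data.frame(
      gene = paste0(rep(families, each = genes_per_family), "_g",
                    seq_len(genes_per_family)),
      family = rep(families, each = genes_per_family),
      stringsAsFactors = FALSE
    )
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    planted_term <- "GO:PLANTED"
    sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms,
                    replace = TRUE)
    sizes <- pmin(sizes, length(families))
    edges <- data.frame(term = rep(terms, sizes),
                        family = unlist(lapply(sizes, function(k)
                          sample(families, k))),
                        stringsAsFactors = FALSE)
    planted_families <- c(
      if (n_focal_members > 0) sample(focal, n_focal_members),
      if (planted_term_size - n_focal_members > 0)
        sample(non_focal, planted_term_size - n_focal_members)
    )
    edges <- rbind(edges, data.frame(term = planted_term,
                                     family = planted_families,
                                     stringsAsFactors = FALSE))
    # realize each term-family link through 1..genes_per_family carrier genes
    n_carriers <- sample.int(genes_per_family, nrow(edges), replace = TRUE)
    gene_go <- data.frame(
      term = rep(edges$term, n_carriers),
      gene = unlist(Map(function(fam, k)
        paste0(fam, "_g", sample.int(genes_per_family, k)), edges$family,
        n_carriers)),
      stringsAsFactors = FALSE, row.names = NULL
    )[, c("gene", "term")]
    list(
      gene_go = gene_go,
      membership = membership,
      truth = list(
        planted_term = planted_term,
        planted_families = sort(planted_families),
        terms = data.frame(term = c(terms, planted_term),
                           planted = c(rep(FALSE, n_terms), TRUE),
                           stringsAsFactors = FALSE)
      )
    )
  })
}

#' Default developmental-stage table for expression simulations
#'
#' @param n_prenatal,n_adult Number of prenatal and adult stages.
#' @return Data frame with columns `stage`, `age`, `phase`; prenatal ages
#'   are in weeks post-conception, adult ages in years.
#' @export
default_stages <- function(n_prenatal = 0, n_adult = 1) {
  rbind(
    if (n_prenatal > 0)
      data.frame(stage = paste0("pcw", seq(8, length.out = n_prenatal, by = 4)),
                 age = seq(8, length.out = n_prenatal, by = 4) / 52,
                 phase = "prenatal", stringsAsFactors = FALSE),
    if (n_adult > 0)
      data.frame(stage = paste0("yr", seq(20, length.out = n_adult, by = 10)),
                 age = seq(20, length.out = n_adult, by = 10),
                 phase = "adult", stringsAsFactors = FALSE)
  )
}

#' Simulate an expression table with planted brain and sex biases
#'
#' Baseline log2 expression is `mu_g + noise`, with a per-gene level
#' `mu_g ~ N(baseline_mean, gene_mean_sd)` and i.i.d. noise per
#' gene x tissue x stage x sex cell. Genes in `brain_bias_set` receive a
#' fixed positive shift of `brain_shift` log2 units in the brain tissues;
#' female cells receive the gene's specified log2 fold change relative to
#' male. Values are returned on the raw scale as `2^L - 1`, so the
#' pipeline's log2(x + 1) transform recovers the simulated log scale
#' exactly.
#'
#' @param n_genes Number of genes (`g0001..`).
#' @param tissues Character vector of tissue labels; must contain the brain
#'   tissue(s).
#' @param stages Data frame as from [default_stages()] (columns `stage`,
#'   `age`, `phase`).
#' @param brain_bias_set Genes receiving the brain shift.
#' @param sexbias_spec Named numeric vector of per-gene log2 fold changes
#'   (female over male); unnamed genes get 0.
#' @param brain_tissues Tissues counted as brain (default `"brain"`).
#' @param brain_shift Planted brain shift in log2 units (default 3).
#' @param baseline_mean,gene_mean_sd,noise_sd Baseline level parameters
#'   (defaults 5, 1, 1 on the log2 scale).
#' @param sexes Sex labels simulated (default female and male).
#' @param seed Integer seed.
#' @return A list with `expr` (data frame gene, tissue, stage, age, phase,
#'   sex, value) and `truth` (list `brain_bias`, `sexbias`).
#' @export
simulate_expression <- function(n_genes = 500,
                                tissues = c("brain", paste0("tissue", 1:19)),
                                stages = default_stages(),
                                brain_bias_set = character(0),
                                sexbias_spec = numeric(0),
                                brain_tissues = "brain",
                                brain_shift = 3,
                                baseline_mean = 5, gene_mean_sd = 1,
                                noise_sd = 1,
                                sexes = c("female", "male"),
                                seed = NULL) {
  if (!all(brain_tissues %in% tissues)) {
    ssd_error("brain tissue label must be present in `tissues`", "ssd_sim_error")
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (!all(brain_bias_set %in% genes)) {
    ssd_error("brain_bias_set contains unknown genes", "ssd_sim_error")
  }
  if (length(sexbias_spec) > 0 && !all(names(sexbias_spec) %in% genes)) {
    ssd_error("sexbias_spec contains unknown genes", "ssd_sim_error")
  }
  log2fc <- stats::setNames(numeric(n_genes), genes)
  log2fc[names(sexbias_spec)] <- sexbias_spec
  with_seed(seed, {
    mu <- stats::setNames(stats::rnorm(n_genes, baseline_mean, gene_mean_sd),
                          genes)
    grid <- expand.grid(gene = genes, tissue = tissues, stage = stages$stage,
                        sex = sexes, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid$age <- stages$age[match(grid$stage, stages$stage)]
    grid$phase <- stages$phase[match(grid$stage, stages$stage)]
    L <- mu[grid$gene] + stats::rnorm(nrow(grid), 0, noise_sd)
    L <- L + brain_shift * (grid$gene %in% brain_bias_set &
                              grid$tissue %in% brain_tissues)
    L <- L + log2fc[grid$gene] * (grid$sex == "female")
    grid$value <- pmax(0, 2^L - 1)
    rownames(grid) <- NULL
    list(expr = grid[, c("gene", "tissue", "stage", "age", "phase", "sex",
                         "value")],
         truth = list(brain_bias = brain_bias_set, sexbias = log2fc))
  })
}
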