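test_that("phylogenetic covariance equals shared root-path lengths", {
  C <- phylo_covariance(toy_tree3(), c("A", "B", "C"))
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))

  star <- make_star_tree(5, len = 1.5)
  Cs <- phylo_covariance(star)
  expect_equal(unname(Cs), 1.5 * diag(5))

  tree <- simulate_tree(8, seed = 31)
  expect_equal(phylo_covariance(tree), cov_path_oracle(tree), tolerance = 1e-12)

  # pruning: request a subset in a chosen order
  sub <- phylo_covariance(tree, c("sp5", "sp2", "sp8"))
  expect_identical(rownames(sub), c("sp5", "sp2", "sp8"))
  expect_equal(sub, cov_path_oracle(tree)[c("sp5", "sp2", "sp8"),
                                          c("sp5", "sp2", "sp8")],
               tolerance = 1e-12)

  expect_error(phylo_covariance(tree, c("sp1", "nosuch")),
               "nosuch", class = "ssd_tree_error")
})

test_that("pgls_fit matches the dense-inverse oracle and reduces to OLS at C = I", {
  tree <- tree6()
  C <- phylo_covariance(tree)
  sp <- rownames(C)
  withr::with_seed(41, {
    X <- cbind(`(Intercept)` = 1, x1 = rnorm(6), x2 = rnorm(6))
    y <- 2 + 0.5 * X[, "x1"] + rnorm(6)
  })
  fit <- pgls_fit(y, X, C)
  oracle <- gls_oracle(y, X, C)
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)
  expect_equal(unname(fit$t), unname(oracle$t), tolerance = 1e-8)
  expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-8)
  expect_equal(fit$df, 3L)

  ols <- lm(y ~ X[, "x1"] + X[, "x2"])
  id_fit <- pgls_fit(y, X, diag(6))
  sm <- summary(ols)$coefficients
  expect_equal(unname(id_fit$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(id_fit$se), unname(sm[, "Std. Error"]), tolerance = 1e-8)
  expect_equal(unname(id_fit$p_raw), unname(sm[, "Pr(>|t|)"]), tolerance = 1e-8)

  # perfect fit: degenerate flag, no division by zero
  perfect <- pgls_fit(drop(X %*% c(1, 2, -1)), X, C)
  expect_true(perfect$degenerate)
  expect_true(all(is.na(perfect$t)))

  expect_error(pgls_fit(y, cbind(X, x3 = X[, "x1"]), C),
               class = "ssd_domain_error")
})

test_that("pgls_fit is invariant to rescaling C and agrees with nlme::gls", {
  # ultrametric tree: corBrownian is then a proper correlation structure and
  # nlme::gls is an independent route to the same GLS solution
  tree <- simulate_tree(8, seed = 40)
  C <- phylo_covariance(tree)
  withr::with_seed(42, {
    x1 <- rnorm(8)
    y <- 1 + x1 + rnorm(8)
  })
  X <- cbind(`(Intercept)` = 1, x1 = x1)
  f1 <- pgls_fit(y, X, C)
  f2 <- pgls_fit(y, X, 3.7 * C)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$t, f2$t, tolerance = 1e-10)
  expect_equal(f1$sigma2, 3.7 * f2$sigma2, tolerance = 1e-8)
  expect_equal(f1$beta, gls_oracle(y, X, C)$beta, tolerance = 1e-10)

  dat <- data.frame(y = y, x1 = x1, sp = rownames(C))
  gfit <- nlme::gls(y ~ x1, data = dat,
                    correlation = ape::corBrownian(1, tree, form = ~sp))
  ct <- summary(gfit)$tTable
  expect_equal(unname(f1$beta), unname(ct[, "Value"]), tolerance = 1e-6)
  expect_equal(unname(f1$t), unname(ct[, "t-value"]), tolerance = 1e-6)
})

test_that("effect sizes are the r-from-t transform with its algebraic identities", {
  expect_equal(effect_size_r(0, 10), 0)
  expect_equal(effect_size_r(11, 121), 1 / sqrt(2))
  r <- effect_size_r(-2.76, 121)
  expect_lt(abs(r - (-0.243)), 1e-3)
  # round trip: t back from r
  expect_equal(r * sqrt(121 / (1 - r^2)), -2.76, tolerance = 1e-10)
  # strictly increasing in t
  ts <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(effect_size_r(ts, 30)) > 0))
  expect_true(all(abs(effect_size_r(c(-1e6, 1e6), 5)) < 1))
  expect_error(effect_size_r(1, 0), class = "ssd_domain_error")
})

test_that("BH adjustment matches the literal step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  withr::with_seed(43, {
    for (i in 1:5) {
      p <- runif(sample(5:50, 1))
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), class = "ssd_domain_error")
})

test_that("on a star tree the screen equals an OLS screen", {
  star <- make_star_tree(30, len = 1)
  traits <- simulate_traits(star, seed = 51)
  fc <- simulate_family_counts(star, traits, n_families = 40, frac_assoc = 0.5,
                               effect_scale = 2, seed = 52)
  screen <- screen_families(fc$counts, traits, star)
  sub <- screen[screen$term == "ssd", ]
  for (i in c(1, 7, 25)) {
    fam <- sub$family[i]
    ols <- summary(lm(fc$counts[fam, ] ~ traits$ssd + traits$log10_mass))
    expect_equal(sub$beta[i], ols$coefficients["traits$ssd", "Estimate"],
                 tolerance = 1e-8)
    expect_equal(sub$t[i], ols$coefficients["traits$ssd", "t value"],
                 tolerance = 1e-8)
    expect_equal(sub$p_raw[i], ols$coefficients["traits$ssd", "Pr(>|t|)"],
                 tolerance = 1e-8)
  }
})

test_that("the screen recovers planted effects and loses them under permutation", {
  tree <- simulate_tree(60, seed = 61)
  traits <- simulate_traits(tree, seed = 62)
  b <- calibrate_effect_scale(tree, traits, target_r = 0.7)
  fc <- simulate_family_counts(tree, traits, n_families = 300,
                               frac_assoc = 0.2, effect_scale = b, seed = 63)
  screen <- screen_families(fc$counts, traits, tree)
  sub <- screen[screen$term == "ssd", ]
  truth <- fc$truth[match(sub$family, fc$truth$family), ]

  called <- sub$call != "ns"
  expect_gt(mean(called[truth$associated]), 0.8)
  # signs agree with the planted direction for every planted call
  agree <- sign(sub$r[truth$associated & called]) ==
    sign(truth$b[truth$associated & called])
  expect_true(all(agree))
  # r and call consistency invariants
  expect_true(all(abs(sub$r) < 1))
  expect_true(all(sign(sub$r[called]) ==
                    ifelse(sub$call[called] == "expanding", 1, -1)))
  expect_true(all(sub$p_adj >= sub$p_raw - 1e-12, na.rm = TRUE))

  # permuting species columns breaks the trait linkage: discoveries collapse
  withr::with_seed(64, {
    perm <- fc$counts
    colnames(perm) <- sample(colnames(perm))
  })
  perm_screen <- screen_families(perm, traits, tree)
  perm_calls <- sum(perm_screen$call[perm_screen$term == "ssd"] != "ns")
  expect_lt(perm_calls, 0.05 * nrow(sub))
})

test_that("the screen accepts the relative-brain-size covariate", {
  tree <- simulate_tree(40, seed = 71)
  traits <- simulate_traits(tree, include_brain = TRUE, seed = 72)
  fc <- simulate_family_counts(tree, traits, n_families = 30, seed = 73)
  screen <- screen_families(fc$counts, traits, tree,
                            predictors = c("ssd", "rel_brain"))
  expect_setequal(unique(screen$term), c("ssd", "rel_brain"))
  expect_equal(nrow(screen), 60)
  # dropping brain data for some species shrinks the analysed set, not the run
  traits2 <- traits
  traits2$brain_mass[1:5] <- NA
  traits2$rel_brain <- NULL
  screen2 <- screen_families(fc$counts, augment_traits(traits2), tree,
                             predictors = c("ssd", "rel_brain"))
  expect_equal(attr(screen2, "n_species"), 35)
})
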