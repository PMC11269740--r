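test_that("simulated trees are deterministic, binary, depth-1 and correctly sized", {
  t1 <- simulate_tree(124, seed = 1)
  t2 <- simulate_tree(124, seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_length(t1$tip.label, 124)
  expect_equal(t1$Nnode, 123)
  expect_true(all(t1$edge.length > 0))
  expect_equal(max(ape::node.depth.edgelength(t1)), 1)

  t3 <- simulate_tree(2, seed = 5)
  expect_setequal(t3$tip.label, c("sp1", "sp2"))
  expect_error(simulate_tree(1), class = "ssd_sim_error")

  expect_false(identical(ape::write.tree(simulate_tree(124, seed = 2)),
                         ape::write.tree(t1)))
})

test_that("trait diffusion on a star tree has the analytic tip variance and zero cross-covariance at rho = 0", {
  star <- make_star_tree(20, len = 2)
  reps <- 400
  ssd_mat <- matrix(NA_real_, reps, 20)
  bm_mat <- matrix(NA_real_, reps, 20)
  for (r in seq_len(reps)) {
    tt <- simulate_traits(star, sigma_ssd = 0.5, sigma_bm = 1, rho = 0,
                          seed = 1000 + r)
    ssd_mat[r, ] <- tt$ssd
    bm_mat[r, ] <- tt$log10_mass
  }
  # tip variance = branch length * sigma^2; MC SE of a variance over 400
  # replicates is about var * sqrt(2/399), use 4 SEs on the tip average
  v_ssd <- mean(apply(ssd_mat, 2, var))
  v_bm <- mean(apply(bm_mat, 2, var))
  expect_equal(v_ssd, 2 * 0.5^2, tolerance = 4 * sqrt(2 / 399) / sqrt(20))
  expect_equal(v_bm, 2 * 1^2, tolerance = 4 * sqrt(2 / 399) / sqrt(20))
  cross <- mean(sapply(seq_len(20), function(i) cov(ssd_mat[, i], bm_mat[, i])))
  expect_lt(abs(cross), 4 * sqrt(2 * 0.25 * 2 * 1 / 399) / sqrt(20))
})

test_that("replicated tip covariance converges to sigma^2 C on a fixed tree", {
  tree <- simulate_tree(8, seed = 7)
  C <- phylo_covariance(tree)
  reps <- 400
  vals <- matrix(NA_real_, reps, 8)
  for (r in seq_len(reps)) {
    vals[r, ] <- simulate_traits(tree, sigma_ssd = 1, sigma_bm = 1, rho = 0,
                                 seed = 2000 + r)$ssd
  }
  emp <- cov(vals)
  expect_lt(max(abs(emp - C)), 5 / sqrt(reps))
})

test_that("degenerate diffusion and mass back-derivation behave exactly", {
  tree <- simulate_tree(10, seed = 3)
  tt0 <- simulate_traits(tree, sigma_ssd = 0, sigma_bm = 1, rho = 0,
                         root_ssd = 0.3, seed = 4)
  expect_equal(tt0$ssd, rep(0.3, 10))

  tt <- simulate_traits(tree, seed = 5)
  expect_equal(compute_ssd(tt$male_mass, tt$female_mass), tt$ssd,
               tolerance = 1e-12)
  expect_equal((tt$male_mass + tt$female_mass) / 2, tt$mean_mass,
               tolerance = 1e-12)
  expect_error(simulate_traits(tree, rho = 1.5), class = "ssd_sim_error")
})

test_that("family-count truth labels partition families exactly as configured", {
  tree <- simulate_tree(20, seed = 1)
  traits <- simulate_traits(tree, seed = 2)
  fc <- simulate_family_counts(tree, traits, n_families = 1000,
                               frac_assoc = 0.1, effect_scale = 1, seed = 3)
  expect_equal(sum(fc$truth$b != 0), 100)
  expect_identical(fc$truth$associated, fc$truth$b != 0)
  expect_true(all(fc$counts >= 0))
  expect_type(fc$counts, "integer")
  expect_identical(dim(fc$counts), c(1000L, 20L))
  expect_true(mean(fc$counts) >= 3)

  fc0 <- simulate_family_counts(tree, traits, n_families = 50,
                                frac_assoc = 0, seed = 4)
  expect_true(all(fc0$truth$b == 0))
  fc1 <- simulate_family_counts(tree, traits, n_families = 50,
                                frac_assoc = 1, effect_scale = 0, seed = 4)
  expect_true(all(fc1$truth$b == 0))

  again <- simulate_family_counts(tree, traits, n_families = 1000,
                                  frac_assoc = 0.1, effect_scale = 1, seed = 3)
  expect_identical(fc$counts, again$counts)
})

test_that("GO generator plants its term at the requested focal overlap", {
  fams <- sprintf("OG%04d", 1:300)
  focal <- fams[1:40]
  go <- simulate_go_annotations(fams, n_terms = 10, planted_term_size = 30,
                                focal = focal, focal_overlap = 1,
                                term_size_range = c(50, 80), seed = 1)
  expect_true(all(go$truth$planted_families %in% focal))
  expect_length(go$truth$planted_families, 30)
  edges <- map_go_to_families(go$gene_go, go$membership)
  planted_edges <- edges$family[edges$term == go$truth$planted_term]
  expect_setequal(planted_edges, go$truth$planted_families)

  again <- simulate_go_annotations(fams, n_terms = 10, planted_term_size = 30,
                                   focal = focal, focal_overlap = 1,
                                   term_size_range = c(50, 80), seed = 1)
  expect_identical(go$gene_go, again$gene_go)

  expect_error(
    simulate_go_annotations(fams, planted_term_size = 30, focal = fams[1:10],
                            focal_overlap = 1),
    class = "ssd_sim_error"
  )
})

test_that("expression generator recovers its planted sex and brain effects", {
  planted <- sprintf("g%04d", 1:20)
  sexed <- sprintf("g%04d", 21:40)
  sim <- simulate_expression(
    n_genes = 60, tissues = c("brain", paste0("t", 1:15)),
    stages = default_stages(n_prenatal = 2, n_adult = 2),
    brain_bias_set = planted, brain_shift = 8,
    sexbias_spec = stats::setNames(rep(2, 20), sexed), seed = 9
  )
  expr <- sim$expr
  # planted sex effect: mean female-minus-male difference on log2(x+1) scale
  l2 <- log2(expr$value + 1)
  fm <- tapply(l2, list(expr$gene, expr$sex), mean)
  diffs <- fm[sexed, "female"] - fm[sexed, "male"]
  expect_equal(unname(mean(diffs)), 2, tolerance = 0.15)
  null_diffs <- fm[planted, "female"] - fm[planted, "male"]
  expect_lt(abs(mean(null_diffs)), 0.15)

  # brain shift far above noise: planted genes rank 0 (brain is top tissue)
  rk <- brain_rank(expr, planted, "brain")
  expect_equal(rk$mean_rank, 0)

  expect_error(simulate_expression(n_genes = 5, brain_bias_set = "g9999"),
               class = "ssd_sim_error")
  again <- simulate_expression(
    n_genes = 60, tissues = c("brain", paste0("t", 1:15)),
    stages = default_stages(n_prenatal = 2, n_adult = 2),
    brain_bias_set = planted, brain_shift = 8,
    sexbias_spec = stats::setNames(rep(2, 20), sexed), seed = 9
  )
  expect_identical(expr$value, again$expr$value)
})
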