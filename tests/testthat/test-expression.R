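test_that("brain rank counts strictly higher non-brain tissues", {
  tissues <- c("brain", paste0("t", 1:48))
  top <- do.call(rbind, Map(expr_row, "gTop", tissues, c(100, runif(48, 0, 50))))
  bottom <- do.call(rbind, Map(expr_row, "gBot", tissues, c(0.1, runif(48, 1, 50))))
  tied <- do.call(rbind, Map(expr_row, "gTie", tissues, rep(5, 49)))
  expr <- rbind(top, bottom, tied)

  expect_equal(brain_rank(expr, "gTop", "brain")$mean_rank, 0)
  expect_equal(brain_rank(expr, "gBot", "brain")$mean_rank, 48)
  # ties do not increment the rank (strict inequality)
  expect_equal(brain_rank(expr, "gTie", "brain")$mean_rank, 0)

  # invariance under a strictly increasing transform
  expr2 <- expr
  expr2$value <- sqrt(expr2$value) + 3
  expect_equal(brain_rank(expr2, c("gTop", "gBot"), "brain")$mean_rank,
               brain_rank(expr, c("gTop", "gBot"), "brain")$mean_rank)

  expect_error(brain_rank(expr, "gTop", "nope"), class = "ssd_validation_error")
})

test_that("exchangeable expression gives mean rank (T-1)/2", {
  T_n <- 21
  sim <- simulate_expression(n_genes = 400,
                             tissues = c("brain", paste0("t", 1:(T_n - 1))),
                             stages = default_stages(n_adult = 1), seed = 91)
  rk <- brain_rank(sim$expr, sprintf("g%04d", 1:400), "brain")
  # per-gene rank is uniform on 0..T-1: SD = sqrt((T^2-1)/12)
  se <- sqrt((T_n^2 - 1) / 12) / sqrt(400)
  expect_equal(rk$mean_rank, (T_n - 1) / 2, tolerance = 3 * se / ((T_n - 1) / 2))
  expect_equal(rk$n_tissues, T_n)
})

test_that("the rank bootstrap is seeded, centred and sensitive to planted bias", {
  planted <- sprintf("g%04d", 1:50)
  sim <- simulate_expression(n_genes = 300,
                             tissues = c("brain", paste0("t", 1:19)),
                             brain_bias_set = planted, brain_shift = 8,
                             stages = default_stages(n_adult = 1), seed = 92)
  cfg <- analysis_config(n_resamples = 100)
  r1 <- bootstrap_rank_p(sim$expr, planted, cfg, seed = 93)
  r2 <- bootstrap_rank_p(sim$expr, planted, cfg, seed = 93)
  expect_identical(r1$p_boot, r2$p_boot)
  expect_equal(r1$p_boot, 1 / 101)

  # focal = whole background: observed mean is the population mean, p ~ 0.5
  all_genes <- sprintf("g%04d", 1:300)
  rall <- bootstrap_rank_p(sim$expr, all_genes,
                           analysis_config(n_resamples = 2000), seed = 94)
  expect_gt(rall$p_boot, 0.35)
  expect_lt(rall$p_boot, 0.65)
})

test_that("temporal trajectories recover exact lines and match an OLS oracle", {
  regions <- brain_structure_groups()$cortex[1:4]
  stages <- paste0("s", 1:6)
  grid <- expand.grid(gene = c("g1", "g2"), tissue = regions, stage = stages,
                      stringsAsFactors = FALSE)
  grid$sex <- "female"
  grid$phase <- "prenatal"

  # constant expression: slope 0
  grid$value <- 7
  expect_equal(temporal_trajectory(grid, c("g1", "g2"), "cortex",
                                   stages = stages)$slope, 0, tolerance = 1e-12)

  # exact increase of d per stage on the log2(x+1) scale
  d <- 0.4
  idx <- match(grid$stage, stages)
  grid$value <- 2^(1 + d * idx) - 1
  expect_equal(temporal_trajectory(grid, c("g1", "g2"), "cortex",
                                   stages = stages)$slope, d, tolerance = 1e-9)

  # random table: slope equals a direct lm on the stage means
  withr::with_seed(95, grid$value <- runif(nrow(grid), 0, 100))
  traj <- temporal_trajectory(grid, c("g1", "g2"), "cortex", stages = stages)
  per_gene <- aggregate(log2(value + 1) ~ gene + stage, data = grid, FUN = mean)
  means <- aggregate(per_gene[[3]], list(stage = per_gene$stage), mean)
  means <- means[match(stages, means$stage), ]
  oracle <- unname(coef(lm(means$x ~ seq_along(stages)))[2])
  expect_equal(traj$slope, oracle, tolerance = 1e-9)
  expect_equal(traj$stage_means$mean_expr, means$x, tolerance = 1e-12)

  expect_error(temporal_trajectory(grid[grid$stage %in% stages[1:2], ],
                                   c("g1", "g2"), "cortex"),
               class = "ssd_validation_error")
  expect_error(temporal_trajectory(grid, "g1", "cerebellum"),
               class = "ssd_validation_error")
})

test_that("sex-biased fold changes recover planted effects and respect symmetries", {
  make_pairs <- function(gene, fvals, mvals, phase = "adult") {
    rbind(
      do.call(rbind, Map(expr_row, gene, "A1C", fvals,
                         paste0("st", seq_along(fvals)), "female", phase)),
      do.call(rbind, Map(expr_row, gene, "A1C", mvals,
                         paste0("st", seq_along(mvals)), "male", phase))
    )
  }
  # female exactly 4x male at large values: log2fc ~ 2
  m <- c(400, 800, 1600, 3200, 6400)
  expr4 <- make_pairs("g1", 4 * m, m)
  sb <- sexbias_foldchange(expr4, "g1", "adult")
  expect_equal(sb$median_log2fc, 2, tolerance = 0.01)

  # identical values: all fold changes 0, p = 1 by convention
  expr0 <- make_pairs("g2", m, m)
  sb0 <- sexbias_foldchange(expr0, "g2", "adult")
  expect_equal(sb0$median_log2fc, 0)
  expect_equal(sb0$p_wilcoxon, 1)
  expect_true(sb0$all_zero)

  # swapping the sex labels negates log2fc and leaves p unchanged
  withr::with_seed(96, {
    f <- runif(8, 10, 1000); g <- runif(8, 10, 1000)
  })
  e1 <- make_pairs("g3", f, g)
  e2 <- e1
  e2$sex <- ifelse(e1$sex == "female", "male", "female")
  s1 <- sexbias_foldchange(e1, "g3", "adult")
  s2 <- sexbias_foldchange(e2, "g3", "adult")
  expect_equal(attr(s1, "log2fc")$g3, -attr(s2, "log2fc")$g3, tolerance = 1e-12)
  expect_equal(s1$p_wilcoxon, s2$p_wilcoxon, tolerance = 1e-12)

  # prenatal and adult phases never share samples
  both <- rbind(make_pairs("g4", f, g, "adult"),
                make_pairs("g4", 2 * f, g, "prenatal"))
  sa <- sexbias_foldchange(both, "g4", "adult")
  sp <- sexbias_foldchange(both, "g4", "prenatal")
  expect_false(isTRUE(all.equal(sa$median_log2fc, sp$median_log2fc)))
  expect_equal(sa$n_pairs + sp$n_pairs, 16)
})

test_that("generator truth is recovered: planted log2FC and null uniformity", {
  planted <- sprintf("g%04d", 1:25)
  sim <- simulate_expression(
    n_genes = 60, tissues = paste0("r", 1:5), brain_tissues = "r1",
    stages = default_stages(n_prenatal = 6, n_adult = 2),
    sexbias_spec = stats::setNames(rep(1.5, 25), planted), seed = 97
  )
  sb <- sexbias_foldchange(sim$expr, sprintf("g%04d", 1:60), "prenatal")
  expect_equal(median(sb$median_log2fc[sb$gene %in% planted]), 1.5,
               tolerance = 0.15)
  null_p <- sb$p_wilcoxon[!sb$gene %in% planted]
  # discrete Wilcoxon p-values tie occasionally; the KS check stays valid
  expect_gt(suppressWarnings(stats::ks.test(null_p, "punif"))$p.value, 0.01)
  planted_adj <- sb$p_adj[sb$gene %in% planted]
  expect_gt(mean(planted_adj < 0.05), 0.9)
})
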