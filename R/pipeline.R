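# End-to-end pipeline driver and the command-line dispatch used by
# inst/scripts/ssdscreen.R. Each subcommand is a thin wrapper over the
# exported functions; all randomness flows through a single --seed.

#' Write a full synthetic study into a directory
#'
#' Generates a tree, traits, family counts, GO annotations and an
#' expression table with known ground truth, and writes them (Newick +
#' TSV) into `out_dir`. The planted families double as the focal set for
#' the GO generator and the planted brain-bias / sex-bias sets for the
#' expression generator, so one simulated study exercises every stage.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_tips,n_families,frac_assoc,effect_scale,noise_sigma Generator
#'   parameters (see [simulate_family_counts()]).
#' @param n_genes,sexbias_log2fc Expression generator parameters.
#' @param seed Integer seed governing every generator.
#' @param config An [analysis_config()].
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_study <- function(out_dir, n_tips = 124, n_families = 1000,
                           frac_assoc = 0.1, effect_scale = 2,
                           noise_sigma = 1, n_genes = 500,
                           sexbias_log2fc = 2, seed = 1,
                           config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(n_tips, seed = seed)
  traits <- simulate_traits(tree, include_brain = TRUE, seed = seed + 1)
  fc <- simulate_family_counts(tree, traits, n_families = n_families,
                               frac_assoc = frac_assoc,
                               effect_scale = effect_scale,
                               noise_sigma = noise_sigma, seed = seed + 2)
  focal <- fc$truth$family[fc$truth$associated]
  planted_size <- max(2, min(30, length(focal)))
  go <- simulate_go_annotations(
    fc$truth$family, n_terms = 30, planted_term_size = planted_size,
    focal = focal, focal_overlap = 1, seed = seed + 3
  )
  genes <- sprintf("g%04d", seq_len(n_genes))
  brain_set <- genes[seq_len(min(50, n_genes))]
  sex_set <- genes[seq(min(51, n_genes), min(100, n_genes))]
  ex <- simulate_expression(
    n_genes = n_genes, stages = default_stages(n_prenatal = 5, n_adult = 5),
    brain_bias_set = brain_set,
    sexbias_spec = stats::setNames(rep(sexbias_log2fc, length(sex_set)), sex_set),
    seed = seed + 4
  )
  paths <- list(
    tree = file.path(out_dir, "tree.nwk"),
    traits = file.path(out_dir, "traits.tsv"),
    counts = file.path(out_dir, "family_counts.tsv"),
    family_truth = file.path(out_dir, "family_truth.tsv"),
    gene_go = file.path(out_dir, "gene_go.tsv"),
    membership = file.path(out_dir, "gene_family.tsv"),
    go_truth = file.path(out_dir, "go_truth.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    expression_truth = file.path(out_dir, "expression_truth.tsv")
  )
  write_newick(tree, paths$tree)
  write_results(traits[, c("species", "male_mass", "female_mass", "brain_mass")],
                paths$traits)
  write_results(fc$counts, paths$counts)
  write_results(fc$truth, paths$family_truth)
  write_results(go$gene_go, paths$gene_go)
  write_results(go$membership, paths$membership)
  write_results(go$truth$terms, paths$go_truth)
  write_results(ex$expr, paths$expression)
  write_results(
    data.frame(gene = genes, brain_bias = genes %in% brain_set,
               sex_log2fc = unname(ex$truth$sexbias[genes])),
    paths$expression_truth
  )
  ssd_log("info", sprintf("simulated study written to %s (seed %d)", out_dir, seed))
  invisible(paths)
}

#' Run the full analysis pipeline on a simulated or on-disk study
#'
#' Chains phenotype derivation, the Rensch test, family filtering, the
#' PGLS screen, GO enrichment of expanding and contracting families, and
#' the expression analyses, writing every result table into `out_dir`.
#'
#' @param in_dir Directory holding `tree.nwk`, `traits.tsv`,
#'   `family_counts.tsv`, `gene_go.tsv`, `gene_family.tsv`,
#'   `expression.tsv` (as written by [simulate_study()]).
#' @param out_dir Output directory for result tables.
#' @param config An [analysis_config()].
#' @param seed Integer seed for the resampling stages.
#' @return Invisibly, a named list of the result objects.
#' @export
run_pipeline <- function(in_dir, out_dir, config = analysis_config(),
                         seed = config$random_seed %||% 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- read_newick(file.path(in_dir, "tree.nwk"))
  traits <- augment_traits(read_table(file.path(in_dir, "traits.tsv"), "traits"))
  counts <- read_table(file.path(in_dir, "family_counts.tsv"), "counts")

  rensch <- test_rensch(traits, config)
  write_results(data.frame(
    n = rensch$n, slope = rensch$slope, intercept = rensch$intercept,
    r = rensch$r, p_slope_vs_1 = rensch$p_slope_vs_1,
    p_assoc = rensch$p_assoc, r_assoc = rensch$r_assoc,
    p_assoc_ssd = rensch$p_assoc_ssd
  ), file.path(out_dir, "rensch.tsv"))
  write_results(traits, file.path(out_dir, "traits_augmented.tsv"))

  filt <- filter_families(counts, config)
  write_results(filt$report, file.path(out_dir, "filter_report.tsv"))
  if (nrow(filt$counts) > 0) {
    write_results(filt$counts, file.path(out_dir, "family_counts_filtered.tsv"))
  }

  screen <- screen_families(filt$counts, traits, tree,
                            predictors = c("ssd", "log10_mass"),
                            config = config)
  write_results(screen, file.path(out_dir, "pgls_ssd_mass.tsv"))

  results <- list(rensch = rensch, filter = filt, screen = screen)

  background <- unique(screen$family)
  go_path <- file.path(in_dir, "gene_go.tsv")
  if (file.exists(go_path)) {
    gene_go <- read_table(go_path, "go_map")
    membership <- read_table(file.path(in_dir, "gene_family.tsv"), "membership")
    map <- pool_small_terms(map_go_to_families(gene_go, membership), config)
    for (dir in c("expanding", "contracting")) {
      focal <- called_families(screen, dir)
      if (length(focal) >= 1 && length(focal) < length(background)) {
        enr <- randomization_enrichment(focal, background, map, config,
                                        seed = seed)
        write_results(enr, file.path(out_dir, paste0("enrichment_", dir, ".tsv")))
        results[[paste0("enrichment_", dir)]] <- enr
      } else {
        ssd_log("warn", sprintf(
          "skipping %s enrichment: focal set empty or equal to background", dir))
      }
    }
  }

  expr_path <- file.path(in_dir, "expression.tsv")
  if (file.exists(expr_path)) {
    expr <- read_table(expr_path, "expression")
    all_genes <- unique(expr$gene)
    focal_genes <- all_genes[seq_len(min(50, length(all_genes)))]
    rank <- bootstrap_rank_p(expr, focal_genes, config, seed = seed)
    write_results(data.frame(
      n_genes = rank$n_genes, n_tissues = rank$n_tissues,
      mean_rank = rank$mean_rank, p_boot = rank$p_boot
    ), file.path(out_dir, "expr_rank.tsv"))
    results$rank <- rank
    if ("phase" %in% names(expr)) {
      for (ph in intersect(c("prenatal", "adult"), unique(expr$phase))) {
        sb <- sexbias_foldchange(expr, all_genes, phase = ph, config = config)
        write_results(sb, file.path(out_dir, paste0("sexbias_", ph, ".tsv")))
        results[[paste0("sexbias_", ph)]] <- sb
      }
    }
  }
  invisible(results)
}

# --- command-line dispatch -------------------------------------------------

# parse "--flag value" pairs (and bare subcommand words) into a list
parse_cli_args <- function(args) {
  flags <- list()
  positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        ssd_error(sprintf("flag %s needs a value", a), "ssd_cli_error")
      }
      flags[[substring(a, 3)]] <- args[i + 1]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

cli_config <- function(flags) {
  config <- if (!is.null(flags[["config"]])) read_config(flags[["config"]])
            else analysis_config()
  if (!is.null(flags[["seed"]])) {
    config$random_seed <- as.integer(flags[["seed"]])
  }
  config
}

#' Command-line entry point
#'
#' Dispatches the subcommands used by `inst/scripts/ssdscreen.R`:
#' `simulate`, `phenotypes`, `filter`, `pgls`, `enrich`, `expr-rank`,
#' `expr-temporal`, `expr-sexbias`, `run-all`. Common flags: `--config`
#' (YAML file of [analysis_config()] keys), `--seed`, `--out-dir`,
#' `--log-level`, plus per-command inputs (`--in-dir`, `--tree`,
#' `--traits`, `--counts`, `--predictors`, `--gene-go`, `--membership`,
#' `--focal`, `--background`, `--expression`, `--genes`, `--group`,
#' `--phase`, `--direction`, `--brain-label`).
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
ssd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- parse_cli_args(args)
  flags <- parsed$flags
  cmd <- parsed$positional[1] %||% NA_character_
  if (is.na(cmd)) {
    message("usage: ssdscreen <simulate|phenotypes|filter|pgls|enrich|expr-rank|expr-temporal|expr-sexbias|run-all> [--config FILE] [--seed N] [--out-dir DIR] ...")
    return(invisible(1L))
  }
  if (!is.null(flags[["log-level"]])) {
    options(ssdscreen.log_level = flags[["log-level"]])
  }
  config <- cli_config(flags)
  seed <- config$random_seed %||% 1L
  out_dir <- flags[["out-dir"]] %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  read_genes <- function() {
    if (is.null(flags[["genes"]])) {
      ssd_error("--genes FILE (one gene per line) is required", "ssd_cli_error")
    }
    readLines(flags[["genes"]], warn = FALSE)
  }
  switch(cmd,
    "simulate" = {
      simulate_study(out_dir, seed = seed, config = config)
    },
    "phenotypes" = {
      traits <- augment_traits(read_table(flags[["traits"]], "traits"))
      rensch <- test_rensch(traits, config)
      write_results(traits, file.path(out_dir, "traits_augmented.tsv"))
      write_results(data.frame(
        n = rensch$n, slope = rensch$slope, r = rensch$r,
        p_slope_vs_1 = rensch$p_slope_vs_1, r_assoc = rensch$r_assoc,
        p_assoc_ssd = rensch$p_assoc_ssd
      ), file.path(out_dir, "rensch.tsv"))
    },
    "filter" = {
      filt <- filter_families(read_table(flags[["counts"]], "counts"), config)
      write_results(filt$report, file.path(out_dir, "filter_report.tsv"))
      if (nrow(filt$counts) > 0) {
        write_results(filt$counts, file.path(out_dir, "family_counts_filtered.tsv"))
      }
    },
    "pgls" = {
      predictors <- strsplit(flags[["predictors"]] %||% "ssd,log10_mass", ",")[[1]]
      screen <- screen_families(
        read_table(flags[["counts"]], "counts"),
        read_table(flags[["traits"]], "traits"),
        read_newick(flags[["tree"]]),
        predictors = predictors, config = config
      )
      write_results(screen, file.path(out_dir, "pgls_results.tsv"))
    },
    "enrich" = {
      map <- pool_small_terms(map_go_to_families(
        read_table(flags[["gene-go"]], "go_map"),
        read_table(flags[["membership"]], "membership")
      ), config)
      background <- readLines(flags[["background"]], warn = FALSE)
      focal <- if (!is.null(flags[["focal"]])) {
        readLines(flags[["focal"]], warn = FALSE)
      } else {
        screen <- utils::read.delim(flags[["pgls"]], stringsAsFactors = FALSE)
        called_families(screen, flags[["direction"]] %||% "expanding")
      }
      enr <- randomization_enrichment(focal, background, map, config, seed = seed)
      write_results(enr, file.path(out_dir, "enrichment.tsv"))
    },
    "expr-rank" = {
      expr <- read_table(flags[["expression"]], "expression")
      if (!is.null(flags[["brain-label"]])) {
        config$brain_label <- flags[["brain-label"]]
      }
      rank <- bootstrap_rank_p(expr, read_genes(), config, seed = seed)
      write_results(data.frame(
        n_genes = rank$n_genes, n_tissues = rank$n_tissues,
        mean_rank = rank$mean_rank, p_boot = rank$p_boot
      ), file.path(out_dir, "expr_rank.tsv"))
    },
    "expr-temporal" = {
      expr <- read_table(flags[["expression"]], "expression")
      traj <- temporal_trajectory(expr, read_genes(),
                                  group = flags[["group"]] %||% "cortex")
      write_results(traj$stage_means, file.path(out_dir, "expr_temporal.tsv"))
      message(sprintf("slope (%s): %.4f", traj$group, traj$slope))
    },
    "expr-sexbias" = {
      expr <- read_table(flags[["expression"]], "expression")
      sb <- sexbias_foldchange(expr, read_genes(),
                               phase = flags[["phase"]] %||% "adult",
                               config = config)
      write_results(sb, file.path(out_dir, "expr_sexbias.tsv"))
    },
    "run-all" = {
      in_dir <- flags[["in-dir"]] %||% out_dir
      if (is.null(flags[["in-dir"]])) {
        simulate_study(in_dir, seed = seed, config = config)
      }
      run_pipeline(in_dir, out_dir, config, seed = seed)
    },
    ssd_error(sprintf("unknown subcommand '%s'", cmd), "ssd_cli_error")
  )
  invisible(0L)
}
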