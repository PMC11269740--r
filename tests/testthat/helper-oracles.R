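# Fixtures and independent oracles shared across tests. Every oracle is a
# literal, brute-force transcription of the defining formula, kept separate
# from the implementation path it checks.

options(ssdscreen.log_level = "error")

toy_tree3 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# fixed 6-species non-ultrametric tree used for GLS oracle checks
tree6 <- function() {
  ape::read.tree(text = "(((A:1,B:1):1,(C:1.5,D:0.5):0.5):1,(E:0.8,F:1.2):2);")
}

make_star_tree <- function(n, len = 1) {
  tree <- list(
    edge = cbind(rep(n + 1L, n), seq_len(n)),
    edge.length = rep(len, n),
    tip.label = paste0("sp", seq_len(n)),
    Nnode = 1L
  )
  class(tree) <- "phylo"
  tree
}

# Brownian covariance by enumerating all tip pairs and summing the branch
# lengths shared by their root paths
cov_path_oracle <- function(tree) {
  n <- length(tree$tip.label)
  n_node <- max(tree$edge)
  parent <- integer(n_node)
  elen <- numeric(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- n + 1L
  root_path <- function(tip) {
    nodes <- integer(0)
    node <- tip
    while (node != root) {
      nodes <- c(nodes, node)  # edges identified by their child node
      node <- parent[node]
    }
    nodes
  }
  paths <- lapply(seq_len(n), root_path)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
    }
  }
  C
}

# generalized least squares by explicit dense inversion of the normal
# equations
gls_oracle <- function(y, X, C) {
  Ci <- solve(C)
  XtCiX <- t(X) %*% Ci %*% X
  beta <- drop(solve(XtCiX, t(X) %*% Ci %*% y))
  resid <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- drop(t(resid) %*% Ci %*% resid) / df
  se <- sqrt(sigma2 * diag(solve(XtCiX)))
  list(beta = beta, se = se, t = beta / se, sigma2 = sigma2, df = df)
}

# Benjamini-Hochberg step-up applied literally to the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- vapply(seq_len(m), function(i) min(1, min(sorted[i:m] * m / (i:m))),
              numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# small deterministic trait table for phenotype tests
toy_traits <- function() {
  data.frame(
    species = paste0("sp", 1:6),
    male_mass = c(1200, 5000, 300, 82000, 45, 900),
    female_mass = c(1000, 5200, 250, 60000, 50, 880),
    brain_mass = c(9, 30, 3.1, 350, 0.9, 7.5),
    stringsAsFactors = FALSE
  )
}

# minimal long-format expression table builder
expr_row <- function(gene, tissue, value, stage = "s1", sex = "female",
                     phase = "adult", age = NA_real_) {
  data.frame(gene = gene, tissue = tissue, stage = stage, age = age,
             phase = phase, sex = sex, value = value,
             stringsAsFactors = FALSE)
}
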