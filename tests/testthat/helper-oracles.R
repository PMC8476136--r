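# Shared fixtures and independent oracles used across the suite.

# Exact (noise-free) genotype likelihoods from a genotype matrix: the called
# genotype has likelihood ~1. Useful when a test needs dosages equal to the
# true genotypes.
gl_exact <- function(geno, chrom = NULL, pos = NULL) {
  n_sites <- nrow(geno); n_ind <- ncol(geno)
  gl <- array(1e-9, dim = c(n_sites, n_ind, 3))
  for (k in 1:3) gl[, , k][geno == (k - 1L)] <- 1 - 2e-9
  sites <- data.frame(chrom = chrom %||% "chr1",
                      pos = pos %||% (seq_len(n_sites) - 1L),
                      allele1 = "0", allele2 = "1", stringsAsFactors = FALSE)
  gl_data(sites, gl, sprintf("ind%03d", seq_len(n_ind)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force oracle for extract_ld_clusters: walks the unique thresholds in
# decreasing order, rebuilding the at-or-above-threshold graph from scratch
# with igraph after each threshold, then emits/freezes every component that
# holds emin internal edges. Independent of the union-find implementation.
oracle_ld_clusters <- function(edges, emin) {
  if (nrow(edges) == 0) return(list())
  thresholds <- sort(unique(edges$r2), decreasing = TRUE)
  frozen <- integer(0)
  kept <- edges[0, , drop = FALSE]
  clusters <- list()
  for (t in thresholds) {
    grp <- edges[edges$r2 == t, , drop = FALSE]
    grp <- grp[!(grp$locus_a %in% frozen | grp$locus_b %in% frozen), , drop = FALSE]
    kept <- rbind(kept, grp)
    if (nrow(kept) == 0) next
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(kept$locus_a),
                 to = as.character(kept$locus_b)), directed = FALSE)
    memb <- igraph::components(g)$membership
    comp_nodes <- split(as.integer(names(memb)), memb)
    sizes <- vapply(comp_nodes, function(nodes)
      sum(kept$locus_a %in% nodes & kept$locus_b %in% nodes), integer(1))
    ready <- which(sizes >= emin)
    ready <- ready[order(vapply(comp_nodes[ready], min, integer(1)))]
    for (ci in ready) {
      nodes <- comp_nodes[[ci]]
      clusters[[length(clusters) + 1L]] <-
        list(loci = sort(nodes), birth_threshold = t, edge_count = sizes[[ci]])
      frozen <- c(frozen, nodes)
      kept <- kept[!(kept$locus_a %in% nodes | kept$locus_b %in% nodes), , drop = FALSE]
    }
  }
  clusters
}

# Exact-GLS oracle for the EMMAX test: full V = sg2*A + se2*I inversion, no
# rotation, variance components fixed at the supplied values.
oracle_gls_test <- function(x, y, X0, A, sg2, se2) {
  n <- length(y)
  V <- sg2 * A + se2 * diag(n)
  Vi <- solve(V)
  X <- cbind(X0, x)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  df <- n - ncol(X)
  s2 <- drop(t(r) %*% Vi %*% r) / df
  se <- sqrt(s2 * solve(XtViX)[ncol(X), ncol(X)])
  t_stat <- beta[ncol(X)] / se
  list(beta = beta[ncol(X)], t = t_stat, p = 2 * pt(-abs(t_stat), df))
}

# Pairwise-table generator under the MLPE model: population random effects
# give correlation rho between pairs sharing a population.
make_mlpe_data <- function(seed, beta = 1e-4, rho = 0.4, n_pops = 12,
                           intercept = 0.1, marginal_sd = 0.05) {
  set.seed(seed)
  pops <- paste0("P", seq_len(n_pops))
  pr <- t(utils::combn(pops, 2))
  x <- runif(nrow(pr), 0, 2000)
  tau2 <- 1; s2 <- tau2 * (1 - 2 * rho) / rho
  v <- marginal_sd^2 / (2 * tau2 + s2)
  u <- rnorm(n_pops, 0, sqrt(tau2 * v))
  e <- rnorm(nrow(pr), 0, sqrt(s2 * v))
  data.frame(pop_i = pr[, 1], pop_j = pr[, 2], x = x,
             y = intercept + beta * x + u[match(pr[, 1], pops)] +
               u[match(pr[, 2], pops)] + e)
}

# Small structured-null helper: simulated metapopulation, pseudo-cluster
# SMLAs from consecutive windows of `chunk` loci, the GRM, and metadata.
structured_null <- function(seed, chunk = 20, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_metapopulation(cfg)
  gl <- genotypes_to_likelihoods(sim, noise_model(10, 0.01), seed = seed + 5000)
  grp <- split(seq_len(nrow(gl$sites)), ceiling(seq_len(nrow(gl$sites)) / chunk))
  grp <- grp[lengths(grp) == chunk]
  smla_mat <- vapply(grp, function(idx) compute_smla(gl, idx)$coordinates,
                     numeric(length(gl$samples)))
  list(sim = sim, gl = gl, smla_mat = smla_mat, A = grm(gl),
       covar = data.frame(lineage = sim$samples$lineage))
}
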