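#' Standardized genomic relationship matrix
#'
#' A = Z'Z / M with Z the column-standardized posterior-mean dosage matrix
#' over the M polymorphic loci; the diagonal averages about 1. A small ridge
#' (1e-6 on the diagonal) keeps the matrix positive semi-definite for the
#' mixed model.
#'
#' @param x A [gl_data] object or a sites x individuals dosage matrix.
#' @param ridge Diagonal ridge added for numerical stability.
#' @return Symmetric individuals x individuals relatedness matrix.
#' @export
grm <- function(x, ridge = 1e-6) {
  D <- if (inherits(x, "gl_data")) dosage_matrix(x) else x
  stopifnot(is.matrix(D), ncol(D) >= 2)
  if (nrow(D) < 10) stop("grm() needs at least 10 loci")
  mu <- rowMeans(D)
  sd_ <- apply(D, 1, stats::sd)
  keep <- sd_ > 0
  if (!any(keep)) stop("all loci are monomorphic; cannot build a relatedness matrix")
  Z <- (D[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  A <- crossprod(Z) / sum(keep)
  A + diag(ridge, ncol(A))
}

# Build the null-model fixed-effect design: intercept plus covariates
# (factors/characters expand to dummies).
build_design <- function(n, covariates = NULL) {
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- if (is.data.frame(covariates)) covariates else data.frame(cv = covariates)
    for (j in seq_along(cv)) {
      v <- cv[[j]]
      if (is.character(v) || is.factor(v)) {
        v <- factor(v)
        if (nlevels(v) > 1) X <- cbind(X, stats::model.matrix(~v)[, -1, drop = FALSE])
      } else {
        X <- cbind(X, v)
      }
    }
  }
  unname(X)
}

#' Null-model variance components for EMMAX tests
#'
#' Estimates sigma_g^2 and sigma_e^2 once, under the model without any SMLA
#' term, by restricted maximum likelihood on the eigendecomposition of the
#' relatedness matrix. The returned object whitens data for all subsequent
#' per-cluster tests (the EMMAX approximation).
#'
#' @param y Response (ecotype, 0/1, treated as Gaussian).
#' @param A Relatedness matrix from [grm()].
#' @param covariates Optional covariates (e.g. lineage labels).
#' @return An `emmax_null` list with the eigendecomposition, delta
#'   (sigma_e^2 / sigma_g^2), variance components and whitened design.
#' @export
emmax_null <- function(y, A, covariates = NULL) {
  n <- length(y)
  stopifnot(nrow(A) == n, ncol(A) == n)
  X0 <- build_design(n, covariates)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    A <- A + diag(2 * abs(min(eg$values)), n)
    eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
    message("relatedness matrix was not PSD; ridge applied")
  }
  U <- eg$vectors
  s <- pmax(eg$values, 0)
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X0)
  p <- ncol(X0)
  reml_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (s + delta)
    XtWX <- crossprod(Xs, Xs * w)
    beta <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - Xs %*% beta
    q <- sum(w * r^2)
    sg2 <- q / (n - p)
    -0.5 * (sum(log(s + delta)) + determinant(XtWX, logarithm = TRUE)$modulus +
              (n - p) * log(sg2) + (n - p))
  }
  opt <- stats::optimize(reml_ll, c(log(1e-5), log(1e5)), maximum = TRUE, tol = 1e-8)
  # guard the boundaries: near-zero or near-infinite genetic variance
  cand <- c(opt$maximum, log(1e-5), log(1e5))
  ll <- vapply(cand, reml_ll, numeric(1))
  delta <- exp(cand[which.max(ll)])
  w <- 1 / (s + delta)
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  q <- sum(w * drop(ys - Xs %*% beta)^2)
  sg2 <- q / (n - p)
  structure(list(U = U, s = s, delta = delta,
                 sigma_g2 = sg2, sigma_e2 = delta * sg2,
                 X0 = X0, y = y,
                 y_white = ys * sqrt(w), X0_white = Xs * sqrt(w),
                 w_sqrt = sqrt(w)),
            class = "emmax_null")
}

# Whiten an individual-level vector/matrix with the null-model transform.
emmax_whiten <- function(null, v) {
  if (is.matrix(v)) crossprod(null$U, v) * null$w_sqrt
  else drop(crossprod(null$U, v)) * null$w_sqrt
}

#' Mixed-model association test of one SMLA against ecotype
#'
#' EMMAX-style test: variance components are estimated once under the null
#' (no SMLA), the data are rotated to the eigenbasis of the relatedness
#' matrix and whitened, and the SMLA effect is tested by generalized least
#' squares (Wald t). With `A = NULL` the test reduces to ordinary linear
#' regression. Effect sizes are reported as plain correlation proxies:
#' `cor_unrl` (SMLA vs ecotype, all individuals assumed unrelated) and
#' `cor_A` (correlation of whitened, covariate-residualized SMLA and
#' ecotype).
#'
#' @param smla An `smla` object or numeric coordinate vector.
#' @param ecotype Binary 0/1 habitat vector (no missing values).
#' @param covariates Optional covariates (e.g. lineage).
#' @param A Optional relatedness matrix; `NULL` for ordinary regression.
#' @param null Optional precomputed [emmax_null()] (must match `A`,
#'   `covariates`).
#' @return An `emmax_fit` list: `beta_smla`, `sigma_g2`, `sigma_e2`,
#'   `p_value`, `cor_unrl`, `cor_A`, `t_stat`, `df`.
#' @export
emmax_test <- function(smla, ecotype, covariates = NULL, A = NULL, null = NULL) {
  x <- if (inherits(smla, "smla")) smla$coordinates else smla
  y <- as.numeric(ecotype)
  if (anyNA(y)) stop("missing ecotype values are not allowed")
  n <- length(y)
  stopifnot(length(x) == n)
  if (stats::sd(x) == 0) {
    return(structure(list(beta_smla = 0, sigma_g2 = NA_real_, sigma_e2 = NA_real_,
                          p_value = 1, cor_unrl = 0, cor_A = 0,
                          t_stat = 0, df = NA_integer_), class = "emmax_fit"))
  }
  cor_unrl <- stats::cor(x, y)
  if (is.null(A) && is.null(null)) {
    X0 <- build_design(n, covariates)
    yr <- stats::lm.fit(X0, y)$residuals
    xr <- stats::lm.fit(X0, x)$residuals
    fit <- summary(stats::lm(y ~ X0 - 1 + x))
    row <- nrow(fit$coefficients)
    t_stat <- fit$coefficients[row, "t value"]
    p <- fit$coefficients[row, "Pr(>|t|)"]
    return(structure(list(beta_smla = fit$coefficients[row, "Estimate"],
                          sigma_g2 = 0, sigma_e2 = fit$sigma^2,
                          p_value = p, cor_unrl = cor_unrl,
                          cor_A = suppressWarnings(stats::cor(xr, yr)),
                          t_stat = t_stat, df = fit$df[2]),
                     class = "emmax_fit"))
  }
  null <- null %||% emmax_null(y, A, covariates)
  yw <- null$y_white
  Xw <- cbind(null$X0_white, emmax_whiten(null, x))
  p_cols <- ncol(Xw)
  fit <- stats::lm.fit(Xw, yw)
  df <- n - p_cols
  rss <- sum(fit$residuals^2)
  XtXi <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(rss / df * XtXi[p_cols, p_cols])
  beta <- unname(fit$coefficients[p_cols])
  t_stat <- beta / se
  xw_r <- stats::lm.fit(null$X0_white, Xw[, p_cols])$residuals
  yw_r <- stats::lm.fit(null$X0_white, yw)$residuals
  structure(list(beta_smla = beta,
                 sigma_g2 = null$sigma_g2, sigma_e2 = null$sigma_e2,
                 p_value = 2 * stats::pt(-abs(t_stat), df),
                 cor_unrl = cor_unrl,
                 cor_A = suppressWarnings(stats::cor(xw_r, yw_r)),
                 t_stat = unname(t_stat), df = df),
            class = "emmax_fit")
}

#' @export
print.emmax_fit <- function(x, ...) {
  cat(sprintf("EMMAX test: beta = %.4g, P = %.3g, cor_unrl = %.3f, cor_A = %.3f\n",
              x$beta_smla, x$p_value, x$cor_unrl, x$cor_A))
  invisible(x)
}

#' Genomic-inflation factor lambda
#'
#' The least-squares slope through the origin of observed on expected
#' -log10(P) order statistics (expected quantiles are -log10((i - 0.5)/m)).
#'
#' @param p Vector of raw P values (at least `min_tests` of them).
#' @param min_tests Minimum number of tests required.
#' @return An `inflation_estimate` list with `lambda` and `n_tests`.
#' @export
estimate_lambda <- function(p, min_tests = 20) {
  if (length(p) < min_tests) {
    stop("estimate_lambda() needs at least ", min_tests, " tests")
  }
  if (any(p <= 0)) {
    warning("P values of 0 clamped to machine minimum")
    p <- pmax(p, .Machine$double.xmin)
  }
  m <- length(p)
  obs <- sort(-log10(p), decreasing = TRUE)
  expd <- -log10((seq_len(m) - 0.5) / m)
  structure(list(lambda = sum(obs * expd) / sum(expd^2), n_tests = m),
            class = "inflation_estimate")
}

#' Genomic-control correction of P values
#'
#' Divides every observed -log10(P) by lambda, i.e. corrected
#' P = 10^(-(-log10 P)/lambda). Applied only when inflation is present
#' (lambda > 1); otherwise the vector is returned unchanged.
#'
#' @param p Vector of P values.
#' @param lambda Inflation factor (> 0).
#' @return Corrected P values (order preserved).
#' @export
gc_correct <- function(p, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  if (lambda <= 1) return(p)
  10^(log10(p) / lambda)
}

#' Benjamini-Hochberg rejection set
#'
#' Standard step-up false-discovery-rate procedure.
#'
#' @param p Vector of P values in \[0, 1\].
#' @param alpha FDR level.
#' @return Integer indices of the rejected hypotheses (may be empty).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(integer(0))
  stopifnot_prob(p, "p")
  which(stats::p.adjust(p, method = "BH") <= alpha)
}

# Number of distinct within-strata label assignments of a binary vector.
count_distinct_assignments <- function(y, strata) {
  idx_by_s <- split(seq_along(y), strata)
  lg <- sum(vapply(idx_by_s, function(idx)
    lchoose(length(idx), sum(y[idx] == 1)), numeric(1)))
  exp(lg)
}

# All distinct assignments of a binary y within strata, as an n x N matrix.
enumerate_assignments <- function(y, strata) {
  idx_by_s <- split(seq_along(y), strata)
  per_stratum <- lapply(idx_by_s, function(idx) {
    k <- sum(y[idx] == 1)
    if (k == 0 || k == length(idx)) return(matrix(y[idx], length(idx), 1))
    sets <- utils::combn(length(idx), k)
    apply(sets, 2, function(ss) { v <- rep(0, length(idx)); v[ss] <- 1; v })
  })
  out <- matrix(0, length(y), 1)
  for (j in seq_along(per_stratum)) {
    blk <- per_stratum[[j]]
    out <- out[, rep(seq_len(ncol(out)), each = ncol(blk)), drop = FALSE]
    out[idx_by_s[[j]], ] <- blk[, rep_len(seq_len(ncol(blk)), ncol(out))]
  }
  out
}

# Generate permutations of y within strata; returns n x n_perm matrix, or all
# distinct assignments when there are fewer than n_perm of them.
permute_within_strata <- function(y, strata, n_perm) {
  n <- length(y)
  strata <- strata %||% rep(1L, n)
  if (all(y %in% c(0, 1)) &&
      count_distinct_assignments(y, strata) <= n_perm) {
    message("fewer distinct permutations than n_perm; using exact enumeration")
    return(enumerate_assignments(y, strata))
  }
  out <- matrix(0, n, n_perm)
  idx_by_s <- split(seq_len(n), strata)
  for (b in seq_len(n_perm)) {
    yp <- y
    for (idx in idx_by_s) yp[idx] <- y[idx][sample.int(length(idx))]
    out[, b] <- yp
  }
  out
}

#' Max-statistic permutation control over a set of SMLA tests
#'
#' Ecotype labels are permuted within strata (e.g. lineage); per permutation
#' the maximum absolute test statistic over all clusters is recorded, and the
#' family-wise adjusted P of each cluster is
#' (1 + #\{permutation max >= observed\}) / (1 + n_perm). With a relatedness
#' matrix the statistics are computed on whitened data with variance
#' components fixed at their null-model values (the EMMAX approximation),
#' which makes the permutation pass a single matrix product.
#'
#' @param smla_mat Individuals x clusters matrix of SMLA coordinates.
#' @param ecotype Binary 0/1 vector.
#' @param covariates Optional covariates included in every fit.
#' @param A Optional relatedness matrix (`NULL` for the unrelated model).
#' @param n_perm Number of permutations (>= 100).
#' @param strata Optional stratum label per individual.
#' @param seed Integer seed (results are deterministic given the seed).
#' @param null Optional precomputed [emmax_null()].
#' @return List with `p_adj` (family-wise adjusted P per cluster),
#'   `stat_obs`, `max_null` (the permutation max-statistic sample).
#' @export
permutation_control <- function(smla_mat, ecotype, covariates = NULL, A = NULL,
                                n_perm = 1000, strata = NULL, seed = NULL,
                                null = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  y <- as.numeric(ecotype)
  n <- length(y)
  stopifnot(nrow(smla_mat) == n)
  K <- ncol(smla_mat)
  if (K == 0) return(list(p_adj = numeric(0), stat_obs = numeric(0), max_null = numeric(0)))
  with_seed(seed, {
    Yp <- permute_within_strata(y, strata, n_perm)
    if (!is.null(A) || !is.null(null)) {
      null <- null %||% emmax_null(y, A, covariates)
      X0w <- null$X0_white
      Sw <- emmax_whiten(null, smla_mat)
      yw <- null$y_white
      Ypw <- emmax_whiten(null, Yp)
    } else {
      X0w <- build_design(n, covariates)
      Sw <- smla_mat
      yw <- y
      Ypw <- Yp
    }
    # residualize everything on the (whitened) null design; |correlation| of
    # residuals is a monotone transform of the Wald t statistic
    q <- qr(X0w)
    Sr <- qr.resid(q, Sw)
    yr <- qr.resid(q, yw)
    Yr <- qr.resid(q, Ypw)
    const_cl <- apply(Sr, 2, stats::sd) == 0
    stat_obs <- abs(suppressWarnings(stats::cor(Sr, yr)))
    stat_obs[const_cl | !is.finite(stat_obs)] <- 0
    Rn <- abs(suppressWarnings(stats::cor(Sr, Yr)))
    Rn[!is.finite(Rn)] <- 0
    max_null <- apply(Rn, 2, max)
    n_drawn <- ncol(Yp)   # < n_perm only under exact enumeration
    p_adj <- vapply(stat_obs, function(s) (1 + sum(max_null >= s)) / (1 + n_drawn),
                    numeric(1))
    list(p_adj = p_adj, stat_obs = drop(stat_obs), max_null = max_null)
  })
}

#' Iterative genomic control with FDR over a parameter grid
#'
#' Alternates between estimating inflation (lambda = median of the per-cell
#' slope estimates over clusters not yet declared significant), correcting
#' all P values when lambda > 1, and applying the Benjamini-Hochberg step-up
#' within each cell, until the significant set stabilizes.
#'
#' @param results data.frame with columns `cell` (grid-cell identifier),
#'   `cluster_id` and `p` (raw P values).
#' @param alpha FDR level.
#' @param max_iter Iteration cap; exceeding it flags non-convergence.
#' @return List with `significant` (logical per input row), `p_corrected`,
#'   `lambda` (final), `lambda_trace`, `converged`.
#' @export
iterative_gc_fdr <- function(results, alpha = 0.05, max_iter = 25) {
  stopifnot(all(c("cell", "cluster_id", "p") %in% names(results)))
  if (nrow(results) == 0) stop("no grid results supplied")
  sig <- rep(FALSE, nrow(results))
  lambda_trace <- numeric(0)
  converged <- FALSE
  p_corr <- results$p
  for (it in seq_len(max_iter)) {
    lam_cells <- vapply(split(results$p[!sig], results$cell[!sig]), function(pp) {
      if (length(pp) >= 20) estimate_lambda(pp)$lambda else NA_real_
    }, numeric(1))
    lambda <- stats::median(lam_cells, na.rm = TRUE)
    if (!is.finite(lambda)) lambda <- 1
    lambda_trace <- c(lambda_trace, lambda)
    p_corr <- gc_correct(results$p, lambda)
    new_sig <- rep(FALSE, nrow(results))
    for (cell in unique(results$cell)) {
      rows <- which(results$cell == cell)
      new_sig[rows[bh_fdr(p_corr[rows], alpha)]] <- TRUE
    }
    if (identical(new_sig, sig)) { converged <- TRUE; break }
    sig <- new_sig
  }
  if (!converged) warning("iterative GC/FDR did not converge within ", max_iter, " iterations")
  list(significant = sig, p_corrected = p_corr,
       lambda = lambda_trace[length(lambda_trace)],
       lambda_trace = lambda_trace, converged = converged)
}

#' Default LDna parameter grid
#'
#' The 3 x 3 x 4 grid of cluster-definition parameters which, crossed with
#' the four correction regimes, yields 144 tests.
#'
#' @param emin,snp_min,cor_th Parameter values to cross.
#' @return data.frame with one row per combination.
#' @export
default_grid <- function(emin = c(10, 20, 40), snp_min = c(10, 20, 40),
                         cor_th = c(0.8, 0.7, 0.6, 0.5)) {
  g <- expand.grid(emin = emin, snp_min = snp_min, cor_th = cor_th,
                   KEEP.OUT.ATTRS = FALSE)
  g$combo <- sprintf("E%d_S%d_C%g", g$emin, g$snp_min, g$cor_th)
  g
}

#' Run the full association grid: LDna x four correction regimes
#'
#' For every grid combination the nested LD-network clustering is run (the
#' pairwise-LD step is shared across combinations), each final cluster's SMLA
#' is tested against ecotype with and without the relatedness random effect,
#' and the four correction regimes are applied: `A_FDR` (relatedness +
#' iterative GC/FDR), `A_perm` (relatedness + max-statistic permutation),
#' `GC_FDR` (unrelated model + iterative GC/FDR), `perm` (unrelated model +
#' permutation). The FDR regimes share a single inflation factor, the median
#' over grid cells, following the iterative scheme of [iterative_gc_fdr()].
#'
#' @param gl A [gl_data] object.
#' @param samples Sample metadata table (needs `ecotype`; `lineage` is used
#'   as covariate and permutation stratum when it varies).
#' @param grid data.frame from [default_grid()].
#' @param window_size,edge_floor Level-1 LDna settings (fixed across the grid).
#' @param n_perm Permutations for the permutation regimes.
#' @param alpha Significance level for the significance flags.
#' @param seed Integer seed for the permutation draws.
#' @return An `assoc_grid` list: `results` (one row per cluster x combination
#'   x regime), `cluster_loci` (per combination, list of locus-index vectors),
#'   `smlas` (per combination coordinate matrix), `grid`, `lambda_info`,
#'   `n_cells`.
#' @export
run_association_grid <- function(gl, samples, grid = default_grid(),
                                 window_size = 1e5, edge_floor = 0.3,
                                 n_perm = 1000, alpha = 0.05, seed = NULL) {
  if (nrow(grid) == 0) stop("empty parameter grid")
  regimes <- c("A_FDR", "A_perm", "GC_FDR", "perm")
  ecotype <- samples$ecotype
  lineage <- samples$lineage
  use_lineage <- !is.null(lineage) && length(unique(lineage)) > 1
  covariates <- if (use_lineage) data.frame(lineage = lineage) else NULL
  strata <- if (use_lineage) lineage else NULL

  A <- grm(gl)
  null_A <- emmax_null(ecotype, A, covariates)
  pre <- ldna_precompute(gl, window_size, edge_floor)

  per_combo <- list()
  for (i in seq_len(nrow(grid))) {
    prm <- ldna_params(grid$emin[i], grid$snp_min[i], grid$cor_th[i],
                       window_size, edge_floor)
    ld <- ldna_nested_run(gl, prm, precomputed = pre)
    K <- length(ld$clusters)
    combo <- grid$combo[i]
    if (K == 0) {
      per_combo[[combo]] <- list(ldna = ld, tests = NULL)
      next
    }
    tests <- vector("list", K)
    for (k in seq_len(K)) {
      fit_A <- emmax_test(ld$smla_mat[, k], ecotype, covariates, null = null_A)
      fit_0 <- emmax_test(ld$smla_mat[, k], ecotype, covariates)
      tests[[k]] <- data.frame(
        combo = combo, cluster_id = names(ld$clusters)[k],
        n_loci = length(ld$clusters[[k]]$loci),
        p_A = fit_A$p_value, p_unrl = fit_0$p_value,
        cor_unrl = fit_A$cor_unrl, cor_A = fit_A$cor_A)
    }
    per_combo[[combo]] <- list(ldna = ld, tests = do.call(rbind, tests))
  }
  tests_all <- do.call(rbind, lapply(per_combo, `[[`, "tests"))
  if (is.null(tests_all) || nrow(tests_all) == 0) {
    stop("no LD clusters found in any grid cell")
  }

  # FDR regimes: iterative genomic control with the grid-median lambda.
  it_A <- iterative_gc_fdr(data.frame(cell = tests_all$combo,
                                      cluster_id = tests_all$cluster_id,
                                      p = tests_all$p_A), alpha = alpha)
  it_0 <- iterative_gc_fdr(data.frame(cell = tests_all$combo,
                                      cluster_id = tests_all$cluster_id,
                                      p = tests_all$p_unrl), alpha = alpha)

  # Permutation regimes per combination.
  perm_res <- list()
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(grid)) else
    as.list(seed + seq_len(nrow(grid)))
  for (i in seq_len(nrow(grid))) {
    combo <- grid$combo[i]
    ld <- per_combo[[combo]]$ldna
    if (length(ld$clusters) == 0) next
    pa <- permutation_control(ld$smla_mat, ecotype, covariates, A = NULL,
                              n_perm = n_perm, strata = strata,
                              seed = seeds[[i]], null = null_A)
    p0 <- permutation_control(ld$smla_mat, ecotype, covariates, A = NULL,
                              n_perm = n_perm, strata = strata,
                              seed = seeds[[i]])
    perm_res[[combo]] <- list(A_perm = pa$p_adj, perm = p0$p_adj)
  }

  rows <- list()
  for (combo in names(per_combo)) {
    t_c <- per_combo[[combo]]$tests
    if (is.null(t_c)) next
    sel <- tests_all$combo == combo
    for (regime in regimes) {
      raw_p <- if (regime %in% c("A_FDR", "A_perm")) t_c$p_A else t_c$p_unrl
      if (regime == "A_FDR") {
        p_corr <- it_A$p_corrected[sel]; sig <- it_A$significant[sel]
        p_adj <- stats::p.adjust(p_corr, "BH")
      } else if (regime == "GC_FDR") {
        p_corr <- it_0$p_corrected[sel]; sig <- it_0$significant[sel]
        p_adj <- stats::p.adjust(p_corr, "BH")
      } else {
        p_adj <- perm_res[[combo]][[regime]]
        sig <- p_adj <= alpha
      }
      rows[[length(rows) + 1L]] <- data.frame(
        combo = combo, regime = regime, cluster_id = t_c$cluster_id,
        n_loci = t_c$n_loci, raw_p = raw_p, p_adj = p_adj,
        significant = sig, cor_unrl = t_c$cor_unrl, cor_A = t_c$cor_A)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results,
                 cluster_loci = lapply(per_combo, function(x)
                   lapply(x$ldna$clusters, `[[`, "loci")),
                 smlas = lapply(per_combo, function(x) x$ldna$smla_mat),
                 grid = grid, regimes = regimes,
                 n_cells = nrow(grid) * length(regimes),
                 lambda_info = list(A_FDR = it_A[c("lambda", "lambda_trace", "converged")],
                                    GC_FDR = it_0[c("lambda", "lambda_trace", "converged")]),
                 sites = gl$sites, samples = samples),
            class = "assoc_grid")
}

#' @export
print.assoc_grid <- function(x, ...) {
  cat(sprintf("assoc_grid: %d grid combinations x %d regimes = %d cells; %d cluster tests\n",
              nrow(x$grid), length(x$regimes), x$n_cells, nrow(x$results)))
  cat(sprintf("  inflation: lambda(A+FDR) = %.2f, lambda(GC+FDR) = %.2f\n",
              x$lambda_info$A_FDR$lambda, x$lambda_info$GC_FDR$lambda))
  invisible(x)
}
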