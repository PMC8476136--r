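test_that("the GRM is a standardized relationship matrix", {
  set.seed(1)
  D <- matrix(rbinom(200 * 30, 2, runif(200, 0.2, 0.8)), 200, 30)
  D[, 30] <- D[, 1]  # duplicated individual
  A <- grm(D)
  expect_equal(A, t(A))
  expect_equal(mean(diag(A)), 1, tolerance = 0.2)
  expect_lt(abs(A[1, 30] - A[1, 1]), 0.05 + 1e-6)
  expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_error(grm(matrix(1, 20, 5)), "monomorphic")
})

test_that("GRM separates demes: within-deme relatedness exceeds between", {
  sc <- structured_null(8, chunk = 20, L = 1e6, n_chromosomes = 1)
  A <- sc$A
  pop <- sc$sim$samples$population
  same <- outer(pop, pop, "==") & upper.tri(A)
  diff <- !outer(pop, pop, "==") & upper.tri(A)
  expect_gt(mean(A[same]), mean(A[diff]))
})

test_that("a perfectly separating SMLA yields cor 1 and tiny P", {
  y <- rep(c(0, 1), each = 25)
  fit <- emmax_test(y + 0, y)
  expect_equal(fit$cor_unrl, 1)
  expect_lt(fit$p_value, 1e-12)
  # constant SMLA degenerates gracefully
  fit0 <- emmax_test(rep(1, 50), y)
  expect_equal(fit0$p_value, 1)
  expect_equal(fit0$cor_unrl, 0)
})

test_that("null P values are uniform without structure", {
  set.seed(2)
  n <- 60
  y <- rbinom(n, 1, 0.5)
  p <- vapply(1:1000, function(i) {
    emmax_test(rnorm(n), y)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("EMMAX matches the exact GLS oracle on a small fixture", {
  set.seed(3)
  n <- 20
  Z <- matrix(rnorm(n * 50), n, 50)
  A <- tcrossprod(Z) / 50
  y <- rbinom(n, 1, 0.5)
  x <- rnorm(n) + 0.8 * y
  null <- emmax_null(y, A)
  fit <- emmax_test(x, y, A = A, null = null)
  # same variance components, exact full-matrix GLS, no rotation
  Ar <- (A + t(A)) / 2 + diag(0, n)
  want <- oracle_gls_test(x, y, matrix(1, n, 1), Ar,
                          null$sigma_g2, null$sigma_e2)
  expect_equal(fit$p_value, want$p, tolerance = 1e-8)
  expect_equal(fit$beta_smla, want$beta, tolerance = 1e-8)
})

test_that("EMMAX reduces to ordinary regression when genetic variance is small", {
  set.seed(4)
  n <- 40
  A <- diag(n) * 1e-4 + diag(1e-6, n)
  y <- rbinom(n, 1, 0.5)
  x <- rnorm(n)
  fit_A <- emmax_test(x, y, A = A)
  fit_0 <- emmax_test(x, y)
  expect_equal(fit_A$p_value, fit_0$p_value, tolerance = 1e-6)
})

test_that("lambda is the through-origin slope of the QQ plot", {
  set.seed(5)
  p <- runif(10000)
  expect_equal(estimate_lambda(p)$lambda, 1, tolerance = 0.05)
  # doubling every -log10(P) doubles lambda
  p2 <- 10^(2 * log10(p))
  expect_equal(estimate_lambda(p2)$lambda, 2 * estimate_lambda(p)$lambda,
               tolerance = 1e-9)
  # rank-based: permutation invariant
  expect_equal(estimate_lambda(sample(p))$lambda, estimate_lambda(p)$lambda)
  expect_error(estimate_lambda(runif(5)), "at least 20")
  expect_warning(lam0 <- estimate_lambda(c(rep(0, 1), runif(99))), "clamped")
  expect_true(is.finite(lam0$lambda))
})

test_that("genomic control divides -log10 P by lambda only when inflated", {
  expect_equal(gc_correct(1e-2, 2), 0.1, tolerance = 1e-12)
  p <- c(0.3, 1e-4, 0.02)
  expect_identical(gc_correct(p, 1), p)
  expect_identical(gc_correct(p, 0.7), p)  # deflation is left alone
  expect_equal(order(gc_correct(p, 3)), order(p))
  expect_error(gc_correct(p, 0), "positive")
})

test_that("BH step-up matches the hand-computed fixture", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.8), alpha = 0.05), 1:3)
  expect_length(bh_fdr(rep(1, 10)), 0)
  expect_length(bh_fdr(numeric(0)), 0)
  p <- c(0.001, 0.013, 0.04, 0.2, 0.9)
  for (i in seq_len(9)) {
    a1 <- bh_fdr(p, alpha = i / 10)
    a2 <- bh_fdr(p, alpha = (i + 1) / 10)
    expect_true(all(a1 %in% a2))  # rejections monotone in alpha
  }
})

test_that("max-statistic permutation dominates the single-cluster test", {
  set.seed(6)
  n <- 50
  y <- rep(c(0, 1), each = 25)
  smla_mat <- matrix(rnorm(n * 15), n, 15)
  smla_mat[, 1] <- y + rnorm(n, 0, 0.6)
  p1 <- permutation_control(smla_mat, y, n_perm = 299, seed = 9)
  p2 <- permutation_control(smla_mat, y, n_perm = 299, seed = 9)
  expect_identical(p1$p_adj, p2$p_adj)  # seed determinism
  # family-wise adjusted P dominates the per-cluster permutation P
  for (k in c(1, 5, 9)) {
    single <- permutation_control(smla_mat[, k, drop = FALSE], y,
                                  n_perm = 299, seed = 9)
    expect_gte(p1$p_adj[k], single$p_adj[1])
  }
  expect_lt(p1$p_adj[1], 0.05)  # the planted signal is detected
  expect_error(permutation_control(smla_mat, y, n_perm = 50), "at least 100")
})

test_that("iterative GC/FDR converges and deflates planted inflation", {
  set.seed(7)
  null_res <- data.frame(cell = rep(sprintf("c%02d", 1:10), each = 50),
                         cluster_id = sprintf("k%03d", 1:500),
                         p = runif(500))
  it <- iterative_gc_fdr(null_res)
  expect_true(it$converged)
  expect_lte(length(it$lambda_trace), 2)
  expect_gt(it$lambda, 0.9); expect_lt(it$lambda, 1.1)
  # idempotence: a second pass reproduces the significant set
  it2 <- iterative_gc_fdr(null_res)
  expect_identical(it$significant, it2$significant)

  # 5% strong signals inflate lambda; removal pulls it back toward 1
  for (s in 1:20) {
    set.seed(100 + s)
    p <- runif(500)
    p[sample(500, 25)] <- 10^runif(25, -14, -10)
    res <- data.frame(cell = rep(sprintf("c%02d", 1:10), each = 50),
                      cluster_id = sprintf("k%03d", 1:500), p = p)
    it3 <- iterative_gc_fdr(res)
    expect_lt(it3$lambda, it3$lambda_trace[1])
  }
})

test_that("the association grid enumerates combos x regimes and shares raw P", {
  expect_equal(nrow(default_grid()) * 4, 144)
  sc <- scenario_parallel_regions(21)
  g1 <- default_grid(emin = 10, snp_min = 10, cor_th = 0.8)
  ag <- run_association_grid(sc$gl, sc$sim$samples, grid = g1,
                             n_perm = 150, seed = 5)
  expect_equal(length(unique(paste(ag$results$combo, ag$results$regime))), 4)
  expect_equal(ag$n_cells, 4)
  # raw P shared within the relatedness model and within the unrelated model
  byc <- split(ag$results, ag$results$cluster_id)
  for (b in byc) {
    expect_equal(b$raw_p[b$regime == "A_FDR"], b$raw_p[b$regime == "A_perm"])
    expect_equal(b$raw_p[b$regime == "GC_FDR"], b$raw_p[b$regime == "perm"])
  }
  # parallel planted loci on different chromosomes merge into genome-wide
  # clusters; significant clusters must still cover at least 3 truth regions
  sigA <- subset(ag$results, regime == "A_FDR" & significant)
  expect_gte(nrow(sigA), 1)
  regs <- call_outlier_regions(ag)
  ov <- function(r, t) r$chrom == t$chrom & r$start < t$end & r$end > t$start
  covered <- vapply(seq_len(nrow(sc$truth)), function(i)
    any(vapply(seq_len(nrow(regs)), function(j)
      ov(regs[j, ], sc$truth[i, ]), logical(1))), logical(1))
  expect_gte(sum(covered), 3)
})

test_that("few distinct permutations trigger exact enumeration", {
  set.seed(11)
  y <- rep(c(0, 1), each = 4)               # C(8,4) = 70 distinct assignments
  smla_mat <- matrix(rnorm(8 * 3), 8, 3)
  expect_message(
    pc <- permutation_control(smla_mat, y, n_perm = 100, seed = 2),
    "exact enumeration")
  expect_length(pc$max_null, 70)
  # enumeration is deterministic: same result without a seed
  pc2 <- suppressMessages(permutation_control(smla_mat, y, n_perm = 100, seed = 99))
  expect_identical(pc$p_adj, pc2$p_adj)
})
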