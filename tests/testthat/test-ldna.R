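test_that("pairwise LD is squared dosage correlation", {
  set.seed(1)
  g <- matrix(rbinom(200, 2, 0.5), 2, 100)
  g <- rbind(g, g[2, , drop = FALSE])  # locus 3 duplicates locus 2
  gl <- gl_exact(g)
  ld <- pairwise_ld(gl, edge_floor = 0)
  expect_equal(ld$r2[ld$locus_a == 2 & ld$locus_b == 3], 1, tolerance = 1e-9)

  # independent loci: median r2 near zero
  set.seed(2)
  g2 <- matrix(rbinom(20 * 500, 2, 0.5), 20, 500)
  ld2 <- pairwise_ld(gl_exact(g2), edge_floor = 0)
  expect_lt(median(ld2$r2), 0.01)

  # monomorphic loci are dropped with a count
  g3 <- rbind(g2[1:3, ], matrix(1L, 1, 500) * 0L)
  ld3 <- pairwise_ld(gl_exact(g3), edge_floor = 0)
  expect_equal(attr(ld3, "n_monomorphic"), 1L)
  expect_false(any(ld3$locus_a == 4 | ld3$locus_b == 4))
})

test_that("two loci with D = 0.1 at p = q = 0.5 give r2 near 0.16", {
  # haplotype frequencies AB 0.35, Ab 0.15, aB 0.15, ab 0.35 -> D = 0.1
  haps <- rbind(matrix(c(1, 1), 280, 2, byrow = TRUE),
                matrix(c(1, 0), 120, 2, byrow = TRUE),
                matrix(c(0, 1), 120, 2, byrow = TRUE),
                matrix(c(0, 0), 280, 2, byrow = TRUE))
  set.seed(3)
  haps <- haps[sample(nrow(haps)), ]
  geno <- haps[seq(1, 799, 2), ] + haps[seq(2, 800, 2), ]   # 400 diploids
  ld <- pairwise_ld(gl_exact(t(geno)), edge_floor = 0)
  expect_equal(ld$r2, 0.1^2 / (0.5^4), tolerance = 0.25)  # sampling noise
})

test_that("cluster extraction emits components at the edge-count birth rule", {
  clique <- function(nodes, r2) {
    pr <- t(combn(nodes, 2))
    data.frame(locus_a = pr[, 1], locus_b = pr[, 2], r2 = r2)
  }
  # complete graph on 5 loci: C(5,2) = 10 edges
  e5 <- clique(1:5, 0.9)
  cl <- extract_ld_clusters(e5, emin = 10)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$loci, 1:5)
  expect_equal(cl[[1]]$birth_threshold, 0.9)
  expect_equal(cl[[1]]$edge_count, 10)
  expect_length(extract_ld_clusters(e5, emin = 11), 0)

  # two cliques joined by a weak bridge never merge
  edges <- rbind(clique(1:5, 0.9), clique(6:10, 0.8),
                 data.frame(locus_a = 5, locus_b = 6, r2 = 0.5))
  cl2 <- extract_ld_clusters(edges, emin = 10)
  expect_length(cl2, 2)
  expect_equal(cl2[[1]]$loci, 1:5)
  expect_equal(cl2[[1]]$birth_threshold, 0.9)
  expect_equal(cl2[[2]]$loci, 6:10)
  expect_equal(cl2[[2]]$birth_threshold, 0.8)

  expect_length(extract_ld_clusters(edges[0, ], emin = 5), 0)
})

test_that("cluster extraction is invariant to edge-list ordering", {
  set.seed(4)
  pr <- t(combn(1:10, 2))
  edges <- data.frame(locus_a = pr[, 1], locus_b = pr[, 2],
                      r2 = round(runif(nrow(pr)), 2))
  ref <- extract_ld_clusters(edges, emin = 6)
  for (i in 1:5) {
    shuf <- edges[sample(nrow(edges)), ]
    expect_identical(extract_ld_clusters(shuf, emin = 6), ref)
  }
})

test_that("cluster extraction matches the brute-force threshold-scan oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:10) {
    set.seed(s)
    n <- sample(6:12, 1)
    pr <- t(combn(seq_len(n), 2))
    keep <- runif(nrow(pr)) < 0.6
    edges <- data.frame(locus_a = pr[keep, 1], locus_b = pr[keep, 2],
                        r2 = round(runif(sum(keep)), 2))
    for (emin in c(2, 4, 8)) {
      got <- extract_ld_clusters(edges, emin)
      want <- oracle_ld_clusters(edges, emin)
      expect_equal(length(got), length(want))
      for (k in seq_along(got)) {
        expect_equal(got[[k]]$loci, want[[k]]$loci)
        expect_equal(got[[k]]$birth_threshold, want[[k]]$birth_threshold)
        expect_equal(got[[k]]$edge_count, want[[k]]$edge_count)
      }
    }
  }
})

test_that("SMLA coordinates summarize a cluster's dosage variation", {
  set.seed(5)
  g <- matrix(rbinom(100, 2, 0.5), 1, 100)
  gl <- gl_exact(g)
  sm <- compute_smla(gl, 1)
  expect_equal(sm$variance_explained, 1)
  centered <- g[1, ] - mean(g[1, ])
  expect_equal(abs(cor(sm$coordinates, centered)), 1, tolerance = 1e-9)
  expect_gt(cor(sm$coordinates, centered), 0)  # sign convention
  expect_equal(mean(sm$coordinates), 0, tolerance = 1e-12)

  # ten perfectly correlated loci are rank one
  g10 <- matrix(rep(g, 10), 10, 100, byrow = TRUE)
  expect_equal(compute_smla(gl_exact(g10), 1:10)$variance_explained, 1)

  expect_error(compute_smla(gl_exact(matrix(1L, 3, 20)), 1:3), "constant")
})

test_that("without between-window LD, level-3 output is the level-1 clusters", {
  # two tight 12-locus blocks in different windows, mutually uncorrelated;
  # heterogeneous r2 makes level-1 clusters emerge in birth-sized pieces
  # which single-linkage at level 3 reunites per block (never across blocks)
  set.seed(6)
  x <- rbinom(80, 2, 0.5); y <- rbinom(80, 2, 0.5)
  noise <- function(v) { f <- rbinom(length(v), 1, 0.02); pmin(pmax(v + f, 0), 2) }
  g <- rbind(t(replicate(12, noise(x))), t(replicate(12, noise(y))))
  pos <- c(seq(0, by = 1000, length.out = 12), seq(2e5, by = 1000, length.out = 12))
  gl <- gl_exact(g, chrom = "chr1", pos = as.integer(pos))
  res <- ldna_nested_run(gl, ldna_params(emin = 10, snp_min = 4, cor_th = 0.8))
  expect_equal(length(res$clusters), 2)
  for (cl in res$clusters) {
    block <- unique(ifelse(cl$loci <= 12, 1L, 2L))
    expect_length(block, 1)           # no mixing across unlinked blocks
    expect_gte(length(cl$loci), 8)
  }
  # snp_min above any level-1 birth size removes everything
  res2 <- ldna_nested_run(gl, ldna_params(emin = 10, snp_min = 12, cor_th = 0.8))
  expect_equal(length(res2$clusters), 0)
})

test_that("correlated clusters on different chromosomes merge at level 3", {
  set.seed(7)
  n <- 150
  x <- rbinom(n, 2, 0.5)
  y <- x
  redraw <- sample(n, 12)                 # decorrelate ~8% of individuals
  y[redraw] <- rbinom(12, 2, 0.5)
  noise <- function(v) { f <- rbinom(length(v), 1, 0.02); pmin(pmax(v + f, 0), 2) }
  g <- rbind(t(replicate(15, noise(x))), t(replicate(15, noise(y))))
  gl <- gl_exact(g, chrom = rep(c("chr1", "chr2"), each = 15),
                 pos = as.integer(rep(seq(0, by = 1000, length.out = 15), 2)))
  # verify the construction: inter-chromosome SMLA r2 sits inside (0.8, 0.9)
  s1 <- compute_smla(gl, 1:15)$coordinates
  s2 <- compute_smla(gl, 16:30)$coordinates
  r2 <- cor(s1, s2)^2
  expect_gt(r2, 0.8); expect_lt(r2, 0.9)
  merged <- ldna_nested_run(gl, ldna_params(10, 4, cor_th = 0.8))
  expect_equal(length(merged$clusters), 1)
  expect_equal(merged$clusters[[1]]$level, 3L)
  split_ <- ldna_nested_run(gl, ldna_params(10, 4, cor_th = 0.9))
  expect_gte(length(split_$clusters), 2)
  chroms <- vapply(split_$clusters, function(cl) gl$sites$chrom[cl$loci[1]],
                   character(1))
  for (cl in split_$clusters) {
    expect_length(unique(gl$sites$chrom[cl$loci]), 1)  # no merge at 0.9
  }
  expect_setequal(unique(chroms), c("chr1", "chr2"))
})

test_that("clusters partition loci and refine monotonically in cor_th", {
  sc <- scenario_parallel_regions(31)
  prev_max <- Inf
  prev_n <- 0
  for (ct in c(0.5, 0.6, 0.7, 0.8)) {
    res <- ldna_nested_run(sc$gl, ldna_params(10, 10, cor_th = ct))
    loci <- unlist(lapply(res$clusters, `[[`, "loci"))
    expect_equal(anyDuplicated(loci), 0)  # partition: no locus in two clusters
    sizes <- vapply(res$clusters, function(x) length(x$loci), integer(1))
    expect_lte(max(sizes), prev_max)      # single-linkage cut only splits
    expect_gte(length(sizes), prev_n)     # ... into at least as many clusters
    prev_max <- max(sizes)
    prev_n <- length(sizes)
  }
})
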