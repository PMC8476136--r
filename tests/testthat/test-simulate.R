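test_that("the generator is a pure function of config and seed", {
  cfg <- sim_config(L = 1e6, n_chromosomes = 2, seed = 42)
  a <- simulate_metapopulation(cfg)
  b <- simulate_metapopulation(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$sites, b$sites)
  expect_identical(a$samples, b$samples)
  c <- simulate_metapopulation(sim_config(L = 1e6, n_chromosomes = 2, seed = 43))
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(m = -0.1), "migration")
  expect_error(sim_config(m = 1.5), "migration")
  expect_error(sim_config(samples_per_deme = 0), "samples_per_deme")
  expect_error(sim_config(admixture_fractions = c(0.5, 0.5)), "one entry per")
  expect_error(simulate_metapopulation(sim_config(mu = 1e-12, L = 1e4,
                                                  n_chromosomes = 1, seed = 1)),
               "zero segregating sites")
})

test_that("long-isolated demes show high Weir-Cockerham F_ST", {
  cfg <- sim_config(n_demes_marine = 2, n_demes_freshwater = 0,
                    Ne = 1000, mu = 2.5e-8, L = 1e6, n_chromosomes = 1,
                    split_time = 10000,  # 10 * Ne generations
                    admixture_fractions = c(1, 0), m = 0,
                    samples_per_deme = 10, seed = 99)
  sim <- simulate_metapopulation(cfg)
  calls <- hard_calls(genotypes_to_likelihoods(sim, noise_model(20, 0.01), seed = 1))
  fst <- wc_fst(calls, sim$samples$population)
  expect_gt(fst$estimate, 0.5)
})

test_that("Watterson's theta matches the 4*Ne*mu coalescent expectation", {
  theta_hat <- vapply(1:10, function(s) {
    cfg <- sim_config(n_demes_marine = 1, n_demes_freshwater = 0,
                      Ne = 5000, mu = 1e-7,   # 4*Ne*mu = 0.002
                      L = 1e6, n_chromosomes = 1, split_time = 0,
                      samples_per_deme = 20, F_block = 0, seed = s)
    sim <- simulate_metapopulation(cfg)
    watterson_theta(nrow(sim$sites), n = 40, L = 1e6)
  }, numeric(1))
  expect_lt(abs(mean(theta_hat) / 0.002 - 1), 0.25)
})

test_that("pi and Watterson's theta agree on neutral panmictic data", {
  ratio <- vapply(1:10, function(s) {
    cfg <- sim_config(n_demes_marine = 1, n_demes_freshwater = 0,
                      Ne = 5000, mu = 1e-7, L = 2e5, n_chromosomes = 1,
                      split_time = 0, samples_per_deme = 20, F_block = 0,
                      seed = 100 + s)
    sim <- simulate_metapopulation(cfg)
    pi_hat <- nucleotide_diversity(rowSums(sim$genotypes), L = 2e5,
                                   n_chrom = rep(40, nrow(sim$sites)))
    pi_hat / watterson_theta(nrow(sim$sites), 40, 2e5)
  }, numeric(1))
  expect_gt(mean(ratio), 0.8)
  expect_lt(mean(ratio), 1.25)
})

test_that("planted haplotypes hit their target frequencies and collide loudly", {
  cfg <- sim_config(L = 1e6, n_chromosomes = 1, samples_per_deme = 20, seed = 7)
  sim <- simulate_metapopulation(cfg)
  spec <- plant_spec("chr1", 2e5, 3e5, n_loci = 20, freshwater_freq = 0.9,
                     marine_freq = 0.1, age_mode = "young",
                     target_demes = c("F1", "F2", "F3", "F4"))
  # frequency control: with 20 diploids per deme the realized deme frequency
  # is a binomial draw, so the +/- 0.1 band holds for ~95% of deme draws
  devs <- unlist(lapply(1:10, function(s) {
    pl <- plant_parallel_haplotype(sim, spec, seed = s)
    idx <- which(pl$sites$pos %in% pl$truth$loci$pos)
    fr <- pl$deme_freqs[idx[1], ]
    abs(fr - rep(c(0.1, 0.9), each = 4))
  }))
  expect_gte(mean(devs <= 0.1), 0.9)
  expect_lt(max(devs), 0.2)
  planted <- plant_parallel_haplotype(sim, spec, seed = 5)
  idx <- which(planted$sites$pos %in% planted$truth$loci$pos)
  # planted loci are perfectly co-inherited
  g <- planted$genotypes[idx, ]
  expect_true(all(apply(g, 2, function(col) length(unique(col)) == 1)))
  # overlapping spans are rejected
  expect_error(plant_parallel_haplotype(planted,
    plant_spec("chr1", 2.5e5, 4e5, 10, 0.9, 0.1, "young", "F1")),
    "collides")
  # unknown demes are rejected
  expect_error(plant_parallel_haplotype(sim,
    plant_spec("chr1", 5e5, 6e5, 10, 0.9, 0.1, "young", "F9")),
    "unknown target")
})

test_that("equal plant frequencies carry no ecotype association", {
  cors <- vapply(1:20, function(s) {
    cfg <- sim_config(L = 2e5, n_chromosomes = 1, mu = 1e-8, seed = 200 + s)
    sim <- simulate_metapopulation(cfg)
    sim <- plant_parallel_haplotype(sim,
      plant_spec("chr1", 5e4, 1e5, 20, 0.5, 0.5, "young",
                 c("F1", "F2", "F3", "F4")), seed = 300 + s)
    gl <- genotypes_to_likelihoods(sim, noise_model(10, 0.01), seed = 400 + s)
    idx <- which(gl$sites$pos %in% sim$truth$loci$pos)
    sm <- compute_smla(gl, idx)
    abs(cor(sm$coordinates, sim$samples$ecotype))
  }, numeric(1))
  expect_lt(mean(cors), 0.1)
})

test_that("planted blocks are in stronger LD than the background", {
  cfg <- sim_config(L = 1e6, n_chromosomes = 1, mu = 1e-8, seed = 17)
  sim <- simulate_metapopulation(cfg)
  sim <- plant_parallel_haplotype(sim,
    plant_spec("chr1", 4e5, 5e5, 30, 0.9, 0.05, "young", c("F1", "F2", "F3", "F4")),
    seed = 18)
  gl <- genotypes_to_likelihoods(sim, noise_model(10, 0.01), seed = 19)
  planted_idx <- which(gl$sites$pos %in% sim$truth$loci$pos)
  bg_idx <- setdiff(seq_len(nrow(gl$sites)), planted_idx)[1:30]
  ld_p <- pairwise_ld(gl, planted_idx, edge_floor = 0)
  ld_b <- pairwise_ld(gl, bg_idx, edge_floor = 0)
  expect_gt(median(ld_p$r2), median(ld_b$r2))
  expect_gt(median(ld_p$r2), 0.8)
})

test_that("ancient blocks carry excess d_XY relative to young blocks", {
  higher <- vapply(1:10, function(s) {
    cfg <- sim_config(L = 1e6, n_chromosomes = 2, mu = 1e-8, seed = 500 + s)
    sim <- simulate_metapopulation(cfg)
    fresh <- c("F1", "F2", "F3", "F4")
    sim <- plant_parallel_haplotype(sim,
      plant_spec("chr1", 4e5, 5e5, 10, 0.9, 0.05, "ancient", fresh), seed = 600 + s)
    sim <- plant_parallel_haplotype(sim,
      plant_spec("chr2", 4e5, 5e5, 10, 0.9, 0.05, "young", fresh), seed = 700 + s)
    span <- function(ch) sim$sites$chrom == ch & sim$sites$pos >= 4e5 & sim$sites$pos < 5e5
    d_anc <- dxy(sim$deme_freqs[span("chr1"), "M1"], sim$deme_freqs[span("chr1"), "F1"], 1e5)
    d_yng <- dxy(sim$deme_freqs[span("chr2"), "M1"], sim$deme_freqs[span("chr2"), "F1"], 1e5)
    d_anc > d_yng
  }, logical(1))
  expect_true(all(higher))
})
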