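#' Canonical validation scenario: parallel outlier-region recovery
#'
#' A metapopulation of 4 marine and 4 freshwater demes (12 diploids each,
#' ~5k background SNPs over four 5-Mb chromosomes) with four planted
#' freshwater-adapted haplotype blocks: three shared by all freshwater demes
#' and one private to the freshwater deme of a single geographic region. All
#' blocks carry 50 co-inherited loci over 200 kb at frequency 0.9 in their
#' target demes versus 0.05 elsewhere (strong parallel selection on rare
#' standing variation).
#'
#' @param seed Integer seed.
#' @param mean_depth,base_error Read-noise settings for the emitted genotype
#'   likelihoods.
#' @return List with `sim` (the planted `metapop_sim`), `gl` ([gl_data]) and
#'   `truth` (the planted-region table).
#' @export
scenario_parallel_regions <- function(seed, mean_depth = 10, base_error = 0.01) {
  cfg <- sim_config(seed = seed)
  sim <- simulate_metapopulation(cfg)
  fresh_all <- sim$demes$deme[sim$demes$ecotype == 1]
  private <- fresh_all[1]
  plants <- list(
    plant_spec("chr1", 1.0e6, 1.2e6, 50, 0.9, 0.05, "ancient", fresh_all),
    plant_spec("chr2", 2.0e6, 2.2e6, 50, 0.9, 0.05, "young", fresh_all),
    plant_spec("chr3", 3.0e6, 3.2e6, 50, 0.9, 0.05, "ancient", fresh_all),
    plant_spec("chr4", 1.5e6, 1.7e6, 50, 0.9, 0.05, "young", private))
  for (i in seq_along(plants)) {
    sim <- plant_parallel_haplotype(sim, plants[[i]], seed = seed * 13 + i)
  }
  gl <- genotypes_to_likelihoods(sim, noise_model(mean_depth, base_error),
                                 seed = seed * 29 + 7)
  list(sim = sim, gl = gl, truth = sim$truth$regions)
}

#' Canonical validation scenario: ancient versus young haplotype divergence
#'
#' A denser-marker genome (four 6-Mb chromosomes, ~45k SNPs) with two planted
#' blocks shared by all freshwater demes: an ancient block (frequency 0.9 in
#' freshwater vs 0.05 in marine, with carrier-exclusive derived variants
#' across the span elevating d_XY) and a young block derived from common
#' marine standing variation (0.9 vs 0.65, no extra divergence). The ancient
#' block should exceed the neutral delta-d_XY interval; the young one should
#' not.
#'
#' @param seed Integer seed.
#' @param mean_depth,base_error Read-noise settings.
#' @return List with `sim`, `gl`, `truth` and `chrom_lengths`.
#' @export
scenario_ancient_young <- function(seed, mean_depth = 10, base_error = 0.01) {
  cfg <- sim_config(mu = 2.5e-8, L = 6e6, n_chromosomes = 4, seed = seed)
  sim <- simulate_metapopulation(cfg)
  fresh_all <- sim$demes$deme[sim$demes$ecotype == 1]
  sim <- plant_parallel_haplotype(
    sim, plant_spec("chr1", 1.0e6, 1.2e6, 10, 0.9, 0.05, "ancient", fresh_all),
    seed = seed * 13 + 1)
  sim <- plant_parallel_haplotype(
    sim, plant_spec("chr2", 1.0e6, 1.2e6, 10, 0.9, 0.65, "young", fresh_all),
    seed = seed * 13 + 2)
  gl <- genotypes_to_likelihoods(sim, noise_model(mean_depth, base_error),
                                 seed = seed * 29 + 7)
  list(sim = sim, gl = gl, truth = sim$truth$regions,
       chrom_lengths = stats::setNames(rep(cfg$L, cfg$n_chromosomes),
                                       paste0("chr", seq_len(cfg$n_chromosomes))))
}

#' Simulate one tight LD cluster as genotype likelihoods
#'
#' All loci are copies of a single haplotype indicator: each individual draws
#' two haplotypes (carrier/non-carrier, probability 1/2), every locus copies
#' the haplotype state with a small per-haplotype flip probability, and the
#' resulting genotypes are emitted as genotype likelihoods under the read
#' noise model. The first principal component of such a cluster typically
#' explains well over 90% of the dosage variance.
#'
#' @param seed Integer seed.
#' @param n_ind Number of diploid individuals.
#' @param n_loci Number of loci copied from the haplotype indicator.
#' @param flip Per-locus per-haplotype flip probability.
#' @param mean_depth,base_error Read-noise settings.
#' @return A [gl_data] object with `n_loci` sites.
#' @export
simulate_tight_ld_cluster <- function(seed, n_ind = 200, n_loci = 40,
                                      flip = 0.02, mean_depth = 20,
                                      base_error = 0.01) {
  with_seed(seed, {
    hap <- matrix(stats::rbinom(2 * n_ind, 1, 0.5), n_ind, 2)
    geno <- vapply(seq_len(n_loci), function(j) {
      fl <- matrix(stats::rbinom(2 * n_ind, 1, flip), n_ind, 2)
      as.integer(rowSums(abs(hap - fl)))
    }, integer(n_ind))
    genotypes_to_likelihoods(t(geno), noise_model(mean_depth, base_error),
                             seed = stats::rbinom(1, .Machine$integer.max, 0.5))
  })
}
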