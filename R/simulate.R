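#' Simulation configuration for the synthetic metapopulation
#'
#' Defines the demographic scenario the generator emulates: a chain of marine
#' demes exchanging migrants with their neighbours (stepping stone, producing
#' isolation by distance), freshwater demes founded from their nearest marine
#' deme (producing founder drift and lower diversity), and two divergent
#' lineages (WL west, EL east) meeting in an admixture cline along the marine
#' chain. Diversity is governed by theta = 4*Ne*mu per site.
#'
#' @param n_demes_marine,n_demes_freshwater Deme counts; freshwater demes are
#'   founded from evenly spaced marine demes.
#' @param Ne Diploid effective size per deme.
#' @param m Per-generation migration rate between adjacent marine demes.
#' @param marine_to_fresh_m Migration rate from a founder marine deme into its
#'   freshwater deme; smaller values mean stronger founder drift.
#' @param mu Per-site per-generation mutation rate.
#' @param L Sequence length per chromosome (bp).
#' @param n_chromosomes Number of chromosomes.
#' @param split_time Generations since the WL/EL lineage split.
#' @param admixture_fractions Optional per-marine-deme WL ancestry proportions;
#'   defaults to an even cline from 1 (west end) to 0 (east end).
#' @param samples_per_deme Diploid individuals sampled per deme.
#' @param n_geographic_regions Number of contiguous geographic region labels
#'   along the marine chain (capped at the number of marine demes).
#' @param block_size Length (bp) of the linkage blocks over which deme-level
#'   genealogical noise is shared (emulating the shared coalescent history of
#'   physically linked sites, the main source of window-to-window variance in
#'   divergence scans).
#' @param F_block Variance of the block-shared drift component (0 disables
#'   it).
#' @param seed Integer seed; all outputs are pure functions of (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_demes_marine = 4, n_demes_freshwater = 4,
                       Ne = 5000, m = 0.005, marine_to_fresh_m = 2.5e-4,
                       mu = 2.5e-9, L = 5e6, n_chromosomes = 4,
                       split_time = 2000, admixture_fractions = NULL,
                       samples_per_deme = 12, n_geographic_regions = 4,
                       block_size = 2e4, F_block = 0.04,
                       seed = 1) {
  cfg <- list(n_demes_marine = n_demes_marine,
              n_demes_freshwater = n_demes_freshwater,
              Ne = Ne, m = m, marine_to_fresh_m = marine_to_fresh_m,
              mu = mu, L = L, n_chromosomes = n_chromosomes,
              split_time = split_time,
              admixture_fractions = admixture_fractions,
              samples_per_deme = samples_per_deme,
              n_geographic_regions = n_geographic_regions,
              block_size = block_size, F_block = F_block,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_demes_marine < 1) stop("need at least one marine deme")
    if (n_demes_freshwater < 0) stop("n_demes_freshwater must be >= 0")
    rates <- c(m = m, marine_to_fresh_m = marine_to_fresh_m)
    if (any(rates < 0) || any(rates > 1)) stop("migration rates must lie in [0, 1]")
    if (mu < 0 || Ne <= 0 || L <= 0 || n_chromosomes < 1) stop("invalid mutation/size parameters")
    if (split_time < 0) stop("split_time must be >= 0")
    if (samples_per_deme < 1) stop("samples_per_deme must be >= 1")
    if (block_size <= 0 || F_block < 0 || F_block > 1) stop("invalid block-noise parameters")
    if (!is.null(admixture_fractions)) {
      if (length(admixture_fractions) != n_demes_marine) {
        stop("admixture_fractions must have one entry per marine deme")
      }
      stopifnot_prob(admixture_fractions, "admixture_fractions")
    }
  })
  invisible(cfg)
}

# Balding-Nichols drift: frequency after drift of strength F around mean p.
# F -> 0 returns p unchanged; F -> 1 is complete fixation.
bn_drift <- function(p, F) {
  if (F <= 1e-12) return(p)
  out <- p
  seg <- p > 0 & p < 1
  if (F >= 1 - 1e-9) {
    out[seg] <- as.numeric(stats::runif(sum(seg)) < p[seg])
  } else {
    shape <- (1 - F) / F
    out[seg] <- stats::rbeta(sum(seg), p[seg] * shape, (1 - p[seg]) * shape)
  }
  out
}

# Local drift strength implied by a migration rate into a deme of size Ne
# (two-deme island-model equilibrium F_ST ~ 1/(1 + 8*Ne*m)).
migration_F <- function(Ne, m) 1 / (1 + 8 * Ne * m)

#' Simulate a structured metapopulation with genotypes
#'
#' Segregating sites are drawn from the neutral site-frequency spectrum
#' (intensity theta/x for population derived-allele frequency x, which makes
#' the expected number of sites segregating in a sample of n chromosomes equal
#' to theta*L*a_n, the standard coalescent expectation), then propagated
#' through lineage-split, stepping-stone and founder drift as independent
#' Balding-Nichols draws, and finally sampled as diploid genotypes under
#' Hardy-Weinberg within demes. Background sites are therefore in linkage
#' equilibrium given deme structure; multi-locus LD enters through admixture
#' structure and through planted haplotype blocks
#' ([plant_parallel_haplotype()]).
#'
#' @param config A [sim_config()].
#' @return A `metapop_sim` object: list with `genotypes` (sites x individuals,
#'   0/1/2), `sites`, `samples` (the sample metadata table), `deme_freqs`
#'   (per-site true deme allele frequencies), `demes`, `truth` (planted-locus
#'   ledger, initially empty) and `config`.
#' @export
simulate_metapopulation <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_metapop_impl(config))
}

simulate_metapop_impl <- function(cfg) {
  nm <- cfg$n_demes_marine; nf <- cfg$n_demes_freshwater
  n_demes <- nm + nf
  n_ind <- n_demes * cfg$samples_per_deme
  n_chrom_sampled <- 2L * n_ind
  theta <- 4 * cfg$Ne * cfg$mu
  L_tot <- cfg$L * cfg$n_chromosomes

  # Candidate sites from the truncated 1/x frequency spectrum.
  x_min <- 0.05 / n_chrom_sampled
  n_cand <- stats::rpois(1, theta * L_tot * log(1 / x_min))
  if (n_cand == 0) stop("zero segregating sites: increase mu, Ne or L")
  p0 <- x_min^(1 - stats::runif(n_cand))

  # Lineage split.
  F_split <- 1 - exp(-cfg$split_time / (2 * cfg$Ne))
  p_wl <- bn_drift(p0, F_split)
  p_el <- bn_drift(p0, F_split)

  # Marine stepping-stone chains anchored in each lineage, admixed by alpha.
  F_step <- migration_F(cfg$Ne, cfg$m)
  alpha <- cfg$admixture_fractions %||%
    (if (nm == 1) 1 else rev(seq(0, 1, length.out = nm)))
  w <- matrix(0, n_cand, nm)
  e <- matrix(0, n_cand, nm)
  w[, 1] <- bn_drift(p_wl, F_step)
  if (nm > 1) for (d in 2:nm) w[, d] <- bn_drift(w[, d - 1], F_step)
  e[, nm] <- bn_drift(p_el, F_step)
  if (nm > 1) for (d in (nm - 1):1) e[, d] <- bn_drift(e[, d + 1], F_step)
  p_marine <- sweep(w, 2, alpha, "*") + sweep(e, 2, 1 - alpha, "*")

  # Freshwater demes founded from evenly spaced marine demes.
  F_fresh <- migration_F(cfg$Ne, cfg$marine_to_fresh_m)
  founder <- if (nf > 0) round(seq(1, nm, length.out = nf)) else integer(0)
  p_fresh <- if (nf > 0) {
    vapply(founder, function(d) bn_drift(p_marine[, d], F_fresh),
           numeric(n_cand))
  } else matrix(0, n_cand, 0)
  freqs <- cbind(p_marine, p_fresh)

  # Deme metadata: chain coordinates, lineage labels, geographic regions.
  n_reg <- max(1, min(cfg$n_geographic_regions, nm))
  reg_of_marine <- paste0("R", ceiling(seq_len(nm) / (nm / n_reg)))
  alpha_fresh <- if (nf > 0) alpha[founder] else numeric(0)
  lineage_label <- function(a) ifelse(a >= 0.75, "WL", ifelse(a <= 0.25, "EL", "ADMIXED"))
  demes <- data.frame(
    deme = c(paste0("M", seq_len(nm)), if (nf > 0) paste0("F", seq_len(nf))),
    ecotype = rep(c(0L, 1L), c(nm, nf)),
    lineage = c(lineage_label(alpha), lineage_label(alpha_fresh)),
    geographic_region = c(reg_of_marine, reg_of_marine[founder]),
    longitude = c(5 + 3 * (seq_len(nm) - 1),
                  if (nf > 0) 5 + 3 * (founder - 1) + 0.4),
    latitude = c(rep(60, nm), if (nf > 0) rep(60.6, nf)),
    stringsAsFactors = FALSE)

  # Site coordinates: uniform over chromosomes, unique, sorted (assigned
  # before genotype sampling so block-shared noise can be applied).
  chrom_id <- sample.int(cfg$n_chromosomes, n_cand, replace = TRUE)
  pos <- as.integer(floor(stats::runif(n_cand, 0, cfg$L)))
  ord <- order(chrom_id, pos)
  chrom_id <- chrom_id[ord]; pos <- pos[ord]
  freqs <- freqs[ord, , drop = FALSE]
  dup <- duplicated(cbind(chrom_id, pos))
  if (any(dup)) {
    chrom_id <- chrom_id[!dup]; pos <- pos[!dup]
    freqs <- freqs[!dup, , drop = FALSE]
  }

  # Block-shared genealogical noise: sites within a linkage block share one
  # standard-normal drift deviate per deme, emulating the shared coalescent
  # history of physically linked sites.
  if (cfg$F_block > 0) {
    block <- paste0(chrom_id, ":", floor(pos / cfg$block_size))
    bidx <- match(block, unique(block))
    z <- matrix(stats::rnorm(max(bidx) * n_demes), max(bidx), n_demes)
    freqs <- clamp(freqs + sqrt(cfg$F_block * freqs * (1 - freqs)) * z[bidx, ], 0, 1)
  }

  # Diploid genotypes per deme, then keep sites polymorphic in the sample.
  n_sites_cand <- nrow(freqs)
  geno <- matrix(0L, n_sites_cand, n_ind)
  deme_of_ind <- rep(seq_len(n_demes), each = cfg$samples_per_deme)
  for (d in seq_len(n_demes)) {
    idx <- which(deme_of_ind == d)
    geno[, idx] <- stats::rbinom(n_sites_cand * length(idx), 2L, freqs[, d])
  }
  ac <- rowSums(geno)
  keep <- ac > 0L & ac < n_chrom_sampled
  if (!any(keep)) stop("zero segregating sites: increase mu, Ne or L")
  geno <- geno[keep, , drop = FALSE]
  freqs <- freqs[keep, , drop = FALSE]
  chrom_id <- chrom_id[keep]; pos <- pos[keep]
  sites <- data.frame(chrom = paste0("chr", chrom_id), pos = pos,
                      allele1 = "0", allele2 = "1", stringsAsFactors = FALSE)

  samples <- data.frame(
    sample_id = sprintf("%s_%02d", demes$deme[deme_of_ind],
                        stats::ave(deme_of_ind, deme_of_ind, FUN = seq_along)),
    population = demes$deme[deme_of_ind],
    ecotype = demes$ecotype[deme_of_ind],
    lineage = demes$lineage[deme_of_ind],
    geographic_region = demes$geographic_region[deme_of_ind],
    latitude = demes$latitude[deme_of_ind],
    longitude = demes$longitude[deme_of_ind],
    stringsAsFactors = FALSE)

  colnames(freqs) <- demes$deme
  colnames(geno) <- samples$sample_id
  structure(list(genotypes = geno, sites = sites, samples = samples,
                 deme_freqs = freqs, demes = demes,
                 truth = empty_truth(), config = cfg),
            class = "metapop_sim")
}

#' @export
print.metapop_sim <- function(x, ...) {
  cat(sprintf("metapop_sim: %d segregating sites, %d individuals, %d demes (%d marine, %d freshwater), %d planted region(s)\n",
              nrow(x$sites), nrow(x$samples), nrow(x$demes),
              sum(x$demes$ecotype == 0), sum(x$demes$ecotype == 1),
              nrow(x$truth$regions)))
  invisible(x)
}

empty_truth <- function() {
  structure(list(
    loci = data.frame(plant_id = character(), chrom = character(), pos = integer(),
                      age_mode = character(), role = character(),
                      stringsAsFactors = FALSE),
    regions = data.frame(plant_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         age_mode = character(), target_demes = character(),
                         stringsAsFactors = FALSE)),
    class = "truth_table")
}

#' Specification of a planted freshwater-adapted haplotype block
#'
#' @param chromosome Chromosome name (e.g. `"chr1"`).
#' @param start,end Span in bp, 0-based half-open.
#' @param n_loci Number of perfectly co-inherited variants in the block
#'   (>= 2).
#' @param freshwater_freq Target haplotype frequency in the targeted
#'   freshwater demes.
#' @param marine_freq Target haplotype frequency everywhere else.
#' @param age_mode `"ancient"` (the haplotype carries extra carrier-exclusive
#'   derived variants across the span, elevating d_XY) or `"young"` (no extra
#'   divergence).
#' @param target_demes Character vector of freshwater deme names the
#'   haplotype is adapted in.
#' @param ancient_k Extra carrier-exclusive variants per kb in ancient mode.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(chromosome, start, end, n_loci,
                       freshwater_freq, marine_freq,
                       age_mode = c("young", "ancient"),
                       target_demes, ancient_k = 1) {
  age_mode <- match.arg(age_mode)
  stopifnot(end > start, start >= 0, n_loci >= 2)
  stopifnot_prob(c(freshwater_freq, marine_freq), "plant frequencies")
  structure(list(chromosome = chromosome, start = as.integer(start),
                 end = as.integer(end), n_loci = as.integer(n_loci),
                 freshwater_freq = freshwater_freq, marine_freq = marine_freq,
                 age_mode = age_mode, target_demes = target_demes,
                 ancient_k = ancient_k),
            class = "plant_spec")
}

#' Overlay a parallel freshwater-adapted haplotype block on simulated genotypes
#'
#' Each individual draws a carrier dosage c ~ Binomial(2, f) with f =
#' `freshwater_freq` in the targeted demes and `marine_freq` elsewhere; all
#' `n_loci` block variants then equal c (perfect co-inheritance, the LD signal
#' the network analysis detects). Ancient mode additionally seeds
#' `ancient_k` extra carrier-exclusive derived variants per kb across the
#' span, reproducing the excess absolute divergence (d_XY) of deeply
#' coalescing haplotypes; young mode adds none.
#'
#' @param sim A `metapop_sim` object.
#' @param spec A [plant_spec()].
#' @param seed Optional seed for the carrier draw.
#' @return The modified `metapop_sim` with updated genotypes, sites,
#'   `deme_freqs` (realized frequencies for planted sites) and truth table.
#' @export
plant_parallel_haplotype <- function(sim, spec, seed = NULL) {
  stopifnot(inherits(sim, "metapop_sim"), inherits(spec, "plant_spec"))
  cfg <- sim$config
  if (!spec$chromosome %in% paste0("chr", seq_len(cfg$n_chromosomes))) {
    stop("unknown chromosome: ", spec$chromosome)
  }
  if (spec$end > cfg$L) stop("plant span exceeds chromosome length")
  bad <- setdiff(spec$target_demes, sim$demes$deme[sim$demes$ecotype == 1])
  if (length(bad)) stop("unknown target freshwater deme(s): ", paste(bad, collapse = ", "))
  prev <- sim$truth$regions
  clash <- prev$chrom == spec$chromosome & prev$start < spec$end & prev$end > spec$start
  if (any(clash)) stop("plant span collides with earlier plant ", prev$plant_id[clash][1])

  with_seed(seed, {
    in_target <- sim$samples$population %in% spec$target_demes
    f_ind <- ifelse(in_target, spec$freshwater_freq, spec$marine_freq)
    carrier <- stats::rbinom(length(f_ind), 2L, f_ind)

    width <- spec$end - spec$start
    n_extra <- if (spec$age_mode == "ancient") max(0L, round(spec$ancient_k * width / 1000)) else 0L
    pos_assoc <- spec$start + floor(width * (seq_len(spec$n_loci) - 0.5) / spec$n_loci)
    pos_extra <- if (n_extra > 0) {
      spec$start + floor(width * (seq_len(n_extra) - 0.25) / n_extra)
    } else integer(0)
    new_pos <- c(pos_assoc, pos_extra)
    role <- rep(c("assoc", "ballast"), c(spec$n_loci, n_extra))
    # nudge collisions with existing or sibling sites to unique coordinates
    taken <- sim$sites$pos[sim$sites$chrom == spec$chromosome]
    for (i in seq_along(new_pos)) {
      while (new_pos[i] %in% taken || new_pos[i] %in% new_pos[-i]) new_pos[i] <- new_pos[i] + 1L
    }

    plant_id <- sprintf("plant%02d", nrow(prev) + 1L)
    n_new <- length(new_pos)
    new_geno <- matrix(rep(as.integer(carrier), each = n_new), n_new)
    colnames(new_geno) <- colnames(sim$genotypes)
    pop_of <- sim$samples$population
    realized <- vapply(sim$demes$deme,
                       function(d) mean(carrier[pop_of == d]) / 2, numeric(1))
    new_freqs <- matrix(rep(realized, each = n_new), n_new,
                        dimnames = list(NULL, sim$demes$deme))
    new_sites <- data.frame(chrom = spec$chromosome, pos = as.integer(new_pos),
                            allele1 = "0", allele2 = "1", stringsAsFactors = FALSE)

    sites <- rbind(sim$sites, new_sites)
    geno <- rbind(sim$genotypes, new_geno)
    freqs <- rbind(sim$deme_freqs, new_freqs)
    ord <- order(match(sites$chrom, paste0("chr", seq_len(cfg$n_chromosomes))), sites$pos)
    sim$sites <- sites[ord, , drop = FALSE]
    rownames(sim$sites) <- NULL
    sim$genotypes <- geno[ord, , drop = FALSE]
    sim$deme_freqs <- freqs[ord, , drop = FALSE]

    sim$truth$loci <- rbind(sim$truth$loci,
      data.frame(plant_id = plant_id, chrom = spec$chromosome,
                 pos = as.integer(new_pos), age_mode = spec$age_mode,
                 role = role, stringsAsFactors = FALSE))
    sim$truth$regions <- rbind(sim$truth$regions,
      data.frame(plant_id = plant_id, chrom = spec$chromosome,
                 start = spec$start, end = spec$end, age_mode = spec$age_mode,
                 target_demes = paste(spec$target_demes, collapse = ","),
                 stringsAsFactors = FALSE))
    sim
  })
}

#' Write or read the sample metadata / truth tables as TSV
#'
#' @param x A sample table or truth-table component (data.frame).
#' @param path File path.
#' @return `path` (writers) or a data.frame (reader), invisibly for writers.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
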