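#' Individual heterozygosity
#'
#' Proportion of called sites at which an individual is heterozygous.
#'
#' @param calls Integer matrix of genotypes (0/1/2, `NA` for no call), sites x
#'   individuals, e.g. from [hard_calls()].
#' @return Named numeric vector of H per individual; individuals with zero
#'   called sites get `NA` with a warning.
#' @export
individual_heterozygosity <- function(calls) {
  stopifnot(is.matrix(calls))
  called <- colSums(!is.na(calls))
  het <- colSums(calls == 1L, na.rm = TRUE)
  H <- het / called
  if (any(called == 0)) {
    warning(sum(called == 0), " individual(s) with zero called sites; H set to NA")
    H[called == 0] <- NA_real_
  }
  H
}

#' Nucleotide diversity
#'
#' Unbiased per-site pairwise diversity
#' pi = (1/L) * sum over sites of \[n/(n-1)\] * 2*p*(1-p), where n is the
#' number of sampled chromosomes and p the sample allele frequency at the
#' site.
#'
#' @param x Either a genotype call matrix (sites x individuals, 0/1/2/NA) or a
#'   numeric vector of per-site alternate-allele counts (then `n_chrom` is
#'   required).
#' @param L Number of accessible sites (monomorphic included).
#' @param n_chrom Per-site number of sampled chromosomes when `x` is a count
#'   vector.
#' @return Per-site nucleotide diversity (a single number).
#' @export
nucleotide_diversity <- function(x, L, n_chrom = NULL) {
  if (L <= 0) stop("L must be positive")
  if (is.matrix(x)) {
    n_chrom <- 2 * rowSums(!is.na(x))
    x <- rowSums(x, na.rm = TRUE)
  }
  stopifnot(length(x) == length(n_chrom))
  keep <- n_chrom >= 2
  x <- x[keep]; n_chrom <- n_chrom[keep]
  p <- x / n_chrom
  sum(n_chrom / (n_chrom - 1) * 2 * p * (1 - p)) / L
}

#' Watterson's theta
#'
#' theta_W = S / (a_n * L) with a_n = sum_{i=1}^{n-1} 1/i; its coalescent
#' expectation per site is 4*Ne*mu.
#'
#' @param S Number of segregating sites.
#' @param n Number of sampled chromosomes (>= 2).
#' @param L Number of accessible sites.
#' @return theta_W per site.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("watterson_theta() requires n >= 2 chromosomes")
  if (L <= 0) stop("L must be positive")
  S / (harmonic_a(n) * L)
}

#' Linearized F_ST
#'
#' f / (1 - f), the genetic-distance transform used for isolation-by-distance
#' regression.
#'
#' @param f F_ST value(s), must be < 1.
#' @return Linearized value(s).
#' @export
linearized_fst <- function(f) {
  if (any(f >= 1)) stop("linearized F_ST is undefined at f = 1")
  f / (1 - f)
}

# Per-locus Weir & Cockerham (1984) variance components for one biallelic
# locus set; nmat/pmat/hmat are sites x populations matrices of sample sizes
# (diploids), allele frequencies and observed heterozygote proportions.
wc_components <- function(nmat, pmat, hmat) {
  r <- ncol(nmat)
  used <- rowSums(nmat > 0) >= 2
  nmat <- nmat[used, , drop = FALSE]
  pmat <- pmat[used, , drop = FALSE]
  hmat <- hmat[used, , drop = FALSE]
  n_tot <- rowSums(nmat)
  r_eff <- rowSums(nmat > 0)
  nbar <- n_tot / r_eff
  nc <- (n_tot - rowSums(nmat^2) / n_tot) / (r_eff - 1)
  pbar <- rowSums(nmat * pmat) / n_tot
  s2 <- rowSums(nmat * (pmat - pbar)^2) / ((r_eff - 1) * nbar)
  hbar <- rowSums(nmat * hmat) / n_tot
  ok <- nbar > 1 & nc > 0
  nbar <- nbar[ok]; nc <- nc[ok]; pbar <- pbar[ok]; s2 <- s2[ok]
  hbar <- hbar[ok]; r_eff <- r_eff[ok]
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r_eff - 1) / r_eff * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r_eff - 1) / r_eff * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  data.frame(a = a, b = b, c = c_)
}

wc_from_calls <- function(calls, pops) {
  pop_levels <- unique(pops)
  nmat <- pmat <- hmat <- matrix(0, nrow(calls), length(pop_levels))
  for (j in seq_along(pop_levels)) {
    sub <- calls[, pops == pop_levels[j], drop = FALSE]
    n <- rowSums(!is.na(sub))
    nmat[, j] <- n
    pmat[, j] <- ifelse(n > 0, rowSums(sub, na.rm = TRUE) / (2 * n), 0)
    hmat[, j] <- ifelse(n > 0, rowSums(sub == 1L, na.rm = TRUE) / n, 0)
  }
  comp <- wc_components(nmat, pmat, hmat)
  est <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  list(estimate = est, components = comp)
}

#' Weir-Cockerham F_ST
#'
#' Ratio-of-sums multi-locus estimator: per-locus variance components a
#' (among populations), b (among individuals within populations) and c
#' (within individuals) following Weir & Cockerham (1984), combined as
#' sum(a) / sum(a + b + c). Negative estimates are reported as computed.
#'
#' @param calls Genotype call matrix (sites x individuals, 0/1/2/NA).
#' @param pops Population label per individual.
#' @param scope `"global"` for one estimate over all populations,
#'   `"pairwise"` for every population pair, `"per_ecotype"` for one global
#'   estimate within each ecotype class (requires `ecotype`).
#' @param ecotype Binary 0/1 vector per individual, used by the
#'   `"per_ecotype"` scope.
#' @return For `"global"`: an `fst_result` list with `estimate`, per-locus
#'   `components`, `scope` and `n_loci`. For `"pairwise"`: the same with
#'   `estimate` a symmetric matrix (zero diagonal). For `"per_ecotype"`: a
#'   list of two `fst_result` objects named `marine` and `freshwater`.
#' @export
wc_fst <- function(calls, pops, scope = c("global", "pairwise", "per_ecotype"),
                   ecotype = NULL) {
  scope <- match.arg(scope)
  stopifnot(is.matrix(calls), length(pops) == ncol(calls))
  pops <- as.character(pops)
  if (scope == "per_ecotype") {
    if (is.null(ecotype) || length(ecotype) != ncol(calls)) {
      stop("scope 'per_ecotype' needs an ecotype vector")
    }
    return(list(
      marine = wc_fst(calls[, ecotype == 0, drop = FALSE], pops[ecotype == 0]),
      freshwater = wc_fst(calls[, ecotype == 1, drop = FALSE], pops[ecotype == 1])))
  }
  all_missing <- vapply(unique(pops), function(p) {
    all(is.na(calls[, pops == p, drop = FALSE]))
  }, logical(1))
  if (any(all_missing)) {
    drop_pops <- unique(pops)[all_missing]
    warning("excluding population(s) with no called data: ",
            paste(drop_pops, collapse = ", "))
    keep <- !pops %in% drop_pops
    calls <- calls[, keep, drop = FALSE]
    pops <- pops[keep]
  }
  pop_levels <- unique(pops)
  if (length(pop_levels) < 2) stop("wc_fst() needs at least two populations with data")
  if (scope == "global") {
    res <- wc_from_calls(calls, pops)
    structure(list(estimate = res$estimate, components = res$components,
                   scope = scope, n_loci = nrow(res$components)),
              class = "fst_result")
  } else {
    k <- length(pop_levels)
    est <- matrix(0, k, k, dimnames = list(pop_levels, pop_levels))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      sel <- pops %in% pop_levels[c(i, j)]
      est[i, j] <- est[j, i] <-
        wc_from_calls(calls[, sel, drop = FALSE], pops[sel])$estimate
    }
    structure(list(estimate = est, components = NULL, scope = scope,
                   n_loci = nrow(calls)),
              class = "fst_result")
  }
}

#' @export
print.fst_result <- function(x, ...) {
  if (x$scope == "global") {
    cat(sprintf("Weir-Cockerham F_ST (global, %d loci): %.4f\n", x$n_loci, x$estimate))
    if (!is.null(x$ci)) cat(sprintf("  95%% bootstrap CI: [%.4f, %.4f]\n", x$ci[1], x$ci[2]))
  } else {
    cat("Weir-Cockerham F_ST (pairwise):\n")
    print(round(x$estimate, 4))
  }
  invisible(x)
}

#' Block bootstrap confidence interval for global F_ST
#'
#' Each resample draws a fraction of the markers and a fraction of the
#' samples (without replacement by default) and recomputes the global
#' ratio-of-sums estimate; the 2.5/97.5 percentiles form the interval.
#'
#' @param calls Genotype call matrix (sites x individuals).
#' @param pops Population label per individual.
#' @param n_boot Number of bootstrap resamples (> 0).
#' @param marker_frac,sample_frac Fractions of markers/samples per resample.
#' @param replace Resample with replacement instead (dialect flag).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @return List with `ci` (length-2 interval), `estimates` (all resample
#'   values) and `n_redraws` (resamples redrawn for having < 2 populations).
#' @export
bootstrap_fst_ci <- function(calls, pops, n_boot = 1000,
                             marker_frac = 1 / 3, sample_frac = 1 / 3,
                             replace = FALSE, seed = NULL) {
  if (n_boot <= 0) stop("n_boot must be positive")
  pops <- as.character(pops)
  n_m <- max(2L, floor(nrow(calls) * marker_frac))
  n_s <- max(4L, floor(ncol(calls) * sample_frac))
  with_seed(seed, {
    est <- numeric(n_boot)
    n_redraws <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        mi <- sample.int(nrow(calls), n_m, replace = replace)
        si <- sample.int(ncol(calls), n_s, replace = replace)
        sub <- calls[mi, si, drop = FALSE]
        sub_pops <- pops[si]
        with_data <- vapply(unique(sub_pops), function(p) {
          any(!is.na(sub[, sub_pops == p, drop = FALSE]))
        }, logical(1))
        if (sum(with_data) >= 2) break
        n_redraws <- n_redraws + 1L
      }
      est[b] <- suppressWarnings(wc_from_calls(sub, sub_pops)$estimate)
    }
    if (n_redraws > 0.01 * n_boot) {
      warning("more than 1% of bootstrap resamples were redrawn (", n_redraws, ")")
    }
    list(ci = unname(stats::quantile(est, c(0.025, 0.975), na.rm = TRUE)),
         estimates = est, n_redraws = n_redraws)
  })
}

#' Per-population diversity estimates
#'
#' Bundles individual heterozygosity with per-population summaries:
#' segregating sites S, sampled chromosomes n (twice the median call count),
#' the harmonic number a_n, nucleotide diversity pi and Watterson's theta
#' (theta_W = S/(a_n*L) exactly).
#'
#' @param calls Genotype call matrix (sites x individuals, 0/1/2/NA).
#' @param pops Population label per individual.
#' @param L Accessible sites per population (single number).
#' @return List with `H` (per individual) and `by_population` (data.frame
#'   with columns `population`, `S`, `n`, `a_n`, `pi`, `theta_w`).
#' @export
diversity_estimates <- function(calls, pops, L) {
  stopifnot(is.matrix(calls), length(pops) == ncol(calls), L > 0)
  H <- individual_heterozygosity(calls)
  by_pop <- lapply(unique(as.character(pops)), function(p) {
    sub <- calls[, pops == p, drop = FALSE]
    ac <- rowSums(sub, na.rm = TRUE)
    nc <- 2 * rowSums(!is.na(sub))
    seg <- ac > 0 & ac < nc
    n <- 2 * round(stats::median(rowSums(!is.na(sub))))
    data.frame(population = p, S = sum(seg), n = n,
               a_n = if (n >= 2) harmonic_a(n) else NA_real_,
               pi = nucleotide_diversity(ac, L, nc),
               theta_w = if (n >= 2) watterson_theta(sum(seg), n, L) else NA_real_)
  })
  list(H = H, by_population = do.call(rbind, by_pop))
}
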