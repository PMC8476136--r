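#' Absolute divergence d_XY between two populations
#'
#' d_XY = (1/L) * sum over sites of \[p1(1-p2) + p2(1-p1)\], the mean
#' pairwise between-population sequence difference per site.
#'
#' @param p1,p2 Allele frequencies of the two populations at the same sites.
#' @param L Number of accessible sites (monomorphic included).
#' @return d_XY per site.
#' @export
dxy <- function(p1, p2, L) {
  if (L <= 0) stop("L must be positive")
  stopifnot(length(p1) == length(p2))
  sum(p1 * (1 - p2) + p2 * (1 - p1)) / L
}

#' Per-population allele frequencies from genotype calls
#'
#' @param calls Genotype call matrix (sites x individuals, 0/1/2/NA).
#' @param pops Population label per individual.
#' @return List with `freq` (sites x populations) and `n_chrom` (called
#'   chromosomes per site and population).
#' @export
freq_by_pop <- function(calls, pops) {
  pop_levels <- unique(as.character(pops))
  freq <- n_chrom <- matrix(0, nrow(calls), length(pop_levels),
                            dimnames = list(NULL, pop_levels))
  for (j in seq_along(pop_levels)) {
    sub <- calls[, pops == pop_levels[j], drop = FALSE]
    n <- 2 * rowSums(!is.na(sub))
    n_chrom[, j] <- n
    freq[, j] <- ifelse(n > 0, rowSums(sub, na.rm = TRUE) / n, NA_real_)
  }
  list(freq = freq, n_chrom = n_chrom)
}

# Window index (0-based start) for each site.
window_of <- function(pos, window_size) floor(pos / window_size) * window_size

#' Excess absolute divergence of a focal region (delta d_XY)
#'
#' For each marine-freshwater population pair, window-wise d_XY is regressed
#' on window-wise pooled-pair nucleotide diversity across the genome
#' (ordinary least squares); the focal statistic is the mean regression
#' residual over the focal region's windows, averaged across pairs. The same
#' statistic on `n_neutral` random size-matched regions (drawn from windows
#' outside all excluded regions) gives a neutral reference distribution whose
#' 95% percentile interval classifies the focal region: ancient haplotypes
#' carry excess divergence and exceed the upper bound, young ones do not.
#'
#' @param sites Site table (`chrom`, `pos`).
#' @param pop_freqs Sites x populations allele-frequency matrix (e.g.
#'   `freq_by_pop()$freq` or a simulator's true deme frequencies).
#' @param pairs data.frame with `pop1`, `pop2` columns naming the population
#'   pairs to average over.
#' @param focal_region One-row data.frame (`chrom`, `start`, `end`).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window_size Window size for the genome-wide regression (bp).
#' @param n_neutral Number of random neutral regions.
#' @param exclude Optional data.frame of regions (e.g. all called outliers)
#'   whose windows are excluded from the neutral draw; the focal region is
#'   always excluded.
#' @param seed Integer seed for the neutral draw.
#' @return A `divergence_profile` list: `delta_dxy` (focal mean residual),
#'   `neutral_ci95`, `exceeds_ci`, `neutral_values`, `windows` (per-window
#'   d_XY, pi and residual, averaged over pairs).
#' @export
delta_dxy <- function(sites, pop_freqs, pairs, focal_region, chrom_lengths,
                      window_size = 2e4, n_neutral = 100, exclude = NULL,
                      seed = NULL) {
  stopifnot(nrow(pop_freqs) == nrow(sites), nrow(pairs) >= 1)
  win_start <- window_of(sites$pos, window_size)
  win_key <- paste0(sites$chrom, ":", win_start)

  # all windows tiling the genome (including SNP-free ones, which carry
  # d_XY = pi = 0 and anchor the regression near the origin)
  all_wins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    st <- seq(0, chrom_lengths[[ch]] - 1, by = window_size)
    data.frame(chrom = ch, start = st, stringsAsFactors = FALSE)
  }))
  all_keys <- paste0(all_wins$chrom, ":", all_wins$start)

  overlaps <- function(region) {
    all_wins$chrom == region$chrom &
      all_wins$start < region$end & (all_wins$start + window_size) > region$start
  }
  blocked <- overlaps(focal_region)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (r in seq_len(nrow(exclude))) blocked <- blocked | overlaps(exclude[r, ])
  }

  # the d_XY ~ pi line is anchored on windows outside all candidate-outlier
  # regions so a few extreme focal windows cannot lever the fit through
  # themselves; residuals are then evaluated for every window
  resid_mat <- matrix(0, nrow(all_wins), nrow(pairs))
  dxy_mat <- pi_mat <- matrix(0, nrow(all_wins), nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    p1 <- pop_freqs[, pairs$pop1[k]]
    p2 <- pop_freqs[, pairs$pop2[k]]
    ok <- !is.na(p1) & !is.na(p2)
    d_site <- ifelse(ok, p1 * (1 - p2) + p2 * (1 - p1), 0)
    pbar <- (p1 + p2) / 2
    pi_site <- ifelse(ok, 2 * pbar * (1 - pbar), 0)
    d_w <- tapply(d_site, win_key, sum)[all_keys]
    pi_w <- tapply(pi_site, win_key, sum)[all_keys]
    d_w[is.na(d_w)] <- 0; pi_w[is.na(pi_w)] <- 0
    d_w <- d_w / window_size; pi_w <- pi_w / window_size
    cf <- stats::lm.fit(cbind(1, pi_w[!blocked]), d_w[!blocked])$coefficients
    resid_mat[, k] <- d_w - (cf[1] + cf[2] * pi_w)
    dxy_mat[, k] <- d_w; pi_mat[, k] <- pi_w
  }
  resid_avg <- rowMeans(resid_mat)

  focal_idx <- which(overlaps(focal_region))
  if (length(focal_idx) == 0) stop("focal region overlaps no window")
  focal_stat <- mean(resid_avg[focal_idx])
  width_w <- length(focal_idx)
  neutral_stats <- with_seed(seed, {
    # candidate neutral regions: non-overlapping runs of `w` consecutive free
    # windows; if too few size-matched candidates exist, the width is relaxed
    # to the nearest smaller size that yields enough
    candidates_of_width <- function(w) {
      cand <- list()
      for (ch in unique(all_wins$chrom)) {
        idx <- which(all_wins$chrom == ch & !blocked)
        if (length(idx) == 0) next
        runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
        for (run in runs) {
          for (j in seq_len(floor(length(run) / w))) {
            cand[[length(cand) + 1L]] <- run[((j - 1) * w + 1):(j * w)]
          }
        }
      }
      cand
    }
    cand <- candidates_of_width(width_w)
    if (length(cand) < n_neutral && width_w > 1) {
      for (w in (width_w - 1):1) {
        cand <- candidates_of_width(w)
        if (length(cand) >= n_neutral) {
          warning("fewer than n_neutral size-matched candidates; ",
                  "relaxed neutral-region width from ", width_w,
                  " to ", w, " window(s)")
          break
        }
      }
    }
    if (length(cand) < n_neutral) {
      stop("not enough neutral candidate windows (", length(cand), " < ", n_neutral, ")")
    }
    sel <- sample(cand, n_neutral)
    vapply(sel, function(idx) mean(resid_avg[idx]), numeric(1))
  })
  ci <- unname(stats::quantile(neutral_stats, c(0.025, 0.975)))
  structure(list(delta_dxy = focal_stat, neutral_ci95 = ci,
                 exceeds_ci = focal_stat > ci[2],
                 neutral_values = neutral_stats,
                 windows = data.frame(chrom = all_wins$chrom,
                                      start = all_wins$start,
                                      dxy = rowMeans(dxy_mat),
                                      pi = rowMeans(pi_mat),
                                      residual = resid_avg)),
            class = "divergence_profile")
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat(sprintf("delta d_XY = %.3g, neutral 95%% CI [%.3g, %.3g] -> %s\n",
              x$delta_dxy, x$neutral_ci95[1], x$neutral_ci95[2],
              if (x$exceeds_ci) "EXCEEDS (ancient-like)" else "within CI"))
  invisible(x)
}
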