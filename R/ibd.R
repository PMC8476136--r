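#' Great-circle distance matrix between populations
#'
#' Haversine distances on a sphere of radius 6371.0088 km between population
#' centroids (mean latitude/longitude of their samples).
#'
#' @param samples Sample metadata table with `population`, `latitude`,
#'   `longitude` columns (one row per sample or per population).
#' @return Symmetric distance matrix in km with zero diagonal, population
#'   names as dimnames.
#' @export
great_circle_distances <- function(samples) {
  stopifnot(all(c("population", "latitude", "longitude") %in% names(samples)))
  if (any(abs(samples$latitude) > 90)) stop("latitude out of range [-90, 90]")
  if (any(abs(samples$longitude) > 180)) stop("longitude out of range [-180, 180]")
  lat <- tapply(samples$latitude, samples$population, mean)
  lon <- tapply(samples$longitude, samples$population, mean)
  pops <- names(lat)
  coords <- cbind(lon = as.numeric(lon), lat = as.numeric(lat))
  d <- geosphere::distm(coords, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371008.8)
  }) / 1000
  dimnames(d) <- list(pops, pops)
  d
}

# Deterministic one-dimensional 2-means: the split of sorted values that
# minimizes total within-group sum of squares.
two_means_split <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ss <- vapply(seq_len(n - 1), function(k) {
    (cs2[k] - cs[k]^2 / k) +
      ((cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k))
  }, numeric(1))
  k <- which.min(ss)
  upper <- logical(n)
  upper[ord[(k + 1):n]] <- TRUE
  upper
}

mlpe_reml <- function(rho, X, y, ZZt, reml = TRUE) {
  n <- nrow(X); p <- ncol(X)
  V <- diag(n) + rho * (ZZt - 2 * diag(n))
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  logdetV <- 2 * sum(log(diag(R)))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  XtViX <- crossprod(X, Vi_X)
  XtViy <- crossprod(X, Vi_y)
  beta <- solve(XtViX, XtViy)
  r <- y - X %*% beta
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  q <- max(drop(crossprod(r, Vi_r)), 1e-300)  # guard exact fits
  if (reml) {
    sigma2 <- q / (n - p)
    ll <- -0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
                    (n - p) * log(sigma2) + (n - p))
  } else {
    sigma2 <- q / n
    ll <- -0.5 * (logdetV + n * log(sigma2) + n)
  }
  list(loglik = as.numeric(ll), beta = drop(beta), sigma2 = sigma2,
       cov_beta = sigma2 * solve(XtViX))
}

#' Fit a maximum-likelihood population effects (MLPE) regression
#'
#' Generalized least squares of a pairwise response (e.g. linearized F_ST, or
#' a parallelism score) on a pairwise predictor (geographic distance,
#' divergence time) under the MLPE residual correlation structure: two
#' observations correlate rho when their population pairs share exactly one
#' population and are independent otherwise. rho is estimated by profiled
#' restricted maximum likelihood (or ML).
#'
#' @param obs data.frame with columns `pop_i`, `pop_j`, `x`, `y`; one row per
#'   unordered population pair.
#' @param method `"REML"` (default) or `"ML"`.
#' @param rho Fix the correlation at a given value instead of estimating it
#'   (`rho = 0` reduces the fit to ordinary least squares).
#' @return An `mlpe_fit` list: `beta` (slope), `intercept`, `rho`, `sigma2`,
#'   `se_beta`, `p_value` (Wald t test of the slope), `loglik`, `df`.
#' @export
mlpe_fit <- function(obs, method = c("REML", "ML"), rho = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("pop_i", "pop_j", "x", "y") %in% names(obs)))
  if (any(obs$pop_i == obs$pop_j)) stop("self-pairs are not allowed")
  if (!all(is.finite(obs$y))) stop("response must be finite")
  pops <- unique(c(obs$pop_i, obs$pop_j))
  if (length(pops) < 4) stop("mlpe_fit() needs at least 4 populations (6 pairs)")
  n <- nrow(obs)
  Z <- matrix(0, n, length(pops))
  Z[cbind(seq_len(n), match(obs$pop_i, pops))] <- 1
  Z[cbind(seq_len(n), match(obs$pop_j, pops))] <- 1
  ZZt <- tcrossprod(Z)
  X <- cbind(1, obs$x)
  if (qr(X)$rank < 2) stop("singular design: predictor is constant")
  y <- obs$y
  reml <- method == "REML"
  ev <- eigen(ZZt, symmetric = TRUE, only.values = TRUE)$values
  rho_hi <- if (min(ev) < 2) 1 / (2 - min(ev)) - 1e-6 else 0.999
  if (is.null(rho)) {
    opt <- stats::optimize(function(r) mlpe_reml(r, X, y, ZZt, reml)$loglik,
                           c(0, rho_hi), maximum = TRUE, tol = 1e-9)
    rho_hat <- opt$maximum
    # the interior optimum can be spurious when the true optimum sits at 0
    if (mlpe_reml(0, X, y, ZZt, reml)$loglik >= opt$objective) rho_hat <- 0
  } else {
    if (rho >= rho_hi + 1e-6 || rho < 0) stop("rho outside the positive-definite range")
    rho_hat <- rho
  }
  fit <- mlpe_reml(rho_hat, X, y, ZZt, reml)
  se <- sqrt(fit$cov_beta[2, 2])
  tval <- fit$beta[2] / se
  df <- n - 2
  structure(list(beta = unname(fit$beta[2]), intercept = unname(fit$beta[1]),
                 rho = rho_hat, sigma2 = fit$sigma2, se_beta = se,
                 p_value = 2 * stats::pt(-abs(tval), df),
                 loglik = fit$loglik, df = df, method = method,
                 n_pops = length(pops), n_pairs = n),
            class = "mlpe_fit")
}

#' @export
print.mlpe_fit <- function(x, ...) {
  cat(sprintf("MLPE fit (%s): beta = %.4g (se %.3g, P = %.3g), rho = %.3f, %d pops / %d pairs\n",
              x$method, x$beta, x$se_beta, x$p_value, x$rho, x$n_pops, x$n_pairs))
  invisible(x)
}

#' Ratio of two MLPE slopes
#'
#' Used to compare the strength of isolation by distance between habitats or
#' species.
#'
#' @param fit_a,fit_b `mlpe_fit` objects (or bare slopes).
#' @return beta_a / beta_b, sign preserved.
#' @export
slope_ratio <- function(fit_a, fit_b) {
  ba <- if (inherits(fit_a, "mlpe_fit")) fit_a$beta else fit_a
  bb <- if (inherits(fit_b, "mlpe_fit")) fit_b$beta else fit_b
  if (bb == 0) stop("denominator slope is zero")
  ba / bb
}

#' Parallelism score for a pair of freshwater populations
#'
#' Proportion (relative to the entire data set) of loci belonging to
#' ecotype-associated LD clusters (-log10 P > 2) whose SMLA groups the two
#' freshwater populations: the cluster's individuals are split by
#' deterministic 2-means on the SMLA coordinate, the in-group is the side
#' with the higher freshwater fraction, and the cluster groups the pair when
#' at least one individual from each population falls in the in-group.
#'
#' @param smla_mat Matrix of SMLA coordinates, individuals x clusters.
#' @param p_values Per-cluster association P values (same order as columns).
#' @param n_loci Per-cluster locus counts.
#' @param samples Sample metadata table aligned with `smla_mat` rows.
#' @param pop_pair Character vector of the two freshwater population names.
#' @param total_loci Total loci in the data set (the score denominator).
#' @return Proportion in \[0, 1\].
#' @export
parallelism_score <- function(smla_mat, p_values, n_loci, samples, pop_pair,
                              total_loci) {
  stopifnot(length(pop_pair) == 2, ncol(smla_mat) == length(p_values),
            length(n_loci) == length(p_values))
  in_pair <- lapply(pop_pair, function(p) which(samples$population == p))
  if (any(vapply(in_pair, length, 1L) == 0)) {
    stop("population pair has no sampled individuals: ",
         paste(pop_pair, collapse = ", "))
  }
  passing <- which(-log10(p_values) > 2)
  if (length(passing) == 0) return(0)
  fresh <- samples$ecotype == 1
  grouped <- vapply(passing, function(k) {
    upper <- two_means_split(smla_mat[, k])
    in_group <- if (mean(fresh[upper]) >= mean(fresh[!upper])) upper else !upper
    all(vapply(in_pair, function(idx) any(in_group[idx]), logical(1)))
  }, logical(1))
  sum(n_loci[passing][grouped]) / total_loci
}
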