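#' Genotype-likelihood container
#'
#' Bundles per-site metadata with normalized genotype likelihoods, the
#' universal input of the pipeline. Likelihood triples (hom-ref, het, hom-alt)
#' are stored per site and individual and must each sum to one. Positions are
#' 0-based half-open internally; the beagle writer emits the conventional
#' 1-based marker ids.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based integer),
#'   `allele1`, `allele2`; positions must be strictly increasing within each
#'   chromosome.
#' @param gl numeric array of dimension `c(nrow(sites), n_samples, 3)`; each
#'   `gl[s, i, ]` triple must sum to 1 (tolerance 1e-9 per triple is enforced
#'   up to 1e-6 to allow text round trips).
#' @param samples character vector of sample identifiers.
#' @return An object of class `gl_data`.
#' @export
gl_data <- function(sites, gl, samples) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos", "allele1", "allele2") %in% names(sites)))
  if (nrow(sites) == 0L) {
    gl <- array(numeric(0), dim = c(0L, length(samples), 3L))
  }
  stopifnot(length(dim(gl)) == 3L, dim(gl)[1] == nrow(sites), dim(gl)[3] == 3L,
            dim(gl)[2] == length(samples))
  if (nrow(sites) > 0L) {
    sums <- gl[, , 1] + gl[, , 2] + gl[, , 3]
    if (any(abs(sums - 1) > 1e-6)) stop("genotype-likelihood triples must sum to 1")
    ord_ok <- all(tapply(sites$pos, sites$chrom, function(p) all(diff(p) > 0)))
    if (!isTRUE(ord_ok)) stop("positions must be strictly increasing within chromosomes")
  }
  structure(list(sites = sites, gl = gl, samples = as.character(samples)),
            class = "gl_data")
}

#' @export
print.gl_data <- function(x, ...) {
  cat(sprintf("gl_data: %d sites x %d individuals on %d chromosome(s)\n",
              nrow(x$sites), length(x$samples), length(unique(x$sites$chrom))))
  invisible(x)
}

#' @export
dim.gl_data <- function(x) c(nrow(x$sites), length(x$samples))

#' Posterior-mean dosages from genotype likelihoods
#'
#' E\[g\] = 0*GL0 + 1*GL1 + 2*GL2 under a uniform genotype prior; this is the
#' quantity all LD, SMLA and relatedness computations operate on.
#'
#' @param gl A [gl_data] object.
#' @return Numeric matrix, sites x individuals.
#' @export
dosage_matrix <- function(gl) {
  stopifnot(inherits(gl, "gl_data"))
  d <- gl$gl[, , 2, drop = FALSE] + 2 * gl$gl[, , 3, drop = FALSE]
  dim(d) <- dim(gl$gl)[1:2]
  dimnames(d) <- list(NULL, gl$samples)
  d
}

#' Hard genotype calls with a confidence mask
#'
#' Argmax-GL calls; entries whose maximum likelihood falls below `min_gl` are
#' set to `NA`. Diversity and differentiation statistics operate on these
#' calls.
#'
#' @param gl A [gl_data] object.
#' @param min_gl Minimum normalized likelihood required to call a genotype.
#' @return Integer matrix (0/1/2/NA), sites x individuals.
#' @export
hard_calls <- function(gl, min_gl = 0.9) {
  stopifnot(inherits(gl, "gl_data"))
  n_sites <- nrow(gl$sites)
  n_ind <- length(gl$samples)
  g0 <- gl$gl[, , 1]; g1 <- gl$gl[, , 2]; g2 <- gl$gl[, , 3]
  best <- pmax(g0, g1, g2)
  call <- ifelse(g2 == best, 2L, ifelse(g1 == best, 1L, 0L))
  call[best < min_gl] <- NA_integer_
  call <- matrix(as.integer(call), n_sites, n_ind)
  colnames(call) <- gl$samples
  call
}

#' Read-depth noise model for genotype-likelihood emulation
#'
#' @param mean_depth Mean sequencing depth (reads per site, Poisson).
#' @param base_error Per-read base-miscall probability (must be < 0.5).
#' @return A `noise_model` list.
#' @export
noise_model <- function(mean_depth = 10, base_error = 0.01) {
  stopifnot(mean_depth >= 0, base_error >= 0, base_error < 0.5)
  structure(list(mean_depth = mean_depth, base_error = base_error),
            class = "noise_model")
}

#' Convert hard genotypes to noisy genotype likelihoods
#'
#' Per site and individual a read depth d ~ Poisson(mean_depth) is drawn, alt
#' reads follow the genotype (P(alt) = eps, 0.5, 1 - eps for genotypes 0, 1,
#' 2), and each genotype's likelihood is the binomial read likelihood
#' p^a (1-p)^(d-a), normalized to sum 1. Zero depth yields the uninformative
#' (1/3, 1/3, 1/3) triple.
#'
#' @param genotypes Integer matrix (0/1/2), sites x individuals, or a
#'   `metapop_sim` object from [simulate_metapopulation()].
#' @param noise A [noise_model()].
#' @param seed Integer seed; the output is a pure function of inputs and seed.
#' @param sites,samples Site table and sample ids; taken from the simulation
#'   object when one is supplied.
#' @return A [gl_data] object.
#' @export
genotypes_to_likelihoods <- function(genotypes, noise = noise_model(), seed = NULL,
                                     sites = NULL, samples = NULL) {
  if (inherits(genotypes, "metapop_sim")) {
    sites <- genotypes$sites
    samples <- genotypes$samples$sample_id
    genotypes <- genotypes$genotypes
  }
  stopifnot(is.matrix(genotypes), all(genotypes %in% 0:2))
  if (is.null(sites)) {
    sites <- data.frame(chrom = "chr1", pos = seq_len(nrow(genotypes)) - 1L,
                        allele1 = "0", allele2 = "1")
  }
  if (is.null(samples)) samples <- sprintf("ind%03d", seq_len(ncol(genotypes)))
  eps <- noise$base_error
  with_seed(seed, {
    n <- length(genotypes)
    depth <- stats::rpois(n, noise$mean_depth)
    p_alt_true <- c(eps, 0.5, 1 - eps)[genotypes + 1L]
    alt <- stats::rbinom(n, depth, p_alt_true)
    ref <- depth - alt
    gl <- array(0, dim = c(nrow(genotypes), ncol(genotypes), 3L))
    p_geno <- c(eps, 0.5, 1 - eps)
    for (k in 1:3) {
      # log-likelihood of the read pile under genotype k-1
      gl[, , k] <- alt * log(p_geno[k]) + ref * log(1 - p_geno[k])
    }
    m <- pmax(gl[, , 1], gl[, , 2], gl[, , 3])
    for (k in 1:3) gl[, , k] <- exp(gl[, , k] - m)
    tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
    for (k in 1:3) gl[, , k] <- gl[, , k] / tot
    gl_data(sites, gl, samples)
  })
}

#' Write genotype likelihoods in beagle format
#'
#' ANGSD dialect: header `marker allele1 allele2` followed by three columns
#' per individual; marker ids are `chrom_position` with 1-based positions.
#' A `.gz` suffix triggers gzip compression.
#'
#' @param gl A [gl_data] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beagle <- function(gl, path) {
  stopifnot(inherits(gl, "gl_data"))
  n_sites <- nrow(gl$sites)
  n_ind <- length(gl$samples)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  header <- c("marker", "allele1", "allele2", rep(gl$samples, each = 3L))
  writeLines(paste(header, collapse = "\t"), con)
  if (n_sites > 0L) {
    flat <- matrix("", n_sites, 3L * n_ind)
    for (k in 1:3) {
      flat[, seq(k, by = 3L, length.out = n_ind)] <- sprintf("%.6f", gl$gl[, , k])
    }
    rows <- paste(paste0(gl$sites$chrom, "_", gl$sites$pos + 1L),
                  gl$sites$allele1, gl$sites$allele2,
                  apply(flat, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read genotype likelihoods from a beagle file
#'
#' @param path Path to a beagle file (optionally gzipped).
#' @return A [gl_data] object; triples are renormalized to sum exactly 1.
#' @export
read_beagle <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) stop("empty beagle file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  if (width < 3L || (width - 3L) %% 3L != 0L) {
    stop("malformed beagle header: expected 3 + 3k columns, got ", width)
  }
  bad <- which(vapply(fields, length, 1L) != width)
  if (length(bad) > 0L) {
    stop(sprintf("malformed beagle row at line %d: expected %d fields, got %d",
                 bad[1], width, length(fields[[bad[1]]])))
  }
  samples <- unique(fields[[1]][-(1:3)])
  n_ind <- (width - 3L) / 3L
  if (length(samples) != n_ind) samples <- sprintf("ind%03d", seq_len(n_ind))
  n_sites <- length(lines) - 1L
  if (n_sites == 0L) {
    return(gl_data(data.frame(chrom = character(), pos = integer(),
                              allele1 = character(), allele2 = character()),
                   array(numeric(0), dim = c(0L, n_ind, 3L)), samples))
  }
  body <- matrix(unlist(fields[-1]), nrow = n_sites, byrow = TRUE)
  marker <- body[, 1]
  us <- regexpr("_[0-9]+$", marker)
  if (any(us < 0)) stop("malformed marker id (expected chrom_position): ", marker[which(us < 0)[1]])
  chrom <- substr(marker, 1L, us - 1L)
  pos <- as.integer(substr(marker, us + 1L, nchar(marker))) - 1L
  vals <- matrix(as.numeric(body[, -(1:3)]), nrow = n_sites)
  if (anyNA(vals)) stop("non-numeric genotype likelihood in beagle file")
  gl <- array(0, dim = c(n_sites, n_ind, 3L))
  for (k in 1:3) gl[, , k] <- vals[, seq(k, by = 3L, length.out = n_ind), drop = FALSE]
  tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
  for (k in 1:3) gl[, , k] <- gl[, , k] / tot
  sites <- data.frame(chrom = chrom, pos = pos,
                      allele1 = body[, 2], allele2 = body[, 3],
                      stringsAsFactors = FALSE)
  gl_data(sites, gl, samples)
}
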