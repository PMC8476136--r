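#' Parameters for nested LD-network clustering
#'
#' @param emin Minimum number of edges a connected component must contain to
#'   be emitted as an LD cluster (the single parameter defining clusters).
#' @param snp_min Minimum locus count (strictly more than `snp_min`) for a
#'   level-1 cluster not absorbed at level 2 to enter the genome-wide stage.
#' @param cor_th Weakest SMLA-SMLA r2 link allowed within a level-3 cluster.
#' @param window_size Window size in bp for level-1 clustering
#'   (non-overlapping windows).
#' @param edge_floor Minimum r2 retained as a graph edge.
#' @return An `ldna_params` list.
#' @export
ldna_params <- function(emin = 10, snp_min = 10, cor_th = 0.8,
                        window_size = 1e5, edge_floor = 0.3) {
  stopifnot(emin >= 1, snp_min >= 0, cor_th > 0, cor_th <= 1,
            window_size > 0, edge_floor >= 0, edge_floor <= 1)
  structure(list(emin = emin, snp_min = snp_min, cor_th = cor_th,
                 window_size = window_size, edge_floor = edge_floor),
            class = "ldna_params")
}

#' Pairwise linkage disequilibrium from genotype likelihoods
#'
#' r2 is the squared Pearson correlation of posterior-mean dosages between
#' loci; D (half the dosage covariance) is kept for diagnostics. Loci with
#' zero dosage variance are dropped (their LD is undefined), with the count
#' reported in the `n_monomorphic` attribute.
#'
#' @param gl A [gl_data] object.
#' @param loci Integer indices of the loci (rows of `gl$sites`) to consider;
#'   default all.
#' @param edge_floor Edges with r2 below this value are dropped.
#' @return data.frame with columns `locus_a`, `locus_b` (site indices,
#'   a < b), `r2`, `D`.
#' @export
pairwise_ld <- function(gl, loci = NULL, edge_floor = 0.3) {
  stopifnot(inherits(gl, "gl_data"))
  loci <- loci %||% seq_len(nrow(gl$sites))
  if (length(loci) < 2) stop("pairwise_ld() needs at least 2 loci")
  if (length(gl$samples) < 2) stop("pairwise_ld() needs at least 2 individuals")
  D <- t(dosage_matrix(gl)[loci, , drop = FALSE])
  ld_from_dosage(D, loci, edge_floor)
}

# D_ind_by_loci: individuals x loci dosage matrix; ids: locus identifiers.
ld_from_dosage <- function(D, ids, edge_floor) {
  sds <- apply(D, 2, stats::sd)
  mono <- sds == 0 | !is.finite(sds)
  keep <- which(!mono)
  out <- data.frame(locus_a = integer(), locus_b = integer(),
                    r2 = numeric(), D = numeric())
  if (length(keep) >= 2) {
    Dk <- D[, keep, drop = FALSE]
    cm <- stats::cor(Dk)
    cv <- stats::cov(Dk)
    ut <- which(upper.tri(cm), arr.ind = TRUE)
    r2 <- cm[ut]^2
    sel <- r2 >= edge_floor
    ia <- ids[keep[ut[sel, 1]]]
    ib <- ids[keep[ut[sel, 2]]]
    swap <- ia > ib
    out <- data.frame(locus_a = ifelse(swap, ib, ia),
                      locus_b = ifelse(swap, ia, ib),
                      r2 = r2[sel], D = cv[ut][sel] / 2)
  }
  attr(out, "n_monomorphic") <- sum(mono)
  out
}

#' Extract LD clusters from a weighted edge list
#'
#' Scans the unique r2 values in decreasing order while maintaining the
#' connected components of the at-or-above-threshold graph; after all edges
#' of a threshold are added, any component whose internal edge count has
#' reached `emin` is emitted as a cluster (its birth threshold is that r2).
#' Emitted loci are frozen and take no further part in merging; the scan
#' continues on the remaining loci. Components qualifying at the same
#' threshold are emitted in order of their lowest locus coordinate, making
#' the result deterministic and independent of input edge order.
#'
#' @param edges data.frame with `locus_a`, `locus_b`, `r2` (e.g. from
#'   [pairwise_ld()]).
#' @param emin Minimum internal edge count for a cluster.
#' @return List of clusters, each a list with `loci` (sorted), `level`
#'   (NA here; set by [ldna_nested_run()]), `birth_threshold` and
#'   `edge_count`.
#' @export
extract_ld_clusters <- function(edges, emin) {
  stopifnot(emin >= 1)
  if (nrow(edges) == 0) return(list())
  ord <- order(-edges$r2, edges$locus_a, edges$locus_b)
  ea <- edges$locus_a[ord]; eb <- edges$locus_b[ord]; er <- edges$r2[ord]
  nodes <- sort(unique(c(ea, eb)))
  ia <- match(ea, nodes); ib <- match(eb, nodes)
  n <- length(nodes)
  parent <- seq_len(n)
  n_edges <- integer(n)
  members <- as.list(seq_len(n))
  frozen <- logical(n)
  clusters <- list()
  group_end <- cumsum(rle(er)$lengths)
  group_start <- c(1L, utils::head(group_end, -1) + 1L)
  for (g in seq_along(group_start)) {
    touched <- integer(0)
    for (k in group_start[g]:group_end[g]) {
      a <- ia[k]; b <- ib[k]
      if (frozen[a] || frozen[b]) next
      ra <- uf_find(parent, a); rb <- uf_find(parent, b)
      if (ra == rb) {
        n_edges[ra] <- n_edges[ra] + 1L
        touched <- c(touched, ra)
      } else {
        if (length(members[[ra]]) < length(members[[rb]])) { tmp <- ra; ra <- rb; rb <- tmp }
        parent[rb] <- ra
        n_edges[ra] <- n_edges[ra] + n_edges[rb] + 1L
        members[[ra]] <- c(members[[ra]], members[[rb]])
        members[[rb]] <- integer(0)
        touched <- c(touched, ra)
      }
    }
    # components are evaluated only after every edge of the threshold is in
    roots <- unique(vapply(unique(touched), function(r) uf_find(parent, r),
                           integer(1)))
    ready <- roots[n_edges[roots] >= emin]
    if (length(ready) > 0) {
      first_locus <- vapply(ready, function(r) min(nodes[members[[r]]]),
                            nodes[1])
      for (r in ready[order(first_locus)]) {
        mem <- members[[r]]
        clusters[[length(clusters) + 1L]] <-
          list(loci = sort(nodes[mem]), level = NA_integer_,
               birth_threshold = er[group_start[g]], edge_count = n_edges[r])
        frozen[mem] <- TRUE
        members[[r]] <- integer(0)
      }
    }
  }
  clusters
}

#' Synthetic multi-locus allele (SMLA) of an LD cluster
#'
#' Individuals x loci posterior-mean dosages are column-centered; the leading
#' eigenvector of the individual covariance gives one coordinate per
#' individual summarizing the cluster's genotypic variation. The sign is
#' fixed so the coordinate correlates positively with mean dosage.
#'
#' @param gl A [gl_data] object.
#' @param loci Integer site indices of the cluster's loci.
#' @return An `smla` list: `coordinates` (centered, one per individual),
#'   `variance_explained` (leading-eigenvalue fraction), `loci`, `n_loci`.
#' @export
compute_smla <- function(gl, loci) {
  stopifnot(inherits(gl, "gl_data"), length(loci) >= 1)
  D <- t(dosage_matrix(gl)[loci, , drop = FALSE])
  out <- smla_from_dosage(D)
  out$loci <- loci
  names(out$coordinates) <- gl$samples
  out
}

smla_from_dosage <- function(D) {
  Dc <- sweep(D, 2, colMeans(D))
  K <- tcrossprod(Dc)
  ev <- eigen(K, symmetric = TRUE)
  tot <- sum(pmax(ev$values, 0))
  if (tot <= .Machine$double.eps * nrow(D)) {
    stop("cannot compute SMLA: all loci are constant across individuals")
  }
  coords <- ev$vectors[, 1]
  msd <- rowMeans(D)
  s <- sum(coords * (msd - mean(msd)))
  if (s < 0 || (s == 0 && coords[which.max(abs(coords))] < 0)) coords <- -coords
  structure(list(coordinates = coords,
                 variance_explained = max(ev$values[1], 0) / tot,
                 loci = NULL, n_loci = ncol(D)),
            class = "smla")
}

#' @export
print.smla <- function(x, ...) {
  cat(sprintf("SMLA over %d loci: PC1 explains %.1f%% of variance\n",
              x$n_loci, 100 * x$variance_explained))
  invisible(x)
}

# Precompute everything that does not depend on (emin, snp_min, cor_th) so
# grid runs share the expensive pairwise-LD step.
ldna_precompute <- function(gl, window_size = 1e5, edge_floor = 0.3) {
  Dt <- t(dosage_matrix(gl))
  win <- paste0(gl$sites$chrom, ":", floor(gl$sites$pos / window_size))
  win_edges <- list()
  for (w in unique(win)) {
    idx <- which(win == w)
    if (length(idx) < 2) next  # windows with < 2 loci are skipped
    win_edges[[w]] <- ld_from_dosage(Dt[, idx, drop = FALSE], idx, edge_floor)
  }
  list(gl = gl, dosage = Dt, window_edges = win_edges,
       window_size = window_size, edge_floor = edge_floor)
}

#' Nested LD-network clustering (levels 1-3) with SMLA summaries
#'
#' Level 1 clusters loci within non-overlapping windows; level 2 clusters the
#' level-1 SMLAs within each chromosome; level 3 joins level-2 SMLAs (plus
#' level-1 clusters with more than `snp_min` loci that were not absorbed at
#' level 2) genome-wide by single linkage, cut so the weakest within-cluster
#' SMLA r2 link is at least `cor_th`. Final SMLAs are recomputed from all
#' member loci.
#'
#' @param gl A [gl_data] object (sites must be position-sorted within
#'   chromosomes).
#' @param params An [ldna_params()] object.
#' @param precomputed Optional result of the internal precompute step (used
#'   by [run_association_grid()] to share pairwise LD across grid cells).
#' @return An `ldna_result` list: `clusters` (final clusters with loci, level
#'   provenance, SMLA), `smla_mat` (individuals x clusters coordinate
#'   matrix), `cluster_table` (summary data.frame), `params`.
#' @export
ldna_nested_run <- function(gl, params = ldna_params(), precomputed = NULL) {
  stopifnot(inherits(params, "ldna_params"))
  pre <- precomputed %||% ldna_precompute(gl, params$window_size, params$edge_floor)
  gl <- pre$gl
  Dt <- pre$dosage

  # ---- LDna-1: clusters within windows
  lev1 <- list()
  for (ed in pre$window_edges) {
    cl <- extract_ld_clusters(ed, params$emin)
    for (x in cl) { x$level <- 1L; lev1[[length(lev1) + 1L]] <- x }
  }
  if (length(lev1) == 0) {
    return(empty_ldna_result(gl, params))
  }
  lev1_chrom <- vapply(lev1, function(x) gl$sites$chrom[x$loci[1]], character(1))
  lev1_smla <- lapply(lev1, function(x) smla_from_dosage(Dt[, x$loci, drop = FALSE]))

  # ---- LDna-2: clusters of level-1 SMLAs within chromosomes
  absorbed <- logical(length(lev1))
  lev2 <- list()
  for (ch in unique(lev1_chrom)) {
    idx <- which(lev1_chrom == ch)
    if (length(idx) >= 2) {
      S <- vapply(idx, function(i) lev1_smla[[i]]$coordinates, numeric(nrow(Dt)))
      ed <- ld_from_dosage(S, idx, pre$edge_floor)
      cl <- extract_ld_clusters(ed, params$emin)
      for (x in cl) {
        member_lev1 <- x$loci           # indices into lev1
        absorbed[member_lev1] <- TRUE
        lev2[[length(lev2) + 1L]] <-
          list(loci = sort(unique(unlist(lapply(lev1[member_lev1], `[[`, "loci")))),
               level = 2L, birth_threshold = x$birth_threshold,
               edge_count = x$edge_count)
      }
    }
  }

  # ---- LDna-3 inputs: level-2 clusters + large unabsorbed level-1 clusters
  inputs <- lev2
  for (i in which(!absorbed)) {
    if (length(lev1[[i]]$loci) > params$snp_min) inputs[[length(inputs) + 1L]] <- lev1[[i]]
  }
  if (length(inputs) == 0) return(empty_ldna_result(gl, params))

  in_smla <- lapply(inputs, function(x) smla_from_dosage(Dt[, x$loci, drop = FALSE]))
  k <- length(inputs)
  parent <- uf_new(k)
  if (k >= 2) {
    S <- vapply(in_smla, `[[`, numeric(nrow(Dt)), "coordinates")
    r2 <- stats::cor(S)^2
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (r2[i, j] >= params$cor_th) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(k), function(i) uf_find(parent, i), integer(1))
  clusters <- lapply(split(seq_len(k), roots), function(mem) {
    loci <- sort(unique(unlist(lapply(inputs[mem], `[[`, "loci"))))
    list(loci = loci,
         level = max(vapply(inputs[mem], `[[`, integer(1), "level"),
                     if (length(mem) > 1) 3L else 0L),
         birth_threshold = max(vapply(inputs[mem], `[[`, numeric(1), "birth_threshold")),
         edge_count = sum(vapply(inputs[mem], `[[`, integer(1), "edge_count")),
         smla = smla_from_dosage(Dt[, loci, drop = FALSE]))
  })
  # deterministic ordering by genomic coordinate of the first locus
  first <- vapply(clusters, function(x) x$loci[1], integer(1))
  clusters <- clusters[order(first)]
  names(clusters) <- sprintf("C%03d", seq_along(clusters))

  smla_mat <- vapply(clusters, function(x) x$smla$coordinates, numeric(nrow(Dt)))
  rownames(smla_mat) <- gl$samples
  tab <- data.frame(
    cluster_id = names(clusters),
    n_loci = vapply(clusters, function(x) length(x$loci), integer(1)),
    level = vapply(clusters, function(x) x$level, integer(1)),
    chrom = vapply(clusters, function(x) gl$sites$chrom[x$loci[1]], character(1)),
    start = vapply(clusters, function(x) min(gl$sites$pos[x$loci]), integer(1)),
    end = vapply(clusters, function(x) max(gl$sites$pos[x$loci]) + 1L, integer(1)),
    variance_explained = vapply(clusters, function(x) x$smla$variance_explained, numeric(1)),
    row.names = NULL)
  structure(list(clusters = clusters, smla_mat = smla_mat,
                 cluster_table = tab, params = params),
            class = "ldna_result")
}

empty_ldna_result <- function(gl, params) {
  structure(list(clusters = list(),
                 smla_mat = matrix(numeric(0), length(gl$samples), 0,
                                   dimnames = list(gl$samples, NULL)),
                 cluster_table = data.frame(cluster_id = character(),
                                            n_loci = integer(), level = integer(),
                                            chrom = character(), start = integer(),
                                            end = integer(),
                                            variance_explained = numeric()),
                 params = params),
            class = "ldna_result")
}

#' @export
print.ldna_result <- function(x, ...) {
  cat(sprintf("ldna_result: %d final cluster(s) [emin=%d, snp_min=%d, cor_th=%.2f]\n",
              length(x$clusters), x$params$emin, x$params$snp_min, x$params$cor_th))
  if (length(x$clusters) > 0) print(utils::head(x$cluster_table, 10))
  invisible(x)
}
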