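#' Collapse significant loci into genomic outlier regions
#'
#' Single-linkage clustering on the genomic coordinate: per chromosome,
#' consecutive unique loci separated by at most `gap_threshold` bp are
#' chained; chains with at least `min_loci` unique positions become regions
#' spanning \[min position, max position + 1).
#'
#' @param loci data.frame with `chrom` and `pos` columns (0-based positions;
#'   duplicates allowed, counted once).
#' @param gap_threshold Maximum gap chained (boundary gaps exactly equal to
#'   the threshold merge).
#' @param min_loci Minimum number of unique loci per region.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `n_unique_loci`; zero rows for empty input.
#' @export
collapse_to_regions <- function(loci, gap_threshold = 5e5, min_loci = 10) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    n_unique_loci = integer(), stringsAsFactors = FALSE)
  if (is.null(loci) || nrow(loci) == 0) return(out)
  loci <- unique(loci[, c("chrom", "pos")])
  for (ch in unique(loci$chrom)) {
    pos <- sort(loci$pos[loci$chrom == ch])
    brk <- which(diff(pos) > gap_threshold)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(pos))
    for (g in seq_along(starts)) {
      p <- pos[starts[g]:ends[g]]
      if (length(p) >= min_loci) {
        out <- rbind(out, data.frame(chrom = ch, start = min(p),
                                     end = max(p) + 1L,
                                     n_unique_loci = length(p),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Consistency score of an outlier region over the parameter grid
#'
#' The proportion of grid cells (parameter combination x correction regime)
#' in which at least one significant LD cluster contributes at least one
#' locus inside the region's span; C = 1 means the region was significant in
#' every test of the grid.
#'
#' @param region One-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param grid_res An `assoc_grid` object from [run_association_grid()].
#' @return C in \[0, 1\].
#' @export
consistency_score <- function(region, grid_res) {
  stopifnot(inherits(grid_res, "assoc_grid"))
  if (grid_res$n_cells == 0) stop("zero grid cells")
  res <- grid_res$results
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(0)
  sites <- grid_res$sites
  hit_cells <- character(0)
  for (combo in unique(sig$combo)) {
    loci_list <- grid_res$cluster_loci[[combo]]
    rows <- sig[sig$combo == combo, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      idx <- loci_list[[rows$cluster_id[r]]]
      inside <- sites$chrom[idx] == region$chrom &
        sites$pos[idx] >= region$start & sites$pos[idx] < region$end
      if (any(inside)) hit_cells <- c(hit_cells, paste(combo, rows$regime[r]))
    }
  }
  length(unique(hit_cells)) / grid_res$n_cells
}

#' Call outlier regions from a full grid run
#'
#' Pools the unique loci of all significant clusters from every grid cell,
#' collapses them into regions ([collapse_to_regions()]), scores each
#' region's consistency C across cells and flags regions with C below
#' `c_drop` as too parameter-sensitive to keep.
#'
#' @param grid_res An `assoc_grid` object.
#' @param gap_threshold,min_loci Region-calling parameters.
#' @param c_drop Consistency threshold below which a region is flagged
#'   `dropped`.
#' @return data.frame of regions with `C` and `dropped` columns.
#' @export
call_outlier_regions <- function(grid_res, gap_threshold = 5e5, min_loci = 10,
                                 c_drop = 0.05) {
  stopifnot(inherits(grid_res, "assoc_grid"))
  res <- grid_res$results
  sig <- res[res$significant, , drop = FALSE]
  sites <- grid_res$sites
  idx <- integer(0)
  for (combo in unique(sig$combo)) {
    cl <- unique(sig$cluster_id[sig$combo == combo])
    idx <- c(idx, unlist(grid_res$cluster_loci[[combo]][cl], use.names = FALSE))
  }
  regions <- collapse_to_regions(
    data.frame(chrom = sites$chrom[idx], pos = sites$pos[idx]),
    gap_threshold = gap_threshold, min_loci = min_loci)
  if (nrow(regions) == 0) {
    regions$C <- numeric(0); regions$dropped <- logical(0)
    return(regions)
  }
  regions$C <- vapply(seq_len(nrow(regions)), function(i) {
    consistency_score(regions[i, ], grid_res)
  }, numeric(1))
  regions$dropped <- regions$C < c_drop
  regions
}

#' Region-wise effect sizes per geographic region
#'
#' Pools all marine samples against the freshwater samples of one geographic
#' region at a time; for each contrast the region's SMLA is recomputed from
#' all unique loci of significant clusters mapping inside the region, and
#' the correlation effect sizes are returned with and without the
#' relatedness random effect.
#'
#' @param region One-row data.frame with `chrom`, `start`, `end`.
#' @param gl A [gl_data] object.
#' @param samples Sample metadata table.
#' @param grid_res An `assoc_grid` object (source of the significant loci).
#' @param min_freshwater Minimum freshwater samples a geographic region must
#'   have; regions below it return `NA` with a warning.
#' @return data.frame with `geographic_region`, `n_freshwater`, `cor_unrl`,
#'   `cor_A`, `p_value`.
#' @export
regional_parallelism <- function(region, gl, samples, grid_res,
                                 min_freshwater = 2) {
  stopifnot(inherits(gl, "gl_data"), inherits(grid_res, "assoc_grid"))
  res <- grid_res$results
  sig <- res[res$significant, , drop = FALSE]
  sites <- grid_res$sites
  idx <- integer(0)
  for (combo in unique(sig$combo)) {
    cl <- unique(sig$cluster_id[sig$combo == combo])
    idx <- c(idx, unlist(grid_res$cluster_loci[[combo]][cl], use.names = FALSE))
  }
  idx <- unique(idx)
  inside <- idx[sites$chrom[idx] == region$chrom &
                  sites$pos[idx] >= region$start & sites$pos[idx] < region$end]
  if (length(inside) < 10) stop("region has fewer than 10 unique significant loci")
  geo <- unique(samples$geographic_region)
  out <- lapply(geo, function(g) {
    fresh <- samples$ecotype == 1 & samples$geographic_region == g
    if (sum(fresh) < min_freshwater) {
      warning("geographic region ", g, " has < ", min_freshwater,
              " freshwater samples; returning NA")
      return(data.frame(geographic_region = g, n_freshwater = sum(fresh),
                        cor_unrl = NA_real_, cor_A = NA_real_,
                        p_value = NA_real_))
    }
    keep <- samples$ecotype == 0 | fresh
    sub_gl <- gl_subset(gl, samples = which(keep))
    sm <- compute_smla(sub_gl, sort(inside))
    lin <- samples$lineage[keep]
    covar <- if (length(unique(lin)) > 1) data.frame(lineage = lin) else NULL
    A <- grm(sub_gl)
    fit <- emmax_test(sm, samples$ecotype[keep], covar, A = A)
    data.frame(geographic_region = g, n_freshwater = sum(fresh),
               cor_unrl = fit$cor_unrl, cor_A = fit$cor_A,
               p_value = fit$p_value)
  })
  do.call(rbind, out)
}

#' Subset a gl_data object by sites and/or samples
#'
#' @param gl A [gl_data] object.
#' @param sites Integer site indices to keep (default all).
#' @param samples Integer sample indices to keep (default all).
#' @return A [gl_data] object.
#' @export
gl_subset <- function(gl, sites = NULL, samples = NULL) {
  si <- sites %||% seq_len(nrow(gl$sites))
  sa <- samples %||% seq_along(gl$samples)
  gl_data(gl$sites[si, , drop = FALSE],
          gl$gl[si, sa, , drop = FALSE],
          gl$samples[sa])
}

#' Write outlier regions as a BED file
#'
#' @param regions data.frame from [call_outlier_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    name = sprintf("region%02d_C%.3f", seq_len(nrow(regions)),
                                   regions$C))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
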