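#' Encode Stage-1 SNPs as the integer data matrix D
#'
#' Builds the clustering data matrix: one row per SNP, one column per
#' training sample, entries in 0..16 where 1..16 are the ordered genotype
#' symbol codes (AA = 1, ..., TT = 16) and 0 marks a masked (reference-
#' homozygous) individual.
#'
#' @param x a \code{masked_variants} object.
#' @param training_ids character vector of training sample ids (the matrix
#'   columns, dimension l of each SNP object).
#' @param snp_ids optional subset of SNP ids (rows); default all.
#' @return integer matrix with rownames = SNP ids, colnames = sample ids.
#' @export
encode_symbols <- function(x, training_ids, snp_ids = NULL) {
  stopifnot(inherits(x, "masked_variants"))
  cols <- match(training_ids, x$sample_ids)
  if (anyNA(cols)) stop("training ids absent from genotype data")
  rows <- if (is.null(snp_ids)) seq_len(nrow(x$info)) else
    match(snp_ids, x$info$rsid)
  if (anyNA(rows)) stop("snp ids absent from data")
  m <- x$codes[rows, cols, drop = FALSE]
  dimnames(m) <- list(x$info$rsid[rows], training_ids)
  m
}

#' Density-based clustering with noise (DBSCAN)
#'
#' Clusters the rows of a numeric matrix by Euclidean distance. A row is a
#' core point when at least \code{min_pts} rows (counting itself) lie within
#' radius \code{eps}; clusters are the maximal density-connected sets grown
#' from core points, and rows assigned to no cluster are labelled outliers.
#' Rows are scanned in input order, so cluster numbering and border-point
#' assignment (to the first-discovered cluster) are deterministic.
#'
#' @param x numeric matrix, one observation per row.
#' @param eps nonnegative radius parameter (Euclidean distance).
#' @param min_pts neighbourhood density threshold (>= 1), self-inclusive.
#' @return integer vector of labels, one per row: cluster index >= 1, or
#'   0 for outliers. Named by rownames of \code{x} when present.
#' @export
dbscan_cluster <- function(x, eps, min_pts = 2L) {
  stopifnot(eps >= 0, min_pts >= 1)
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- rep(NA_integer_, n)
  if (n == 0) return(stats::setNames(integer(0), rownames(x)))
  d <- as.matrix(stats::dist(x))
  nbrs <- apply(d <= eps, 1L, which, simplify = FALSE)
  is_core <- lengths(nbrs) >= min_pts
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    if (!is_core[i]) {
      labels[i] <- 0L  # noise for now; a later cluster may claim it as border
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- nbrs[[i]][nbrs[[i]] != i]
    while (length(seeds)) {
      j <- seeds[[1]]
      seeds <- seeds[-1]
      if (!is.na(labels[j]) && labels[j] > 0L) next
      labels[j] <- cl
      if (is_core[j]) {
        cand <- nbrs[[j]]
        seeds <- c(seeds, cand[is.na(labels[cand]) | labels[cand] == 0L])
      }
    }
  }
  stats::setNames(labels, rownames(x))
}

#' Extract the outlier SNPs from DBSCAN labels
#'
#' The outliers -- SNPs that no dense group absorbed -- are the candidates
#' carrying seemingly unique ancestry information.
#'
#' @param labels integer label vector from [dbscan_cluster()] (named by SNP).
#' @return character vector of outlier SNP ids (or integer indices when
#'   labels are unnamed).
#' @export
select_outliers <- function(labels) {
  idx <- which(labels == 0L)
  if (is.null(names(labels))) idx else names(labels)[idx]
}

#' Empirical scan over the DBSCAN radius parameter
#'
#' The radius has no closed-form choice; it is picked empirically by
#' measuring, for each candidate value, the downstream multi-class
#' classification accuracy obtained from the outlier SNP set. Ties are
#' broken toward the smaller radius.
#'
#' @param x integer code matrix from [encode_symbols()].
#' @param eps_grid numeric vector of radii to try.
#' @param eval_fn function(outlier_snp_ids) -> accuracy (numeric scalar).
#' @param min_pts density threshold, default 2.
#' @return list with \code{best_eps}, \code{labels} (for the best radius),
#'   \code{outliers} and a per-radius \code{table} (eps, n_outliers,
#'   accuracy; accuracy is NA when a radius yields no outliers).
#' @export
scan_epsilon <- function(x, eps_grid, eval_fn, min_pts = 2L) {
  stopifnot(length(eps_grid) >= 1)
  eps_grid <- sort(eps_grid)
  rows <- lapply(eps_grid, function(eps) {
    labels <- dbscan_cluster(x, eps, min_pts)
    out <- select_outliers(labels)
    acc <- if (length(out) >= 1) eval_fn(out) else NA_real_
    list(labels = labels, outliers = out, eps = eps, accuracy = acc)
  })
  tab <- data.frame(eps = eps_grid,
                    n_outliers = vapply(rows, function(r) length(r$outliers), 1L),
                    accuracy = vapply(rows, function(r) r$accuracy, 1.0))
  if (all(is.na(tab$accuracy))) {
    stop("no radius in the grid yields any outlier SNP")
  }
  best <- which(tab$accuracy == max(tab$accuracy, na.rm = TRUE))[1]
  list(best_eps = eps_grid[best], labels = rows[[best]]$labels,
       outliers = rows[[best]]$outliers, table = tab)
}
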