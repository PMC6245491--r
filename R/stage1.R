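#' Per-(SNP, population) retention and modal-genotype statistics
#'
#' For every SNP i and population p, over TRAINING individuals only,
#' computes
#' \deqn{\alpha = n_p^i / n_p, \qquad \beta = f_p^i / n_p^i,}
#' where \eqn{n_p} is the number of training individuals of population p,
#' \eqn{n_p^i} the number of them retained at SNP i (not reference-
#' homozygous), and \eqn{f_p^i} the count of the most frequent genotype
#' symbol of p at SNP i. \eqn{\beta} is \code{NA} (undefined) when
#' \eqn{n_p^i = 0}.
#'
#' @param x a \code{masked_variants} object (dissimilarity set).
#' @param metadata sample metadata data.frame.
#' @param training_ids character vector of training sample ids.
#' @return data.frame with columns snp_id, population, n_p, n_p_i, f_p_i,
#'   alpha, beta (one row per SNP x population).
#' @export
compute_alpha_beta <- function(x, metadata, training_ids) {
  stopifnot(inherits(x, "masked_variants"))
  if (!all(training_ids %in% metadata$sample_id)) {
    stop("training ids absent from metadata")
  }
  tr_cols <- match(training_ids, x$sample_ids)
  if (anyNA(tr_cols)) stop("training ids absent from genotype data")
  pops <- sort(unique(metadata$population))
  pop_of <- stats::setNames(metadata$population, metadata$sample_id)
  tr_pop <- pop_of[training_ids]
  m <- nrow(x$info)
  out <- vector("list", length(pops))
  for (ip in seq_along(pops)) {
    p <- pops[ip]
    cols <- tr_cols[tr_pop == p]
    n_p <- length(cols)
    if (n_p == 0L) stop("population with no training individuals: ", p)
    sub <- x$codes[, cols, drop = FALSE]
    n_pi <- as.integer(rowSums(sub > 0L))
    f <- integer(m)
    for (k in 1:16) f <- pmax(f, as.integer(rowSums(sub == k)))
    alpha <- n_pi / n_p
    beta <- ifelse(n_pi > 0L, f / n_pi, NA_real_)
    out[[ip]] <- data.frame(snp_id = x$info$rsid, population = p,
                            n_p = n_p, n_p_i = n_pi, f_p_i = f,
                            alpha = alpha, beta = beta)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stage-1 parameter-based SNP selection
#'
#' A SNP is important for population p when \eqn{\alpha \times \beta = 1}
#' (i.e. every training individual of p is retained at the SNP and all of
#' them share one genotype symbol). Returns the union over all populations
#' of their important SNP sets, in genomic order.
#'
#' @inheritParams compute_alpha_beta
#' @param stats optional precomputed result of [compute_alpha_beta()].
#' @return character vector of selected SNP ids.
#' @export
select_important <- function(x, metadata, training_ids, stats = NULL) {
  if (is.null(stats)) stats <- compute_alpha_beta(x, metadata, training_ids)
  hit <- stats$alpha == 1 & !is.na(stats$beta) & stats$beta == 1
  sel <- unique(stats$snp_id[hit])
  x$info$rsid[x$info$rsid %in% sel]
}

#' Remove SNPs uniform across the pooled training set
#'
#' Drops, from a Stage-1 selection, SNPs whose retained training
#' individuals -- pooled across all populations -- share a single genotype
#' symbol: such SNPs show no variation between population groups and cannot
#' distinguish them.
#'
#' @param selected character vector of SNP ids from [select_important()].
#' @inheritParams compute_alpha_beta
#' @return character vector: \code{selected} minus the uniform SNPs.
#' @export
drop_uniform <- function(selected, x, metadata, training_ids) {
  if (length(selected) == 0) return(character())
  tr_cols <- match(training_ids, x$sample_ids)
  rows <- match(selected, x$info$rsid)
  if (anyNA(rows)) stop("selected SNP ids absent from data")
  sub <- x$codes[rows, tr_cols, drop = FALSE]
  uniform <- .n_distinct_codes(sub) == 1L
  selected[!uniform]
}

#' Run all of Stage 1 (parameters, union, uniform removal)
#'
#' @inheritParams compute_alpha_beta
#' @return list with \code{stats} (alpha/beta table), \code{important}
#'   (union of per-population selections) and \code{kept} (after uniform
#'   removal).
#' @export
stage1_select <- function(x, metadata, training_ids) {
  stats <- compute_alpha_beta(x, metadata, training_ids)
  important <- select_important(x, metadata, training_ids, stats = stats)
  kept <- drop_uniform(important, x, metadata, training_ids)
  log_note("stage1: ", length(important), " SNPs in the union, ",
           length(kept), " after uniform removal")
  list(stats = stats, important = important, kept = kept)
}
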