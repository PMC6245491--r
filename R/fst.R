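#' Multi-locus Weir-Cockerham F_st estimate
#'
#' Estimates the fixation index between groups of samples from biallelic
#' genotypes using the Weir-Cockerham (1984) variance-components estimator,
#' combined across loci as a ratio of averages
#' (\eqn{\hat\theta = \sum_i a_i / \sum_i (a_i + b_i + c_i)}). Used to
#' validate that the simulator produces the configured differentiation;
#' monomorphic loci contribute nothing, and an input with only monomorphic
#' loci yields \code{NA} (undefined).
#'
#' @param x a [variant_set()] with biallelic SNPs (multi-allelic and
#'   multi-base records are skipped).
#' @param metadata sample metadata.
#' @param grouping \code{"population"} or \code{"continent"}.
#' @return numeric scalar estimate of F_st (or \code{NA_real_}).
#' @export
estimate_fst <- function(x, metadata, grouping = c("population", "continent")) {
  stopifnot(inherits(x, "variant_set"))
  grouping <- match.arg(grouping)
  grp <- metadata[[grouping]][match(x$sample_ids, metadata$sample_id)]
  groups <- unique(grp)
  r <- length(groups)
  if (r < 2) stop("need at least 2 groups")
  ok <- nchar(x$info$ref) == 1L & !grepl(",", x$info$alt, fixed = TRUE)
  alt <- x$info$alt
  num <- 0; den <- 0
  cols <- lapply(groups, function(g) which(grp == g))
  for (i in which(ok)) {
    n_i <- lengths(cols)
    is_alt1 <- x$a1[i, ] == alt[i]
    is_alt2 <- x$a2[i, ] == alt[i]
    p_i <- vapply(cols, function(cc) mean(c(is_alt1[cc], is_alt2[cc])),
                  numeric(1))
    h_i <- vapply(cols, function(cc) mean(is_alt1[cc] != is_alt2[cc]),
                  numeric(1))
    n_bar <- mean(n_i)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    if (p_bar == 0 || p_bar == 1) next
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    a <- n_bar / n_c *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) /
         (n_bar - 1))
    b <- n_bar / (n_bar - 1) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}
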