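#' Allele-context feature: count of non-reference nucleotides
#'
#' The per-sample classification feature of a SNP takes three values:
#' 0 when both nucleotides equal the reference nucleotide, 1 when exactly
#' one differs, 2 when both differ.
#'
#' @param ref reference nucleotide(s).
#' @param a1,a2 first/second genotype nucleotide(s).
#' @return integer vector in \{0, 1, 2\}.
#' @export
#' @examples
#' allele_context("A", "A", "G")  # 1
#' allele_context("A", "G", "T")  # 2
allele_context <- function(ref, a1, a2) {
  as.integer(a1 != ref) + as.integer(a2 != ref)
}

#' Allele-context feature matrix (samples x SNPs)
#'
#' Builds the feature matrix whose column i holds the allele-context values
#' of SNP i for every sample. Masked entries of a \code{masked_variants}
#' object are reference homozygotes and therefore have context 0.
#'
#' @param x a [variant_set()] or \code{masked_variants} object.
#' @return integer matrix, rows = samples (named), columns = SNPs (named).
#' @export
allele_context_matrix <- function(x) {
  if (inherits(x, "variant_set")) {
    ac <- (x$a1 != x$info$ref) + (x$a2 != x$info$ref)
  } else if (inherits(x, "masked_variants")) {
    dec <- decode_genotype(x$codes)
    a1 <- matrix(dec$a1, nrow = nrow(x$codes))
    a2 <- matrix(dec$a2, nrow = nrow(x$codes))
    ac <- (a1 != x$info$ref) + (a2 != x$info$ref)
    ac[x$codes == 0L] <- 0L  # masked = reference homozygote
  } else {
    stop("x must be a variant_set or masked_variants object")
  }
  storage.mode(ac) <- "integer"
  dimnames(ac) <- list(x$info$rsid, x$sample_ids)
  t(ac)
}

#' Stratified train/test split
#'
#' Splits samples into training and test sets, stratified by population so
#' that every population appears in both sets. Within each population the
#' training count is \code{floor(n * train_fraction)} (clamped to keep at
#' least one sample on each side); the remainder goes to the test set. The
#' split is deterministic given the seed and leaves the caller's RNG state
#' untouched.
#'
#' @param metadata sample metadata data.frame.
#' @param train_fraction fraction of each population used for training.
#' @param seed integer RNG seed.
#' @return list with character vectors \code{train} and \code{test}
#'   (in metadata order), partitioning all samples.
#' @export
make_split <- function(metadata, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  sizes <- table(metadata$population)
  if (any(sizes < 2)) {
    stop("population with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  pops <- sort(unique(metadata$population))
  train <- withr::with_seed(seed, {
    unlist(lapply(pops, function(p) {
      ids <- metadata$sample_id[metadata$population == p]
      n_tr <- min(max(floor(length(ids) * train_fraction), 1L),
                  length(ids) - 1L)
      sample(ids, n_tr)
    }), use.names = FALSE)
  })
  list(train = metadata$sample_id[metadata$sample_id %in% train],
       test = metadata$sample_id[!metadata$sample_id %in% train])
}

# Train a per-SNP softmax on the collapsed (feature value, class) table:
# mathematically identical to the expanded fit (case weights = counts).
.single_snp_fit <- function(x_tr, y_tr, classes, control) {
  tab <- table(x_tr, y_tr)
  idx <- which(tab > 0, arr.ind = TRUE)
  xg <- as.numeric(rownames(tab))[idx[, 1L]]
  yg <- colnames(tab)[idx[, 2L]]
  wg <- as.numeric(tab[idx])
  softmax_train(matrix(xg, ncol = 1L), yg, control = control,
                classes = classes, sample_weights = wg)
}

#' Single-SNP performance matrix X
#'
#' Evaluates every candidate SNP independently as a single-feature
#' multi-class (one class per population) classifier, on a fixed train/test
#' split, and assembles the m x 6 performance matrix: column
#' \code{overall} is the test accuracy (percent) of the multi-population
#' classification using that SNP alone, and the five continent columns give
#' the percentage of test individuals of each continent whose predicted
#' population lies in that continent. The shared classifier and
#' hyperparameters of [softmax_train()] are used with no per-SNP tuning.
#'
#' @param ac allele-context matrix from [allele_context_matrix()].
#' @param snp_ids candidate SNP ids (columns of \code{ac}).
#' @param metadata sample metadata.
#' @param split list(train, test) from [make_split()].
#' @param positions optional named vector of genomic positions (used as the
#'   deterministic tie-break when ranking); defaults to NA.
#' @param control a [softmax_control()].
#' @return data.frame of class \code{performance_matrix} with columns rsid,
#'   pos, overall, then one column per continent (canonical order).
#' @export
build_performance_matrix <- function(ac, snp_ids, metadata, split,
                                     positions = NULL,
                                     control = softmax_control()) {
  if (!all(snp_ids %in% colnames(ac))) {
    stop("candidate SNPs absent from the feature matrix")
  }
  classes <- sort(unique(metadata$population))
  pop_of <- stats::setNames(metadata$population, metadata$sample_id)
  y_tr <- unname(pop_of[split$train])
  y_te <- unname(pop_of[split$test])
  tc <- label_to_continent(y_te, metadata)
  lev <- continent_levels(metadata)
  n_const <- 0L
  rows <- matrix(NA_real_, length(snp_ids), 1L + length(lev))
  for (s in seq_along(snp_ids)) {
    x_tr <- ac[split$train, snp_ids[s]]
    x_te <- ac[split$test, snp_ids[s]]
    if (length(unique(x_tr)) == 1L) n_const <- n_const + 1L
    fit <- .single_snp_fit(x_tr, y_tr, classes, control)
    lut <- softmax_predict(fit, matrix(0:2, ncol = 1L))
    pred <- lut[x_te + 1L]
    pc <- label_to_continent(pred, metadata)
    rows[s, 1L] <- 100 * mean(pred == y_te)
    rows[s, -1L] <- vapply(lev, function(j) 100 * mean(pc[tc == j] == j),
                           numeric(1))
  }
  if (n_const > 0) {
    log_note("performance matrix: ", n_const,
             " SNP(s) with a constant training feature (bias-only fit)")
  }
  pos <- if (is.null(positions)) rep(NA_integer_, length(snp_ids)) else
    unname(positions[snp_ids])
  out <- data.frame(rsid = snp_ids, pos = pos)
  out <- cbind(out, as.data.frame(rows))
  names(out)[-(1:2)] <- c("overall", lev)
  class(out) <- c("performance_matrix", "data.frame")
  out
}
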