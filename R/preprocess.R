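#' Apply the three SNP cleaning rules
#'
#' Filters a [variant_set()] with three rules, applied in order:
#' \enumerate{
#'   \item remove a SNP whose reference allele contains more than one
#'     nucleotide;
#'   \item remove a SNP if any alternate allele nucleotide also exists in the
#'     reference allele;
#'   \item remove a SNP at which every individual's two nucleotides both
#'     match the reference nucleotide (no variation observed).
#' }
#' The filter is idempotent and purely record-wise.
#'
#' @param x a [variant_set()].
#' @return list with elements \code{kept} (a \code{variant_set}) and
#'   \code{removed} (named integer vector of per-rule removal counts;
#'   rules are counted sequentially, each among the survivors of the
#'   previous rule).
#' @export
clean_variants <- function(x) {
  stopifnot(inherits(x, "variant_set"))
  info <- x$info
  r1 <- nchar(info$ref) > 1L
  alt_list <- strsplit(info$alt, ",", fixed = TRUE)
  r2 <- !r1 & mapply(function(alts, ref) any(grepl(ref, alts, fixed = TRUE)),
                     alt_list, info$ref)
  hom_ref <- (x$a1 == info$ref) & (x$a2 == info$ref)
  r3 <- !r1 & !r2 & rowSums(!hom_ref) == 0L
  removed <- c(multi_base_ref = sum(r1), alt_contains_ref = sum(r2),
               all_hom_ref = sum(r3))
  if (any(removed > 0)) {
    log_note("clean_variants: removed ",
             paste(removed, names(removed), collapse = ", "))
  }
  list(kept = subset_variants(x, !(r1 | r2 | r3)), removed = removed)
}

#' Mask reference-homozygous individuals and encode genotype symbols
#'
#' For each SNP, an individual's allele information is removed when both of
#' their nucleotides equal the reference nucleotide; everyone else is
#' retained with their ordered genotype symbol. Heterozygotes containing the
#' reference nucleotide (e.g. ref A, genotype (A,G)) are retained: masking
#' requires BOTH nucleotides to match the reference. Symbols are stored as
#' integer codes 1..16 (see [genotype_code()]); masked entries are 0.
#'
#' @param x a cleaned [variant_set()].
#' @return An object of class \code{masked_variants}: list with
#'   \code{sample_ids}, \code{info} and integer matrix \code{codes}
#'   (variants x samples, 0 = masked).
#' @export
mask_reference_homozygotes <- function(x) {
  stopifnot(inherits(x, "variant_set"))
  if (any(nchar(x$info$ref) > 1L)) {
    stop("mask expects cleaned variants (single-nucleotide reference)")
  }
  codes <- matrix(genotype_code(x$a1, x$a2), nrow = nrow(x$a1))
  hom_ref <- (x$a1 == x$info$ref) & (x$a2 == x$info$ref)
  codes[hom_ref] <- 0L
  structure(list(sample_ids = x$sample_ids, info = x$info, codes = codes),
            class = "masked_variants")
}

#' @export
print.masked_variants <- function(x, ...) {
  cat("masked_variants:", nrow(x$info), "variants x", length(x$sample_ids),
      "samples (", sum(x$codes == 0L), "masked entries )\n")
  invisible(x)
}

subset_masked <- function(x, idx) {
  structure(list(sample_ids = x$sample_ids,
                 info = x$info[idx, , drop = FALSE],
                 codes = x$codes[idx, , drop = FALSE]),
            class = "masked_variants")
}

# number of distinct positive (retained) codes per row
.n_distinct_codes <- function(codes) {
  out <- integer(nrow(codes))
  for (k in 1:16) out <- out + (rowSums(codes == k) > 0L)
  out
}

#' Partition masked SNPs into similarity and dissimilarity sets
#'
#' A SNP joins the similarity set when all retained (non reference-
#' homozygous) individuals share one genotype symbol, and the dissimilarity
#' set otherwise. Only the dissimilarity set carries between-individual
#' variation and is used by the downstream selection stages.
#'
#' @param x a \code{masked_variants} object.
#' @return list with \code{masked_variants} elements \code{similarity} and
#'   \code{dissimilarity}.
#' @export
partition_similarity <- function(x) {
  stopifnot(inherits(x, "masked_variants"))
  uniform <- .n_distinct_codes(x$codes) == 1L
  list(similarity = subset_masked(x, uniform),
       dissimilarity = subset_masked(x, !uniform))
}
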