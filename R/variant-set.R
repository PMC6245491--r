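#' In-memory collection of biallelic/multiallelic SNP genotypes
#'
#' A \code{variant_set} bundles a vector of sample identifiers, a per-variant
#' annotation table and two character matrices holding the first and second
#' nucleotide of every sample's diploid genotype. Genotype pairs are ORDERED
#' as read from the VCF GT field: \code{(A,G)} and \code{(G,A)} are distinct
#' symbols, matching the 16-symbol genotype alphabet used throughout the
#' selection pipeline.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param info data.frame with columns \code{rsid}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt} (comma-separated alternate alleles).
#' @param a1,a2 character matrices (variants x samples) of first/second
#'   genotype nucleotides, each in \code{A,C,G,T}.
#' @return An object of class \code{variant_set}.
#' @export
variant_set <- function(sample_ids, info, a1, a2) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  needed <- c("rsid", "chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(info))) {
    stop("info must have columns: ", paste(needed, collapse = ", "))
  }
  info <- as.data.frame(info)[, needed]
  info$pos <- as.integer(info$pos)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  m <- nrow(info); n <- length(sample_ids)
  if (!identical(dim(a1), c(m, n)) || !identical(dim(a2), c(m, n))) {
    stop("genotype matrices must be variants x samples")
  }
  if (m > 0) {
    if (any(info$pos < 1L)) stop("positions must be >= 1")
    if (any(!nzchar(info$ref)) ||
        any(grepl("[^ACGT]", info$ref)) ||
        any(grepl("[^ACGT,]", info$alt)) ||
        any(!nzchar(info$alt))) {
      stop("ref/alt alleles must be non-empty strings over {A,C,G,T}")
    }
    if (any(!(a1 %in% BASES)) || any(!(a2 %in% BASES))) {
      stop("genotype nucleotides must be in {A,C,G,T}")
    }
  }
  dimnames(a1) <- dimnames(a2) <- NULL
  rownames(info) <- NULL
  structure(list(sample_ids = sample_ids, info = info, a1 = a1, a2 = a2),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$info), "variants x", length(x$sample_ids),
      "samples\n")
  invisible(x)
}

#' Number of variants in a variant_set
#' @param x a \code{variant_set}.
#' @export
n_variants <- function(x) nrow(x$info)

# Row subset preserving structure (internal).
subset_variants <- function(x, idx) {
  variant_set(x$sample_ids, x$info[idx, , drop = FALSE],
              x$a1[idx, , drop = FALSE], x$a2[idx, , drop = FALSE])
}
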