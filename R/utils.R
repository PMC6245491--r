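# Shared constants and small helpers.

BASES <- c("A", "C", "G", "T")

# The 16 ordered diploid genotype symbols AA, AC, AG, AT, CA, ..., TT.
# Code k encodes first nucleotide (k-1) %/% 4 + 1 and second (k-1) %% 4 + 1.
GENOTYPE_SYMBOLS <- as.vector(t(outer(BASES, BASES, paste0)))

# Canonical display order for the five continental groups (super-populations).
CONTINENT_ORDER <- c("EUR", "AMR", "AFR", "EAS", "SAS")

#' Encode ordered genotype nucleotide pairs as integer codes 1..16
#'
#' The 16 ordered diploid symbols are numbered lexicographically:
#' AA = 1, AC = 2, AG = 3, AT = 4, CA = 5, ..., TT = 16.
#'
#' @param a1,a2 character vectors of single nucleotides in \code{A,C,G,T}
#'   (first and second allele of each genotype).
#' @return Integer vector of codes in 1..16.
#' @seealso [decode_genotype()]
#' @export
#' @examples
#' genotype_code("A", "A")  # 1
#' genotype_code("T", "T")  # 16
genotype_code <- function(a1, a2) {
  i1 <- match(a1, BASES)
  i2 <- match(a2, BASES)
  if (anyNA(i1) || anyNA(i2)) {
    stop("genotype nucleotides must be one of A, C, G, T")
  }
  (i1 - 1L) * 4L + i2
}

#' Decode integer genotype codes back to nucleotide pairs
#'
#' Inverse of [genotype_code()]. Code 0 (masked entry) decodes to \code{NA}.
#'
#' @param code integer vector with entries in 0..16.
#' @return A list with character vectors \code{a1} and \code{a2}.
#' @export
decode_genotype <- function(code) {
  code <- as.integer(code)
  if (any(code < 0L | code > 16L, na.rm = TRUE)) {
    stop("genotype codes must lie in 0..16")
  }
  idx <- pmax(code, 1L)
  a1 <- BASES[(idx - 1L) %/% 4L + 1L]
  a2 <- BASES[(idx - 1L) %% 4L + 1L]
  masked <- !is.na(code) & code < 1L
  a1[masked] <- NA_character_
  a2[masked] <- NA_character_
  list(a1 = a1, a2 = a2)
}

# Continent levels present in a metadata table, canonical codes first.
continent_levels <- function(metadata) {
  present <- unique(as.character(metadata$continent))
  c(intersect(CONTINENT_ORDER, present), sort(setdiff(present, CONTINENT_ORDER)))
}

# population -> continent lookup (named character vector).
population_continent_map <- function(metadata) {
  m <- unique(metadata[, c("population", "continent")])
  stats::setNames(as.character(m$continent), as.character(m$population))
}

# Map labels (population codes or continent codes) to continent codes.
label_to_continent <- function(labels, metadata) {
  map <- population_continent_map(metadata)
  out <- unname(map[as.character(labels)])
  miss <- is.na(out)
  out[miss] <- as.character(labels)[miss]  # already a continent code
  out
}

log_note <- function(...) message("[chromaim] ", ...)
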