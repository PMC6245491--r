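#' Read a VCF file into a variant_set
#'
#' Parses a (plain or gzip-compressed) VCF v4.x file via \pkg{vcfR} and
#' resolves every diploid GT field to an ordered nucleotide pair using the
#' REF/ALT allele indices. Phased (\code{|}) and unphased (\code{/})
#' separators are treated identically. Records are dropped, with counts
#' reported on stderr, when they carry non-SNP alleles (any REF/ALT longer
#' than one nucleotide, or symbolic/missing ALT) or when any sample genotype
#' is missing (\code{./.}): all downstream statistics assume complete diploid
#' single-nucleotide data.
#'
#' @param path path to a VCF file (\code{.vcf} or \code{.vcf.gz}).
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  sample_ids <- if (!is.null(gt) && ncol(gt) > 1) colnames(gt)[-1] else character()
  m <- nrow(fix)
  if (is.null(m) || m == 0) {
    return(variant_set(sample_ids,
                       data.frame(rsid = character(), chrom = character(),
                                  pos = integer(), ref = character(),
                                  alt = character()),
                       matrix(character(), 0, length(sample_ids)),
                       matrix(character(), 0, length(sample_ids))))
  }
  if (length(sample_ids) == 0) stop("VCF contains no sample columns")

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  alt_list <- strsplit(alt, ",", fixed = TRUE)

  # non-SNP records: multi-base or non-ACGT alleles (REF may stay multi-base;
  # cleaning rule 1 owns that case -- only ALT length > 1 marks an indel here)
  bad_ref <- !nzchar(ref) | grepl("[^ACGT]", ref)
  is_indel <- vapply(alt_list, function(a) {
    length(a) == 0 || any(!nzchar(a)) || any(nchar(a) != 1L) || any(!a %in% BASES)
  }, logical(1))
  drop_allele <- bad_ref | is_indel
  if (any(drop_allele)) {
    log_note("read_vcf: dropped ", sum(drop_allele),
             " record(s) with non-SNP alleles")
  }

  # GT is the first colon-separated subfield
  gtv <- sub(":.*", "", gt[, -1, drop = FALSE])
  i1 <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\1", gtv)
  i2 <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\2", gtv)
  malformed <- i1 == gtv  # no diploid separator found
  missing_gt <- is.na(gtv) | malformed | i1 == "." | i2 == "."
  missing_gt[is.na(missing_gt)] <- TRUE
  drop_missing <- rowSums(matrix(missing_gt, nrow = m)) > 0 & !drop_allele
  if (any(drop_missing)) {
    log_note("read_vcf: dropped ", sum(drop_missing),
             " record(s) with missing genotypes")
  }

  keep <- which(!(drop_allele | drop_missing))
  a1 <- matrix(NA_character_, length(keep), length(sample_ids))
  a2 <- matrix(NA_character_, length(keep), length(sample_ids))
  for (r in seq_along(keep)) {
    i <- keep[r]
    alleles <- c(ref[i], alt_list[[i]])
    j1 <- as.integer(i1[i, ]) + 1L
    j2 <- as.integer(i2[i, ]) + 1L
    if (any(j1 > length(alleles)) || any(j2 > length(alleles))) {
      stop("GT allele index beyond ALT list at data line ", i,
           " (", fix[i, "ID"], ")")
    }
    a1[r, ] <- alleles[j1]
    a2[r, ] <- alleles[j2]
  }

  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("var", keep[is.na(ids) | ids == "."])
  variant_set(sample_ids,
              data.frame(rsid = ids, chrom = fix[keep, "CHROM"],
                         pos = as.integer(fix[keep, "POS"]),
                         ref = ref[keep], alt = alt[keep]),
              a1, a2)
}

#' Write a variant_set to a minimal VCF v4.2 file
#'
#' Emits a deterministic, minimal VCF: fixed two-line meta header, one data
#' line per variant, GT-only FORMAT. Genotype pairs are written in stored
#' order (unphased separator), so \code{read_vcf(write_vcf(x))} round-trips.
#' A \code{.gz} suffix triggers gzip compression.
#'
#' @param x a [variant_set()].
#' @param path output path (\code{.vcf} or \code{.vcf.gz}).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "variant_set"))
  m <- n_variants(x)
  lines <- character(m + 3L)
  lines[1] <- "##fileformat=VCFv4.2"
  lines[2] <- "##source=chromaim"
  lines[3] <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x$sample_ids), collapse = "\t")
  for (i in seq_len(m)) {
    alleles <- c(x$info$ref[i], strsplit(x$info$alt[i], ",", fixed = TRUE)[[1]])
    j1 <- match(x$a1[i, ], alleles)
    j2 <- match(x$a2[i, ], alleles)
    if (anyNA(j1) || anyNA(j2)) {
      stop("genotype nucleotide not representable by REF/ALT at ",
           x$info$rsid[i])
    }
    gt <- paste0(j1 - 1L, "/", j2 - 1L)
    lines[i + 3L] <- paste(c(x$info$chrom[i], x$info$pos[i], x$info$rsid[i],
                             x$info$ref[i], x$info$alt[i], ".", ".", ".",
                             "GT", gt), collapse = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a tab-separated file with header columns \code{sample_id},
#' \code{population}, \code{continent} mapping each sample to its
#' (sub-)population code and continental group. The population-to-continent
#' mapping must be a function: a population appearing under two continents
#' is rejected, as are duplicate sample ids.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns sample_id, population, continent.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata a metadata data.frame to write.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(df) {
  wanted <- c("sample_id", "population", "continent")
  if (!identical(sort(names(df)), sort(wanted))) {
    stop("metadata must have exactly the columns: ",
         paste(wanted, collapse = ", "))
  }
  df <- df[, wanted]
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  pc <- unique(df[, c("population", "continent")])
  dup <- pc$population[duplicated(pc$population)]
  if (length(dup)) {
    stop("population mapped to more than one continent: ",
         paste(unique(dup), collapse = ", "))
  }
  df
}
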