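#' Default 26-population study design
#'
#' The five continental groups and their sub-populations (with the standard
#' 1000 Genomes-style codes): 4 American, 5 European, 5 East-Asian,
#' 5 South-Asian and 7 African sub-populations.
#'
#' @return data.frame with columns population, continent.
#' @export
default_populations <- function() {
  data.frame(
    population = c("PUR", "CLM", "PEL", "MXL",
                   "GBR", "FIN", "IBS", "CEU", "TSI",
                   "CHS", "CDX", "KHV", "CHB", "JPT",
                   "PJL", "BEB", "STU", "ITU", "GIH",
                   "ACB", "GWD", "ESN", "MSL", "YRI", "LWK", "ASW"),
    continent = rep(c("AMR", "EUR", "EAS", "SAS", "AFR"),
                    times = c(4L, 5L, 5L, 5L, 7L)))
}

#' Configuration for the structured-population simulator
#'
#' Describes a hierarchical Balding-Nichols population model: each SNP has
#' an ancestral alternate-allele frequency p ~ Uniform(0.05, 0.95); each
#' continent draws its frequency from Beta(p(1-Fc)/Fc, (1-p)(1-Fc)/Fc) and
#' each sub-population draws analogously around its continent frequency
#' with Fs. Genotypes are two independent allele draws per individual
#' (no linkage disequilibrium between SNPs). On top of the background SNPs,
#' a number of fixed-difference ancestry-informative markers (AIMs) are
#' planted per population with known ground truth.
#'
#' @param populations data.frame(population, continent); default the
#'   26-population, 5-continent design of [default_populations()].
#' @param subpops_per_continent optional named integer vector (continent ->
#'   number of sub-populations) used to synthesize a generic design instead
#'   of \code{populations}.
#' @param samples_per_subpop individuals simulated per sub-population.
#' @param n_snps total number of SNPs emitted (background + planted AIMs).
#' @param fst_continental divergence Fc of continents from the ancestral
#'   pool, in (0, 1).
#' @param fst_subpop divergence Fs of sub-populations from their continent,
#'   in (0, 1).
#' @param n_planted_aims_per_pop planted AIMs per population (each with a
#'   distinct (REF, ALT) pair; at most 12 per population).
#' @param seed integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(populations = default_populations(),
                       subpops_per_continent = NULL,
                       samples_per_subpop = 20L, n_snps = 5000L,
                       fst_continental = 0.15, fst_subpop = 0.05,
                       n_planted_aims_per_pop = 2L, seed = 1L) {
  if (!is.null(subpops_per_continent)) {
    populations <- do.call(rbind, lapply(names(subpops_per_continent),
      function(cc) data.frame(
        population = sprintf("%s%d", cc,
                             seq_len(subpops_per_continent[[cc]])),
        continent = cc)))
  }
  stopifnot(samples_per_subpop >= 1, n_snps >= 1,
            fst_continental > 0, fst_continental < 1,
            fst_subpop > 0, fst_subpop < 1,
            n_planted_aims_per_pop >= 0, n_planted_aims_per_pop <= 12,
            nrow(populations) * n_planted_aims_per_pop <= n_snps)
  structure(list(populations = populations,
                 samples_per_subpop = as.integer(samples_per_subpop),
                 n_snps = as.integer(n_snps),
                 fst_continental = fst_continental,
                 fst_subpop = fst_subpop,
                 n_planted_aims_per_pop = as.integer(n_planted_aims_per_pop),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.beta_draw <- function(n, p, f) {
  stats::rbeta(n, p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# the 12 ordered (REF, ALT) pairs, cycled over when planting AIMs
.ref_alt_pairs <- function() {
  g <- expand.grid(alt = BASES, ref = BASES, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, c("ref", "alt")]
  rownames(g) <- NULL
  g
}

#' Simulate a structured-population genotype dataset (in memory)
#'
#' Draws the hierarchical Balding-Nichols dataset described by a
#' [sim_config()] and plants the fixed-difference AIMs. Each planted AIM
#' makes its target population homozygous for the alternate allele and one
#' deterministic contrast population (the first sub-population of the next
#' continent) uniformly heterozygous (REF, ALT); all remaining individuals
#' are reference homozygotes. The contrast population guarantees that the
#' AIM shows between-individual variation after reference-homozygote
#' masking -- i.e. lands in the dissimilarity set and survives the
#' pooled-uniformity removal -- while the target population still attains
#' alpha = beta = 1.
#'
#' @param config a [sim_config()].
#' @return list with \code{variants} (a [variant_set()]), \code{metadata}
#'   (data.frame) and \code{truth} (list: \code{aims} data.frame with rsid,
#'   population, continent, contrast_population, ref, alt;
#'   \code{ancestral_freq}; \code{pop_freq} matrix SNPs x populations of
#'   alternate-allele frequencies).
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  pops <- config$populations
  npop <- nrow(pops)
  ns <- config$samples_per_subpop
  m <- config$n_snps
  n_aims <- npop * config$n_planted_aims_per_pop

  metadata <- data.frame(
    sample_id = sprintf("%s_%03d", rep(pops$population, each = ns),
                        rep(seq_len(ns), npop)),
    population = rep(pops$population, each = ns),
    continent = rep(pops$continent, each = ns))

  withr::with_seed(config$seed, {
    pos <- sort(sample.int(240000000L, m))
    aim_rows <- if (n_aims > 0) sort(sample.int(m, n_aims)) else integer(0)
    bg_rows <- setdiff(seq_len(m), aim_rows)

    # background: hierarchical allele frequencies, then genotypes
    p_anc <- rep(NA_real_, m)
    pop_freq <- matrix(NA_real_, m, npop,
                       dimnames = list(NULL, pops$population))
    mb <- length(bg_rows)
    ref <- rep(NA_character_, m)
    alt <- rep(NA_character_, m)
    n <- npop * ns
    a1 <- matrix(NA_character_, m, n)
    a2 <- matrix(NA_character_, m, n)
    if (mb > 0) {
      p_anc[bg_rows] <- stats::runif(mb, 0.05, 0.95)
      conts <- unique(pops$continent)
      cont_freq <- vapply(conts, function(cc) {
        .beta_draw(mb, p_anc[bg_rows], config$fst_continental)
      }, numeric(mb))
      cont_freq <- matrix(cont_freq, nrow = mb,
                          dimnames = list(NULL, conts))
      for (j in seq_len(npop)) {
        cf <- cont_freq[, pops$continent[j]]
        pop_freq[bg_rows, j] <- .beta_draw(mb, cf, config$fst_subpop)
      }
      ref[bg_rows] <- sample(BASES, mb, replace = TRUE)
      alt[bg_rows] <- vapply(ref[bg_rows],
                             function(r) sample(setdiff(BASES, r), 1L), "")
      for (j in seq_len(npop)) {
        cols <- (j - 1L) * ns + seq_len(ns)
        sf <- pop_freq[bg_rows, j]
        d1 <- matrix(stats::rbinom(mb * ns, 1L, sf), mb, ns)
        d2 <- matrix(stats::rbinom(mb * ns, 1L, sf), mb, ns)
        a1[bg_rows, cols] <- ifelse(d1 == 1L, alt[bg_rows], ref[bg_rows])
        a2[bg_rows, cols] <- ifelse(d2 == 1L, alt[bg_rows], ref[bg_rows])
      }
    }
  })

  # planted AIMs (deterministic construction, no RNG)
  aims <- NULL
  if (n_aims > 0) {
    pairs <- .ref_alt_pairs()
    cont_seq <- unique(pops$continent)
    first_of_cont <- vapply(cont_seq, function(cc) {
      pops$population[pops$continent == cc][1]
    }, "")
    tgt <- rep(seq_len(npop), each = config$n_planted_aims_per_pop)
    within_k <- rep(seq_len(config$n_planted_aims_per_pop), npop)
    pair_idx <- (within_k - 1L) %% nrow(pairs) + 1L
    contrast <- vapply(tgt, function(j) {
      ci <- match(pops$continent[j], cont_seq)
      first_of_cont[[cont_seq[ci %% length(cont_seq) + 1L]]]
    }, "")
    for (a in seq_len(n_aims)) {
      i <- aim_rows[a]
      r <- pairs$ref[pair_idx[a]]; al <- pairs$alt[pair_idx[a]]
      ref[i] <- r; alt[i] <- al
      a1[i, ] <- r; a2[i, ] <- r
      tcols <- which(metadata$population == pops$population[tgt[a]])
      ccols <- which(metadata$population == contrast[a])
      a1[i, tcols] <- al; a2[i, tcols] <- al
      a2[i, ccols] <- al  # heterozygous (REF, ALT)
      p_anc[i] <- 0
      pop_freq[i, ] <- 0
      pop_freq[i, pops$population[tgt[a]]] <- 1
      pop_freq[i, contrast[a]] <- 0.5
    }
    aims <- data.frame(rsid = sprintf("rs%07d", aim_rows),
                       population = pops$population[tgt],
                       continent = pops$continent[tgt],
                       contrast_population = contrast,
                       ref = ref[aim_rows], alt = alt[aim_rows])
  }

  info <- data.frame(rsid = sprintf("rs%07d", seq_len(m)), chrom = "1",
                     pos = pos, ref = ref, alt = alt)
  list(variants = variant_set(metadata$sample_id, info, a1, a2),
       metadata = metadata,
       truth = list(aims = aims, ancestral_freq = p_anc,
                    pop_freq = pop_freq))
}

#' Simulate a dataset and write it to disk
#'
#' Runs [simulate_population()] and writes \code{genotypes.vcf},
#' \code{metadata.tsv} and \code{truth.json} (the AIM manifest) into
#' \code{out_dir}. Output is byte-identical for identical configurations.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return list with \code{vcf}, \code{metadata_path}, \code{truth_path}
#'   and the in-memory \code{truth} manifest.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_population(config)
  vcf <- file.path(out_dir, "genotypes.vcf")
  meta <- file.path(out_dir, "metadata.tsv")
  truth <- file.path(out_dir, "truth.json")
  write_vcf(sim$variants, vcf)
  write_metadata(sim$metadata, meta)
  jsonlite::write_json(list(aims = sim$truth$aims), truth, digits = NA,
                       auto_unbox = TRUE)
  list(vcf = vcf, metadata_path = meta, truth_path = truth,
       truth = sim$truth)
}
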