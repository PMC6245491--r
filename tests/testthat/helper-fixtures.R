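# Small fixture builders shared across test files.

# variant_set from genotype symbol strings: geno is a character matrix
# (variants x samples) of two-letter symbols like "AG".
make_vs <- function(ref, alt, geno, sample_ids = NULL, pos = NULL,
                    rsid = NULL) {
  geno <- as.matrix(geno)
  m <- nrow(geno)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(ncol(geno)))
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(rsid)) rsid <- sprintf("rs%d", seq_len(m))
  variant_set(sample_ids,
              data.frame(rsid = rsid, chrom = "1", pos = pos, ref = ref,
                         alt = alt),
              substr(geno, 1, 1), substr(geno, 2, 2))
}

# random valid variant_set for round-trip tests (biallelic SNPs)
random_vs <- function(n_var, n_samp, seed) {
  withr::with_seed(seed, {
    ref <- sample(c("A", "C", "G", "T"), n_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                          1), "")
    pick <- function() {
      i <- sample.int(2L, n_var * n_samp, replace = TRUE)
      matrix(ifelse(i == 1L, ref, alt), n_var, n_samp)
    }
    variant_set(sprintf("samp%03d", seq_len(n_samp)),
                data.frame(rsid = sprintf("rs%05d", seq_len(n_var)),
                           chrom = "1", pos = sort(sample.int(1e6, n_var)),
                           ref = ref, alt = alt),
                pick(), pick())
  })
}

# random performance matrix (iid uniform percent entries)
random_perf <- function(m, seed) {
  withr::with_seed(seed, {
    perf <- data.frame(rsid = sprintf("s%04d", seq_len(m)),
                       pos = sample.int(1e6, m),
                       overall = runif(m, 0, 100))
    for (cc in c("EUR", "AMR", "AFR", "EAS", "SAS")) {
      perf[[cc]] <- runif(m, 0, 100)
    }
    class(perf) <- c("performance_matrix", "data.frame")
    perf
  })
}

# --- default-study-conditions simulation, computed once per test run ------
# The default sim_config() IS the study condition set (26 sub-populations x
# 20 samples x 5000 SNPs, Fc = 0.15, Fs = 0.05, 2 planted AIMs per
# population, seed 1); derived pipeline products are cached alongside.
.cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.cache$sim)) .cache$sim <- simulate_population(sim_config())
  .cache$sim
}

default_products <- function() {
  if (is.null(.cache$prod)) {
    sim <- default_sim()
    cleaned <- clean_variants(sim$variants)
    masked <- mask_reference_homozygotes(cleaned$kept)
    parts <- partition_similarity(masked)
    split <- make_split(sim$metadata, 0.8, seed = 1)
    s1 <- stage1_select(parts$dissimilarity, sim$metadata, split$train)
    codes <- encode_symbols(parts$dissimilarity, split$train, s1$kept)
    labels <- dbscan_cluster(codes, eps = 0.1, min_pts = 2)
    outliers <- select_outliers(labels)
    ac <- allele_context_matrix(parts$dissimilarity)
    pos <- stats::setNames(parts$dissimilarity$info$pos,
                           parts$dissimilarity$info$rsid)
    perf <- build_performance_matrix(ac, outliers, sim$metadata, split,
                                     positions = pos)
    .cache$prod <- list(sim = sim, cleaned = cleaned,
                        dissimilarity = parts$dissimilarity, split = split,
                        stage1 = s1, outliers = outliers, ac = ac,
                        perf = perf)
  }
  .cache$prod
}

# canonical form of a clustering: outlier set + unordered set of clusters
canonical_partition <- function(labels) {
  labels <- unname(labels)
  cl <- sort(unique(labels[labels > 0]))
  groups <- lapply(cl, function(k) which(labels == k))
  list(outliers = which(labels == 0),
       clusters = groups[order(vapply(groups, min, 1L))])
}
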