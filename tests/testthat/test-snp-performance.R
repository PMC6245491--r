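test_that("allele context counts nucleotides differing from the reference", {
  expect_identical(allele_context("A", "A", "A"), 0L)
  expect_identical(allele_context("A", "A", "G"), 1L)
  expect_identical(allele_context("A", "G", "A"), 1L)
  expect_identical(allele_context("A", "G", "T"), 2L)
  vs <- make_vs("A", "G", matrix(c("AA", "AG", "GG"), 1, 3))
  ac <- allele_context_matrix(vs)
  expect_identical(unname(ac[, "rs1"]), c(0L, 1L, 2L))
  # masked entries are reference homozygotes: context 0 either way
  ac2 <- allele_context_matrix(mask_reference_homozygotes(vs))
  expect_identical(ac, ac2)
})

test_that("the split is stratified, deterministic and exhaustive", {
  meta <- data.frame(sample_id = sprintf("s%03d", 1:260),
                     population = rep(sprintf("P%02d", 1:26), each = 10),
                     continent = rep(c("EUR", "AMR", "AFR", "EAS", "SAS"),
                                     each = 52))
  sp <- make_split(meta, 0.8, seed = 3)
  pop_of <- stats::setNames(meta$population, meta$sample_id)
  expect_equal(as.integer(table(pop_of[sp$train])), rep(8L, 26))
  expect_equal(as.integer(table(pop_of[sp$test])), rep(2L, 26))
  expect_identical(sort(c(sp$train, sp$test)), sort(meta$sample_id))
  expect_identical(make_split(meta, 0.8, seed = 3), sp)
  expect_false(identical(make_split(meta, 0.8, seed = 4), sp))
})

test_that("per-stratum floor rounding reproduces the study-design train count", {
  sizes <- c(PUR = 104, CLM = 94, PEL = 85, MXL = 64, GBR = 91, FIN = 99,
             IBS = 107, CEU = 99, TSI = 107, CHS = 105, CDX = 93, KHV = 99,
             CHB = 103, JPT = 104, PJL = 96, BEB = 86, STU = 102, ITU = 102,
             GIH = 103, ACB = 96, GWD = 113, ESN = 99, MSL = 85, YRI = 108,
             LWK = 99, ASW = 61)
  expect_equal(sum(sizes), 2504)
  meta <- data.frame(
    sample_id = sprintf("i%04d", seq_len(sum(sizes))),
    population = rep(names(sizes), times = sizes),
    continent = rep(default_populations()$continent[
      match(names(sizes), default_populations()$population)], times = sizes))
  sp <- make_split(meta, 0.8, seed = 1)
  expect_equal(length(sp$train), sum(floor(0.8 * sizes)))
  expect_equal(length(sp$test), sum(sizes) - sum(floor(0.8 * sizes)))
})

test_that("a population with fewer than two samples cannot be split", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     population = c("P1", "P1", "P2"),
                     continent = "EUR")
  expect_error(make_split(meta, 0.8), "fewer than 2")
})

perf_fixture <- function() {
  sim <- simulate_population(sim_config(samples_per_subpop = 6, n_snps = 400,
                                        seed = 33))
  keep <- suppressMessages(clean_variants(sim$variants))$kept
  dis <- partition_similarity(mask_reference_homozygotes(keep))$dissimilarity
  split <- make_split(sim$metadata, 0.8, seed = 1)
  ac <- allele_context_matrix(dis)
  list(sim = sim, dis = dis, split = split, ac = ac,
       pos = stats::setNames(dis$info$pos, dis$info$rsid))
}

test_that("a perfectly continent-separating SNP scores 100 on its continent", {
  f <- perf_fixture()
  ac <- f$ac
  # manufacture a feature that is 2 for every AMR sample and 0 elsewhere
  amr <- f$sim$metadata$sample_id[f$sim$metadata$continent == "AMR"]
  ac[, 1] <- 0L
  ac[amr, 1] <- 2L
  perf <- build_performance_matrix(ac, colnames(ac)[1], f$sim$metadata,
                                   f$split, positions = f$pos)
  expect_equal(perf$AMR, 100)
  expect_true(all(perf[, -(1:2)] >= 0 & perf[, -(1:2)] <= 100))
})

test_that("a constant SNP scores the majority-class test rate", {
  f <- perf_fixture()
  # manufacture a constant feature column
  ac <- f$ac
  ac[, 1] <- 1L
  msgs <- capture_messages(
    perf <- build_performance_matrix(ac, colnames(ac)[1], f$sim$metadata,
                                     f$split, positions = f$pos))
  expect_match(msgs, "constant training feature", all = FALSE)
  pop_of <- stats::setNames(f$sim$metadata$population,
                            f$sim$metadata$sample_id)
  y_te <- pop_of[f$split$test]
  majority <- names(which.max(table(pop_of[f$split$train])))
  expect_equal(perf$overall, 100 * mean(y_te == majority))
})

test_that("performance rows are deterministic and match a per-SNP reference", {
  f <- perf_fixture()
  ids <- f$dis$info$rsid[1:8]
  perf1 <- build_performance_matrix(f$ac, ids, f$sim$metadata, f$split,
                                    positions = f$pos)
  perf2 <- build_performance_matrix(f$ac, ids, f$sim$metadata, f$split,
                                    positions = f$pos)
  expect_identical(perf1, perf2)
  # independent re-implementation: expanded (uncompressed) training loop
  pop_of <- stats::setNames(f$sim$metadata$population,
                            f$sim$metadata$sample_id)
  classes <- sort(unique(f$sim$metadata$population))
  for (id in ids[c(1, 5)]) {
    fit <- softmax_train(matrix(f$ac[f$split$train, id], ncol = 1),
                         unname(pop_of[f$split$train]), classes = classes)
    pred <- softmax_predict(fit, matrix(f$ac[f$split$test, id], ncol = 1))
    y_te <- unname(pop_of[f$split$test])
    expect_equal(perf1$overall[perf1$rsid == id], 100 * mean(pred == y_te),
                 tolerance = 1e-9)
  }
})

test_that("a row depends only on its own SNP's feature column", {
  f <- perf_fixture()
  ids <- f$dis$info$rsid[1:5]
  perf1 <- build_performance_matrix(f$ac, ids, f$sim$metadata, f$split,
                                    positions = f$pos)
  ac_perm <- f$ac
  other <- setdiff(colnames(f$ac), ids[1])
  ac_perm[, other] <- ac_perm[sample(nrow(ac_perm)), other]
  perf2 <- build_performance_matrix(ac_perm, ids[1], f$sim$metadata, f$split,
                                    positions = f$pos)
  expect_equal(perf2[1, -(1:2)], perf1[1, -(1:2)])
})

test_that("overall accuracy is the count-weighted mean over populations", {
  f <- perf_fixture()
  id <- f$dis$info$rsid[3]
  perf <- build_performance_matrix(f$ac, id, f$sim$metadata, f$split,
                                   positions = f$pos)
  pop_of <- stats::setNames(f$sim$metadata$population,
                            f$sim$metadata$sample_id)
  classes <- sort(unique(f$sim$metadata$population))
  fit <- softmax_train(matrix(f$ac[f$split$train, id], ncol = 1),
                       unname(pop_of[f$split$train]), classes = classes)
  pred <- softmax_predict(fit, matrix(f$ac[f$split$test, id], ncol = 1))
  y_te <- unname(pop_of[f$split$test])
  per_pop <- vapply(classes, function(p) mean(pred[y_te == p] == p),
                    numeric(1))
  wts <- vapply(classes, function(p) sum(y_te == p), numeric(1))
  expect_equal(perf$overall, 100 * sum(per_pop * wts) / sum(wts))
})
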