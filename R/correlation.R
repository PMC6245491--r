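#' Pearson correlation of two SNPs' continent performance profiles
#'
#' Computes the Pearson correlation coefficient over the five per-continent
#' elements of two performance vectors (elements 2..6 of a 6-vector; the
#' overall-accuracy element does not enter). Returns \code{NA} (undefined)
#' when either continent profile has zero variance.
#'
#' @param x_i,x_k numeric performance vectors of length 6 (overall + five
#'   continents) or length 5 (continent elements only).
#' @return correlation in [-1, 1], or \code{NA_real_} when undefined.
#' @export
continent_correlation <- function(x_i, x_k) {
  pick <- function(v) {
    if (length(v) == 6L) v[2:6] else if (length(v) == 5L) v else
      stop("performance vectors must have length 5 or 6")
  }
  a <- pick(as.numeric(x_i)); b <- pick(as.numeric(x_k))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

.continent_cols <- function(perf) {
  setdiff(names(perf), c("rsid", "pos", "overall"))
}

#' Greedy selection of non-redundant SNPs
#'
#' Ranks SNPs from highest to lowest on the chosen performance column
#' (overall accuracy, or one continent's element), initializes the panel
#' with the best-performing SNP, then scans down the ranking keeping a SNP
#' iff its continent-profile correlation with every already-kept SNP is at
#' most \code{threshold}; when two SNPs are redundant the better-ranked one
#' is the "non-redundant" member kept. Undefined correlations (zero-variance
#' profiles) never trigger pruning. Ranking ties are broken by genomic
#' position ascending, so the panel is fully reproducible.
#'
#' @param perf a \code{performance_matrix} from [build_performance_matrix()].
#' @param threshold correlation threshold th in [-1, 1].
#' @param ranking \code{"overall"} or a continent code (a column of
#'   \code{perf}).
#' @return object of class \code{snp_panel}: list with \code{snp_ids}
#'   (retention order), \code{threshold}, \code{ranking}, \code{accuracy}
#'   (NA until evaluated).
#' @export
greedy_nonredundant <- function(perf, threshold, ranking = "overall") {
  stopifnot(nrow(perf) >= 1, threshold >= -1, threshold <= 1)
  if (!ranking %in% names(perf)) stop("unknown ranking column: ", ranking)
  key <- perf[[ranking]]
  ord <- order(-key, perf$pos)
  cc <- as.matrix(perf[ord, .continent_cols(perf), drop = FALSE])
  xc <- cc - rowMeans(cc)
  css <- rowSums(xc^2)
  kept <- integer(0)
  for (i in seq_len(nrow(cc))) {
    if (length(kept) == 0L) {
      kept <- i
      next
    }
    cors <- as.numeric(xc[kept, , drop = FALSE] %*% xc[i, ]) /
      sqrt(css[kept] * css[i])
    cors[css[kept] == 0 | css[i] == 0] <- NA_real_
    if (all(is.na(cors) | cors <= threshold)) kept <- c(kept, i)
  }
  structure(list(snp_ids = perf$rsid[ord][kept], threshold = threshold,
                 ranking = ranking, accuracy = NA_real_),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel:", length(x$snp_ids), "SNPs (th =", x$threshold,
      ", ranking =", x$ranking, ")\n")
  invisible(x)
}

#' Train and evaluate a classifier on a SNP panel
#'
#' Fits the shared softmax classifier on the panel's allele-context features
#' over the training split and evaluates on the test split. The task is
#' either continental (labels = continent codes, all samples) or pairwise
#' (binary, restricted to the samples of two sub-populations).
#'
#' @param snp_ids panel SNP ids (or an \code{snp_panel}).
#' @param ac allele-context matrix from [allele_context_matrix()].
#' @param metadata sample metadata.
#' @param split list(train, test) from [make_split()].
#' @param task \code{"continental"} or a character vector of two
#'   sub-population codes.
#' @param control a [softmax_control()].
#' @return list from [softmax_evaluate()] plus \code{panel_size}.
#' @export
evaluate_panel <- function(snp_ids, ac, metadata, split,
                           task = "continental",
                           control = softmax_control()) {
  if (inherits(snp_ids, "snp_panel")) snp_ids <- snp_ids$snp_ids
  pop_of <- stats::setNames(metadata$population, metadata$sample_id)
  if (identical(task, "continental")) {
    tr <- split$train; te <- split$test
    y_tr <- label_to_continent(pop_of[tr], metadata)
    y_te <- label_to_continent(pop_of[te], metadata)
  } else {
    stopifnot(length(task) == 2)
    in_task <- metadata$sample_id[metadata$population %in% task]
    tr <- intersect(split$train, in_task)
    te <- intersect(split$test, in_task)
    y_tr <- unname(pop_of[tr]); y_te <- unname(pop_of[te])
  }
  fit <- softmax_train(ac[tr, snp_ids, drop = FALSE], y_tr, control = control)
  res <- softmax_evaluate(fit, ac[te, snp_ids, drop = FALSE], y_te,
                          metadata = metadata)
  res$panel_size <- length(snp_ids)
  res
}

#' Correlation-threshold scan
#'
#' For each threshold in the grid, builds the non-redundant panel, trains
#' and evaluates the classifier on its features, and records panel size and
#' test accuracy. Also reports the "best small panel": the highest-accuracy
#' panel whose size does not exceed \code{size_cap} (ties broken toward the
#' smaller panel, then the smaller threshold).
#'
#' @inheritParams evaluate_panel
#' @param perf a \code{performance_matrix}.
#' @param th_grid thresholds to scan (default 0.10..0.99 step 0.01).
#' @param ranking ranking column; defaults to \code{"overall"} for the
#'   continental task and the pair's continent for a pairwise task.
#' @param size_cap panel-size cap for the "best small panel" report.
#' @return list with \code{table} (threshold, panel_size, accuracy) and
#'   \code{best} (threshold, panel, accuracy).
#' @export
scan_thresholds <- function(perf, ac, metadata, split,
                            th_grid = seq(0.10, 0.99, by = 0.01),
                            task = "continental", ranking = NULL,
                            size_cap = 206L,
                            control = softmax_control()) {
  stopifnot(length(th_grid) >= 1)
  if (is.null(ranking)) {
    ranking <- if (identical(task, "continental")) "overall" else {
      cj <- unique(label_to_continent(task, metadata))
      if (length(cj) != 1) stop("pairwise task spans two continents")
      cj
    }
  }
  th_grid <- sort(th_grid)
  panels <- lapply(th_grid, greedy_nonredundant, perf = perf,
                   ranking = ranking)
  acc <- vapply(panels, function(p) {
    evaluate_panel(p, ac, metadata, split, task = task,
                   control = control)$accuracy
  }, numeric(1))
  sizes <- vapply(panels, function(p) length(p$snp_ids), integer(1))
  tab <- data.frame(threshold = th_grid, panel_size = sizes, accuracy = acc)
  ok <- which(sizes <= size_cap)
  if (length(ok) == 0) ok <- which.min(sizes)  # nothing under the cap
  best <- ok[order(-acc[ok], sizes[ok], th_grid[ok])][1]
  panel <- panels[[best]]
  panel$accuracy <- acc[best]
  list(table = tab, best = list(threshold = th_grid[best], panel = panel,
                                accuracy = acc[best]))
}

#' Panel for pairwise classification of two sub-populations
#'
#' Ranks the candidate SNPs by the continent-j element of the performance
#' matrix (j = the continent holding both sub-populations) and applies the
#' greedy non-redundancy scan at the given threshold. The resulting panel
#' is intended for binary classification restricted to samples of the two
#' sub-populations.
#'
#' @param perf a \code{performance_matrix}.
#' @param continent continent code of both sub-populations.
#' @param s1,s2 sub-population codes.
#' @param threshold correlation threshold.
#' @param metadata sample metadata (validates the sub-populations).
#' @return an \code{snp_panel} (with \code{task} attached).
#' @export
pairwise_panel <- function(perf, continent, s1, s2, threshold, metadata) {
  map <- population_continent_map(metadata)
  for (s in c(s1, s2)) {
    if (is.na(map[s]) || map[s] != continent) {
      stop(s, " is not a sub-population of ", continent)
    }
  }
  panel <- greedy_nonredundant(perf, threshold, ranking = continent)
  panel$task <- c(s1, s2)
  panel
}
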