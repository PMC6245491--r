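#' Configuration for the full panel-construction pipeline
#'
#' Aggregates the operating points of every stage: the 80/20 stratified
#' train-test split, the DBSCAN radius (default 0.1) and density threshold
#' (default 2), the correlation-threshold grid (default 0.10..0.99 step
#' 0.01) with the small-panel size cap, and the shared classifier
#' hyperparameters. A single global \code{seed} derives all stage seeds
#' deterministically (split seed = seed; any baseline/replicate seeds are
#' documented offsets of it), so partial re-runs reproduce bit-identically.
#'
#' @param vcf path to the input VCF (ignored when \code{sim} is given).
#' @param metadata path to the metadata TSV (ignored when \code{sim} given).
#' @param sim optional [sim_config()]: simulate the input instead of
#'   reading files.
#' @param out_dir directory for all persisted artifacts.
#' @param train_fraction training fraction of the split.
#' @param eps DBSCAN radius; \code{eps_grid} (optional) triggers the
#'   empirical radius scan instead.
#' @param min_pts DBSCAN density threshold.
#' @param th_grid correlation-threshold grid for the continental scan.
#' @param size_cap panel-size cap for the reported best small panel.
#' @param pairwise list of 2-vectors of sub-population codes (or a single
#'   continent code, expanded to all pairs within it) to evaluate as binary
#'   tasks; \code{NULL} for none.
#' @param pairwise_th_grid threshold grid for pairwise panels.
#' @param control a [softmax_control()].
#' @param seed global pipeline seed.
#' @param eps_grid optional radius grid for [scan_epsilon()].
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(vcf = NULL, metadata = NULL, sim = NULL,
                            out_dir = tempfile("chromaim_run_"),
                            train_fraction = 0.8,
                            eps = 0.1, min_pts = 2L, eps_grid = NULL,
                            th_grid = seq(0.10, 0.99, by = 0.01),
                            size_cap = 206L,
                            pairwise = NULL,
                            pairwise_th_grid = seq(0.10, 0.90, by = 0.10),
                            control = softmax_control(), seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, length(th_grid) >= 1)
  if (is.null(sim) && (is.null(vcf) || is.null(metadata))) {
    stop("provide either input paths (vcf, metadata) or a sim config")
  }
  structure(list(vcf = vcf, metadata = metadata, sim = sim,
                 out_dir = out_dir, train_fraction = train_fraction,
                 eps = eps, min_pts = as.integer(min_pts),
                 eps_grid = eps_grid, th_grid = th_grid,
                 size_cap = as.integer(size_cap), pairwise = pairwise,
                 pairwise_th_grid = pairwise_th_grid, control = control,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_lines <- function(x, path) {
  con <- file(path, "wb")  # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(x, con)
  path
}

.expand_pairwise <- function(pairwise, metadata) {
  if (is.null(pairwise)) return(list())
  if (!is.list(pairwise)) pairwise <- list(pairwise)
  out <- list()
  for (task in pairwise) {
    if (length(task) == 1) {  # a continent code -> all pairs within it
      pops <- sort(unique(metadata$population[metadata$continent == task]))
      cmb <- utils::combn(pops, 2)
      out <- c(out, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
    } else {
      out <- c(out, list(task))
    }
  }
  out
}

#' Run the full SNP-panel construction pipeline
#'
#' Executes, in order: read (or simulate) input -> cleaning ->
#' reference-homozygote masking and similarity partition -> Stage-1
#' parameter selection (training individuals only) -> Stage-2 DBSCAN
#' outlier selection -> single-SNP performance matrix -> correlation
#' threshold scan and continental panel -> final continental classification
#' -> optional pairwise sub-population tasks. Every intermediate artifact
#' is persisted under \code{out_dir} (cleaned VCF, SNP lists, performance
#' and scan tables, panel, JSON reports) and a manifest records the seeds
#' and the SNP counts at every stage of the selection funnel. A stage
#' failure aborts with the stage name; artifacts of completed stages
#' remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with all in-memory results and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input
  if (!is.null(config$sim)) {
    paths <- stage("input", simulate_dataset(config$sim, config$out_dir))
    variants <- stage("input", read_vcf(paths$vcf))
    metadata <- stage("input", read_metadata(paths$metadata_path))
  } else {
    variants <- stage("input", read_vcf(config$vcf))
    metadata <- stage("input", read_metadata(config$metadata))
  }

  # --- cleaning and partition
  cleaned <- stage("clean", clean_variants(variants))
  write_vcf(cleaned$kept, art("cleaned.vcf"))
  masked <- stage("mask", mask_reference_homozygotes(cleaned$kept))
  parts <- stage("partition", partition_similarity(masked))
  dis <- parts$dissimilarity

  # --- split (single shared split for selection and classification)
  split <- make_split(metadata, config$train_fraction, seed = config$seed)
  jsonlite::write_json(split, art("split.json"), digits = NA)

  # --- stage 1
  s1 <- stage("stage1", stage1_select(dis, metadata, split$train))
  .write_lines(s1$kept, art("stage1_snps.txt"))

  # --- stage 2
  if (length(s1$kept) == 0) {
    stop("pipeline aborted at stage 'stage2': Stage-1 selection is empty ",
         "(no SNP with alpha = beta = 1 for any population)", call. = FALSE)
  }
  codes <- encode_symbols(dis, split$train, snp_ids = s1$kept)
  ac <- allele_context_matrix(dis)
  pos <- stats::setNames(dis$info$pos, dis$info$rsid)
  s2 <- stage("stage2", {
    if (!is.null(config$eps_grid)) {
      eval_fn <- function(out_ids) {
        fit <- softmax_train(ac[split$train, out_ids, drop = FALSE],
                             metadata$population[match(split$train,
                                                       metadata$sample_id)],
                             control = config$control)
        softmax_evaluate(fit, ac[split$test, out_ids, drop = FALSE],
                         metadata$population[match(split$test,
                                                   metadata$sample_id)])$accuracy
      }
      sc <- scan_epsilon(codes, config$eps_grid, eval_fn,
                         min_pts = config$min_pts)
      list(labels = sc$labels, outliers = sc$outliers, eps = sc$best_eps,
           scan = sc$table)
    } else {
      labels <- dbscan_cluster(codes, config$eps, config$min_pts)
      list(labels = labels, outliers = select_outliers(labels),
           eps = config$eps, scan = NULL)
    }
  })
  if (length(s2$outliers) == 0) {
    stop("pipeline aborted at stage 'stage3': DBSCAN produced no outlier ",
         "SNPs at eps = ", s2$eps, call. = FALSE)
  }
  .write_lines(s2$outliers, art("stage2_snps.txt"))

  # --- performance matrix
  perf <- stage("performance",
                build_performance_matrix(ac, s2$outliers, metadata, split,
                                         positions = pos,
                                         control = config$control))
  utils::write.table(format(perf, digits = 10, scientific = FALSE),
                     art("perf.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- continental panel
  scan <- stage("panel",
                scan_thresholds(perf, ac, metadata, split,
                                th_grid = config$th_grid,
                                task = "continental",
                                size_cap = config$size_cap,
                                control = config$control))
  utils::write.table(format(scan$table, digits = 10, scientific = FALSE),
                     art("scan_continental.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  panel <- scan$best$panel
  .write_lines(panel$snp_ids, art("panel_continental.txt"))
  continental <- stage("classify",
                       evaluate_panel(panel, ac, metadata, split,
                                      task = "continental",
                                      control = config$control))

  # --- pairwise tasks
  pair_tasks <- .expand_pairwise(config$pairwise, metadata)
  pairwise <- lapply(pair_tasks, function(task) {
    cj <- unique(label_to_continent(task, metadata))
    best <- scan_thresholds(perf, ac, metadata, split,
                            th_grid = config$pairwise_th_grid, task = task,
                            ranking = cj, size_cap = config$size_cap,
                            control = config$control)$best
    data.frame(continent = cj, pair = paste(task, collapse = "-"),
               n_snps = length(best$panel$snp_ids),
               threshold = best$threshold, accuracy = best$accuracy)
  })
  pairwise <- if (length(pairwise)) do.call(rbind, pairwise) else NULL
  if (!is.null(pairwise)) {
    utils::write.table(format(pairwise, digits = 10, scientific = FALSE),
                       art("pairwise.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # --- manifest: the selection funnel with seeds and operating points
  manifest <- list(
    seed = config$seed,
    split = list(train_fraction = config$train_fraction,
                 n_train = length(split$train), n_test = length(split$test)),
    classifier = unclass(config$control),
    funnel = list(input = n_variants(variants),
                  cleaned = n_variants(cleaned$kept),
                  removed = as.list(cleaned$removed),
                  similarity = nrow(parts$similarity$info),
                  dissimilarity = nrow(dis$info),
                  stage1_union = length(s1$important),
                  stage1 = length(s1$kept),
                  stage2_outliers = length(s2$outliers),
                  panel = length(panel$snp_ids)),
    stage2 = list(eps = s2$eps, min_pts = config$min_pts,
                  n_clusters = max(c(0L, s2$labels))),
    panel = list(threshold = scan$best$threshold,
                 size = length(panel$snp_ids),
                 accuracy = continental$accuracy))
  jsonlite::write_json(manifest, art("manifest.json"), digits = NA,
                       auto_unbox = TRUE)

  report <- list(accuracy = continental$accuracy,
                 per_continent = as.list(continental$per_continent),
                 confusion = as.data.frame.matrix(continental$confusion),
                 panel_size = length(panel$snp_ids),
                 threshold = scan$best$threshold,
                 seed = config$seed,
                 hyperparameters = unclass(config$control))
  jsonlite::write_json(report, art("report_continental.json"), digits = NA,
                       auto_unbox = TRUE)

  invisible(list(metadata = metadata, split = split, cleaned = cleaned,
                 dissimilarity = dis, stage1 = s1, stage2 = s2, perf = perf,
                 scan = scan, panel = panel, continental = continental,
                 pairwise = pairwise, manifest = manifest,
                 out_dir = config$out_dir))
}

#' Summarize a pipeline run
#'
#' Prints a human-readable summary (selection funnel, continental confusion
#' matrix as row percentages, pairwise table) and returns the
#' machine-readable summary list. Missing artifacts are listed as absent
#' rather than raising an error.
#'
#' @param run result of [run_pipeline()] or the path of its output
#'   directory.
#' @return (invisibly) list with \code{manifest}, \code{continental} and
#'   \code{pairwise} components (entries may be NULL when absent).
#' @export
pipeline_report <- function(run) {
  if (is.character(run)) {
    grab <- function(f, reader) {
      p <- file.path(run, f)
      if (file.exists(p)) reader(p) else NULL
    }
    manifest <- grab("manifest.json", jsonlite::read_json)
    continental <- grab("report_continental.json", jsonlite::read_json)
    pairwise <- grab("pairwise.tsv",
                     function(p) utils::read.delim(p))
  } else {
    manifest <- run$manifest
    continental <- list(accuracy = run$continental$accuracy,
                        panel_size = length(run$panel$snp_ids),
                        confusion = run$continental$confusion)
    pairwise <- run$pairwise
  }
  for (part in c("manifest", "continental", "pairwise")) {
    if (is.null(get(part))) cat("[absent:", part, "]\n")
  }
  if (!is.null(manifest)) {
    cat("Selection funnel:\n")
    f <- manifest$funnel
    for (nm in c("input", "cleaned", "dissimilarity", "stage1",
                 "stage2_outliers", "panel")) {
      cat(sprintf("  %-16s %s\n", nm, f[[nm]]))
    }
  }
  if (!is.null(continental)) {
    cat(sprintf("Continental accuracy: %.2f%% (panel of %s SNPs)\n",
                as.numeric(continental$accuracy),
                continental$panel_size %||% NA))
    conf <- continental$confusion
    if (!is.null(conf) && is.table(conf)) {
      pct <- round(100 * prop.table(conf, margin = 1), 2)
      print(pct)
    }
  }
  if (!is.null(pairwise)) {
    cat("Pairwise sub-population tasks:\n")
    print(pairwise, row.names = FALSE)
  }
  invisible(list(manifest = manifest, continental = continental,
                 pairwise = pairwise))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
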