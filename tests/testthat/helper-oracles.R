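# Independent reference implementations used as test oracles. Each is a
# deliberately naive re-implementation kept separate from the package code.

# per-rule brute-force cleaning checker: returns rsids surviving all rules
oracle_clean <- function(vs) {
  keep <- character()
  for (i in seq_len(nrow(vs$info))) {
    ref <- vs$info$ref[i]
    alts <- strsplit(vs$info$alt[i], ",")[[1]]
    if (nchar(ref) > 1) next                                   # rule 1
    if (any(vapply(alts, function(a) grepl(ref, a, fixed = TRUE),
                   logical(1)))) next                          # rule 2
    all_hom_ref <- TRUE
    for (s in seq_along(vs$sample_ids)) {
      if (vs$a1[i, s] != ref || vs$a2[i, s] != ref) {
        all_hom_ref <- FALSE
        break
      }
    }
    if (all_hom_ref) next                                      # rule 3
    keep <- c(keep, vs$info$rsid[i])
  }
  keep
}

# declarative DBSCAN reference: core points by neighbour count, clusters as
# connected components of cores (breadth-first search), border points
# assigned to the earliest-created cluster with a core within eps
oracle_dbscan <- function(x, eps, min_pts) {
  n <- nrow(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(x))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  comp <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(comp[i])) next
    cl <- cl + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cl
      nxt <- which(core & nb[v, ] & is.na(comp))
      queue <- c(queue, nxt)
    }
  }
  labels <- integer(n)
  for (i in seq_len(n)) {
    if (core[i]) {
      labels[i] <- comp[i]
    } else {
      near_cores <- which(core & nb[i, ])
      labels[i] <- if (length(near_cores)) min(comp[near_cores]) else 0L
    }
  }
  labels
}

# plain-formula Pearson coefficient over the five continent elements
oracle_pearson <- function(xi, xk) {
  a <- xi[2:6]; b <- xk[2:6]
  am <- sum(a) / 5; bm <- sum(b) / 5
  num <- sum((a - am) * (b - bm))
  den <- sqrt(sum((a - am)^2)) * sqrt(sum((b - bm)^2))
  if (den == 0) NA_real_ else num / den
}

# step-by-step reference of the greedy non-redundancy scan
oracle_greedy <- function(perf, th, ranking = "overall") {
  ord <- order(-perf[[ranking]], perf$pos)
  df <- perf[ord, ]
  cc <- as.matrix(df[, c("EUR", "AMR", "AFR", "EAS", "SAS")])
  kept <- c()
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in kept) {
      r <- oracle_pearson(c(0, cc[i, ]), c(0, cc[j, ]))
      if (!is.na(r) && r > th) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  df$rsid[kept]
}

# brute-force alpha/beta for one SNP row of a masked_variants object
oracle_alpha_beta <- function(masked, row, metadata, training_ids) {
  out <- NULL
  for (p in sort(unique(metadata$population))) {
    ids <- intersect(training_ids,
                     metadata$sample_id[metadata$population == p])
    codes <- masked$codes[row, match(ids, masked$sample_ids)]
    retained <- codes[codes > 0]
    n_p <- length(ids)
    n_pi <- length(retained)
    f <- if (n_pi > 0) max(table(retained)) else 0L
    out <- rbind(out, data.frame(
      population = p, n_p = n_p, n_p_i = n_pi, f_p_i = as.integer(f),
      alpha = n_pi / n_p,
      beta = if (n_pi > 0) f / n_pi else NA_real_))
  }
  out
}
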