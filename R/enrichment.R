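# Set-level statistics: DE gene sets, hypergeometric overlap, Fisher exact,
# BH-FDR, per-cluster dysregulation calls, K-S, and the random-cluster null.

#' Threshold a differential-expression table into up/down/all gene sets
#'
#' Strict inequalities throughout: a gene is up-regulated if
#' \code{adj_p < p_cut} and \code{beta > beta_cut}, down-regulated if
#' \code{adj_p < p_cut} and \code{beta < -beta_cut}.
#'
#' @param de data frame with columns \code{gene}, \code{beta}, \code{adj_p}.
#' @param p_cut adjusted-p cutoff (default 0.05).
#' @param beta_cut absolute effect-size cutoff (default 0.5).
#' @return list with character vectors \code{up}, \code{down}, \code{all}.
#' @export
de_gene_sets <- function(de, p_cut = 0.05, beta_cut = 0.5) {
  missing <- setdiff(c("gene", "beta", "adj_p"), names(de))
  if (length(missing) > 0L) {
    stop("missing column(s) in DE table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(p_cut > 0, beta_cut > 0)
  sig <- de$adj_p < p_cut
  up <- de$gene[sig & de$beta > beta_cut]
  down <- de$gene[sig & de$beta < -beta_cut]
  list(up = up, down = down, all = union(up, down))
}

#' Hypergeometric overlap of two gene sets
#'
#' One-sided upper-tail test of whether \code{set_a} contains more members of
#' \code{set_b} than expected when drawing \code{|set_a|} genes from the
#' background without replacement: \eqn{p = P(X \ge k)} for
#' \eqn{X \sim} Hypergeometric(\eqn{N = |background|, K = |set_b|,
#' n = |set_a|}).
#'
#' @param set_a,set_b character vectors, subsets of \code{background}.
#' @param background the gene universe.
#' @param name optional label carried into the record.
#' @return one-row data frame (class \code{enrichment_record}) with columns
#'   \code{name}, \code{k}, \code{n}, \code{K}, \code{N_bg}, \code{p}.
#' @export
hypergeometric_overlap <- function(set_a, set_b, background, name = NA_character_) {
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  out_a <- setdiff(set_a, background)
  out_b <- setdiff(set_b, background)
  if (length(out_a) > 0L || length(out_b) > 0L) {
    stop("sets must be subsets of the background (",
         length(out_a) + length(out_b), " offending genes)", call. = FALSE)
  }
  k <- length(intersect(set_a, set_b))
  n <- length(set_a)
  K <- length(set_b)
  N <- length(background)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(data.frame(name = name, k = k, n = n, K = K, N_bg = N, p = p,
                       stringsAsFactors = FALSE),
            class = c("enrichment_record", "data.frame"))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing the probabilities of all tables with the same
#' margins whose probability does not exceed the observed table's. The
#' reported odds ratio is the sample OR \eqn{(ad)/(bc)} (not the conditional
#' MLE); it is \code{Inf} when \eqn{bc = 0} with \eqn{ad > 0} and \code{NA}
#' when a margin is zero (in which case \eqn{p = 1}).
#'
#' @param table a 2x2 matrix of nonnegative integer counts.
#' @return list with \code{odds_ratio} and \code{p}.
#' @export
fisher_exact <- function(table) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2L, 2L)) || any(x < 0) || any(x != round(x))) {
    stop("`table` must be a 2x2 matrix of nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  ad <- x[1, 1] * x[2, 2]
  bc <- x[1, 2] * x[2, 1]
  or <- if (bc == 0) Inf else ad / bc
  list(odds_ratio = or, p = stats::fisher.test(x)$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; output order
#' matches the input.
#'
#' @param pvalues numeric vector of p-values in \code{[0, 1]}.
#' @return adjusted q-values, entrywise at least the input and at most 1.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-cluster transcriptomic dysregulation calls
#'
#' For every cluster with at least \code{min_size} genes in the background
#' (genes present in both the network and the DE table), tests whether the
#' cluster holds more differentially expressed genes than expected
#' (hypergeometric upper tail against the all-DE set), adjusts across the
#' tested clusters by Benjamini-Hochberg, and tags the predominant direction
#' (\code{"up"} if up-regulated DE genes outnumber down-regulated ones,
#' \code{"down"} for the reverse, \code{"mixed"} on ties). Directional
#' hypergeometric p-values are reported unadjusted, as secondary evidence.
#' Cluster genes missing from the background are dropped from the cluster
#' size with a message.
#'
#' @param partition a \code{cluster_partition}.
#' @param de DE table (columns \code{gene}, \code{beta}, \code{adj_p}).
#' @param background gene universe: genes in both the network and DE table.
#' @param min_size minimum cluster size (within background) to test
#'   (default 10).
#' @param p_cut,beta_cut DE thresholds passed to [de_gene_sets()].
#' @return data frame (class \code{dysregulation_calls}) with one row per
#'   tested cluster: \code{cluster}, \code{n_bg}, \code{n_de}, \code{n_up},
#'   \code{n_down}, \code{p}, \code{q}, \code{p_up}, \code{p_down},
#'   \code{direction}.
#' @export
cluster_dysregulation <- function(partition, de, background, min_size = 10L,
                                  p_cut = 0.05, beta_cut = 0.5) {
  stopifnot(inherits(partition, "cluster_partition"))
  background <- unique(as.character(background))
  sets <- de_gene_sets(de, p_cut, beta_cut)
  de_all <- intersect(sets$all, background)
  de_up <- intersect(sets$up, background)
  de_down <- intersect(sets$down, background)
  N <- length(background)

  n_missing <- sum(!unlist(partition$clusters, use.names = FALSE) %in% background)
  if (n_missing > 0L) {
    message(sprintf(
      "cluster_dysregulation: %d cluster gene(s) not in the background were dropped",
      n_missing))
  }

  rows <- lapply(names(partition$clusters), function(cid) {
    genes <- intersect(partition$clusters[[cid]], background)
    n <- length(genes)
    if (n < min_size) return(NULL)
    k_all <- length(intersect(genes, de_all))
    k_up <- length(intersect(genes, de_up))
    k_down <- length(intersect(genes, de_down))
    data.frame(cluster = cid,
               n_bg = n,
               n_de = k_all,
               n_up = k_up,
               n_down = k_down,
               p = stats::phyper(k_all - 1, length(de_all),
                                 N - length(de_all), n, lower.tail = FALSE),
               p_up = stats::phyper(k_up - 1, length(de_up),
                                    N - length(de_up), n, lower.tail = FALSE),
               p_down = stats::phyper(k_down - 1, length(de_down),
                                      N - length(de_down), n, lower.tail = FALSE),
               direction = if (k_up > k_down) "up"
                           else if (k_down > k_up) "down" else "mixed",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    out <- data.frame(cluster = character(), n_bg = integer(),
                      n_de = integer(), n_up = integer(), n_down = integer(),
                      p = numeric(), q = numeric(), p_up = numeric(),
                      p_down = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("dysregulation_calls", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[, c("cluster", "n_bg", "n_de", "n_up", "n_down",
                 "p", "q", "p_up", "p_down", "direction")]
  structure(out, class = c("dysregulation_calls", "data.frame"))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' \eqn{D = \sup_x |ECDF_a(x) - ECDF_b(x)|}; the p-value is exact (by
#' enumeration over the pooled sample) when both samples have at most 10
#' observations, and the asymptotic Kolmogorov distribution otherwise.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return list with \code{D} and \code{p}.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- length(sample_a) <= 10L && length(sample_b) <= 10L
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = exact))
  list(D = unname(res$statistic), p = min(1, res$p.value))
}

#' Random-cluster null for per-cluster dysregulation
#'
#' Control analysis for [cluster_dysregulation()]: replicates the whole
#' module-building pipeline with degree-matched random seeds (same per-bin
#' composition as the true seeds), clusters each random module and counts
#' clusters passing the dysregulation FDR cut. If the DE signal is specific
#' to the true seeds' network neighbourhood, random replicates should yield
#' far fewer passing clusters.
#'
#' All replicates share one degree-matched null-score ensemble (replicate
#' seed sets have the same bin composition as the true seeds, so the
#' ensemble is exchangeable across replicates); the ensemble and the
#' replicate "observed" sets are drawn independently.
#'
#' @param graph the network (largest component).
#' @param seeds true seed genes (used for size and bin composition).
#' @param de DE table.
#' @param background genes in both network and DE table.
#' @param n_reps number of random-seed replicates (must be >= 1).
#' @param n_null null-ensemble size used for each replicate's z-scores.
#' @param alpha,z_threshold,min_bin_size propagation/module parameters.
#' @param q_cut FDR cut counted per replicate (default 0.2).
#' @param min_size minimum cluster size to test.
#' @param p_cut,beta_cut DE thresholds.
#' @param rng_seed integer seed.
#' @return object of class \code{random_cluster_null}: \code{n_pass} (per
#'   replicate count of clusters with \code{q < q_cut}), \code{calls}
#'   (per-replicate dysregulation tables), \code{q_cut}.
#' @export
random_cluster_null <- function(graph, seeds, de, background,
                                n_reps = 50L, n_null = 300L,
                                alpha = 0.5, z_threshold = 2,
                                min_bin_size = 10L, q_cut = 0.2,
                                min_size = 10L, p_cut = 0.05, beta_cut = 0.5,
                                rng_seed = NULL) {
  check_graph(graph)
  if (!is.numeric(n_reps) || n_reps < 1L) {
    stop("`n_reps` must be >= 1", call. = FALSE)
  }
  seeds <- unique(as.character(seeds))
  W <- normalize_adjacency(graph)
  bins <- assign_degree_bins(graph, min_bin_size)

  with_rng(rng_seed, {
    sets <- replicate(n_null + n_reps, sample_matched_set(seeds, bins),
                      simplify = FALSE)
    scores <- propagate_matrix(W, seed_heat_matrix(W, sets), alpha)
    null_scores <- scores[, seq_len(n_null), drop = FALSE]
    logn <- log(pmax(null_scores, .Machine$double.xmin))
    any_zero <- rowSums(null_scores <= 0) > 0
    mu <- rowMeans(logn)
    sdv <- apply(logn, 1L, stats::sd)

    calls <- vector("list", n_reps)
    n_pass <- integer(n_reps)
    for (r in seq_len(n_reps)) {
      obs <- scores[, n_null + r]
      z <- (log(pmax(obs, .Machine$double.xmin)) - mu) / sdv
      z[obs <= 0 | any_zero | sdv == 0] <- NA_real_
      rep_seeds <- sets[[n_null + r]]
      is_seed <- rownames(scores) %in% rep_seeds
      proximal <- rownames(scores)[!is_seed & !is.na(z) & z > z_threshold]
      module <- union(rep_seeds, proximal)
      part <- louvain_cluster(module_subgraph(graph, module),
                              rng_seed = sample.int(.Machine$integer.max, 1L),
                              min_report_size = min_size)
      dys <- suppressMessages(
        cluster_dysregulation(part, de, background, min_size = min_size,
                              p_cut = p_cut, beta_cut = beta_cut))
      calls[[r]] <- dys
      n_pass[r] <- sum(dys$q < q_cut)
    }
    structure(list(n_pass = n_pass, calls = calls, q_cut = q_cut,
                   n_reps = n_reps, n_null = n_null),
              class = "random_cluster_null")
  })
}

#' @export
print.random_cluster_null <- function(x, ...) {
  cat(sprintf(
    "random-cluster null: %d replicates; mean %.2f clusters with q < %g (max %d)\n",
    x$n_reps, mean(x$n_pass), x$q_cut, max(x$n_pass)))
  invisible(x)
}
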