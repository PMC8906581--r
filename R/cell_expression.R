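# Cluster-by-cell-type expression summaries and preferential-expression tests.

#' Mean cell-type expression per cluster
#'
#' Entry (c, t) is the arithmetic mean FPKM of cluster c's genes (those
#' present in the expression matrix) in cell type t. Clusters with no genes
#' in the matrix get an NA row; genes missing from the matrix are counted in
#' a message.
#'
#' @param partition a \code{cluster_partition}.
#' @param expr genes-by-cell-types FPKM matrix (see [read_fpkm_matrix()]).
#' @return numeric matrix, clusters x cell types.
#' @export
cluster_celltype_profile <- function(partition, expr) {
  stopifnot(inherits(partition, "cluster_partition"), is.matrix(expr))
  all_genes <- unlist(partition$clusters, use.names = FALSE)
  n_missing <- sum(!all_genes %in% rownames(expr))
  if (n_missing == length(all_genes)) {
    stop("no cluster gene is present in the expression matrix", call. = FALSE)
  }
  if (n_missing > 0L) {
    message(sprintf(
      "cluster_celltype_profile: %d cluster gene(s) absent from the expression matrix",
      n_missing))
  }
  out <- t(vapply(partition$clusters, function(genes) {
    genes <- intersect(genes, rownames(expr))
    if (length(genes) == 0L) return(rep(NA_real_, ncol(expr)))
    colMeans(expr[genes, , drop = FALSE])
  }, numeric(ncol(expr))))
  dimnames(out) <- list(names(partition$clusters), colnames(expr))
  out
}

# Wilcoxon rank-sum wrapper: exact null distribution when both samples are
# small and untied, otherwise the normal approximation with midranks and the
# tie-corrected variance (no continuity correction).
#' Wilcoxon rank-sum test
#'
#' @param x,y numeric samples.
#' @param alternative \code{"greater"}, \code{"less"} or \code{"two.sided"};
#'   one-sided alternatives refer to \code{x} against \code{y}.
#' @return list with \code{W} (rank-sum statistic of \code{x}, shifted as in
#'   \code{\link[stats]{wilcox.test}}) and \code{p}.
#' @export
rank_sum_test <- function(x, y, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(list(W = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(pooled) > 0L
  small <- length(x) < 50L && length(y) < 50L
  res <- if (!ties && small) {
    stats::wilcox.test(x, y, alternative = alternative, exact = TRUE)
  } else {
    stats::wilcox.test(x, y, alternative = alternative, exact = FALSE,
                       correct = FALSE)
  }
  list(W = unname(res$statistic), p = res$p.value)
}

#' Preferential expression of a cluster in a focal cell type
#'
#' One-sided Wilcoxon rank-sum test comparing the cluster genes' FPKM in the
#' focal cell type against the same genes' FPKM pooled across all other cell
#' types (alternative: focal values are greater).
#'
#' @param partition a \code{cluster_partition}.
#' @param expr genes-by-cell-types FPKM matrix.
#' @param cluster_id cluster id (name in \code{partition$clusters}).
#' @param cell_type focal cell type (a column of \code{expr}).
#' @return list with \code{p}, \code{direction} (\code{"higher"} or
#'   \code{"lower"} by mean contrast), \code{n_genes}, \code{cell_type},
#'   \code{comparison} (a note fixing the contrast definition).
#' @export
preferential_expression <- function(partition, expr, cluster_id, cell_type) {
  stopifnot(inherits(partition, "cluster_partition"), is.matrix(expr))
  cluster_id <- as.character(cluster_id)
  if (!cluster_id %in% names(partition$clusters)) {
    stop("unknown cluster id: ", cluster_id, call. = FALSE)
  }
  if (!cell_type %in% colnames(expr)) {
    stop("unknown cell type: ", cell_type, call. = FALSE)
  }
  if (ncol(expr) < 2L) stop("need at least 2 cell types", call. = FALSE)
  genes <- intersect(partition$clusters[[cluster_id]], rownames(expr))
  if (length(genes) < 3L) {
    stop("cluster must have at least 3 genes in the expression matrix",
         call. = FALSE)
  }
  focal <- expr[genes, cell_type]
  other <- as.vector(expr[genes, setdiff(colnames(expr), cell_type), drop = FALSE])
  res <- rank_sum_test(focal, other, alternative = "greater")
  list(p = res$p,
       direction = if (mean(focal) >= mean(other)) "higher" else "lower",
       n_genes = length(genes),
       cell_type = cell_type,
       comparison = "focal cell type vs same genes pooled over other cell types, one-sided greater")
}
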