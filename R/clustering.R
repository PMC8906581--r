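# Modularity clustering of the disease-module subgraph.

#' Induced subgraph on the disease-module genes
#'
#' @param graph the full network.
#' @param module a \code{disease_module} or a character vector of gene ids.
#' @return the induced igraph subgraph (nodes without internal edges are
#'   retained and become orphan clusters downstream).
#' @export
module_subgraph <- function(graph, module) {
  check_graph(graph)
  genes <- if (inherits(module, "disease_module")) module$module
           else unique(as.character(module))
  unknown <- setdiff(genes, node_names(graph))
  if (length(unknown) > 0L) {
    stop("module genes absent from the graph: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  igraph::induced_subgraph(graph, genes)
}

#' Newman-Girvan modularity of a partition
#'
#' \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)} over communities \eqn{c}, with
#' \eqn{e_c} internal edges, \eqn{d_c} the total degree of the community and
#' \eqn{m} the edge count. Computed on the unweighted (thresholded) graph.
#'
#' @param graph an igraph graph with at least one edge.
#' @param membership named community assignment covering all vertices, or a
#'   \code{cluster_partition}.
#' @return modularity Q in \eqn{[-0.5, 1]}.
#' @export
graph_modularity <- function(graph, membership) {
  check_graph(graph)
  m <- igraph::ecount(graph)
  if (m == 0L) stop("modularity is undefined for an edgeless graph", call. = FALSE)
  if (inherits(membership, "cluster_partition")) membership <- membership$membership
  memb <- membership[node_names(graph)]
  if (anyNA(memb)) stop("membership must cover every vertex", call. = FALSE)
  el <- igraph::as_edgelist(graph)
  internal <- memb[el[, 1L]] == memb[el[, 2L]]
  # internal edges per community (edges whose both ends share the community)
  e_c <- table(factor(memb[el[, 1L]][internal], levels = unique(memb)))
  d_c <- tapply(igraph::degree(graph), memb, sum)
  sum(e_c[names(d_c)] / m) - sum((d_c / (2 * m))^2)
}

#' Louvain modularity clustering with size-class reporting
#'
#' Partitions the (module sub)graph by two-phase Louvain modularity
#' maximization at resolution 1. The node visiting order is randomized, so a
#' fixed \code{rng_seed} makes the partition reproducible. Cluster ids are
#' reassigned deterministically after the fact: decreasing size, ties broken
#' by the lexicographically smallest member. Clusters are labelled
#' \code{"large"} (\code{>= min_report_size} genes), \code{"small"} (2 to
#' \code{min_report_size - 1}) or \code{"orphan"} (singletons).
#'
#' @param subgraph an igraph graph (typically from [module_subgraph()]).
#' @param rng_seed integer seed fixing the Louvain node order.
#' @param min_report_size size cutoff for the "large" reporting class
#'   (default 10).
#' @return object of class \code{cluster_partition}: \code{membership}
#'   (named integer), \code{clusters} (list id -> genes), \code{sizes},
#'   \code{size_class}, \code{modularity} (NA for an edgeless graph),
#'   \code{min_report_size}.
#' @export
louvain_cluster <- function(subgraph, rng_seed = NULL, min_report_size = 10L) {
  check_graph(subgraph)
  n <- igraph::vcount(subgraph)
  if (n == 0L) stop("empty subgraph", call. = FALSE)
  if (igraph::ecount(subgraph) == 0L) {
    memb <- stats::setNames(seq_len(n), node_names(subgraph))
  } else {
    comm <- with_rng(rng_seed,
                     igraph::cluster_louvain(subgraph, weights = NA,
                                             resolution = 1))
    memb <- stats::setNames(igraph::membership(comm), node_names(subgraph))
  }

  clusters <- split(names(memb), memb)
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, "", 1L), method = "radix")
  clusters <- clusters[ord]
  names(clusters) <- seq_along(clusters)
  membership <- stats::setNames(rep(seq_along(clusters), lengths(clusters)),
                                unlist(clusters, use.names = FALSE))
  membership <- membership[node_names(subgraph)]
  sizes <- lengths(clusters)
  size_class <- ifelse(sizes >= min_report_size, "large",
                       ifelse(sizes >= 2L, "small", "orphan"))
  Q <- if (igraph::ecount(subgraph) > 0L) {
    graph_modularity(subgraph, membership)
  } else NA_real_
  structure(list(membership = membership,
                 clusters = clusters,
                 sizes = sizes,
                 size_class = stats::setNames(size_class, names(clusters)),
                 modularity = Q,
                 min_report_size = min_report_size),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  tab <- table(factor(x$size_class, levels = c("large", "small", "orphan")))
  cat(sprintf("cluster partition: %d genes in %d clusters (Q = %s)\n",
              length(x$membership), length(x$clusters),
              if (is.na(x$modularity)) "NA" else sprintf("%.4f", x$modularity)))
  cat(sprintf("  %d large (>= %d genes), %d small (2-%d), %d orphans\n",
              tab[["large"]], x$min_report_size, tab[["small"]],
              x$min_report_size - 1L, tab[["orphan"]]))
  invisible(x)
}

#' @export
as.data.frame.cluster_partition <- function(x, ...) {
  data.frame(gene = names(x$membership),
             cluster = unname(x$membership),
             size_class = unname(x$size_class[as.character(x$membership)]),
             stringsAsFactors = FALSE)
}
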