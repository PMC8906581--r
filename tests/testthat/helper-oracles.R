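# Independent brute-force oracles and small fixture builders.
# Oracles enumerate outcomes directly (combinations / factorials) and never
# call the implementation paths they check.

# upper-tail hypergeometric P(X >= k) by enumerating every draw of n from a
# background of N with the first K elements "marked"
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# two-sided Fisher p: enumerate all tables with the observed margins,
# probabilities from factorials via lchoose; sum those not exceeding the
# observed table's probability (with the conventional 1e-7 relative slack
# against floating-point ties)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  N <- r1 + r2
  aa <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(lchoose(r1, aa) + lchoose(r2, c1 - aa) - lchoose(N, c1))
  p_obs <- pr[aa == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# exact two-sample K-S p by enumerating every assignment of the pooled
# sample into two groups of the observed sizes
ks_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  d_obs <- ks_stat(x, y)
  ds <- apply(idx, 2L, function(i) ks_stat(pooled[i], pooled[-i]))
  mean(ds >= d_obs - 1e-12)
}

# exact one-sided (greater) Wilcoxon rank-sum p by enumeration; statistic is
# the Mann-Whitney U of the first sample (midranks for ties)
wilcox_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_of <- function(i) sum(r[i]) - n * (n + 1) / 2
  # ranks are recomputed per assignment on the same pooled multiset, so
  # u_of is valid for every relabeling
  idx <- utils::combn(length(pooled), n)
  u_obs <- u_of(seq_len(n))
  us <- apply(idx, 2L, u_of)
  mean(us >= u_obs - 1e-12)
}

# all set partitions of n items as restricted-growth strings
set_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxv) {
    i <- length(prefix) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  res
}

# Newman-Girvan Q evaluated from first principles on an edge list
modularity_oracle <- function(el, n, memb) {
  m <- nrow(el)
  deg <- tabulate(c(el[, 1L], el[, 2L]), n)
  e_c <- tapply(rep(1L, m), list(ifelse(memb[el[, 1L]] == memb[el[, 2L]],
                                        memb[el[, 1L]], NA)), sum)
  e_c <- e_c[!is.na(names(e_c))]
  d_c <- tapply(deg, memb, sum)
  sum(unlist(e_c)) / m - sum((d_c / (2 * m))^2)
}

# exhaustive modularity optimum over all partitions (tiny graphs only)
best_partition_oracle <- function(el, n) {
  parts <- set_partitions(n)
  qs <- vapply(parts, function(p) modularity_oracle(el, n, p), 0)
  list(membership = parts[[which.max(qs)]], Q = max(qs))
}

# adjusted Rand index by exact pair counting
ari <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  sij <- s(tab); si <- s(rowSums(tab)); sj <- s(colSums(tab))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# --- fixture builders -------------------------------------------------------

named_graph <- function(edges_chr) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_chr[, 1L], to = edges_chr[, 2L],
               stringsAsFactors = FALSE), directed = FALSE)
  igraph::E(g)$score <- 0.9
  g
}

# small random connected-ish graph with named vertices
random_named_graph <- function(n, p = 0.15) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  igraph::E(g)$score <- stats::runif(igraph::ecount(g), 0.71, 1)
  g
}

# two cliques of size k joined by one bridge edge
two_clique_graph <- function(k) {
  e1 <- t(utils::combn(sprintf("a%d", seq_len(k)), 2L))
  e2 <- t(utils::combn(sprintf("b%d", seq_len(k)), 2L))
  named_graph(rbind(e1, e2, c("a1", "b1")))
}

# minimal hand-built cluster partition (only the fields the consumers use)
make_partition <- function(clusters, min_report_size = 10L) {
  clusters <- lapply(clusters, sort)
  names(clusters) <- seq_along(clusters)
  membership <- stats::setNames(rep(seq_along(clusters), lengths(clusters)),
                                unlist(clusters, use.names = FALSE))
  sizes <- lengths(clusters)
  structure(list(membership = membership, clusters = clusters, sizes = sizes,
                 size_class = stats::setNames(
                   ifelse(sizes >= min_report_size, "large",
                          ifelse(sizes >= 2, "small", "orphan")),
                   names(clusters)),
                 modularity = NA_real_, min_report_size = min_report_size),
            class = "cluster_partition")
}

edge_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
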