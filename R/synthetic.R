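# Planted-community synthetic benchmark generator with ground truth:
# a heavy-tailed planted-partition network, seeds concentrated in designated
# communities, a DE table with effects planted in those communities, and a
# cell-type FPKM matrix with cluster-by-cell-type signal.

#' Generate a planted-partition network with hubs and ground truth
#'
#' Nodes are split into \code{n_communities} near-equal communities; each
#' within-community pair is joined with probability \code{p_in}, each
#' between-community pair with \code{p_out}. A \code{degree_tail} fraction of
#' nodes become hubs by gaining extra edges to uniformly random partners
#' (one-tenth of the node count each), emulating the heavy degree tail of
#' real interactomes and stressing the degree-matched null. Edge confidence
#' scores are drawn uniformly on (0.7, 1], so the conventional 0.7 threshold
#' keeps every edge.
#'
#' The ground truth also fixes the community roles used by the other
#' generators: the first \code{n_seed_communities} communities are
#' seed-enriched; the first half of those are DE-up and the second half
#' DE-down (so all planted DE signal sits in seed communities); every
#' community is marked for one cell type, cycling through
#' \code{n_cell_types} types.
#'
#' @param n_nodes number of genes (default 600).
#' @param n_communities number of planted communities (default 12).
#' @param p_in,p_out within- and between-community edge probabilities
#'   (defaults 0.25 and 0.01; requires \code{0 <= p_out < p_in <= 1}).
#' @param degree_tail fraction of nodes promoted to hubs (default 0.05).
#' @param n_seed_communities number of seed-enriched communities (default 4).
#' @param n_cell_types number of cell types in the truth marks (default 5).
#' @param rng_seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return list with \code{graph} (igraph, edge attribute \code{score}) and
#'   \code{truth} (class \code{synthetic_truth}: \code{membership},
#'   \code{seed_enriched}, \code{de_up}, \code{de_down}, \code{hubs},
#'   \code{celltype_marks}, \code{cell_types}).
#' @export
generate_network <- function(n_nodes = 600L, n_communities = 12L,
                             p_in = 0.25, p_out = 0.01, degree_tail = 0.05,
                             n_seed_communities = 4L, n_cell_types = 5L,
                             rng_seed = NULL) {
  stopifnot(n_nodes >= 2L, n_communities >= 1L,
            n_seed_communities <= n_communities)
  check_fraction(p_in, "p_in")
  check_fraction(p_out, "p_out")
  check_fraction(degree_tail, "degree_tail")
  if (!(p_out < p_in)) stop("need p_out < p_in", call. = FALSE)

  genes <- sprintf("g%04d", seq_len(n_nodes))
  # contiguous blocks: community sizes differ by at most 1
  membership <- stats::setNames(sort(rep(seq_len(n_communities),
                                         length.out = n_nodes)), genes)

  with_rng(rng_seed, {
    pair_i <- rep(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
    pair_j <- unlist(lapply(seq_len(n_nodes - 1L),
                            function(i) (i + 1L):n_nodes),
                     use.names = FALSE)
    same <- membership[pair_i] == membership[pair_j]
    prob <- ifelse(same, p_in, p_out)
    keep <- stats::runif(length(prob)) < prob
    ei <- pair_i[keep]
    ej <- pair_j[keep]

    hubs <- if (degree_tail > 0) {
      sample(seq_len(n_nodes), max(1L, round(degree_tail * n_nodes)))
    } else integer(0)
    extra <- max(1L, round(n_nodes / 10))
    for (h in hubs) {
      partners <- sample(setdiff(seq_len(n_nodes), h), extra)
      ei <- c(ei, pmin(h, partners))
      ej <- c(ej, pmax(h, partners))
    }
    key <- ei * (n_nodes + 1) + ej
    dup <- duplicated(key)
    ei <- ei[!dup]; ej <- ej[!dup]

    edges <- data.frame(from = genes[ei], to = genes[ej],
                        score = stats::runif(length(ei), 0.7, 1),
                        stringsAsFactors = FALSE)
    graph <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = genes, stringsAsFactors = FALSE))

    seed_enriched <- seq_len(n_seed_communities)
    half <- ceiling(n_seed_communities / 2)
    truth <- structure(list(
      membership = membership,
      seed_enriched = seed_enriched,
      de_up = seed_enriched[seq_len(half)],
      de_down = seed_enriched[setdiff(seq_len(n_seed_communities),
                                      seq_len(half))],
      hubs = genes[hubs],
      celltype_marks = stats::setNames(
        rep(seq_len(n_cell_types), length.out = n_communities),
        seq_len(n_communities)),
      cell_types = sprintf("celltype_%d", seq_len(n_cell_types))),
      class = "synthetic_truth")
    list(graph = graph, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic truth: %d genes, %d communities (%d seed-enriched; DE up: %s, down: %s)\n",
    length(x$membership), length(unique(x$membership)),
    length(x$seed_enriched),
    paste(x$de_up, collapse = ","), paste(x$de_down, collapse = ",")))
  invisible(x)
}

#' Draw a seed gene set concentrated in the seed-enriched communities
#'
#' A \code{concentration} fraction of the seeds is drawn uniformly (without
#' replacement) from genes of seed-enriched communities, the remainder
#' uniformly from all other genes.
#'
#' @param truth a \code{synthetic_truth}.
#' @param n_seeds number of seeds (default 40, about 7\% of the default
#'   network).
#' @param concentration fraction of seeds placed in enriched communities
#'   (default 0.9).
#' @param rng_seed integer seed.
#' @return character vector of seed gene ids.
#' @export
generate_seeds <- function(truth, n_seeds = 40L, concentration = 0.9,
                           rng_seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_fraction(concentration, "concentration")
  genes <- names(truth$membership)
  if (n_seeds > length(genes)) {
    stop("`n_seeds` exceeds the number of genes", call. = FALSE)
  }
  inside <- genes[truth$membership %in% truth$seed_enriched]
  outside <- setdiff(genes, inside)
  n_in <- min(round(concentration * n_seeds), length(inside))
  n_out <- n_seeds - n_in
  if (n_out > length(outside)) {
    n_out <- length(outside)
    n_in <- n_seeds - n_out
  }
  with_rng(rng_seed, sort(c(sample(inside, n_in), sample(outside, n_out))))
}

#' Generate a differential-expression table with planted community effects
#'
#' Genes of DE-up communities get \code{beta ~ Normal(effect_mu, effect_sd)}
#' and small adjusted p-values (uniform on (0, 0.01)); DE-down communities
#' the mirror image; all remaining genes get \code{beta ~ Normal(0, null_sd)}
#' and adjusted p uniform on (0, 1) except for a \code{frac_sig_bg} spike of
#' background genes with p uniform on (0, 0.05). Setting \code{effect_mu = 0}
#' switches the planted communities off entirely (a no-signal tissue, like a
#' cerebellum control), so significant calls arise at the background rate
#' only.
#'
#' @param truth a \code{synthetic_truth}.
#' @param effect_mu planted |beta| mean (default 2; 0 disables the signal).
#' @param effect_sd planted beta standard deviation (default 0.5).
#' @param null_sd background beta standard deviation (default 0.3).
#' @param frac_sig_bg fraction of background genes given a small adjusted p
#'   (default 0.02).
#' @param rng_seed integer seed.
#' @return data frame with columns \code{gene}, \code{beta}, \code{adj_p}.
#' @export
generate_de_table <- function(truth, effect_mu = 2, effect_sd = 0.5,
                              null_sd = 0.3, frac_sig_bg = 0.02,
                              rng_seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), effect_sd > 0, null_sd > 0)
  check_fraction(frac_sig_bg, "frac_sig_bg")
  genes <- names(truth$membership)
  n <- length(genes)
  comm <- truth$membership
  up <- effect_mu > 0 & comm %in% truth$de_up
  down <- effect_mu > 0 & comm %in% truth$de_down
  bg <- !up & !down
  with_rng(rng_seed, {
    beta <- numeric(n)
    adj_p <- numeric(n)
    beta[up] <- stats::rnorm(sum(up), effect_mu, effect_sd)
    beta[down] <- stats::rnorm(sum(down), -effect_mu, effect_sd)
    beta[bg] <- stats::rnorm(sum(bg), 0, null_sd)
    adj_p[up | down] <- stats::runif(sum(up | down), 0, 0.01)
    spike <- bg & stats::runif(n) < frac_sig_bg
    adj_p[spike] <- stats::runif(sum(spike), 0, 0.05)
    adj_p[bg & !spike] <- stats::runif(sum(bg & !spike))
    data.frame(gene = genes, beta = beta, adj_p = adj_p,
               stringsAsFactors = FALSE)
  })
}

#' Generate a genes-by-cell-type FPKM matrix with planted marks
#'
#' Each gene gets a log-normal baseline expression level; values per cell
#' type are the baseline times multiplicative log-normal noise
#' (\code{exp(Normal(0, noise_sd))}); genes of a community marked for cell
#' type t are multiplied by \code{fold} in t. \code{fold = 1} yields no
#' preferential expression.
#'
#' @param truth a \code{synthetic_truth}.
#' @param n_cell_types number of cell types (default 5).
#' @param fold expression fold-change in the marked cell type (default 10;
#'   must be >= 1).
#' @param noise_sd log-scale noise standard deviation (default 0.5).
#' @param rng_seed integer seed.
#' @return numeric genes x cell types matrix of nonnegative FPKM values.
#' @export
generate_celltype_fpkm <- function(truth, n_cell_types = 5L, fold = 10,
                                   noise_sd = 0.5, rng_seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), fold >= 1, noise_sd > 0)
  genes <- names(truth$membership)
  n <- length(genes)
  marks <- truth$celltype_marks[as.character(truth$membership)]
  marks <- ((marks - 1L) %% n_cell_types) + 1L
  with_rng(rng_seed, {
    base <- stats::rlnorm(n, meanlog = 1, sdlog = 1)
    m <- base * matrix(exp(stats::rnorm(n * n_cell_types, 0, noise_sd)),
                       n, n_cell_types)
    m[cbind(seq_len(n), marks)] <- m[cbind(seq_len(n), marks)] * fold
    dimnames(m) <- list(genes, sprintf("celltype_%d", seq_len(n_cell_types)))
    m
  })
}

#' Write a full synthetic input bundle to disk
#'
#' Generates the network, seed list, DE table and FPKM matrix with the
#' default study conditions and writes them in the dialects accepted by the
#' loaders, plus the ground truth as JSON. Deterministic in \code{rng_seed}
#' (stage seeds are derived from it).
#'
#' @param dir output directory (created if needed).
#' @param rng_seed integer master seed.
#' @param ... overrides passed to [generate_network()].
#' @param n_seeds,concentration passed to [generate_seeds()].
#' @return list with the file \code{paths}, the \code{truth} and the
#'   generated \code{seeds}.
#' @export
synthetic_bundle <- function(dir, rng_seed = 1L, ...,
                             n_seeds = 40L, concentration = 0.9) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng_seed <- as.integer(rng_seed)
  sim <- generate_network(..., rng_seed = rng_seed)
  seeds <- generate_seeds(sim$truth, n_seeds = n_seeds,
                          concentration = concentration,
                          rng_seed = rng_seed + 1L)
  de <- generate_de_table(sim$truth, rng_seed = rng_seed + 2L)
  fpkm <- generate_celltype_fpkm(sim$truth, rng_seed = rng_seed + 3L)

  paths <- list(edges = file.path(dir, "edges.tsv"),
                seeds = file.path(dir, "seeds.txt"),
                de = file.path(dir, "de.tsv"),
                fpkm = file.path(dir, "fpkm.tsv"),
                truth = file.path(dir, "truth.json"))
  write_interactome(sim$graph, paths$edges)
  writeLines(seeds, paths$seeds)
  utils::write.table(de, paths$de, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(fpkm), fpkm,
                                check.names = FALSE),
                     paths$fpkm, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(membership = as.list(sim$truth$membership),
                            seed_enriched = sim$truth$seed_enriched,
                            de_up = sim$truth$de_up,
                            de_down = sim$truth$de_down,
                            hubs = sim$truth$hubs,
                            celltype_marks = as.list(sim$truth$celltype_marks)),
                       paths$truth, auto_unbox = TRUE)
  list(paths = paths, truth = sim$truth, seeds = seeds)
}
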