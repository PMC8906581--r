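# Heat propagation from seed genes, degree-matched null ensemble, log-space
# z-scores and disease-module assembly.

# Fixed-point iteration F <- alpha W' F + (1 - alpha) Y from F0 = Y, run
# simultaneously on every column of Y; converges geometrically because the
# spectral radius of alpha W' is at most alpha < 1.
propagate_matrix <- function(W, Y, alpha, tol = 1e-8, max_iter = 1000L) {
  check_fraction(alpha, "alpha", open_lo = TRUE, open_hi = TRUE)
  F0 <- Y
  base <- (1 - alpha) * Y
  for (it in seq_len(max_iter)) {
    F1 <- alpha * (W %*% F0) + base
    res <- max(abs(F1 - F0))
    F0 <- F1
    if (res < tol) {
      return(structure(as.matrix(F0), iterations = it, residual = res))
    }
  }
  stop(sprintf("propagation did not converge in %d iterations (residual %.3g)",
               max_iter, res), call. = FALSE)
}

seed_heat_matrix <- function(W, seed_sets) {
  n <- nrow(W)
  nodes <- rownames(W)
  Y <- matrix(0, n, length(seed_sets), dimnames = list(nodes, NULL))
  for (j in seq_along(seed_sets)) {
    idx <- match(seed_sets[[j]], nodes)
    Y[idx, j] <- 1 / length(idx)
  }
  Y
}

#' Propagate heat from a seed set over the normalized network operator
#'
#' Iterates \eqn{F \leftarrow \alpha W' F + (1-\alpha) Y} to its fixed point,
#' where \eqn{Y} places \eqn{1/S} on each of the \eqn{S} seed genes and 0
#' elsewhere, and \eqn{\alpha} is the fraction of heat retained on the network
#' at each step. The fixed point equals the direct linear solution
#' \eqn{(1-\alpha)(I - \alpha W')^{-1} Y}.
#'
#' @param W normalized adjacency operator from [normalize_adjacency()].
#' @param seeds character vector of seed gene ids, all present in the network.
#' @param alpha dissipation parameter in (0, 1); default 0.5.
#' @param tol convergence tolerance on the max-norm change per iteration.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return named numeric vector of propagation scores, with attributes
#'   \code{alpha}, \code{iterations} and \code{residual}.
#' @export
propagate <- function(W, seeds, alpha = 0.5, tol = 1e-8, max_iter = 1000L) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("seed set is empty", call. = FALSE)
  missing <- setdiff(seeds, rownames(W))
  if (length(missing) > 0L) {
    stop("seed genes absent from the network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Fm <- propagate_matrix(W, seed_heat_matrix(W, list(seeds)), alpha,
                         tol = tol, max_iter = max_iter)
  structure(stats::setNames(Fm[, 1L], rownames(W)),
            alpha = alpha,
            iterations = attr(Fm, "iterations"),
            residual = attr(Fm, "residual"))
}

# Draw one degree-matched replacement of `seeds`: within each degree bin the
# seeds falling in that bin are replaced by a uniform sample (without
# replacement) of the bin's members. The original seeds stay in the candidate
# pool, which keeps the degree matching unbiased.
sample_matched_set <- function(seeds, bins) {
  bin_ids <- bins$bin_of[seeds]
  if (anyNA(bin_ids)) {
    stop("seed genes missing from the degree bins: ",
         paste(seeds[is.na(bin_ids)], collapse = ", "), call. = FALSE)
  }
  out <- character(length(seeds))
  for (b in unique(bin_ids)) {
    take <- which(bin_ids == b)
    pool <- bins$bins[[as.character(b)]]
    if (length(take) > length(pool)) {
      stop(sprintf("degree bin %s has %d members but must supply %d seeds",
                   b, length(pool), length(take)), call. = FALSE)
    }
    out[take] <- sample(pool, length(take), replace = FALSE)
  }
  out
}

#' Degree-matched null ensemble of propagation scores
#'
#' Each replicate replaces every seed by a gene drawn uniformly from the same
#' degree bin (without replacement within the replicate) and reruns the heat
#' propagation, yielding the per-gene null score distribution used for the
#' proximity z-scores.
#'
#' @inheritParams propagate
#' @param bins degree bins from [assign_degree_bins()].
#' @param n_samples number of null replicates (default 5000).
#' @param rng_seed integer seed making the ensemble reproducible.
#' @return an object of class \code{null_ensemble}: list with \code{scores}
#'   (genes x replicates matrix), \code{seed_sets} (S x replicates character
#'   matrix) and \code{alpha}.
#' @export
sample_null_ensemble <- function(W, seeds, bins, n_samples = 5000L,
                                 alpha = 0.5, rng_seed = NULL,
                                 tol = 1e-8, max_iter = 1000L) {
  seeds <- unique(as.character(seeds))
  if (n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  sets <- with_rng(rng_seed,
                   replicate(n_samples, sample_matched_set(seeds, bins),
                             simplify = FALSE))
  scores <- propagate_matrix(W, seed_heat_matrix(W, sets), alpha,
                             tol = tol, max_iter = max_iter)
  structure(list(scores = scores,
                 seed_sets = do.call(cbind, sets),
                 alpha = alpha,
                 n_samples = n_samples),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("degree-matched null ensemble: %d replicates, %d seeds, %d genes\n",
              x$n_samples, nrow(x$seed_sets), nrow(x$scores)))
  invisible(x)
}

#' Log-space proximity z-scores against a null ensemble
#'
#' Propagation scores are log transformed (natural log) so they are
#' approximately normal, and each gene's observed log score is compared with
#' the mean and sample standard deviation (denominator \eqn{N-1}) of its log
#' null scores: \eqn{z_n = (\log F_n - \langle \log F_{n,rand} \rangle) /
#' \sigma(\log F_{n,rand})}. Genes with a zero observed or null score, or a
#' zero null standard deviation, get \code{NA} (they are reported, and
#' excluded from the module downstream).
#'
#' @param observed named score vector from [propagate()].
#' @param ensemble a \code{null_ensemble} sharing the same gene index.
#' @return data frame (class \code{proximity_result}) with columns
#'   \code{gene}, \code{score}, \code{null_mean_log}, \code{null_sd_log},
#'   \code{z}.
#' @export
proximity_zscores <- function(observed, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  null <- ensemble$scores
  if (ncol(null) < 2L) {
    stop("at least 2 null replicates are required for a standard deviation",
         call. = FALSE)
  }
  if (!identical(names(observed), rownames(null))) {
    stop("observed scores and ensemble do not share a gene index", call. = FALSE)
  }
  ok <- observed > 0 & Matrix::rowSums(null <= 0) == 0
  logn <- log(pmax(null, .Machine$double.xmin))
  mu <- rowMeans(logn)
  sdv <- apply(logn, 1L, stats::sd)
  z <- (log(pmax(observed, .Machine$double.xmin)) - mu) / sdv
  z[!ok | sdv == 0] <- NA_real_
  mu[!ok] <- NA_real_
  sdv[!ok] <- NA_real_
  structure(data.frame(gene = names(observed),
                       score = unname(observed),
                       null_mean_log = unname(mu),
                       null_sd_log = unname(sdv),
                       z = unname(z),
                       stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("proximity_result", "data.frame"))
}

#' Assemble the disease module from proximity z-scores
#'
#' The module is the union of the seed genes and the proximal genes: non-seed
#' genes whose z-score strictly exceeds \code{z_threshold}. Seeds are retained
#' regardless of their own z. Genes with undefined z are never proximal; their
#' ids are carried along for reporting.
#'
#' @param z a \code{proximity_result} from [proximity_zscores()].
#' @param seeds character vector of seed genes.
#' @param z_threshold proximity cutoff; the default 2 corresponds to the
#'   upper ~2\% tail of a standard normal.
#' @return object of class \code{disease_module}: list with \code{seeds},
#'   \code{proximal}, \code{module}, \code{undefined}, \code{z_threshold}.
#' @export
build_module <- function(z, seeds, z_threshold = 2) {
  stopifnot(inherits(z, "proximity_result"), is.finite(z_threshold))
  seeds <- unique(as.character(seeds))
  is_seed <- z$gene %in% seeds
  proximal <- z$gene[!is_seed & !is.na(z$z) & z$z > z_threshold]
  structure(list(seeds = seeds,
                 proximal = proximal,
                 module = union(seeds, proximal),
                 undefined = z$gene[is.na(z$z)],
                 z_threshold = z_threshold),
            class = "disease_module")
}

#' @export
print.disease_module <- function(x, ...) {
  cat(sprintf("disease module: %d genes (%d seeds + %d proximal at z > %g)\n",
              length(x$module), length(x$seeds), length(x$proximal),
              x$z_threshold))
  if (length(x$undefined) > 0L) {
    cat(sprintf("  %d genes with undefined z excluded\n", length(x$undefined)))
  }
  invisible(x)
}

#' Expand a seed gene set into a disease module by network propagation
#'
#' The main fitting function. Given a thresholded interaction network and a
#' set of risk genes, it (i) builds the symmetric degree-normalized operator,
#' (ii) propagates heat from the seeds, (iii) draws a degree-matched null
#' ensemble via degree binning, (iv) computes per-gene log-space proximity
#' z-scores, and (v) assembles the disease module as seeds plus genes with
#' \code{z > z_threshold}.
#'
#' Seed genes absent from the network are dropped with a message (the model
#' mirrors the common situation where some GWAS-mapped genes are not in the
#' interactome).
#'
#' @param graph thresholded network from [load_interactome()] (ideally
#'   restricted to its largest component, see [largest_component()]).
#' @param seeds character vector of seed gene ids.
#' @param alpha dissipation parameter in (0, 1); default 0.5.
#' @param n_null number of degree-matched null replicates (default 5000).
#' @param z_threshold module inclusion cutoff on the proximity z-score.
#' @param min_bin_size minimum size of a degree bin.
#' @param rng_seed integer seed for the null ensemble.
#' @param tol,max_iter propagation convergence controls.
#' @return an object of class \code{netprop}; see [summary.netprop()].
#'   Component \code{scores} is a per-gene data frame with columns
#'   \code{gene}, \code{is_seed}, \code{score}, \code{null_mean_log},
#'   \code{null_sd_log}, \code{z}, \code{in_module}.
#' @examples
#' sim <- generate_network(n_nodes = 120, n_communities = 4, p_in = 0.3,
#'                         p_out = 0.02, rng_seed = 1)
#' seeds <- generate_seeds(sim$truth, n_seeds = 15, rng_seed = 2)
#' fit <- netprop(sim$graph, seeds, n_null = 50, rng_seed = 3)
#' summary(fit)
#' @export
netprop <- function(graph, seeds, alpha = 0.5, n_null = 5000L,
                    z_threshold = 2, min_bin_size = 10L, rng_seed = NULL,
                    tol = 1e-8, max_iter = 1000L) {
  check_graph(graph)
  seeds <- unique(as.character(seeds))
  dropped <- setdiff(seeds, node_names(graph))
  seeds <- intersect(seeds, node_names(graph))
  if (length(seeds) == 0L) stop("no seed genes present in the network", call. = FALSE)
  if (length(dropped) > 0L) {
    message(sprintf("netprop: %d seed gene(s) not in the network were dropped",
                    length(dropped)))
  }

  W <- normalize_adjacency(graph)
  bins <- assign_degree_bins(graph, min_bin_size)
  observed <- propagate(W, seeds, alpha, tol = tol, max_iter = max_iter)
  ensemble <- sample_null_ensemble(W, seeds, bins, n_samples = n_null,
                                   alpha = alpha, rng_seed = rng_seed,
                                   tol = tol, max_iter = max_iter)
  prox <- proximity_zscores(observed, ensemble)
  module <- build_module(prox, seeds, z_threshold)

  scores <- data.frame(gene = prox$gene,
                       is_seed = prox$gene %in% seeds,
                       score = prox$score,
                       null_mean_log = prox$null_mean_log,
                       null_sd_log = prox$null_sd_log,
                       z = prox$z,
                       stringsAsFactors = FALSE)
  scores$in_module <- scores$gene %in% module$module

  structure(list(scores = scores,
                 seeds = seeds,
                 dropped_seeds = dropped,
                 module = module,
                 bins = bins,
                 alpha = alpha,
                 n_null = n_null,
                 z_threshold = z_threshold,
                 rng_seed = rng_seed,
                 call = match.call()),
            class = "netprop")
}

#' @export
print.netprop <- function(x, ...) {
  cat("Network-propagation disease module\n")
  cat(sprintf("  network: %d genes; seeds: %d (alpha = %g, %d null replicates)\n",
              nrow(x$scores), length(x$seeds), x$alpha, x$n_null))
  print(x$module)
  invisible(x)
}

#' Summarize a network-propagation fit
#'
#' @param object a \code{netprop} fit.
#' @param n_top number of top proximal genes to display.
#' @param ... unused.
#' @export
summary.netprop <- function(object, n_top = 10L, ...) {
  sc <- object$scores
  prox <- sc[!sc$is_seed & !is.na(sc$z) & sc$z > object$z_threshold, ]
  prox <- prox[order(-prox$z), ]
  structure(list(n_genes = nrow(sc),
                 n_seeds = length(object$seeds),
                 n_dropped_seeds = length(object$dropped_seeds),
                 n_proximal = nrow(prox),
                 n_module = length(object$module$module),
                 n_undefined = sum(is.na(sc$z)),
                 z_threshold = object$z_threshold,
                 alpha = object$alpha,
                 n_null = object$n_null,
                 z_quantiles = stats::quantile(sc$z, c(.05, .25, .5, .75, .95),
                                               na.rm = TRUE),
                 top = utils::head(prox[, c("gene", "score", "z")], n_top)),
            class = "summary.netprop")
}

#' @export
print.summary.netprop <- function(x, ...) {
  cat("Network-propagation disease module\n")
  cat(sprintf("  genes: %d; seeds used: %d (%d absent from network)\n",
              x$n_genes, x$n_seeds, x$n_dropped_seeds))
  cat(sprintf("  alpha = %g, null replicates = %d, z threshold = %g\n",
              x$alpha, x$n_null, x$z_threshold))
  cat(sprintf("  module: %d genes = %d seeds + %d proximal (z > %g); %d undefined z\n",
              x$n_module, x$n_seeds, x$n_proximal, x$z_threshold, x$n_undefined))
  cat("  z-score quantiles:\n")
  print(round(x$z_quantiles, 3))
  if (nrow(x$top) > 0L) {
    cat("  top proximal genes:\n")
    print(x$top, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.netprop <- function(object, ...) {
  stats::setNames(object$scores$z, object$scores$gene)
}

#' Plot the proximity z-score distribution of a fit
#'
#' Histogram of the per-gene z-scores with the module threshold marked;
#' seeds are excluded (their z plays no role in module membership).
#'
#' @param x a \code{netprop} fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.netprop <- function(x, ...) {
  z <- x$scores$z[!x$scores$is_seed]
  z <- z[is.finite(z)]
  graphics::hist(z, breaks = 50, main = "Proximity z-scores (non-seed genes)",
                 xlab = "z", ...)
  graphics::abline(v = x$z_threshold, col = "red3", lty = 2)
  invisible(x)
}

#' @export
as.data.frame.netprop <- function(x, ...) x$scores
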