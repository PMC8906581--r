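# One-call pipeline driver: load -> propagate -> localize -> cluster ->
# enrich -> cell types, with a reproducible run manifest.

default_config <- function() {
  list(score_threshold = 0.7,
       alpha = 0.5,
       z_threshold = 2,
       p_cut = 0.05,
       beta_cut = 0.5,
       fdr_cut = 0.2,
       min_cluster_size = 10L,
       min_bin_size = 10L,
       n_null = 5000L,
       n_loc_null = 5000L,
       n_subsamples = 5000L,
       rng_seed_propagation = 1L,
       rng_seed_localization = 2L,
       rng_seed_clustering = 3L)
}

#' Run the full disease-module pipeline from a configuration
#'
#' Stages: load and threshold the interactome, restrict to its largest
#' component, expand the seed genes into a disease module by propagation
#' ([netprop()]), test network localization of the seeds, cluster the module
#' ([louvain_cluster()]), score clusters for transcriptomic dysregulation
#' (when a DE table is configured) and for cell-type expression (when an
#' FPKM matrix is configured), annotate module genes against supplied gene
#' lists, and write all tables plus a manifest with input checksums. Rerunning
#' with the same configuration reproduces identical tables.
#'
#' @param config path to a YAML file or a named list. Required fields:
#'   \code{edges}, \code{seeds}, \code{out_dir}. Optional inputs: \code{de}
#'   (DE table), \code{fpkm} (cell-type matrix), \code{gene_lists} (GMT used
#'   for Fisher annotation enrichment of the module). Parameters (defaults in
#'   parentheses): \code{score_threshold} (0.7), \code{alpha} (0.5),
#'   \code{z_threshold} (2), \code{p_cut} (0.05), \code{beta_cut} (0.5),
#'   \code{fdr_cut} (0.2), \code{min_cluster_size} (10), \code{min_bin_size}
#'   (10), \code{n_null} (5000), \code{n_loc_null} (5000),
#'   \code{n_subsamples} (5000), and per-stage seeds
#'   \code{rng_seed_propagation}, \code{rng_seed_localization},
#'   \code{rng_seed_clustering}.
#' @return object of class \code{run_report}: list of output \code{paths},
#'   the \code{fit}, \code{localization}, \code{partition}, optional
#'   \code{dysregulation} / \code{celltype_means} / \code{set_enrichment},
#'   and the \code{manifest}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (req in c("edges", "seeds", "out_dir")) {
    if (is.null(config[[req]])) stop("config field missing: ", req, call. = FALSE)
  }
  cfg <- utils::modifyList(default_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # --- load ---------------------------------------------------------------
  graph <- load_interactome(cfg$edges, cfg$score_threshold)
  graph <- largest_component(graph)
  dropped_nodes <- attr(graph, "dropped")
  seeds_all <- read_seed_list(cfg$seeds)
  seeds <- intersect(seeds_all, node_names(graph))
  if (length(seeds) == 0L) stop("no seed genes in the network", call. = FALSE)

  # --- propagation --------------------------------------------------------
  fit <- netprop(graph, seeds, alpha = cfg$alpha, n_null = cfg$n_null,
                 z_threshold = cfg$z_threshold,
                 min_bin_size = cfg$min_bin_size,
                 rng_seed = cfg$rng_seed_propagation)
  paths$module <- file.path(cfg$out_dir, "module.tsv")
  utils::write.table(fit$scores, paths$module, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- localization -------------------------------------------------------
  loc <- localization_test(graph, seeds, bins = fit$bins,
                           n_samples = cfg$n_loc_null,
                           n_subsamples = cfg$n_subsamples,
                           rng_seed = cfg$rng_seed_localization)
  paths$localization <- file.path(cfg$out_dir, "localization.json")
  jsonlite::write_json(list(set_size = loc$set_size,
                            observed_edges = loc$observed,
                            null_mean = loc$null_mean,
                            null_sd = loc$null_sd,
                            z = loc$z,
                            p_empirical = loc$p_empirical,
                            p_normal_approximate = loc$p_normal,
                            subsample_size = loc$subsample_size,
                            subsample_observed_median =
                              stats::median(loc$subsample_observed),
                            subsample_null_median =
                              stats::median(loc$subsample_null)),
                       paths$localization, auto_unbox = TRUE, digits = NA)

  # --- clustering ---------------------------------------------------------
  part <- louvain_cluster(module_subgraph(graph, fit$module),
                          rng_seed = cfg$rng_seed_clustering,
                          min_report_size = cfg$min_cluster_size)
  paths$clusters_tsv <- file.path(cfg$out_dir, "clusters.tsv")
  utils::write.table(as.data.frame(part), paths$clusters_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$clusters_gmt <- file.path(cfg$out_dir, "clusters.gmt")
  gmt <- part$clusters
  names(gmt) <- sprintf("cluster_%s", names(gmt))
  attr(gmt, "descriptions") <- stats::setNames(
    sprintf("size_class=%s", part$size_class), names(gmt))
  write_gmt(gmt, paths$clusters_gmt)

  # --- transcriptomic dysregulation ---------------------------------------
  dys <- NULL
  if (!is.null(cfg$de) && file.exists(cfg$de)) {
    de <- read_de_table(cfg$de)
    background <- intersect(node_names(graph), de$gene)
    dys <- cluster_dysregulation(part, de, background,
                                 min_size = cfg$min_cluster_size,
                                 p_cut = cfg$p_cut, beta_cut = cfg$beta_cut)
    paths$dysregulation <- file.path(cfg$out_dir, "dysregulation.tsv")
    utils::write.table(dys, paths$dysregulation, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (!is.null(cfg$de)) {
    warning("DE table not found (", cfg$de, "); dysregulation stage skipped")
  } else {
    message("no DE table configured; dysregulation stage skipped")
  }

  # --- cell-type expression -----------------------------------------------
  ct <- NULL
  if (!is.null(cfg$fpkm) && file.exists(cfg$fpkm)) {
    expr <- read_fpkm_matrix(cfg$fpkm)
    ct <- suppressMessages(cluster_celltype_profile(part, expr))
    paths$celltype_means <- file.path(cfg$out_dir, "celltype_means.tsv")
    utils::write.table(data.frame(cluster = rownames(ct), ct,
                                  check.names = FALSE),
                       paths$celltype_means, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (!is.null(cfg$fpkm)) {
    warning("FPKM matrix not found (", cfg$fpkm, "); cell-type stage skipped")
  }

  # --- gene-list annotation enrichment ------------------------------------
  enr <- NULL
  if (!is.null(cfg$gene_lists) && file.exists(cfg$gene_lists)) {
    sets <- read_gmt(cfg$gene_lists)
    bg <- node_names(graph)
    module_genes <- fit$module$module
    enr <- do.call(rbind, lapply(names(sets), function(nm) {
      members <- intersect(sets[[nm]], bg)
      tab <- matrix(c(length(intersect(module_genes, members)),
                      length(setdiff(module_genes, members)),
                      length(setdiff(members, module_genes)),
                      length(bg) - length(union(module_genes, members))),
                    2L, 2L, byrow = TRUE)
      ft <- fisher_exact(tab)
      data.frame(set = nm, k = tab[1, 1], module_size = length(module_genes),
                 set_size_in_network = length(members),
                 odds_ratio = ft$odds_ratio, p = ft$p,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(enr)) enr$q <- bh_fdr(enr$p)
    paths$set_enrichment <- file.path(cfg$out_dir, "set_enrichment.tsv")
    utils::write.table(enr, paths$set_enrichment, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # --- manifest -----------------------------------------------------------
  inputs <- Filter(function(p) is.character(p) && file.exists(p),
                   cfg[c("edges", "seeds", "de", "fpkm", "gene_lists")])
  manifest <- list(
    package = "netmodule",
    package_version = as.character(utils::packageVersion("netmodule")),
    r_version = as.character(getRversion()),
    config = cfg,
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    network = list(n_genes = igraph::vcount(graph),
                   n_edges = igraph::ecount(graph),
                   dropped_outside_largest_component = length(dropped_nodes)),
    seeds = list(n_listed = length(seeds_all), n_in_network = length(seeds)),
    module_size = length(fit$module$module),
    output_md5 = as.list(tools::md5sum(unlist(paths))))
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  structure(list(paths = paths, fit = fit, localization = loc,
                 partition = part, dysregulation = dys,
                 celltype_means = ct, set_enrichment = enr,
                 manifest = manifest),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run complete\n")
  cat(sprintf("  module: %d genes; clusters: %d (Q = %.3f)\n",
              length(x$fit$module$module), length(x$partition$clusters),
              x$partition$modularity))
  cat(sprintf("  localization z = %.2f (empirical p = %.3g)\n",
              x$localization$z, x$localization$p_empirical))
  if (!is.null(x$dysregulation)) {
    cat(sprintf("  dysregulated clusters (q < %g): %d of %d tested\n",
                x$manifest$config$fdr_cut,
                sum(x$dysregulation$q < x$manifest$config$fdr_cut),
                nrow(x$dysregulation)))
  }
  cat("  outputs:", paste(basename(unlist(x$paths)), collapse = ", "), "\n")
  invisible(x)
}

#' Flag module genes against user-supplied gene lists
#'
#' Adds one logical column per gene set: is the module gene a member? Genes
#' appearing in the lists but not in the module are ignored (their count is
#' reported in a message).
#'
#' @param module a \code{disease_module} or character vector of genes.
#' @param lists named list of character vectors (e.g. from [read_gmt()]).
#' @return data frame with column \code{gene} plus one logical column per
#'   list.
#' @export
annotate_module <- function(module, lists) {
  genes <- if (inherits(module, "disease_module")) module$module
           else unique(as.character(module))
  stopifnot(is.list(lists))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  unknown <- 0L
  for (nm in names(lists)) {
    out[[nm]] <- genes %in% lists[[nm]]
    unknown <- unknown + length(setdiff(lists[[nm]], genes))
  }
  if (unknown > 0L) {
    message(sprintf("annotate_module: %d list gene(s) not in the module", unknown))
  }
  out
}
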