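#' Load a scored interaction network from an edge table
#'
#' Reads a STRING-style edge list (tab- or space-separated columns:
#' \code{protein1}, \code{protein2}, \code{combined_score}; header optional)
#' and keeps the edges whose confidence score strictly exceeds
#' \code{score_threshold}. Scores on the STRING 0--1000 integer scale are
#' rescaled to \code{[0, 1]}. Self-loops are dropped and reversed duplicate
#' rows are collapsed to a single undirected edge keeping the larger score.
#'
#' @param path path to the edge table.
#' @param score_threshold confidence cutoff in \code{[0, 1]}; an edge survives
#'   only if its rescaled score is strictly greater than this value. The
#'   default 0.7 keeps the conventional "high confidence" tier.
#' @param score_scale \code{"auto"} (rescale by 1/1000 when any score exceeds
#'   1), \code{"unit"} (scores already in \code{[0, 1]}) or \code{"thousand"}.
#' @return an undirected \pkg{igraph} graph whose vertices are the endpoints of
#'   the surviving edges, with edge attribute \code{score} in \code{(0, 1]}.
#' @export
load_interactome <- function(path, score_threshold = 0.7,
                             score_scale = c("auto", "unit", "thousand")) {
  score_scale <- match.arg(score_scale)
  check_fraction(score_threshold, "score_threshold")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  nf <- utils::count.fields(path, sep = "", comment.char = "#", quote = "")
  if (length(nf) == 0L || all(is.na(nf))) {
    stop("empty edge table: ", path, call. = FALSE)
  }
  bad <- which(!is.na(nf) & nf < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row (fewer than 3 columns) at line %d of %s",
                 bad[1L], path), call. = FALSE)
  }

  first <- scan(path, what = character(), nlines = 1L, quiet = TRUE,
                comment.char = "#")
  has_header <- is.na(suppressWarnings(as.numeric(first[3L])))
  df <- utils::read.table(path, header = has_header, sep = "",
                          comment.char = "#", quote = "",
                          colClasses = c("character", "character", "character"),
                          col.names = c("protein1", "protein2", "combined_score"))
  if (nrow(df) == 0L) stop("empty edge table: ", path, call. = FALSE)

  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score)) {
    line <- which(is.na(score))[1L] + as.integer(has_header)
    stop(sprintf("malformed row (non-numeric score) at line %d of %s",
                 line, path), call. = FALSE)
  }
  if (score_scale == "thousand" || (score_scale == "auto" && any(score > 1))) {
    score <- score / 1000
  }
  if (any(score < 0 | score > 1)) {
    stop("scores outside [0, 1] after rescaling; check `score_scale`",
         call. = FALSE)
  }

  keep <- df$protein1 != df$protein2
  a <- pmin(df$protein1, df$protein2)[keep]
  b <- pmax(df$protein1, df$protein2)[keep]
  score <- score[keep]
  if (length(a) > 0L) {
    key <- paste(a, b, sep = "\r")
    score <- tapply(score, key, max)
    ab <- strsplit(names(score), "\r", fixed = TRUE)
    a <- vapply(ab, `[`, "", 1L)
    b <- vapply(ab, `[`, "", 2L)
    score <- unname(score)
  }

  keep <- score > score_threshold
  if (!any(keep)) {
    stop(sprintf("no edges survive the score threshold %g in %s",
                 score_threshold, path), call. = FALSE)
  }
  edges <- data.frame(from = a[keep], to = b[keep], score = score[keep],
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Write a scored network back to the STRING edge-table dialect
#'
#' @param graph an undirected igraph graph with a \code{score} edge attribute.
#' @param path output path; a tab-separated table with header
#'   \code{protein1}, \code{protein2}, \code{combined_score} is written.
#' @return \code{path}, invisibly.
#' @export
write_interactome <- function(graph, path) {
  check_graph(graph)
  el <- igraph::as_edgelist(graph)
  df <- data.frame(protein1 = el[, 1L], protein2 = el[, 2L],
                   combined_score = format(igraph::E(graph)$score, digits = 15L),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a network to its largest connected component
#'
#' Diffusion scores of nodes unreachable from every possible seed placement
#' are identically zero, which breaks the log-scale null comparison; the
#' analysis therefore runs on the largest component.
#'
#' @param graph an igraph graph.
#' @return the induced subgraph on the largest component, with attribute
#'   \code{dropped} listing the removed vertex names.
#' @export
largest_component <- function(graph) {
  check_graph(graph)
  comp <- igraph::components(graph)
  keep <- which(comp$membership == which.max(comp$csize))
  out <- igraph::induced_subgraph(graph, keep)
  attr(out, "dropped") <- setdiff(node_names(graph), node_names(out))
  out
}

#' Symmetric degree-normalized adjacency operator
#'
#' Builds the operator \eqn{W' = D^{-1/2} A D^{-1/2}} on the binary adjacency
#' \eqn{A} of the thresholded graph (edge scores are used for thresholding
#' only, not as weights). Its spectral radius is at most 1, which guarantees
#' convergence of the heat propagation for any dissipation \eqn{\alpha < 1}.
#' Rows and columns of isolated vertices are zero.
#'
#' @param graph an igraph graph with named vertices.
#' @return a sparse symmetric matrix with dimnames equal to the vertex names.
#' @export
normalize_adjacency <- function(graph) {
  check_graph(graph)
  if (igraph::vcount(graph) == 0L) stop("graph has no vertices", call. = FALSE)
  A <- igraph::as_adjacency_matrix(graph, type = "both", sparse = TRUE)
  A@x[] <- 1
  d <- igraph::degree(graph)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  W <- Matrix::Diagonal(x = s) %*% A %*% Matrix::Diagonal(x = s)
  dimnames(W) <- list(node_names(graph), node_names(graph))
  methods::as(W, "generalMatrix")
}

#' Partition nodes into degree bins for degree-matched sampling
#'
#' Nodes are sorted by (degree, name) and filled greedily: a bin closes once
#' it holds at least \code{min_bin_size} nodes \emph{and} the next node has a
#' different degree, so a single degree value is never split across bins. A
#' trailing bin smaller than \code{min_bin_size} is merged into its
#' predecessor; a graph with fewer than \code{min_bin_size} nodes yields one
#' bin.
#'
#' @param graph an igraph graph with named vertices.
#' @param min_bin_size minimum nodes per bin (default 10).
#' @return an object of class \code{degree_bins}: a list with \code{bins}
#'   (list of character vectors), \code{bin_of} (named integer vector) and
#'   \code{degree} (named degrees).
#' @export
assign_degree_bins <- function(graph, min_bin_size = 10L) {
  check_graph(graph)
  bin_degrees(igraph::degree(graph), min_bin_size)
}

# greedy binning of a named degree vector; the rule never splits a degree
# value across bins
bin_degrees <- function(d, min_bin_size = 10L) {
  if (!is.numeric(min_bin_size) || min_bin_size < 1) {
    stop("`min_bin_size` must be >= 1", call. = FALSE)
  }
  ord <- order(d, names(d), method = "radix")
  d <- d[ord]
  n <- length(d)

  bin_id <- integer(n)
  cur <- 1L
  count <- 0L
  for (i in seq_len(n)) {
    if (count >= min_bin_size && d[i] != d[i - 1L]) {
      cur <- cur + 1L
      count <- 0L
    }
    bin_id[i] <- cur
    count <- count + 1L
  }
  # merge an undersized trailing bin into its predecessor
  if (cur > 1L && sum(bin_id == cur) < min_bin_size) {
    bin_id[bin_id == cur] <- cur - 1L
    bin_id <- match(bin_id, sort(unique(bin_id)))
  }
  names(bin_id) <- names(d)
  bins <- split(names(d), bin_id)
  names(bins) <- seq_along(bins)
  structure(list(bins = bins,
                 bin_of = stats::setNames(bin_id, names(d)),
                 degree = d),
            class = "degree_bins")
}

#' @export
print.degree_bins <- function(x, ...) {
  sizes <- lengths(x$bins)
  cat(sprintf("degree bins: %d bins over %d nodes (sizes %s)\n",
              length(x$bins), length(x$bin_of),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Read a seed gene list
#'
#' One gene identifier per line; blank lines and \code{#} comments ignored;
#' duplicates removed.
#'
#' @param path path to the list file.
#' @return character vector of gene ids.
#' @export
read_seed_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Read a differential-expression table
#'
#' @param path tab-separated table with one row per gene.
#' @param gene_col,beta_col,p_col column names for the gene id, the effect
#'   size (log-scale beta statistic) and the multiplicity-adjusted p-value.
#' @return data frame with columns \code{gene}, \code{beta}, \code{adj_p}.
#' @export
read_de_table <- function(path, gene_col = "gene", beta_col = "beta",
                          p_col = "adj_p") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c(gene_col, beta_col, p_col), names(df))
  if (length(missing) > 0L) {
    stop("missing column(s) in DE table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(gene = as.character(df[[gene_col]]),
                    beta = as.numeric(df[[beta_col]]),
                    adj_p = as.numeric(df[[p_col]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) {
    stop("duplicate gene ids in DE table", call. = FALSE)
  }
  if (any(is.na(out$adj_p)) || any(out$adj_p < 0 | out$adj_p > 1)) {
    stop("adjusted p-values must lie in [0, 1]", call. = FALSE)
  }
  out
}

#' Read / write gene-set collections in GMT format
#'
#' GMT records are tab-separated: set name, description, then member genes.
#'
#' @param path file path.
#' @return \code{read_gmt}: a named list of character vectors with a
#'   \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT record without members at line %d", short[1L]),
         call. = FALSE)
  }
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[`, "", 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors; an optional
#'   \code{descriptions} attribute is written into the second column.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-by-cell-type FPKM matrix
#'
#' @param path tab-separated table, first column gene ids, remaining columns
#'   one per cell type; values are FPKM and must be nonnegative.
#' @return numeric matrix with gene rownames.
#' @export
read_fpkm_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("FPKM matrix must be numeric", call. = FALSE)
  if (any(m < 0, na.rm = TRUE)) stop("FPKM values must be nonnegative", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("cell-type names must be unique", call. = FALSE)
  m
}
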