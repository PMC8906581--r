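# internal helpers shared across modules

# Evaluate `expr` under a reproducible RNG state without disturbing the
# caller's stream; a NULL seed leaves the current stream untouched.
with_rng <- function(rng_seed, expr) {
  if (is.null(rng_seed)) return(expr)
  stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(rng_seed))
  expr
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (if (open_lo) x <= lo else x < lo) ||
      (if (open_hi) x >= hi else x > hi)) {
    stop(sprintf("`%s` must be a number in %s%g, %g%s",
                 name, if (open_lo) "(" else "[", lo, hi,
                 if (open_hi) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

check_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("`graph` must be an igraph object", call. = FALSE)
  if (is.null(igraph::V(graph)$name)) stop("graph vertices must be named", call. = FALSE)
  invisible(graph)
}

node_names <- function(graph) igraph::V(graph)$name
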