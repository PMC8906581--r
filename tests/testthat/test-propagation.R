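test_that("fixed-point propagation equals the direct linear solve", {
  # 3-node path, seed at one end: frozen values from (I - aW')^-1 (1-a)Y
  g <- named_graph(rbind(c("a", "b"), c("b", "c")))
  W <- normalize_adjacency(g)
  f <- propagate(W, "a", alpha = 0.5)
  expect_equal(unname(f[c("a", "b", "c")]),
               c(7 / 12, 1 / (3 * sqrt(2)), 1 / 12), tolerance = 1e-7)

  direct <- solve(diag(3) - 0.5 * as.matrix(W), 0.5 * c(1, 0, 0))
  expect_equal(unname(f), as.vector(direct), tolerance = 1e-8,
               ignore_attr = TRUE)

  # random instances against the solver oracle
  withr::with_seed(3, {
    for (i in 1:5) {
      g <- random_named_graph(sample(10:60, 1), 0.15)
      W <- normalize_adjacency(g)
      seeds <- sample(igraph::V(g)$name, 4)
      f <- propagate(W, seeds, alpha = 0.5, tol = 1e-10)
      y <- as.numeric(rownames(W) %in% seeds) / 4
      direct <- solve(diag(nrow(W)) - 0.5 * as.matrix(W), 0.5 * y)
      expect_lt(max(abs(f - direct)), 1e-8)
    }
  })
})

test_that("propagation respects symmetry and validates arguments", {
  star <- named_graph(cbind("hub", paste0("leaf", 1:6)))
  W <- normalize_adjacency(star)
  f <- propagate(W, "hub")
  expect_equal(length(unique(round(f[paste0("leaf", 1:6)], 12))), 1L)
  expect_gt(f[["hub"]], f[["leaf1"]])

  expect_error(propagate(W, "hub", alpha = 0), "alpha")
  expect_error(propagate(W, "hub", alpha = 1), "alpha")
  expect_error(propagate(W, "nope"), "absent")
  expect_error(propagate(W, character(0)), "empty")
  expect_error(propagate(W, "hub", alpha = 0.99, max_iter = 2L),
               "did not converge")
})

test_that("adding a seed-to-node edge never decreases that node's score", {
  withr::with_seed(21, {
    for (i in 1:8) {
      g <- random_named_graph(25, 0.12)
      nodes <- igraph::V(g)$name
      seed <- nodes[1]
      v <- nodes[25]
      if (igraph::are_adjacent(g, seed, v)) next
      f0 <- propagate(normalize_adjacency(g), seed)[[v]]
      g2 <- igraph::add_edges(g, c(seed, v))
      f1 <- propagate(normalize_adjacency(g2), seed)[[v]]
      expect_gte(f1, f0)
    }
  })
})

test_that("relabeling nodes permutes propagation output consistently", {
  withr::with_seed(5, {
    g <- random_named_graph(20, 0.2)
    seeds <- igraph::V(g)$name[1:3]
    f <- propagate(normalize_adjacency(g), seeds)
    perm <- setNames(sprintf("m%03d", sample(20)), igraph::V(g)$name)
    g2 <- g
    igraph::V(g2)$name <- unname(perm[igraph::V(g)$name])
    f2 <- propagate(normalize_adjacency(g2), unname(perm[seeds]))
    expect_equal(unname(f2[unname(perm[names(f)])]), unname(f),
                 tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("null ensembles are degree-matched, sized and reproducible", {
  withr::with_seed(13, {
    sim <- generate_network(n_nodes = 100, n_communities = 4, p_in = 0.3,
                            p_out = 0.03, rng_seed = 8)
    g <- largest_component(sim$graph)
    W <- normalize_adjacency(g)
    bins <- assign_degree_bins(g)
    seeds <- sample(igraph::V(g)$name, 8)

    ens <- sample_null_ensemble(W, seeds, bins, n_samples = 200,
                                rng_seed = 17)
    expect_equal(dim(ens$seed_sets), c(8L, 200L))
    # every sampled member shares the bin of the seed it replaces, and
    # members are unique within a replicate
    for (j in sample(200, 20)) {
      s <- ens$seed_sets[, j]
      expect_false(anyDuplicated(s) > 0)
      expect_equal(unname(bins$bin_of[s]), unname(bins$bin_of[seeds]))
    }
    ens2 <- sample_null_ensemble(W, seeds, bins, n_samples = 200,
                                 rng_seed = 17)
    expect_identical(ens$seed_sets, ens2$seed_sets)
    expect_equal(ens$scores, ens2$scores)
  })
})

test_that("a seed alone in its bin is always resampled as itself", {
  # path graph: ends have degree 1, middle degree 2; min_bin_size 1 gives
  # a singleton bin for the middle node
  g <- named_graph(rbind(c("a", "b"), c("b", "c")))
  bins <- assign_degree_bins(g, min_bin_size = 1)
  W <- normalize_adjacency(g)
  ens <- sample_null_ensemble(W, "b", bins, n_samples = 20, rng_seed = 1)
  expect_true(all(ens$seed_sets == "b"))
  expect_equal(apply(ens$scores, 1, stats::sd), c(a = 0, b = 0, c = 0))
})

test_that("proximity z-scores follow the log-space formula and flag zeros", {
  mk_ens <- function(scores) {
    structure(list(scores = scores,
                   seed_sets = matrix("x", 1, ncol(scores)),
                   alpha = 0.5, n_samples = ncol(scores)),
              class = "null_ensemble")
  }
  obs <- setNames(exp(4), "g1")
  ens <- mk_ens(matrix(exp(c(0, 2)), 1, 2, dimnames = list("g1", NULL)))
  z <- proximity_zscores(obs, ens)
  expect_equal(z$z, (4 - 1) / sqrt(2), tolerance = 1e-12)

  # observed equal to the null mean gives z = 0
  obs0 <- setNames(exp(1), "g1")
  expect_equal(proximity_zscores(obs0, ens)$z, 0, tolerance = 1e-12)

  # zero scores and zero sd are flagged undefined
  obs2 <- setNames(c(exp(1), 0), c("g1", "g2"))
  sc <- matrix(c(exp(0), exp(2), 0.5, 0.5), 2, 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), NULL))
  z2 <- proximity_zscores(obs2, mk_ens(sc))
  expect_true(is.na(z2$z[2]))   # zero observed
  expect_true(is.na(proximity_zscores(setNames(c(1, 1), c("g1", "g2")),
                                      mk_ens(sc))$z[2]))  # zero null sd
  expect_error(proximity_zscores(obs, mk_ens(sc[1, 1, drop = FALSE])),
               "2 null replicates")
})

test_that("module assembly keeps seeds and strictly-above-threshold genes", {
  z <- structure(data.frame(gene = c("s1", "a", "b", "c"),
                            score = c(1, 1, 1, 0),
                            null_mean_log = 0, null_sd_log = 1,
                            z = c(-1, 2.5, 2, NA)),
                 class = c("proximity_result", "data.frame"))
  mod <- build_module(z, "s1", z_threshold = 2)
  expect_equal(mod$proximal, "a")          # z = 2 is excluded (strict)
  expect_setequal(mod$module, c("s1", "a"))
  expect_equal(mod$undefined, "c")

  z$z <- c(10, 10, 10, 10)
  expect_setequal(build_module(z, "s1")$module, c("s1", "a", "b", "c"))
  z$z <- c(-1, -1, -1, -1)
  expect_equal(build_module(z, "s1")$module, "s1")
})

test_that("netprop fits are internally consistent and reproducible", {
  sim <- generate_network(n_nodes = 120, n_communities = 4, p_in = 0.3,
                          p_out = 0.02, rng_seed = 1)
  seeds <- generate_seeds(sim$truth, n_seeds = 12, rng_seed = 2)
  fit <- netprop(sim$graph, seeds, n_null = 60, rng_seed = 3)
  expect_s3_class(fit, "netprop")
  sc <- fit$scores
  expect_setequal(sc$gene[sc$is_seed], seeds)
  expect_setequal(sc$gene[sc$in_module], fit$module$module)
  expect_true(all(sc$z[!sc$is_seed & sc$in_module] > 2, na.rm = TRUE))
  expect_equal(coef(fit), setNames(sc$z, sc$gene))

  fit2 <- netprop(sim$graph, seeds, n_null = 60, rng_seed = 3)
  expect_equal(fit$scores, fit2$scores)

  s <- summary(fit)
  expect_equal(s$n_module, length(fit$module$module))
  expect_output(print(s), "disease module|module")

  expect_message(netprop(sim$graph, c(seeds, "ghost"), n_null = 10,
                         rng_seed = 1), "dropped")
})
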