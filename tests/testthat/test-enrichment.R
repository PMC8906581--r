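test_that("DE thresholding uses strict inequalities in both dimensions", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   beta = c(0.6, 0.5, 3.0, -0.7),
                   adj_p = c(0.01, 0.01, 0.06, 0.01))
  sets <- de_gene_sets(de)
  expect_equal(sets$up, "a")         # b at the beta boundary, c above p cut
  expect_equal(sets$down, "d")
  expect_setequal(sets$all, c("a", "d"))
  expect_error(de_gene_sets(de[, 1:2]), "adj_p")
})

test_that("hypergeometric overlap matches enumeration over all draws", {
  bg <- sprintf("g%02d", 1:10)
  rec <- hypergeometric_overlap(bg[1:4], bg[1:5], bg)
  expect_equal(rec$k, 4)
  expect_equal(rec$p, 5 / 210, tolerance = 1e-12)
  expect_equal(rec$p, hyper_oracle(4, 5, 4, 10), tolerance = 1e-12)

  # no overlap: upper tail at 0 is 1
  expect_equal(hypergeometric_overlap(bg[1:3], bg[8:10], bg)$p, 1)
  # annotation equals the background: k = n and p = 1
  rec2 <- hypergeometric_overlap(bg[1:4], bg, bg)
  expect_equal(rec2$k, 4)
  expect_equal(rec2$p, 1)
  expect_error(hypergeometric_overlap("x", "y", character(0)), "background")
  expect_error(hypergeometric_overlap("zz", bg[1], bg), "subsets")
})

test_that("Fisher exact p and sample odds ratio match enumeration", {
  even <- fisher_exact(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$odds_ratio, 1)
  expect_equal(even$p, 1)

  diag_ <- fisher_exact(matrix(c(5, 0, 0, 5), 2))
  expect_true(is.infinite(diag_$odds_ratio))
  expect_equal(diag_$p, 2 / 252, tolerance = 1e-12)
  expect_equal(diag_$p, fisher_oracle(matrix(c(5, 0, 0, 5), 2)),
               tolerance = 1e-12)

  zero_margin <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(zero_margin$p, 1)
  expect_true(is.na(zero_margin$odds_ratio))

  withr::with_seed(55, {
    for (i in 1:20) {
      tab <- matrix(rpois(4, 4), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab)$p, fisher_oracle(tab),
                   tolerance = 1e-12)
    }
  })
})

test_that("one-sided hypergeometric equals one-sided Fisher on the same 2x2", {
  withr::with_seed(66, {
    for (i in 1:10) {
      N <- sample(20:60, 1); K <- sample(3:10, 1); n <- sample(3:10, 1)
      bg <- sprintf("g%03d", 1:N)
      set_b <- bg[1:K]
      set_a <- sample(bg, n)
      rec <- hypergeometric_overlap(set_a, set_b, bg)
      tab <- matrix(c(rec$k, rec$K - rec$k,
                      rec$n - rec$k, rec$N_bg - rec$K - rec$n + rec$k), 2)
      expect_equal(rec$p, stats::fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("BH adjustment reproduces the step-up rule and is order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::with_seed(77, {
    p <- runif(20)
    q <- bh_fdr(p)
    expect_true(all(q >= p) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= 0))  # ranking preserved
    perm <- sample(20)
    expect_equal(bh_fdr(p[perm]), q[perm])
  })
})

test_that("cluster dysregulation calls match closed-form tails and tag direction", {
  bg <- sprintf("g%03d", 1:100)
  de <- data.frame(gene = bg,
                   beta = c(rep(2, 20), rep(0, 80)),
                   adj_p = c(rep(0.001, 20), rep(0.9, 80)))
  # one testable cluster: 10 genes of which 8 DE
  part <- make_partition(list(c(bg[1:8], bg[95:96]), bg[97:99]))
  calls <- cluster_dysregulation(part, de, bg, min_size = 10)
  expect_equal(nrow(calls), 1L)
  k <- 8:10
  p_expected <- sum(exp(lchoose(20, k) + lchoose(80, 10 - k) - lchoose(100, 10)))
  expect_equal(calls$p, p_expected, tolerance = 1e-12)
  expect_equal(calls$q, calls$p)    # single tested cluster
  expect_equal(calls$direction, "up")
  expect_equal(calls$n_de, 8L)

  # predominantly down-regulated cluster
  de2 <- de
  de2$beta[1:8] <- c(-2, -2, -2, -2, -2, -2, -2, 2)
  calls2 <- cluster_dysregulation(part, de2, bg, min_size = 10)
  expect_equal(calls2$direction, "down")
  expect_equal(calls2$n_down, 7L)
  expect_equal(calls2$n_up, 1L)

  # cluster without DE genes: large p, mixed direction
  part3 <- make_partition(list(bg[81:95]))
  calls3 <- cluster_dysregulation(part3, de, bg, min_size = 10)
  expect_gte(calls3$p, 0.5)
  expect_equal(calls3$direction, "mixed")

  # genes outside the background are dropped with a message
  part4 <- make_partition(list(c(bg[1:10], "ghost1", "ghost2")))
  expect_message(cluster_dysregulation(part4, de, bg, min_size = 10),
                 "2 cluster gene")
})

test_that("K-S two-sample statistic and p match enumeration", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  sep <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$D, 1)
  expect_equal(sep$p, 0.1, tolerance = 1e-12)
  expect_equal(sep$p, ks_oracle(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)

  withr::with_seed(88, {
    for (i in 1:10) {
      x <- round(runif(sample(3:6, 1)), 2)
      y <- round(runif(sample(3:6, 1)), 2)
      if (length(intersect(x, y)) > 0) next  # tie-free enumeration check here
      res <- ks_two_sample(x, y)
      expect_equal(res$D, ks_stat(x, y), tolerance = 1e-12)
      expect_equal(res$p, ks_oracle(x, y), tolerance = 1e-12)
    }
  })
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("random-cluster null is reproducible and validates n_reps", {
  sim <- generate_network(n_nodes = 150, n_communities = 5, p_in = 0.35,
                          p_out = 0.02, rng_seed = 3)
  g <- largest_component(sim$graph)
  seeds <- intersect(generate_seeds(sim$truth, n_seeds = 15, rng_seed = 4),
                     igraph::V(g)$name)
  de <- generate_de_table(sim$truth, rng_seed = 5)
  bg <- intersect(igraph::V(g)$name, de$gene)

  expect_error(random_cluster_null(g, seeds, de, bg, n_reps = 0), "n_reps")

  r1 <- random_cluster_null(g, seeds, de, bg, n_reps = 3, n_null = 30,
                            rng_seed = 9)
  r2 <- random_cluster_null(g, seeds, de, bg, n_reps = 3, n_null = 30,
                            rng_seed = 9)
  expect_identical(r1$n_pass, r2$n_pass)
  expect_equal(length(r1$n_pass), 3L)
})

test_that("null DE tables rarely produce dysregulated clusters", {
  # FDR sanity: with no planted signal the q < 0.2 call rate stays low
  withr::with_seed(101, {
    sim <- generate_network(n_nodes = 200, n_communities = 5, p_in = 0.3,
                            p_out = 0.02, rng_seed = 12)
    part <- louvain_cluster(sim$graph, rng_seed = 13)
    bg <- names(sim$truth$membership)
    hits <- 0L; total <- 0L
    for (i in 1:30) {
      de <- generate_de_table(sim$truth, effect_mu = 0, rng_seed = 1000 + i)
      calls <- suppressMessages(cluster_dysregulation(part, de, bg))
      hits <- hits + sum(calls$q < 0.2)
      total <- total + nrow(calls)
    }
    expect_gt(total, 0)
    expect_lte(hits / total, 0.25)
  })
})
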