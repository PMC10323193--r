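test_that("spearman association matches the rank-then-Pearson definition", {
  expect_equal(spearman_assoc(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_assoc(1:5, c(10, 8, 6, 4, 2))$rho, -1)

  # ties: mid-rank hand computation
  x <- c(1, 2, 3, 3, 5)
  y <- c(2, 1, 4, 4, 5)
  rx <- c(1, 2, 3.5, 3.5, 5)
  ry <- c(2, 1, 3.5, 3.5, 5)
  hand_rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res <- spearman_assoc(x, y)
  expect_equal(res$rho, hand_rho, tolerance = 1e-12)

  # t-approximation p agrees with the standard implementation
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(12)
    b <- 0.5 * a + rnorm(12)
    ours <- spearman_assoc(a, b)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman",
                                     exact = FALSE))
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }

  # degenerate input
  d <- spearman_assoc(rep(1, 6), rnorm(6))
  expect_equal(d$rho, 0)
  expect_equal(d$p, 1)
  expect_true(d$degenerate)
})

test_that("crossboruta recovers a planted pair and isolates noise", {
  ok <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    g1 <- rnorm(40)
    vals <- cbind(g1 = g1, g2 = g1 + rnorm(40, sd = 0.2), g3 = rnorm(40))
    net <- crossboruta(vals, boruta_config(rng_seed = seed))
    keys <- paste(net$edges$gene_a, net$edges$gene_b)
    deg3 <- sum(net$edges$gene_a == "g3" | net$edges$gene_b == "g3")
    hit <- "g1 g2" %in% keys &&
      net$edges$color[keys == "g1 g2"] == "positive" && deg3 == 0
    if (hit) ok <- ok + 1L
  }
  expect_gte(ok, 4L)

  # duplicated two-gene panel: one positive edge with positive weight
  set.seed(2)
  g1 <- rnorm(30)
  net2 <- crossboruta(cbind(g1 = g1, g2 = g1), boruta_config(rng_seed = 3))
  expect_equal(nrow(net2$edges), 1L)
  expect_gt(net2$edges$raw_weight, 0)
  expect_equal(net2$edges$color, "positive")
})

test_that("edge annotations are reproducible from the expression pool", {
  cfg <- module_recovery_config(master_seed = 5)
  sim <- simulate_study(cfg)
  vals <- ml_matrix(sim, cfg)$values
  net <- crossboruta(vals, boruta_config(rng_seed = 5))
  expect_gt(nrow(net$edges), 0)
  for (i in seq_len(nrow(net$edges))) {
    sp <- spearman_assoc(vals[, net$edges$gene_a[i]],
                         vals[, net$edges$gene_b[i]])
    expect_identical(sp$rho, net$edges$rho[i])
    expect_identical(sp$p, net$edges$rho_p[i])
  }
  # adjacency is symmetric / pairs unique by construction
  keys <- paste(pmin(net$edges$gene_a, net$edges$gene_b),
                pmax(net$edges$gene_a, net$edges$gene_b))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(net$edges$gene_a != net$edges$gene_b))

  # union rule admits a superset of the intersection rule's edges
  net_int <- crossboruta(vals, boruta_config(rng_seed = 5),
                         edge_rule = "intersection")
  keys_int <- paste(pmin(net_int$edges$gene_a, net_int$edges$gene_b),
                    pmax(net_int$edges$gene_a, net_int$edges$gene_b))
  expect_true(all(keys_int %in% keys))
})

test_that("network summaries count colors, homogeneity and isolates", {
  mknet <- function(nodes, rho, p = rep(0.001, length(rho))) {
    pairs <- t(combn(nodes, 2))[seq_along(rho), , drop = FALSE]
    edges <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                        weight = 1, raw_weight = 1, rho = rho, rho_p = p,
                        color = ifelse(p < 0.05 & rho > 0, "positive",
                                       ifelse(p < 0.05 & rho < 0,
                                              "negative", "grey")),
                        stringsAsFactors = FALSE)
    crossboruta:::new_gene_network(nodes, edges, "test", character(0))
  }
  empty <- crossboruta:::new_gene_network(
    paste0("g", 1:5),
    crossboruta:::empty_edge_frame(), "test", character(0))
  s0 <- summarize_network(empty)
  expect_equal(s0$n_edges, 0L)
  expect_equal(length(s0$disconnected_genes), 5L)
  expect_equal(s0$homogeneity, 1)

  s1 <- summarize_network(mknet(paste0("g", 1:4), rep(0.8, 3)))
  expect_equal(s1$n_positive, 3L)
  expect_equal(s1$homogeneity, 1)            # zero spread
  expect_equal(s1$n_positive + s1$n_negative + s1$n_grey, s1$n_edges)

  s2 <- summarize_network(mknet(paste0("g", 1:3), c(0.9, -0.9)))
  expect_equal(s2$n_positive, 1L)
  expect_equal(s2$n_negative, 1L)
  expect_equal(s2$homogeneity, 1 - sd(c(0.9, -0.9)), tolerance = 1e-12)
})

test_that("network contrasts difference counts and list one-sided isolates", {
  cfg <- module_recovery_config(master_seed = 7)
  sim <- simulate_study(cfg)
  vals <- ml_matrix(sim, cfg)$values
  net <- crossboruta(vals, boruta_config(rng_seed = 2))
  self <- compare_networks(net, net)
  expect_equal(self$d_n_positive, 0L)
  expect_equal(self$d_n_negative, 0L)
  expect_equal(self$d_homogeneity, 0)
  expect_equal(self$jaccard, 1)
  expect_length(self$disconnected_only_a, 0)

  other <- net
  other$edges$rho <- -abs(other$edges$rho)
  other$edges$color <- ifelse(other$edges$rho_p < 0.05, "negative", "grey")
  cmp <- compare_networks(net, other)
  sn <- summarize_network(net)
  so <- summarize_network(other)
  expect_equal(cmp$d_n_positive, sn$n_positive - so$n_positive)
  expect_equal(cmp$d_n_negative, sn$n_negative - so$n_negative)
  expect_lt(cmp$d_n_negative, 0)

  bad <- net
  bad$nodes <- c(bad$nodes, "extra_gene")
  expect_error(compare_networks(net, bad), "extra_gene")
})

test_that("arm pools with coherent vs mixed-sign modules separate as expected", {
  # single-seed structural check; the multi-seed version backs the
  # acceptance suite
  cfg <- arm_contrast_config(master_seed = 3)
  sim <- simulate_study(cfg)
  vals <- ml_matrix(sim, cfg)$values
  bcfg <- boruta_config(rng_seed = 3)
  net_t <- crossboruta(vals[sim$ct$group == "treated", ], bcfg,
                       pool_label = "treated")
  net_v <- crossboruta(vals[sim$ct$group == "vehicle", ], bcfg,
                       pool_label = "vehicle")
  cmp <- compare_networks(net_t, net_v)
  expect_gt(cmp$d_homogeneity, 0)
  expect_lt(cmp$d_n_negative, 0)
})

test_that("network export writes edge, node and summary files", {
  set.seed(8)
  g1 <- rnorm(30)
  net <- crossboruta(cbind(a = g1, b = g1 + rnorm(30, sd = 0.2),
                           c = rnorm(30)),
                     boruta_config(rng_seed = 1), pool_label = "demo")
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  edges <- read.delim(paths[1])
  expect_equal(nrow(edges), nrow(net$edges))
  nodes <- read.delim(paths[2])
  expect_setequal(nodes$gene, net$nodes)
  js <- jsonlite::fromJSON(paths[3])
  expect_equal(js$n_edges, nrow(net$edges))
})
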