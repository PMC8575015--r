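test_that("MI estimator: symmetry, self-dependence, signal vs noise", {
  set.seed(1)
  x <- rnorm(200); y <- rnorm(200)
  expect_equal(mutual_information(x, y), mutual_information(y, x),
               tolerance = 1e-9)
  expect_gte(mutual_information(x, y), 0)

  # identical profiles dominate any shuffled pairing
  mi_self <- mutual_information(x, x)
  for (s in 1:5) {
    set.seed(s)
    expect_gte(mi_self, mutual_information(x, sample(x)))
  }

  # linear signal clearly above the independent baseline on shared seeds
  set.seed(7)
  base <- mean(replicate(10, {
    a <- rnorm(200); b <- rnorm(200); mutual_information(a, b)
  }))
  set.seed(7)
  signal <- mean(replicate(10, {
    a <- rnorm(200); b <- 2 * a + rnorm(200, 0, 0.3); mutual_information(a, b)
  }))
  expect_gt(signal, base + 0.2)

  expect_warning(mi0 <- mutual_information(rep(1, 50), rnorm(50)), "constant")
  expect_identical(mi0, 0)
  expect_error(mutual_information(1:5, 1:4), "equal length")
})

test_that("independent profiles have MI indistinguishable from permuted pairings", {
  mi_pairs <- t(sapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(200); y <- rnorm(200)
    c(obs = mutual_information(x, y),
      perm = mutual_information(x, sample(y)))
  }))
  expect_lt(mean(mi_pairs[, "obs"]), 0.05)
  tt <- t.test(mi_pairs[, "obs"], mi_pairs[, "perm"], paired = TRUE)
  expect_gt(tt$p.value, 0.01)
})

test_that("network construction thresholds edges monotonically", {
  sim <- simulate_expression(synthetic_spec(m = 6, n_background = 30, seed = 5))
  panel <- colnames(sim$S)[1:10]
  net_all <- build_network(sim$S, panel, cutoff = -1)
  expect_identical(nrow(net_all$edges), 15L)   # complete graph on 6 nodes
  net_none <- build_network(sim$S, panel, cutoff = Inf)
  expect_identical(nrow(net_none$edges), 0L)
  cuts <- c(0, 0.1, 0.25, 0.5, 1)
  n_edges <- sapply(cuts, function(cc) nrow(build_network(sim$S, panel, cc)$edges))
  expect_true(all(diff(n_edges) <= 0))
  expect_equal(net_all$mi, t(net_all$mi))
  # self-information dominates each row
  expect_true(all(diag(net_all$mi) >= apply(net_all$mi, 1, max) - 1e-9))

  expect_error(build_network(sim$S, c(panel, "nope"), 0.25), "nope")
  expect_warning(build_network(sim$S, panel[1:3], cutoff = Inf), "unstable")
})

test_that("duplicated profiles give the largest off-diagonal MI", {
  sim <- simulate_expression(synthetic_spec(m = 5, n_background = 40, seed = 6))
  S <- sim$S
  S["ct02", ] <- S["ct01", ] * (1 + 1e-6)   # near-exact duplicate
  net <- build_network(S, colnames(S), cutoff = Inf)
  off <- net$mi; diag(off) <- -Inf
  top <- which(off == max(off), arr.ind = TRUE)[1, ]
  expect_setequal(rownames(net$mi)[top], c("ct01", "ct02"))
})

test_that("module detection reproduces hand-computed modularity", {
  # two disconnected triangles: 2 modules, Q = 2 * (1/2 - 1/4) = 0.5
  S <- matrix(1, 6, 10, dimnames = list(paste0("n", 1:6), paste0("g", 1:10)))
  net <- suppressWarnings(build_network(S, colnames(S), cutoff = Inf))
  net$edges <- tibble::tibble(from = c("n1", "n2", "n1", "n4", "n5", "n4"),
                              to = c("n2", "n3", "n3", "n5", "n6", "n6"),
                              mi = 1)
  net$graph <- igraph::graph_from_data_frame(net$edges[1:2], directed = FALSE,
                                             vertices = data.frame(name = net$nodes))
  net <- detect_modules(net)
  expect_identical(length(unique(net$modules$module)), 2L)
  expect_equal(net$Q, 0.5)
  # independent recomputation of Q from the returned partition
  mem <- setNames(net$modules$module, net$modules$node)
  expect_equal(net$Q, markpanel:::modularity_q(net$edges, mem), tolerance = 1e-9)
  # and igraph's own modularity as a cross-check
  expect_equal(net$Q, igraph::modularity(net$graph, mem[net$nodes]),
               tolerance = 1e-9)

  # complete graph: no structure beyond the whole, Q = 0
  net_k5 <- suppressWarnings(build_network(S[1:5, ], colnames(S), cutoff = -1))
  net_k5 <- detect_modules(net_k5)
  expect_identical(length(unique(net_k5$modules$module)), 1L)
  expect_equal(net_k5$Q, 0, tolerance = 1e-12)

  # triangle plus isolated node: hand Q = (1 - 1) + (0 - 0) = 0
  net_ti <- suppressWarnings(build_network(S[1:4, ], colnames(S), cutoff = Inf))
  net_ti$edges <- tibble::tibble(from = c("n1", "n2", "n1"),
                                 to = c("n2", "n3", "n3"), mi = 1)
  net_ti$graph <- igraph::graph_from_data_frame(net_ti$edges[1:2], directed = FALSE,
                                                vertices = data.frame(name = net_ti$nodes))
  net_ti <- detect_modules(net_ti)
  mem_ti <- setNames(net_ti$modules$module, net_ti$modules$node)
  expect_identical(length(unique(mem_ti[c("n1", "n2", "n3")])), 1L)
  expect_false(mem_ti["n4"] %in% mem_ti[c("n1", "n2", "n3")])
  expect_equal(net_ti$Q, 0, tolerance = 1e-12)

  # edgeless network: singletons with Q = 0 by convention
  net0 <- detect_modules(suppressWarnings(build_network(S[1:4, ], colnames(S), cutoff = Inf)))
  expect_identical(net0$modules$module, seq_len(4L))
  expect_identical(net0$Q, 0)
})

test_that("module annotation ranks labels by frequency with lexical ties", {
  modules <- tibble::tibble(node = paste0("n", 1:6), module = 1L)
  labels <- setNames(c("T", "T", "T", "B", "B", "NK"), modules$node)
  ann <- annotate_modules(modules, labels)
  expect_identical(ann$label, c("T", "B", "NK"))
  expect_identical(ann$count, c(3L, 2L, 1L))

  same <- annotate_modules(modules, setNames(rep("T", 6), modules$node))
  expect_identical(nrow(same), 1L)

  many <- annotate_modules(modules, setNames(c("a", "b", "c", "d", "e", "f"),
                                             modules$node))
  expect_identical(nrow(many), 5L)   # truncated to top 5
  expect_identical(many$label, c("a", "b", "c", "d", "e"))

  expect_error(annotate_modules(modules, labels[-1]), "n1")
})

test_that("network artifacts write to TSV and glance summarizes", {
  sim <- simulate_expression(synthetic_spec(m = 5, n_background = 30, seed = 8))
  net <- detect_modules(build_network(sim$S, colnames(sim$S)[1:8], cutoff = 0.25))
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- write_network(net, prefix)
  expect_true(all(file.exists(paths)))
  gl <- glance(net)
  expect_identical(gl$n_nodes, 5L)
  expect_true(gl$Q >= -0.5 && gl$Q < 1)
})
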