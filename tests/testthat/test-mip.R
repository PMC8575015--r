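test_that("model description counts variables and constraints correctly", {
  p <- random_problem(3, 4, k = 2, lambda = 1, mu = 1, seed = 1)
  mdl <- build_mip(p)
  expect_identical(mdl$n_binary, 4L)
  expect_identical(mdl$n_continuous, 3L)            # m(m-1)/2 pairs
  expect_identical(mdl$n_constraints, 4L)           # 1 cardinality + 3 pair
  expect_equal(mdl$objective$w, -(p$a + p$mu * p$ss))
  expect_equal(mdl$objective$constant, p$D)

  # mu = 0 drops the specificity term from the objective
  p0 <- random_problem(3, 4, k = 2, lambda = 1, mu = 0, seed = 1)
  expect_equal(build_mip(p0)$objective$w, -p0$a)

  zt <- difference_tensor(random_expression(3, 4, seed = 1))
  expect_error(panel_problem(zt, rep(1, 4), k = 5), "k must be")
})

test_that("solver matches the exhaustive oracle on many random instances", {
  set.seed(42)
  n_inst <- 60
  params <- data.frame(
    m = sample(3:6, n_inst, replace = TRUE),
    n = sample(6:12, n_inst, replace = TRUE),
    k = sample(1:4, n_inst, replace = TRUE),
    lambda = sample(c(0, 1, 100), n_inst, replace = TRUE),
    mu = sample(c(0, 1, 100), n_inst, replace = TRUE),
    seed = sample.int(1e6, n_inst)
  )
  for (r in seq_len(n_inst)) {
    p <- random_problem(params$m[r], params$n[r], params$k[r],
                        params$lambda[r], params$mu[r], params$seed[r])
    sol <- solve_mip(p)
    orc <- exhaustive_oracle(p)
    expect_identical(sol$status, "optimal")
    expect_equal(sol$objective, orc$objective, tolerance = 1e-6)
    expect_identical(sol$selected, orc$selected)
  }
})

test_that("slacks are tight and the objective decomposes exactly", {
  for (seed in 1:5) {
    p <- random_problem(4, 8, k = 3, lambda = 10, mu = 5, seed = seed)
    sol <- solve_mip(p)
    d <- sol$d$pairs$d
    expect_equal(sol$xi$xi, pmax(0, p$r - d / p$k), tolerance = 1e-12)
    recomputed <- (p$D - sum(d)) + p$lambda * sum(sol$xi$xi) -
      p$mu * sum(p$ss[sol$w > 0.5])
    expect_equal(sol$objective, recomputed, tolerance = 1e-8)
    expect_equal(sum(sol$w), p$k)
  }
})

test_that("model reductions behave as the formulation implies", {
  p <- random_problem(4, 7, k = 3, lambda = 0, mu = 0, seed = 8)
  sol <- solve_mip(p)
  # mu = lambda = 0: objective is the total-discrepancy term alone
  expect_equal(sol$objective, p$D - sol$d$selected_total, tolerance = 1e-12)

  # k = n: full panel, all slack zero, objective -mu * sum(ss)
  pf <- random_problem(4, 6, k = 6, lambda = 7, mu = 2, seed = 9)
  sf <- solve_mip(pf)
  expect_equal(unname(sf$w), rep(1, 6))
  expect_equal(sf$xi$xi, rep(0, nrow(pf$zt$pairs)), tolerance = 1e-12)
  expect_equal(sf$objective, -pf$mu * sum(pf$ss), tolerance = 1e-8)

  # k = n with mu = lambda = 0: optimum exactly zero
  p0 <- random_problem(4, 6, k = 6, lambda = 0, mu = 0, seed = 10)
  expect_equal(solve_mip(p0)$objective, 0, tolerance = 1e-12)

  # lambda = mu = 0, k = 1: picks the gene with the largest pair total
  p1 <- random_problem(5, 9, k = 1, lambda = 0, mu = 0, seed = 11)
  s1 <- solve_mip(p1)
  expect_identical(s1$selected, p1$zt$genes[which.max(p1$a)])
})

test_that("continuous relaxation lower-bounds the integer optimum", {
  for (seed in 1:8) {
    p <- random_problem(4, 8, k = 3,
                        lambda = c(0, 1, 100)[1 + seed %% 3],
                        mu = c(0, 1, 10)[1 + seed %% 3], seed = 200 + seed)
    rel <- solve_relaxation(p)
    sol <- solve_mip(p)
    expect_identical(rel$status, "optimal")
    expect_lte(rel$objective, sol$objective + 1e-6)
    expect_true(all(rel$w >= -1e-9 & rel$w <= 1 + 1e-9))
    expect_equal(sum(rel$w), p$k, tolerance = 1e-6)
  }
})

test_that("oracle is a true minimum and breaks ties lexicographically", {
  p <- random_problem(3, 6, k = 2, lambda = 1, mu = 1, seed = 31)
  orc <- exhaustive_oracle(p)
  subs <- combn(p$n, p$k)
  objs <- apply(subs, 2, function(s) markpanel:::panel_objective(p, s)$objective)
  expect_equal(orc$objective, min(objs), tolerance = 1e-12)

  # exact tie via duplicated gene columns: the lower index must win
  zp <- rbind(c(0.4, 0.4, 0.2), c(0.6, 0.6, 0.1), c(0.5, 0.5, 0.3))
  zt <- manual_tensor(zp, c("A", "B", "C"), c("g1", "g2", "g3"))
  pt <- panel_problem(zt, c(1, 1, 0.5), k = 1, lambda = 1, mu = 1)
  expect_identical(exhaustive_oracle(pt)$selected, "g1")
  expect_identical(solve_mip(pt)$selected, "g1")

  expect_error(exhaustive_oracle(random_problem(3, 12, 6, 1, 1, 1),
                                 max_subsets = 100), "max_subsets")
})

test_that("forced single-gene instance and tidy/glance accessors work", {
  zp <- matrix(c(0.7), 1, 1)
  zt <- manual_tensor(zp, c("A", "B"), "g1")
  p <- panel_problem(zt, 2, k = 1, lambda = 3, mu = 1)
  sol <- solve_mip(p)
  expect_identical(sol$selected, "g1")
  # by hand: d = 0.7 = D, xi = max(0, 0.7/1 - 0.7/1) = 0, obj = 0 + 0 - 2
  expect_equal(sol$objective, -2, tolerance = 1e-12)

  td <- tidy(sol)
  expect_identical(td$selected, TRUE)
  gl <- glance(sol)
  expect_equal(gl$objective, -2)
  expect_identical(gl$status, "optimal")
})

test_that("parameter sweep covers the grid and survives per-cell failure", {
  S <- example_expression()
  zt <- difference_tensor(S)
  spec <- specificity_scores(S)
  sw <- sweep_parameters(zt, spec, k_values = 2, lambda_values = 1,
                         mu_values = c(0, 1))
  expect_identical(nrow(sw), 2L)
  expect_named(sw, c("k", "lambda", "mu", "panel", "objective", "status",
                     "C1", "C2", "C3"))
  expect_true(all(sw$status == "optimal"))
  expect_true(all(sw$C2 >= sw$C3))
  expect_error(sweep_parameters(zt, spec, k_values = numeric()), "nonempty")
})
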