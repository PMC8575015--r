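# shared fixtures: small matrices and random instances built in code

tiny_matrix <- function() {
  S <- rbind(A = c(g1 = 7, g2 = 1, g3 = 30),
             B = c(1, 1, 2),
             C = c(0, 15, 2))
  colnames(S) <- c("g1", "g2", "g3")
  S
}

# random expression matrix with lognormal values, reproducible per seed
random_expression <- function(m, n, seed) {
  set.seed(seed)
  S <- matrix(exp(rnorm(m * n, log(10), 1)), m, n,
              dimnames = list(sprintf("ct%02d", seq_len(m)),
                              sprintf("g%03d", seq_len(n))))
  S
}

# difference tensor with prescribed pair x gene z values (for hand examples)
manual_tensor <- function(zp, cell_types, genes, theta = 10, y0 = 3) {
  markpanel:::new_difference_tensor(
    zp, markpanel:::pair_index(cell_types), cell_types, genes, theta, y0
  )
}

# random full problem (tensor + specificity) for solver properties
random_problem <- function(m, n, k, lambda, mu, seed) {
  S <- random_expression(m, n, seed)
  zt <- difference_tensor(S)
  ss <- specificity_scores(S)
  panel_problem(zt, ss, k = k, lambda = lambda, mu = mu)
}
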