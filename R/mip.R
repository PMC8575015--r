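#' Marker-panel selection problem
#'
#' Bundles everything model needs: the distinguishability tensor, the
#' per-gene specificity scores, the panel size `k`, the slack penalty
#' `lambda` and the specificity weight `mu`.  The objective being minimized
#' over binary selections `w` (with slack `xi_ij >= 0`) is
#' \deqn{D - \sum_{i<j} d_{ij} + \lambda \sum_{i<j} \xi_{ij}
#'       - \mu \sum_l w_l ss_l,}
#' subject to `sum_l w_l = k` and
#' `(1/k) d_ij + xi_ij >= (1/n) sum_l z_ijl` for every unordered pair,
#' where `d_ij = sum_l w_l z_ijl` and `D` is the all-gene total.  The first
#' term keeps the total pairwise structure, the slack term keeps every
#' individual pair's (normalized) distance, and the last term favours cell
#' type-specific genes.
#'
#' @param zt a `difference_tensor`.
#' @param ss per-gene specificity scores: a `specificity_table` or a
#'   numeric vector of length n.
#' @param k panel size, `1 <= k <= n`.
#' @param lambda nonnegative slack penalty.
#' @param mu nonnegative specificity weight (`mu = 0` drops specificity and
#'   leaves a pure dimension-reduction model; `mu = lambda = 0` reduces to
#'   distance-preserving feature selection alone).
#' @return a `panel_problem`.
#' @export
panel_problem <- function(zt, ss, k, lambda = 100, mu = 10) {
  stopifnot(inherits(zt, "difference_tensor"))
  if (inherits(ss, "specificity_table")) ss <- ss$ss_gene
  ss <- as.numeric(ss)
  if (length(ss) != zt$n) abort("specificity vector length must equal gene count")
  if (any(ss < 0)) abort("specificity scores must be nonnegative")
  if (k < 1 || k > zt$n) abort(sprintf("k must be in [1, %d], got %s", zt$n, format(k)))
  if (lambda < 0 || mu < 0) abort("lambda and mu must be nonnegative")
  structure(list(
    zt = zt, ss = ss, k = as.integer(k), lambda = lambda, mu = mu,
    n = zt$n, P = nrow(zt$pairs),
    a = colSums(zt$zp),            # per-gene total over pairs
    r = rowSums(zt$zp) / zt$n,     # all-gene normalized pair distance
    D = sum(zt$zp)
  ), class = "panel_problem")
}

#' @export
print.panel_problem <- function(x, ...) {
  cat(sprintf("<panel_problem> n=%d genes, %d pairs, k=%d, lambda=%g, mu=%g\n",
              x$n, x$P, x$k, x$lambda, x$mu))
  invisible(x)
}

#' Abstract mixed-integer model description
#'
#' Builds the explicit MILP: n binary selection variables, one continuous
#' slack per unordered pair, a cardinality row and one covering row per
#' pair; `d_ij` is substituted inline so the model is linear in `w`.
#' This is an inspectable description — [solve_mip()] works from the
#' `panel_problem` directly.
#'
#' @param problem a `panel_problem`.
#' @return a `mip_model` list with objective coefficients (gene part
#'   `-(a_l + mu ss_l)`, slack part `lambda`, constant `D`) and the
#'   constraint system.
#' @export
build_mip <- function(problem) {
  stopifnot(inherits(problem, "panel_problem"))
  p <- problem
  structure(list(
    n_binary = p$n, n_continuous = p$P, n_constraints = 1L + p$P,
    objective = list(w = -(p$a + p$mu * p$ss), xi = rep(p$lambda, p$P),
                     constant = p$D),
    cardinality = p$k,
    pair_lhs_w = p$zt$zp / p$k,   # row p: (1/k) z_p. w + xi_p >= r_p
    pair_rhs = p$r,
    variables = list(w = p$zt$genes, xi = paste0(p$zt$pairs$cell_i, ":", p$zt$pairs$cell_j))
  ), class = "mip_model")
}

#' @export
print.mip_model <- function(x, ...) {
  cat(sprintf("<mip_model> %d binary + %d continuous variables, %d constraints (1 cardinality + %d pair)\n",
              x$n_binary, x$n_continuous, x$n_constraints, x$n_continuous))
  invisible(x)
}

# exact objective of a complete k-subset (gene indices)
panel_objective <- function(p, sel) {
  d <- as.vector(p$zt$zp[, sel, drop = FALSE] %*% rep(1, length(sel)))
  xi <- pmax(0, p$r - d / p$k)
  list(objective = p$D - sum(d) + p$lambda * sum(xi) - p$mu * sum(p$ss[sel]),
       d = d, xi = xi)
}

# valid lower bound over all completions of a node: drop-slack linear part
# plus a per-pair slack bound using the best achievable d_ij
node_bound <- function(p, coef, in_idx, free_idx, t) {
  lin <- p$D - sum(coef[in_idx]) -
    (if (t > 0) sum(sort(coef[free_idx], decreasing = TRUE)[seq_len(t)]) else 0)
  if (p$lambda > 0) {
    d_in <- if (length(in_idx)) as.vector(p$zt$zp[, in_idx, drop = FALSE] %*% rep(1, length(in_idx))) else numeric(p$P)
    dmax <- d_in
    if (t > 0 && length(free_idx)) {
      zf <- p$zt$zp[, free_idx, drop = FALSE]
      top <- apply(zf, 1L, function(row) sum(sort(row, decreasing = TRUE)[seq_len(min(t, length(row)))]))
      dmax <- dmax + top
    }
    lin <- lin + p$lambda * sum(pmax(0, p$r - dmax / p$k))
  }
  lin
}

new_panel_solution <- function(p, sel, obj, status, nodes = NA_integer_,
                               relaxed = FALSE, w = NULL) {
  if (is.null(w)) {
    w <- setNames(numeric(p$n), p$zt$genes)
    w[sel] <- 1
  }
  structure(list(
    w = w,
    selected = p$zt$genes[sort(sel)],
    xi = dplyr::mutate(p$zt$pairs, xi = obj$xi),
    objective = obj$objective,
    status = status,
    d = structure(list(pairs = dplyr::mutate(p$zt$pairs, d = obj$d),
                       D = p$D, selected_total = sum(obj$d)),
                  class = "pairwise_distances"),
    k = p$k, lambda = p$lambda, mu = p$mu,
    nodes = nodes, relaxed = relaxed, problem = p
  ), class = "panel_solution")
}

#' Solve the panel-selection MIP exactly
#'
#' Exact branch and bound.  Phase one finds the optimal objective with a
#' best-coefficient-first search under a valid lower bound (the slack-free
#' linear term plus a per-pair bound on the achievable slack); phase two
#' re-searches in gene-index order and returns the lexicographically
#' smallest panel whose objective is within `tie_tol` of the optimum, the
#' same tie-break as [exhaustive_oracle()].
#'
#' @param problem a `panel_problem`.
#' @param time_limit seconds; when exceeded the incumbent is returned with
#'   status `"feasible"`.
#' @param gap_tol absolute pruning tolerance.
#' @param tie_tol tolerance within which objectives are treated as tied.
#' @param max_nodes node budget; exceeded also yields status `"feasible"`.
#' @return a `panel_solution` with binary weights `w`, tight slacks `xi`,
#'   the recomputed objective, the induced pairwise distances, and
#'   `status` in `optimal | feasible | error`.
#' @export
solve_mip <- function(problem, time_limit = Inf, gap_tol = 1e-9,
                      tie_tol = 1e-9, max_nodes = 5e5) {
  stopifnot(inherits(problem, "panel_problem"))
  p <- problem
  coef <- p$a + p$mu * p$ss
  deadline <- proc.time()[[3L]] + time_limit
  st <- new.env(parent = emptyenv())
  st$best <- Inf; st$best_sel <- integer(); st$nodes <- 0L; st$capped <- FALSE

  greedy_complete <- function(in_idx, free_idx, t) {
    if (t > 0) c(in_idx, free_idx[order(-coef[free_idx])][seq_len(t)]) else in_idx
  }

  # phase 1: optimal value; branch on the largest-coefficient free gene
  search <- function(in_idx, free_idx) {
    st$nodes <- st$nodes + 1L
    if (st$nodes > max_nodes || proc.time()[[3L]] > deadline) {
      st$capped <- TRUE
      return(invisible())
    }
    t <- p$k - length(in_idx)
    if (t == 0L) {
      obj <- panel_objective(p, in_idx)$objective
      if (obj < st$best - gap_tol) { st$best <- obj; st$best_sel <- in_idx }
      return(invisible())
    }
    if (length(free_idx) < t) return(invisible())
    if (node_bound(p, coef, in_idx, free_idx, t) >= st$best - gap_tol) return(invisible())
    cand <- greedy_complete(in_idx, free_idx, t)
    obj <- panel_objective(p, cand)$objective
    if (obj < st$best - gap_tol) { st$best <- obj; st$best_sel <- cand }
    g <- free_idx[which.max(coef[free_idx])]
    rest <- setdiff(free_idx, g)
    search(c(in_idx, g), rest)
    search(in_idx, rest)
    invisible()
  }
  # seed incumbent so bounds prune from the start
  seed <- greedy_complete(integer(), seq_len(p$n), p$k)
  st$best <- panel_objective(p, seed)$objective; st$best_sel <- seed
  search(integer(), seq_len(p$n))

  if (!st$capped) {
    # phase 2: lexicographically smallest panel within tie_tol of the optimum
    target <- st$best + tie_tol
    lex <- function(in_idx, next_g) {
      if (!is.null(st$lex_sel)) return(invisible())
      t <- p$k - length(in_idx)
      if (t == 0L) {
        if (panel_objective(p, in_idx)$objective <= target) st$lex_sel <- in_idx
        return(invisible())
      }
      if (p$n - next_g + 1L < t) return(invisible())
      free_idx <- next_g:p$n
      if (node_bound(p, coef, in_idx, free_idx, t) > target) return(invisible())
      lex(c(in_idx, next_g), next_g + 1L)
      lex(in_idx, next_g + 1L)
      invisible()
    }
    st$lex_sel <- NULL
    lex(integer(), 1L)
    if (!is.null(st$lex_sel)) st$best_sel <- st$lex_sel
  }

  sel <- sort(st$best_sel)
  obj <- panel_objective(p, sel)
  new_panel_solution(p, sel, obj,
                     status = if (st$capped) "feasible" else "optimal",
                     nodes = st$nodes)
}

#' Exhaustive enumeration oracle
#'
#' Evaluates the exact objective of every k-subset (slacks at their tight
#' values) and returns the global optimum; among objectives tied within
#' `tie_tol`, the lexicographically first subset in enumeration order wins.
#' Intended as an independent reference for small instances.
#'
#' @param problem a `panel_problem` with `choose(n, k) <= max_subsets`.
#' @param tie_tol tie tolerance on objectives.
#' @param max_subsets guard against oversized enumerations.
#' @return a `panel_solution` with status `"optimal"`.
#' @export
exhaustive_oracle <- function(problem, tie_tol = 1e-9, max_subsets = 1e6) {
  stopifnot(inherits(problem, "panel_problem"))
  p <- problem
  if (choose(p$n, p$k) > max_subsets) {
    abort(sprintf("choose(%d, %d) exceeds max_subsets = %g", p$n, p$k, max_subsets))
  }
  subs <- combn(p$n, p$k)   # columns come out in lexicographic order
  best <- Inf; best_sel <- integer()
  for (s in seq_len(ncol(subs))) {
    obj <- panel_objective(p, subs[, s])$objective
    if (obj < best - tie_tol) { best <- obj; best_sel <- subs[, s] }
  }
  obj <- panel_objective(p, best_sel)
  new_panel_solution(p, best_sel, obj, status = "optimal",
                     nodes = ncol(subs))
}

#' Continuous relaxation of the selection MIP
#'
#' Same objective and constraints as [solve_mip()] with `w` relaxed from
#' binary to `[0, 1]`; solved as a plain LP.  Its optimum is a lower bound
#' on the MIP optimum.
#'
#' @param problem a `panel_problem`.
#' @return list with fields `w`, `xi`, `objective`, `status`.
#' @export
solve_relaxation <- function(problem) {
  stopifnot(inherits(problem, "panel_problem"))
  p <- problem
  nv <- p$n + p$P
  cc <- c(-(p$a + p$mu * p$ss), rep(p$lambda, p$P))
  # rows: -(1/k) Z w - xi <= -r   and   w <= 1 ; variables implicitly >= 0
  A <- rbind(cbind(-p$zt$zp / p$k, -diag(p$P)),
             cbind(diag(p$n), matrix(0, p$n, p$P)))
  b <- c(-p$r, rep(1, p$n))
  Aeq <- matrix(c(rep(1, p$n), rep(0, p$P)), 1L)
  res <- linprog_robust(cc, A = A, b = b, Aeq = Aeq, beq = p$k,
                        maxiter = 200L * nv)
  if (inherits(res, "error") || is.null(res$x)) {
    msg <- if (inherits(res, "error")) conditionMessage(res) else res$message
    return(list(w = NULL, xi = NULL, objective = NA_real_, status = "error",
                message = msg))
  }
  list(w = setNames(res$x[seq_len(p$n)], p$zt$genes),
       xi = res$x[p$n + seq_len(p$P)],
       objective = res$fval + p$D,
       status = "optimal")
}

#' @export
print.panel_solution <- function(x, ...) {
  cat(sprintf("<panel_solution> k=%d, lambda=%g, mu=%g, status=%s\n",
              x$k, x$lambda, x$mu, x$status))
  cat(sprintf("  objective = %.6g; panel: %s\n", x$objective,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.panel_solution <- function(x, ...) {
  p <- x$problem
  tibble(gene_id = p$zt$genes, weight = unname(x$w),
         selected = unname(x$w) > 0.5,
         ss = p$ss, pair_total = unname(p$a))
}

#' @exportS3Method generics::glance
glance.panel_solution <- function(x, ...) {
  tibble(k = x$k, lambda = x$lambda, mu = x$mu, objective = x$objective,
         status = x$status, n_genes = x$problem$n,
         discrepancy = x$d$D - x$d$selected_total,
         slack_total = sum(x$xi$xi),
         specificity_total = sum(x$problem$ss[x$w > 0.5]))
}

#' Sweep the model over k, lambda and mu grids
#'
#' Solves the MIP at every grid point and scores each panel by the three
#' accuracy criteria.  Solver errors in one cell are recorded in the
#' `status` column and the sweep continues.  The published grids are
#' `lambda = 1, 10, 100, 1000, 10000` and
#' `mu = 0, 1, 10, 20, 50, 100, 1000, 10000`.
#'
#' @param zt a `difference_tensor`.
#' @param ss specificity scores (`specificity_table` or numeric vector).
#' @param k_values,lambda_values,mu_values nonempty numeric grids.
#' @param c1_threshold,z_threshold criteria thresholds (see
#'   [panel_criteria()]).
#' @param ... passed to [solve_mip()].
#' @return a `panel_sweep` tibble: one row per (k, lambda, mu) with the
#'   selected panel (list column), objective, status and C1, C2, C3.
#' @export
sweep_parameters <- function(zt, ss, k_values,
                             lambda_values = c(1, 10, 100, 1000, 10000),
                             mu_values = c(0, 1, 10, 20, 50, 100, 1000, 10000),
                             c1_threshold = 0.5, z_threshold = 0.5, ...) {
  if (!length(k_values) || !length(lambda_values) || !length(mu_values)) {
    abort("all parameter grids must be nonempty")
  }
  if (inherits(ss, "specificity_table")) ss <- ss$ss_gene
  grid <- tidyr::expand_grid(k = k_values, lambda = lambda_values, mu = mu_values)
  rows <- purrr::pmap(grid, function(k, lambda, mu) {
    res <- tryCatch({
      sol <- solve_mip(panel_problem(zt, ss, k, lambda, mu), ...)
      cr <- panel_criteria(zt, sol$w, c1_threshold = c1_threshold,
                           z_threshold = z_threshold)
      tibble(panel = list(sol$selected), objective = sol$objective,
             status = sol$status, C1 = cr$C1, C2 = cr$C2, C3 = cr$C3)
    }, error = function(e) {
      tibble(panel = list(character()), objective = NA_real_,
             status = paste0("error: ", conditionMessage(e)),
             C1 = NA_real_, C2 = NA_real_, C3 = NA_real_)
    })
    res
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(rows))
  class(out) <- c("panel_sweep", class(out))
  out
}
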