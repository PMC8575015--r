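#' Linear-programming formulation for high-dimensional selection
#'
#' The scalable variant drops both the binary restriction and the
#' cardinality constraint: weights `w_l >= 0` are continuous, each pair's
#' discrepancy `sum_l z_ijl - sum_l w_l z_ijl` is split into nonnegative
#' parts `xi+_ij - xi-_ij`, and the objective
#' \deqn{\sum_{i<j} \xi^+_{ij} + \sum_{i<j} \xi^-_{ij}
#'       + \lambda \sum_l w_l - \mu \sum_l w_l ss_l}
#' trades pairwise-structure preservation against panel size (`lambda`)
#' and specificity (`mu`).  There is no upper bound on `w`.
#'
#' @param zt a `difference_tensor`.
#' @param ss specificity scores (`specificity_table` or numeric vector).
#' @param lambda nonnegative weight-size penalty.
#' @param mu nonnegative specificity weight.
#' @return an `lp_model`: objective vector, equality system, and metadata.
#' @export
build_lp <- function(zt, ss, lambda, mu = 0) {
  stopifnot(inherits(zt, "difference_tensor"))
  if (inherits(ss, "specificity_table")) ss <- ss$ss_gene
  ss <- as.numeric(ss)
  if (length(ss) != zt$n) abort("specificity vector length must equal gene count")
  if (lambda < 0 || mu < 0) abort("lambda and mu must be nonnegative")
  P <- nrow(zt$pairs)
  structure(list(
    zt = zt, ss = ss, lambda = lambda, mu = mu,
    n = zt$n, P = P,
    n_variables = zt$n + 2L * P, n_constraints = P,
    objective = c(lambda - mu * ss, rep(1, 2L * P)),
    rhs = rowSums(zt$zp)   # sum_l z_ijl per pair
  ), class = "lp_model")
}

#' @export
print.lp_model <- function(x, ...) {
  cat(sprintf("<lp_model> %d variables (%d weights + %d slack pairs), %d equality constraints, lambda=%g, mu=%g\n",
              x$n_variables, x$n, 2L * x$P, x$n_constraints, x$lambda, x$mu))
  invisible(x)
}

#' Solve the LP selection model
#'
#' Simplex solve of [build_lp()]'s model.  Because `w` is unbounded above,
#' a too-small `lambda` relative to `mu * max(ss)` makes the LP unbounded;
#' the conservative guard `mu * max(ss) >= lambda + sum_ij sum_l z_ijl` is
#' rejected before solving, and solver-detected unboundedness is surfaced
#' as status `"unbounded"` with advice to raise `lambda`.
#'
#' @param model an `lp_model` (or a `difference_tensor`, in which case
#'   `ss`, `lambda`, `mu` are forwarded to [build_lp()]).
#' @param ss,lambda,mu used only when `model` is a `difference_tensor`.
#' @param tau support threshold for the default discretization.
#' @return an `lp_solution`: nonnegative weights `w`, slack vectors
#'   `xi_plus`/`xi_minus`, objective, status, and `selected` — the support
#'   `{l : w_l > tau}` ordered by descending weight.
#' @export
solve_lp <- function(model, ss = NULL, lambda = NULL, mu = 0, tau = 1e-6) {
  if (inherits(model, "difference_tensor")) {
    model <- build_lp(model, ss, lambda, mu)
  }
  stopifnot(inherits(model, "lp_model"))
  m <- model
  if (m$mu * max(m$ss) >= m$lambda + sum(m$rhs)) {
    abort(paste0("LP is unbounded: mu * max(ss) = ", format(m$mu * max(m$ss)),
                 " dominates lambda; raise lambda or lower mu"))
  }
  P <- m$P; n <- m$n
  # equality rows:  rhs - Zw = xi+ - xi-,  written as  Zw + xi+ - xi- = rhs
  Aeq <- cbind(m$zt$zp, diag(P), -diag(P))
  res <- linprog_robust(m$objective, Aeq = Aeq, beq = m$rhs,
                        maxiter = 400L * (n + 2L * P))
  if (inherits(res, "error") || is.null(res$x)) {
    msg <- if (inherits(res, "error")) conditionMessage(res) else res$message
    status <- if (grepl("unbounded", msg, ignore.case = TRUE)) "unbounded" else "error"
    if (status == "unbounded") {
      warn("LP reported unbounded; raise lambda relative to mu * max(ss)")
    }
    return(structure(list(w = NULL, xi_plus = NULL, xi_minus = NULL,
                          objective = NA_real_, status = status,
                          selected = character(), message = msg,
                          model = m),
                     class = "lp_solution"))
  }
  w <- setNames(res$x[seq_len(n)], m$zt$genes)
  sol <- structure(list(
    w = w,
    xi_plus = res$x[n + seq_len(P)],
    xi_minus = res$x[n + P + seq_len(P)],
    objective = res$fval,
    status = "optimal",
    model = m
  ), class = "lp_solution")
  sol$selected <- discretize_weights(sol, mode = "threshold", tau = tau)
  sol
}

#' Turn continuous LP weights into a panel
#'
#' The LP reports weights, not a panel; two published-usage-compatible
#' rules are provided.  `top_k` keeps the `k` largest-weight genes (ties
#' lexicographic by gene ID); `threshold` keeps the support
#' `{l : w_l > tau}`.  Both return genes ordered by descending weight.
#'
#' @param sol a solved `lp_solution`.
#' @param mode `"top_k"` or `"threshold"`.
#' @param k panel size for `top_k`; if it exceeds the positive support a
#'   warning is issued and the support is returned.
#' @param tau weight threshold for `threshold` (default 1e-6).
#' @return ordered character vector of gene IDs.
#' @export
discretize_weights <- function(sol, mode = c("top_k", "threshold"),
                               k = NULL, tau = 1e-6) {
  stopifnot(inherits(sol, "lp_solution"))
  if (sol$status != "optimal") abort("LP was not solved to optimality")
  mode <- match.arg(mode)
  w <- sol$w
  ord <- order(-w, names(w))
  if (mode == "threshold") {
    sel <- ord[w[ord] > tau]
    return(names(w)[sel])
  }
  if (is.null(k)) abort("k is required for top_k discretization")
  support <- sum(w > 0)
  if (k > support) {
    warn(sprintf("k = %d exceeds the positive support (%d); returning the support", k, support))
    k <- support
  }
  names(w)[ord[seq_len(k)]]
}

#' @export
print.lp_solution <- function(x, ...) {
  cat(sprintf("<lp_solution> status=%s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective=%.6g, support=%d genes", x$objective,
                sum(x$w > 1e-6)))
  }
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lp_solution <- function(x, ...) {
  if (x$status != "optimal") abort("LP was not solved to optimality")
  tibble(gene_id = names(x$w), weight = unname(x$w),
         selected = names(x$w) %in% x$selected) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$gene_id)
}

#' @exportS3Method generics::glance
glance.lp_solution <- function(x, ...) {
  tibble(lambda = x$model$lambda, mu = x$model$mu,
         objective = x$objective, status = x$status,
         support = if (is.null(x$w)) NA_integer_ else sum(x$w > 1e-6),
         slack_total = if (is.null(x$xi_plus)) NA_real_ else sum(x$xi_plus) + sum(x$xi_minus))
}
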