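#' Panel accuracy criteria
#'
#' Three fractions over the m(m-1)/2 unordered cell-type pairs:
#' * **C1** — pairs whose panel distance `d_ij = sum_l w_l z_ijl` exceeds
#'   the threshold `T` (default 0.5).  `d_ij` is the raw sum, so this
#'   criterion grows with panel size by construction.
#' * **C2** — pairs with at least one selected gene whose `z_ijl` exceeds
#'   `z_threshold` (default 0.5, i.e. fold change above the sigmoid
#'   midpoint `y0`).
#' * **C3** — pairs with at least two such genes.
#'
#' All comparisons are strict (`>`).  C2 >= C3 always, and all three are
#' nondecreasing when genes are added to the panel.
#'
#' @param zt a `difference_tensor`.
#' @param w binary selection vector or character vector of panel genes.
#' @param c1_threshold threshold `T` on the pairwise panel distance.
#' @param z_threshold threshold on individual `z_ijl` values, in (0, 1).
#' @return one-row tibble with columns `C1`, `C2`, `C3`, `k`,
#'   `c1_threshold`, `z_threshold`; the per-pair indicator table is
#'   attached as attribute `"pairs"`.
#' @export
panel_criteria <- function(zt, w, c1_threshold = 0.5, z_threshold = 0.5) {
  stopifnot(inherits(zt, "difference_tensor"))
  w <- as_selection(zt, w)
  d <- as.vector(zt$zp %*% w)
  sel <- which(w == 1)
  counts <- if (length(sel)) {
    rowSums(zt$zp[, sel, drop = FALSE] > z_threshold)
  } else {
    numeric(nrow(zt$pairs))
  }
  pairs <- dplyr::mutate(zt$pairs, d = d, qualifying = counts,
                         c1 = d > c1_threshold, c2 = counts > 0, c3 = counts > 1)
  out <- tibble(C1 = mean(pairs$c1), C2 = mean(pairs$c2), C3 = mean(pairs$c3),
                k = sum(w), c1_threshold = c1_threshold,
                z_threshold = z_threshold)
  attr(out, "pairs") <- pairs
  out
}

#' @rdname panel_criteria
#' @param d a `pairwise_distances` object from [panel_distances()].
#' @export
criterion1 <- function(d, c1_threshold = 0.5) {
  stopifnot(inherits(d, "pairwise_distances"))
  mean(d$pairs$d > c1_threshold)
}

#' @rdname panel_criteria
#' @export
criterion2 <- function(zt, w, z_threshold = 0.5) {
  panel_criteria(zt, w, z_threshold = z_threshold)$C2
}

#' @rdname panel_criteria
#' @export
criterion3 <- function(zt, w, z_threshold = 0.5) {
  panel_criteria(zt, w, z_threshold = z_threshold)$C3
}

#' Accuracy as a function of panel size
#'
#' Solves the selection MIP for each `k` and evaluates the three criteria,
#' producing the accuracy-versus-k curve used to choose a panel size
#' (accuracies typically plateau once the panel covers every pair).
#'
#' @param zt a `difference_tensor`.
#' @param ss specificity scores (`specificity_table` or numeric vector).
#' @param k_range integer vector of panel sizes.
#' @param lambda,mu model parameters.
#' @param c1_threshold,z_threshold criteria thresholds.
#' @param ... passed to [solve_mip()].
#' @return an `accuracy_curve` tibble: one row per `k` with `C1`, `C2`,
#'   `C3`, `objective`, `status` and the panel (list column).  Empty
#'   `k_range` gives an empty table.
#' @export
accuracy_curve <- function(zt, ss, k_range, lambda = 100, mu = 10,
                           c1_threshold = 0.5, z_threshold = 0.5, ...) {
  if (!length(k_range)) {
    out <- tibble(k = integer(), C1 = numeric(), C2 = numeric(),
                  C3 = numeric(), objective = numeric(), status = character(),
                  panel = list())
    class(out) <- c("accuracy_curve", class(out))
    return(out)
  }
  out <- sweep_parameters(zt, ss, k_values = k_range, lambda_values = lambda,
                          mu_values = mu, c1_threshold = c1_threshold,
                          z_threshold = z_threshold, ...)
  out <- dplyr::select(out, "k", "C1", "C2", "C3", "objective", "status", "panel")
  class(out) <- c("accuracy_curve", setdiff(class(out), "panel_sweep"))
  out
}
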