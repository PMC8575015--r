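#' Specification for hierarchical synthetic expression data
#'
#' Describes a rooted binary hierarchy of cell types with clade-specific
#' planted marker genes.  The default tree is balanced over `m` leaves;
#' by default one marker is planted per internal split (elevated in that
#' split's first child clade), giving `m - 1` markers on a balanced tree.
#' All genes carry multiplicative log-normal noise with log-sd
#' `noise_sigma`, and planted genes are elevated `fold`-fold inside their
#' clade.  The defaults (fold = 8, above twice the sigmoid midpoint
#' `y0 = 3`; sigma = 0.2, mild biological dispersion; base = 10, a typical
#' moderately expressed FPKM) are the study conditions used in the
#' package's own validation.
#'
#' @param m number of leaf cell types (power of 2 for the balanced tree).
#' @param n_background number of non-marker genes.
#' @param fold planted fold elevation (> 1).
#' @param noise_sigma log-sd of the multiplicative noise.
#' @param base_expression baseline expression level.
#' @param tree optional tree as a nested list of leaf names; default
#'   balanced binary over `ct01..ctm`.
#' @param planted optional tibble/data.frame with columns `gene`, `clade`
#'   (list column of leaf names), `fold`; default one marker per internal
#'   split.
#' @param seed integer seed; all randomness in [simulate_expression()]
#'   derives from it.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 8L, n_background = 50L, fold = 8,
                           noise_sigma = 0.2, base_expression = 10,
                           tree = NULL, planted = NULL, seed = 1L) {
  stopifnot(m >= 2, n_background >= 0, fold > 1, noise_sigma >= 0,
            base_expression > 0)
  if (is.null(tree)) {
    leaves <- sprintf("ct%02d", seq_len(m))
    tree <- balanced_tree(leaves)
  }
  leaves <- tree_leaves(tree)
  if (length(leaves) != m) abort("tree has a different number of leaves than m")
  if (is.null(planted)) {
    clades <- internal_first_child_clades(tree)
    planted <- tibble(
      gene = sprintf("mk%02d", seq_along(clades)),
      clade = clades,
      fold = rep(fold, length(clades))
    )
  } else {
    planted <- as_tibble(planted)
    stopifnot(all(c("gene", "clade", "fold") %in% names(planted)))
    if (anyDuplicated(planted$gene)) abort("planted genes must be distinct")
    if (any(planted$fold <= 1)) abort("planted folds must exceed 1")
    bad <- !purrr::map_lgl(planted$clade, ~ all(.x %in% leaves))
    if (any(bad)) abort("every planted clade must be a set of tree leaves")
  }
  structure(list(m = as.integer(m), leaves = leaves, tree = tree,
                 n_background = as.integer(n_background), fold = fold,
                 noise_sigma = noise_sigma,
                 base_expression = base_expression,
                 planted = planted, seed = as.integer(seed)),
            class = "synthetic_spec")
}

balanced_tree <- function(leaves) {
  if (length(leaves) == 1L) return(leaves[[1L]])
  half <- ceiling(length(leaves) / 2)
  list(balanced_tree(leaves[seq_len(half)]),
       balanced_tree(leaves[-seq_len(half)]))
}

tree_leaves <- function(tree) {
  if (!is.list(tree)) return(tree)
  unlist(lapply(tree, tree_leaves), use.names = FALSE)
}

# one clade per internal node: the leaves of its first child
internal_first_child_clades <- function(tree) {
  if (!is.list(tree)) return(list())
  c(list(tree_leaves(tree[[1L]])),
    internal_first_child_clades(tree[[1L]]),
    internal_first_child_clades(tree[[2L]]))
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d cell types, %d background + %d planted genes (fold=%g, sigma=%g, seed=%d)\n",
              x$m, x$n_background, nrow(x$planted), x$fold, x$noise_sigma,
              x$seed))
  invisible(x)
}

#' Simulate hierarchical expression with planted markers
#'
#' Background genes are `base * lognormal(0, sigma)` in every cell type;
#' the planted gene for a clade is additionally elevated `fold`-fold inside
#' that clade.  The same `spec` (including its seed) always produces the
#' same matrix; the caller's RNG state is untouched.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `S` (expression matrix, planted genes first) and
#'   `truth` (the planted tibble, plus `leaves` and the spec).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  m <- spec$m
  genes <- c(spec$planted$gene,
             if (spec$n_background > 0) sprintf("bg%03d", seq_len(spec$n_background)))
  n <- length(genes)
  noise <- matrix(exp(rnorm(m * n, 0, spec$noise_sigma)), m, n)
  base <- matrix(spec$base_expression, m, n)
  for (g in seq_len(nrow(spec$planted))) {
    inside <- spec$leaves %in% spec$planted$clade[[g]]
    base[inside, g] <- spec$base_expression * spec$planted$fold[g]
  }
  S <- base * noise
  dimnames(S) <- list(spec$leaves, genes)
  validate_expression_matrix(S)
  list(S = S, truth = list(planted = spec$planted, leaves = spec$leaves,
                           spec = spec))
}

#' Planted-marker recovery of a solved panel
#'
#' Compares a panel against the planted truth: recall and precision of the
#' selected set, plus `pair_separation` — the fraction of cell-type pairs
#' split by at least one planted clade that have at least one selected
#' gene with `z_ijl` above `z_threshold` (the criterion-2 notion of a
#' distinguishing gene).
#'
#' @param solution a `panel_solution` (or character vector of panel genes,
#'   in which case `zt` must be supplied).
#' @param truth the `truth` element of [simulate_expression()]'s output.
#' @param zt optional `difference_tensor` (taken from the solution's
#'   problem when absent).
#' @param z_threshold criterion-2 threshold.
#' @return one-row tibble: `recall`, `precision`, `n_recovered`,
#'   `n_planted`, `n_selected`, `pair_separation`.
#' @export
recovery_report <- function(solution, truth, zt = NULL, z_threshold = 0.5) {
  panel <- if (inherits(solution, "panel_solution")) {
    if (is.null(zt)) zt <- solution$problem$zt
    solution$selected
  } else {
    as.character(solution)
  }
  if (is.null(zt)) abort("zt is required when solution is a plain gene vector")
  planted <- truth$planted$gene
  recovered <- intersect(planted, panel)
  # pairs split by >= 1 planted clade
  split_pair <- purrr::map(truth$planted$clade, function(cl) {
    inside <- zt$cell_types %in% cl
    inside[zt$pairs$i] != inside[zt$pairs$j]
  })
  is_split <- Reduce(`|`, split_pair)
  sep <- if (any(is_split)) {
    counts <- rowSums(zt$zp[, zt$genes %in% panel, drop = FALSE] > z_threshold)
    mean(counts[is_split] > 0)
  } else {
    NA_real_
  }
  tibble(recall = length(recovered) / length(planted),
         precision = if (length(panel)) length(recovered) / length(panel) else NA_real_,
         n_recovered = length(recovered), n_planted = length(planted),
         n_selected = length(panel), pair_separation = sep)
}
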