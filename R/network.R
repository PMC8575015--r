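#' Kernel-density mutual information between two profiles
#'
#' Plug-in estimate of \eqn{MI = \iint p(x,y) \log(p(x,y)/(p_1(x) p_2(y)))}
#' from a bivariate Gaussian kernel density (Silverman's rule bandwidth per
#' variable, 64-point grid), in nats.  Marginals are obtained by
#' integrating the joint on the same grid so the estimate is exactly
#' symmetric in its arguments.  The estimate is clipped at 0; a constant
#' input has no usable density, so MI is defined as 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 5 recommended); in
#'   [build_network()] these are the two cell types' log2(expression + 1)
#'   values over the panel genes.
#' @param grid_size KDE grid points per axis.
#' @return nonnegative MI estimate in nats.
#' @export
mutual_information <- function(x, y, grid_size = 64L) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2L) abort("need at least 2 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant profile: mutual information defined as 0")
    return(0)
  }
  bw <- function(v) {
    s <- min(sd(v), stats::IQR(v) / 1.34)
    if (s == 0) s <- sd(v)
    1.06 * s * length(v)^(-1 / 5)
  }
  h <- c(4 * bw(x), 4 * bw(y))   # kde2d scales its bandwidth by 1/4
  lims <- c(range(x) + c(-1, 1) * h[1L], range(y) + c(-1, 1) * h[2L])
  kd <- MASS::kde2d(x, y, h = h, n = grid_size, lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  pxy <- kd$z / (sum(kd$z) * dx * dy)
  px <- rowSums(pxy) * dy
  py <- colSums(pxy) * dx
  term <- pxy * log(pxy / outer(px, py))
  term[!is.finite(term)] <- 0
  max(0, sum(term) * dx * dy)
}

#' Cell-type association network from a marker panel
#'
#' Restricts the expression matrix to the panel genes, log2(x+1)-transforms
#' it, estimates mutual information between every pair of cell types with
#' [mutual_information()], and keeps an (undirected, unweighted) edge
#' wherever MI exceeds `cutoff` (default 0.25).  Isolated nodes are
#' retained.
#'
#' @param S expression matrix (cell types x genes).
#' @param panel character vector of panel gene IDs (must all be present;
#'   fewer than 5 genes triggers a warning since the density estimate gets
#'   unstable).
#' @param cutoff MI edge threshold.
#' @return a `celltype_network`: node IDs, symmetric `mi` matrix, `edges`
#'   tibble (`from`, `to`, `mi`), the `igraph` graph, and slots `modules` /
#'   `Q` filled by [detect_modules()].
#' @export
build_network <- function(S, panel, cutoff = 0.25) {
  validate_expression_matrix(S)
  missing <- setdiff(panel, colnames(S))
  if (length(missing)) {
    abort(paste0("panel genes missing from the matrix: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(panel) < 5L) {
    warn(sprintf("panel has only %d genes; MI estimates on so few values are unstable",
                 length(panel)))
  }
  X <- log2(S[, panel, drop = FALSE] + 1)
  m <- nrow(X)
  mi <- matrix(0, m, m, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(m)) {
    for (j in i:m) {
      mi[i, j] <- mi[j, i] <- mutual_information(X[i, ], X[j, ])
    }
  }
  pr <- pair_index(rownames(X))
  edges <- tibble(from = pr$cell_i, to = pr$cell_j,
                  mi = mi[cbind(pr$i, pr$j)]) |>
    dplyr::filter(.data$mi > cutoff)
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to")], directed = FALSE,
    vertices = data.frame(name = rownames(X))
  )
  structure(list(nodes = rownames(X), mi = mi, edges = edges, graph = g,
                 cutoff = cutoff, panel = panel,
                 modules = NULL, Q = NA_real_),
            class = "celltype_network")
}

#' @export
print.celltype_network <- function(x, ...) {
  cat(sprintf("<celltype_network> %d nodes, %d edges (MI cutoff %g)\n",
              length(x$nodes), nrow(x$edges), x$cutoff))
  if (!is.null(x$modules)) {
    cat(sprintf("  %d modules, Q = %.4f\n", length(unique(x$modules$module)), x$Q))
  }
  invisible(x)
}

# Q = sum over modules of (e_cc - a_c^2): e_cc the fraction of edges inside
# module c, a_c the fraction of edge endpoints in c
modularity_q <- function(edges, membership) {
  E <- nrow(edges)
  if (E == 0L) return(0)
  mf <- membership[edges$from]
  mt <- membership[edges$to]
  mods <- unique(membership)
  e_cc <- vapply(mods, function(c) sum(mf == c & mt == c) / E, numeric(1))
  a_c <- vapply(mods, function(c) (sum(mf == c) + sum(mt == c)) / (2 * E), numeric(1))
  sum(e_cc - a_c^2)
}

#' Detect network modules by fast-greedy modularity maximization
#'
#' Agglomerative greedy merging on the unweighted edge set; the returned
#' partition is the cut along the merge path with the largest modularity
#' `Q = sum(e_ii - a_i^2)`, recomputed by the package for every candidate
#' cut (ties go to the coarser partition).  An edgeless network yields one
#' module per node with `Q = 0` by convention.
#'
#' @param net a `celltype_network`.
#' @return the network with `modules` (tibble `node`, `module`) and `Q`
#'   filled in.
#' @export
detect_modules <- function(net) {
  stopifnot(inherits(net, "celltype_network"))
  nodes <- net$nodes
  if (nrow(net$edges) == 0L) {
    net$modules <- tibble(node = nodes, module = seq_along(nodes))
    net$Q <- 0
    return(net)
  }
  fc <- igraph::cluster_fast_greedy(net$graph)
  vnames <- igraph::V(net$graph)$name
  cut_q <- function(nc) {
    mem <- igraph::cut_at(fc, no = nc)
    names(mem) <- vnames
    modularity_q(net$edges, mem)
  }
  nc_range <- igraph::count_components(net$graph):length(vnames)
  qs <- vapply(nc_range, cut_q, numeric(1))
  best_nc <- nc_range[min(which(qs >= max(qs) - 1e-12))]   # ties -> coarsest cut
  best_mem <- igraph::cut_at(fc, no = best_nc)
  names(best_mem) <- vnames
  net$modules <- tibble(node = nodes, module = unname(best_mem[nodes]))
  net$Q <- modularity_q(net$edges, setNames(net$modules$module, net$modules$node))
  net
}

#' Annotate modules with their most frequent labels
#'
#' Labels each module with its top `top` most frequent node labels
#' (descending count, ties broken lexicographically).
#'
#' @param net a `celltype_network` after [detect_modules()], or a tibble
#'   with columns `node`, `module`.
#' @param node_labels named character vector mapping every node to a label.
#' @param top number of labels to keep per module.
#' @return tibble `module`, `label`, `count`, `rank`.
#' @export
annotate_modules <- function(net, node_labels, top = 5L) {
  modules <- if (inherits(net, "celltype_network")) {
    if (is.null(net$modules)) abort("run detect_modules() first")
    net$modules
  } else {
    net
  }
  unlabeled <- setdiff(modules$node, names(node_labels))
  if (length(unlabeled)) {
    abort(paste0("nodes without a label: ", paste(unlabeled, collapse = ", ")))
  }
  modules |>
    dplyr::mutate(label = unname(node_labels[.data$node])) |>
    dplyr::count(.data$module, .data$label, name = "count") |>
    dplyr::arrange(.data$module, dplyr::desc(.data$count), .data$label) |>
    dplyr::group_by(.data$module) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= top) |>
    dplyr::ungroup()
}

#' @exportS3Method generics::tidy
tidy.celltype_network <- function(x, ...) {
  out <- x$edges
  if (!is.null(x$modules)) {
    mem <- setNames(x$modules$module, x$modules$node)
    out <- dplyr::mutate(out, module_from = unname(mem[.data$from]),
                         module_to = unname(mem[.data$to]))
  }
  out
}

#' @exportS3Method generics::glance
glance.celltype_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         cutoff = x$cutoff, n_panel = length(x$panel),
         n_modules = if (is.null(x$modules)) NA_integer_ else length(unique(x$modules$module)),
         Q = x$Q)
}

#' Write network artifacts to disk
#'
#' Emits the MI matrix, the edge list, and (if modules were detected)
#' module membership, all as TSV next to `prefix`.
#'
#' @param net a `celltype_network`.
#' @param prefix path prefix; files get `_mi.tsv`, `_edges.tsv`,
#'   `_modules.tsv` suffixes.
#' @return character vector of written paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "celltype_network"))
  paths <- character()
  mi_df <- data.frame(cell_type = rownames(net$mi), net$mi, check.names = FALSE)
  p <- paste0(prefix, "_mi.tsv")
  utils::write.table(mi_df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_edges.tsv")
  utils::write.table(as.data.frame(net$edges), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(net$modules)) {
    p <- paste0(prefix, "_modules.tsv")
    utils::write.table(as.data.frame(net$modules), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
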