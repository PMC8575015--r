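#' Pairwise fold change between cell types
#'
#' For every unordered pair of cell types and every gene, the symmetric
#' pseudocounted fold change
#' \deqn{y_{ijl} = (S_{il}+1)/(S_{jl}+1) \textrm{ if } S_{il} > S_{jl},
#'       \textrm{ else } (S_{jl}+1)/(S_{il}+1),}
#' so that all entries are >= 1 and y is symmetric in (i, j).  The branch
#' condition is written on the raw values (`S_il > S_jl`), which coincides
#' with the ratio test for positive values and stays defined at zero.
#'
#' @param S expression matrix (cell types x genes).
#' @return numeric array `m x m x n`, `y[i, j, l] >= 1`, diagonal 1.
#' @export
fold_change <- function(S) {
  validate_expression_matrix(S)
  m <- nrow(S); n <- ncol(S)
  y <- array(1, dim = c(m, m, n),
             dimnames = list(rownames(S), rownames(S), colnames(S)))
  P1 <- S + 1
  for (l in seq_len(n)) {
    hi <- pmax(outer(P1[, l], P1[, l], "/"), outer(P1[, l], P1[, l], function(a, b) b / a))
    y[, , l] <- hi
  }
  y
}

pair_index <- function(cell_types) {
  m <- length(cell_types)
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble(i = idx[, 1L], j = idx[, 2L],
         cell_i = cell_types[idx[, 1L]], cell_j = cell_types[idx[, 2L]])
}

Z_CLAMP <- 1e-15

new_difference_tensor <- function(zp, pairs, cell_types, genes, theta, y0) {
  structure(list(zp = zp, pairs = pairs, cell_types = cell_types,
                 genes = genes, m = length(cell_types), n = length(genes),
                 theta = theta, y0 = y0),
            class = "difference_tensor")
}

#' Sigmoid-transformed distinguishability scores
#'
#' Maps fold changes into (0, 1) with the logistic transform
#' \deqn{z_{ijl} = 1 / (1 + \exp(-\theta (y_{ijl} - y_0))),}
#' so a fold change near 1 gives z near 0 (at the defaults
#' `theta = 10, y0 = 3`, z(1) is about 2.1e-9) and a fold change of `y0`
#' gives exactly 0.5.  Values are clamped into `[1e-15, 1 - 1e-15]` so
#' downstream logarithms stay finite.
#'
#' @param y either the `m x m x n` fold-change array from [fold_change()],
#'   or an expression matrix (in which case fold changes are computed
#'   pair-at-a-time without materializing the full array).
#' @param theta positive steepness.
#' @param y0 sigmoid midpoint (> 1).
#' @return a `difference_tensor`: the canonical `m(m-1)/2 x n` matrix of
#'   z-scores over unordered pairs, plus the pair index.  Use
#'   [as.array.difference_tensor()] for the symmetric tensor view.
#' @export
sigmoid_difference <- function(y, theta = 10, y0 = 3) {
  stopifnot(theta > 0)
  if (is.matrix(y)) return(difference_tensor(y, theta = theta, y0 = y0))
  stopifnot(is.array(y), length(dim(y)) == 3L, dim(y)[1L] == dim(y)[2L])
  if (any(y < 1)) abort("fold changes must be >= 1")
  m <- dim(y)[1L]
  cts <- dimnames(y)[[1L]] %||% paste0("ct", seq_len(m))
  genes <- dimnames(y)[[3L]] %||% paste0("g", seq_len(dim(y)[3L]))
  pairs <- pair_index(cts)
  zp <- matrix(0, nrow(pairs), dim(y)[3L], dimnames = list(NULL, genes))
  for (p in seq_len(nrow(pairs))) {
    zp[p, ] <- sigmoid_z(y[pairs$i[p], pairs$j[p], ], theta, y0)
  }
  new_difference_tensor(zp, pairs, cts, genes, theta, y0)
}

sigmoid_z <- function(y, theta, y0) {
  z <- 1 / (1 + exp(-theta * (y - y0)))
  pmin(pmax(z, Z_CLAMP), 1 - Z_CLAMP)
}

#' Distinguishability tensor straight from an expression matrix
#'
#' Convenience composition of [fold_change()] and [sigmoid_difference()]
#' that never materializes the `m x m x n` array: each unordered pair's
#' fold-change row is computed and transformed in place.
#'
#' @inheritParams fold_change
#' @inheritParams sigmoid_difference
#' @return a `difference_tensor`.
#' @export
difference_tensor <- function(S, theta = 10, y0 = 3) {
  validate_expression_matrix(S)
  stopifnot(theta > 0)
  pairs <- pair_index(rownames(S))
  P1 <- S + 1
  zp <- matrix(0, nrow(pairs), ncol(S), dimnames = list(NULL, colnames(S)))
  for (p in seq_len(nrow(pairs))) {
    a <- P1[pairs$i[p], ]; b <- P1[pairs$j[p], ]
    zp[p, ] <- sigmoid_z(pmax(a / b, b / a), theta, y0)
  }
  new_difference_tensor(zp, pairs, rownames(S), colnames(S), theta, y0)
}

#' @export
print.difference_tensor <- function(x, ...) {
  cat(sprintf("<difference_tensor> %d cell types, %d genes, %d pairs (theta=%g, y0=%g)\n",
              x$m, x$n, nrow(x$pairs), x$theta, x$y0))
  invisible(x)
}

#' Symmetric tensor view of a difference tensor
#'
#' @param x a `difference_tensor`.
#' @param ... unused.
#' @return `m x m x n` array with `z[i,j,l] = z[j,i,l]`; diagonal entries
#'   hold the (constant) z value at fold change 1.
#' @export
as.array.difference_tensor <- function(x, ...) {
  z1 <- sigmoid_z(1, x$theta, x$y0)
  arr <- array(z1, dim = c(x$m, x$m, x$n),
               dimnames = list(x$cell_types, x$cell_types, x$genes))
  for (p in seq_len(nrow(x$pairs))) {
    arr[x$pairs$i[p], x$pairs$j[p], ] <- x$zp[p, ]
    arr[x$pairs$j[p], x$pairs$i[p], ] <- x$zp[p, ]
  }
  arr
}

#' @exportS3Method tibble::as_tibble
as_tibble.difference_tensor <- function(x, ...) {
  dplyr::bind_cols(
    x$pairs[rep(seq_len(nrow(x$pairs)), times = x$n), ],
    tibble(gene_id = rep(x$genes, each = nrow(x$pairs)), z = as.vector(x$zp))
  )
}

as_selection <- function(zt, w) {
  if (is.character(w)) {
    missing <- setdiff(w, zt$genes)
    if (length(missing)) {
      abort(paste0("panel genes not in the tensor: ", paste(missing, collapse = ", ")))
    }
    w <- as.numeric(zt$genes %in% w)
  }
  if (length(w) != zt$n) abort(sprintf("selection length %d != number of genes %d",
                                       length(w), zt$n))
  if (!all(w %in% c(0, 1))) abort("selection vector must be binary (0/1)")
  w
}

#' Pairwise cell-type distances under a panel
#'
#' For a binary selection `w`, the distance between cell types i and j is
#' `d_ij = sum_l w_l z_ijl`; `D = sum_{i<j} sum_l z_ijl` is the all-gene
#' total (independent of `w`), so `D - sum d_ij >= 0` measures how much of
#' the full pairwise structure the panel discards.
#'
#' @param zt a `difference_tensor`.
#' @param w binary vector of length n, or a character vector of panel genes.
#' @return a `pairwise_distances` list: tibble `pairs` (with column `d`),
#'   scalar `D`, and `selected_total = sum_{i<j} d_ij`.
#' @export
panel_distances <- function(zt, w) {
  w <- as_selection(zt, w)
  d <- as.vector(zt$zp %*% w)
  structure(list(pairs = dplyr::mutate(zt$pairs, d = d),
                 D = sum(zt$zp), selected_total = sum(d)),
            class = "pairwise_distances")
}

#' @export
print.pairwise_distances <- function(x, ...) {
  cat(sprintf("<pairwise_distances> %d pairs; sum d_ij = %.6g of D = %.6g\n",
              nrow(x$pairs), x$selected_total, x$D))
  invisible(x)
}

#' Export the gene-summed pairwise distance matrix
#'
#' Writes the square matrix of `d_ij` values (all genes or a panel) for
#' external clustering or heatmaps.
#'
#' @param zt a `difference_tensor`.
#' @param path output TSV path.
#' @param w optional selection (default: all genes).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(zt, path, w = rep(1, zt$n)) {
  pd <- panel_distances(zt, w)
  M <- matrix(0, zt$m, zt$m, dimnames = list(zt$cell_types, zt$cell_types))
  for (p in seq_len(nrow(pd$pairs))) {
    M[pd$pairs$i[p], pd$pairs$j[p]] <- M[pd$pairs$j[p], pd$pairs$i[p]] <- pd$pairs$d[p]
  }
  df <- data.frame(cell_type = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
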