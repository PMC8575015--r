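#' Jensen-Shannon divergence (base 2)
#'
#' \deqn{JSD(u, v) = \tfrac12 KL(u \| m) + \tfrac12 KL(v \| m), \quad
#'       m = (u + v)/2,}
#' with base-2 logarithms so the value lies in [0, 1]; `0 log 0` terms are
#' zero.  Inputs must be probability vectors (nonnegative, summing to 1
#' within 1e-9).
#'
#' @param u,v probability vectors of equal length.
#' @return divergence in [0, 1].
#' @examples
#' jsd(c(0.5, 0.5), c(1, 0))  # ~0.31128
#' @export
jsd <- function(u, v) {
  if (length(u) != length(v)) abort("u and v must have equal length")
  if (any(u < 0) || any(v < 0)) abort("probability vectors must be nonnegative")
  if (abs(sum(u) - 1) > 1e-9 || abs(sum(v) - 1) > 1e-9) {
    abort("probability vectors must sum to 1 (tolerance 1e-9)")
  }
  mid <- (u + v) / 2
  kl <- function(p, q) {
    i <- p > 0
    sum(p[i] * log2(p[i] / q[i]))
  }
  0.5 * kl(u, mid) + 0.5 * kl(v, mid)
}

#' Observed and idealized expression patterns for one gene in one cell type
#'
#' The observed vector contrasts the expression of gene `l` in cell type
#' `j` with a background summary, the third quartile of the gene's
#' expression across all cell types (including `j`; linear interpolation
#' between order statistics).  Both elements take a pseudocount of 1 before
#' normalization, so silent genes give (0.5, 0.5) rather than 0/0.  The
#' idealized pattern is (1, 0): all mass in cell type `j`, none in the
#' background.
#'
#' @param S expression matrix.
#' @param j cell-type index or name.
#' @param l gene index or name.
#' @return list with probability vectors `u` (observed) and `v` (ideal) and
#'   the background value `b`.
#' @export
observed_ideal_vectors <- function(S, j, l) {
  validate_expression_matrix(S)
  b <- unname(quantile(S[, l], 0.75))
  raw <- c(S[j, l] + 1, b + 1)
  list(u = raw / sum(raw), v = c(1, 0), b = b)
}

SS_FLOOR <- 1e-12

#' Cell type-specificity scores for every gene
#'
#' For each gene `l` and cell type `j`, `ds_jl` is the base-2
#' Jensen-Shannon divergence between the observed pattern (gene's
#' expression in `j` versus the third-quartile background) and the
#' idealized single-cell-type pattern; the score is
#' `ss_jl = -log10(ds_jl)` with `ds` floored at 1e-12 (so `ss` caps at 12),
#' and the gene-level score is `ss_l = max_j ss_jl`.  A low divergence —
#' expression far above background — gives a high score.
#'
#' @param S expression matrix (cell types x genes).
#' @return a `specificity_table`: matrices `ds` and `ss` (cell types x
#'   genes), vector `ss_gene` (per-gene maxima), vector `background`
#'   (per-gene third quartile).
#' @export
specificity_scores <- function(S) {
  validate_expression_matrix(S)
  b <- apply(S, 2L, quantile, probs = 0.75)
  # closed form of jsd(u, (1,0)) for u = (p, 1-p): the v-side KL collapses
  # to log2(2/(p+1)) and the (1-p) term of the u-side KL to (1-p)*log2(2)
  ds <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  for (l in seq_len(ncol(S))) {
    p <- (S[, l] + 1) / (S[, l] + 1 + b[l] + 1)
    mid1 <- (p + 1) / 2
    mid2 <- (1 - p) / 2
    klu <- p * log2(p / mid1) + ifelse(1 - p > 0, (1 - p) * log2((1 - p) / mid2), 0)
    klv <- log2(1 / mid1)
    ds[, l] <- 0.5 * klu + 0.5 * klv
  }
  ds <- pmax(ds, SS_FLOOR)
  ss <- -log10(ds)
  structure(list(ds = ds, ss = ss, ss_gene = apply(ss, 2L, max),
                 background = b, cell_types = rownames(S),
                 genes = colnames(S)),
            class = "specificity_table")
}

#' @export
print.specificity_table <- function(x, ...) {
  cat(sprintf("<specificity_table> %d cell types x %d genes; top gene: %s (ss=%.3f)\n",
              length(x$cell_types), length(x$genes),
              x$genes[which.max(x$ss_gene)], max(x$ss_gene)))
  invisible(x)
}

#' @describeIn specificity_scores long tibble with one row per (cell type,
#'   gene): columns `cell_type`, `gene_id`, `ds`, `ss`, `ss_gene`.
#' @param x a `specificity_table`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.specificity_table <- function(x, ...) {
  tibble(
    cell_type = rep(x$cell_types, times = length(x$genes)),
    gene_id = rep(x$genes, each = length(x$cell_types)),
    ds = as.vector(x$ds),
    ss = as.vector(x$ss),
    ss_gene = rep(unname(x$ss_gene), each = length(x$cell_types))
  )
}

#' Assign marker genes to cell types by specificity
#'
#' Gene `l` is assigned to cell type `j` whenever `ss_jl >= cutoff`
#' (boundary inclusive); the published default cutoff is 1.3, i.e.
#' `ds_jl <= 10^-1.3 ~ 0.05`.
#'
#' @param spec a `specificity_table`.
#' @param cutoff nonnegative score cutoff.
#' @return tibble with columns `gene_id`, `cell_type`, `ss`, one row per
#'   assignment, sorted by gene then descending score.  Genes with no
#'   assignment do not appear.
#' @export
assign_markers <- function(spec, cutoff = 1.3) {
  stopifnot(inherits(spec, "specificity_table"), cutoff >= 0)
  hits <- which(spec$ss >= cutoff, arr.ind = TRUE)
  out <- tibble(
    gene_id = spec$genes[hits[, 2L]],
    cell_type = spec$cell_types[hits[, 1L]],
    ss = spec$ss[hits]
  )
  dplyr::arrange(out, .data$gene_id, dplyr::desc(.data$ss))
}

#' Top-k single-gene baseline panel
#'
#' The standard single-gene comparator: rank genes within each cell type by
#' `ss_jl`, take the per-cell-type best genes, pool, and keep the top `k`
#' distinct genes by their gene-level score (ties broken lexicographically).
#' Provided as a baseline utility, not as part of the optimization model.
#'
#' @param spec a `specificity_table`.
#' @param k panel size.
#' @return character vector of `k` gene IDs.
#' @export
single_gene_baseline <- function(spec, k) {
  stopifnot(inherits(spec, "specificity_table"), k >= 1)
  ord <- order(-spec$ss_gene, spec$genes)
  head(spec$genes[ord], k)
}
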