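#' Validate an expression matrix
#'
#' The canonical container for expression data in this package is a plain
#' numeric matrix with `m >= 2` cell-type rows and `n >= 1` gene columns,
#' unique dimnames, and finite nonnegative entries (any nonnegative unit,
#' e.g. FPKM or TPM; one profile per cell type — collapse replicates by
#' averaging before calling in).
#'
#' @param S numeric matrix, cell types in rows, genes in columns, with
#'   unique row and column names.
#' @return `S` invisibly, after validation.
#' @export
validate_expression_matrix <- function(S) {
  if (!is.matrix(S) || !is.numeric(S)) {
    abort("expression matrix must be a numeric matrix (cell types x genes)")
  }
  if (nrow(S) < 2L) abort("need at least 2 cell types (rows)")
  if (ncol(S) < 1L) abort("need at least 1 gene (column)")
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    abort("expression matrix must have cell-type rownames and gene colnames")
  }
  dup_ct <- rownames(S)[duplicated(rownames(S))]
  if (length(dup_ct)) {
    abort(paste0("duplicated cell-type IDs: ", paste(unique(dup_ct), collapse = ", ")))
  }
  dup_g <- colnames(S)[duplicated(colnames(S))]
  if (length(dup_g)) {
    abort(paste0("duplicated gene IDs: ", paste(unique(dup_g), collapse = ", ")))
  }
  bad <- which(!is.finite(S) | S < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    abort(sprintf(
      "expression values must be finite and >= 0; offending cell: cell type '%s', gene '%s' (value %s)",
      rownames(S)[i], colnames(S)[j], format(S[i, j])
    ))
  }
  invisible(S)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV (default) or CSV file with one header row and one leading ID
#' column.  The on-disk default layout is genes in rows and cell types in
#' columns; internally the matrix is always oriented cell types x genes.
#'
#' @param path file path; delimiter is inferred from the extension
#'   (`.csv` comma, anything else tab).
#' @param orientation `"genes_in_rows"` (default) or `"cell_types_in_rows"`,
#'   describing the file layout.
#' @return validated numeric matrix, cell types x genes.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression_matrix(example_expression(), tf)
#' em <- read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows", "cell_types_in_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("expected an ID column plus at least one data column")
  ids <- as.character(df[[1L]])
  body <- df[-1L]
  for (cn in names(body)) {
    v <- body[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) & !anyNA(v)) {
        row <- which(is.na(num))[1L]
        abort(sprintf("non-numeric cell at row ID '%s', column '%s': '%s'",
                      ids[row], cn, v[row]))
      }
      body[[cn]] <- num
    }
  }
  M <- as.matrix(body)
  rownames(M) <- ids
  if (orientation == "genes_in_rows") M <- t(M)
  validate_expression_matrix(M)
  M
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()]: genes in rows, cell types in
#' columns, tab-separated unless the path ends in `.csv`.  Values are
#' written with 12 significant digits so read/write round-trips are
#' value-identical at that precision.
#'
#' @param S expression matrix (cell types x genes).
#' @param path output path.
#' @param id_column header name for the gene ID column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(S, path, id_column = "gene_id") {
  validate_expression_matrix(S)
  G <- t(S)
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   id = rownames(G))
  names(df) <- id_column
  for (ct in colnames(G)) df[[ct]] <- signif(G[, ct], 12)
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Subset an expression matrix to a gene list
#'
#' Restricts the matrix to the genes in `gene_list`, preserving the list's
#' order.  IDs absent from the matrix are reported with a warning; an empty
#' intersection is an error.
#'
#' @param S expression matrix (cell types x genes).
#' @param gene_list character vector of gene IDs (e.g. a surface-marker or
#'   transcription-factor list).
#' @return the restricted expression matrix.
#' @export
subset_genes <- function(S, gene_list) {
  validate_expression_matrix(S)
  if (!length(gene_list)) abort("gene_list is empty")
  gene_list <- as.character(gene_list)
  found <- gene_list[gene_list %in% colnames(S)]
  missing <- setdiff(gene_list, colnames(S))
  if (!length(found)) {
    abort(paste0("none of the requested genes are present: ",
                 paste(head(missing, 10L), collapse = ", ")))
  }
  if (length(missing)) {
    warn(paste0("gene IDs not found and dropped: ", paste(missing, collapse = ", ")))
  }
  S[, found, drop = FALSE]
}

#' Read a plain-text gene list
#'
#' One ID per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of IDs.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Expression matrix in long (tidy) form
#'
#' @param S expression matrix.
#' @return tibble with columns `cell_type`, `gene_id`, `expression`.
#' @export
expression_long <- function(S) {
  validate_expression_matrix(S)
  tibble(
    cell_type = rep(rownames(S), times = ncol(S)),
    gene_id = rep(colnames(S), each = nrow(S)),
    expression = as.vector(S)
  )
}

#' A small worked expression matrix
#'
#' Four cell types by six genes, with two clean markers (`mk_ab` high in the
#' first two cell types, `mk_c` high in the third) and four background
#' genes.  Used throughout the examples.
#'
#' @return expression matrix, 4 x 6.
#' @export
example_expression <- function() {
  S <- rbind(
    A = c(mk_ab = 80, mk_c = 10, bg1 = 12, bg2 = 9,  bg3 = 11, bg4 = 10),
    B = c(80, 10, 10, 11, 10, 9),
    C = c(10, 80, 9,  10, 12, 10),
    D = c(10, 10, 11, 10, 9,  12)
  )
  colnames(S) <- c("mk_ab", "mk_c", "bg1", "bg2", "bg3", "bg4")
  S
}

#' Run configuration
#'
#' Bundles the method's tunable parameters with their published defaults:
#' sigmoid steepness `theta = 10` and midpoint `y0 = 3`, panel size `k`,
#' slack penalty `lambda`, specificity weight `mu`, criterion-1 distance
#' threshold `T = 0.5`, criterion-2/3 distinguishability threshold
#' `z_threshold = 0.5`, mutual-information edge cutoff `mi_cutoff = 0.25`,
#' marker-assignment `specificity_cutoff = 1.3`, and an RNG `seed`.
#'
#' @param theta positive sigmoid steepness.
#' @param y0 sigmoid midpoint on the fold-change scale (> 1).
#' @param k panel size (positive integer; must be <= n at solve time).
#' @param lambda nonnegative slack penalty.
#' @param mu nonnegative specificity weight.
#' @param c1_threshold criterion-1 threshold on the pairwise panel distance.
#' @param z_threshold criterion-2/3 threshold on z, in (0, 1).
#' @param mi_cutoff mutual-information edge cutoff.
#' @param specificity_cutoff marker-to-cell-type assignment cutoff.
#' @param seed integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(theta = 10, y0 = 3, k = 8L, lambda = 100, mu = 10,
                       c1_threshold = 0.5, z_threshold = 0.5,
                       mi_cutoff = 0.25, specificity_cutoff = 1.3,
                       seed = 1L) {
  stopifnot(theta > 0, y0 > 1, k >= 1, lambda >= 0, mu >= 0,
            c1_threshold > 0, z_threshold > 0, z_threshold < 1,
            mi_cutoff >= 0, specificity_cutoff >= 0)
  structure(list(theta = theta, y0 = y0, k = as.integer(k), lambda = lambda,
                 mu = mu, c1_threshold = c1_threshold,
                 z_threshold = z_threshold, mi_cutoff = mi_cutoff,
                 specificity_cutoff = specificity_cutoff,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the published defaults.
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}
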