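#' Write a panel report (TSV + JSON sidecar)
#'
#' The TSV lists the panel: one row per gene with positive weight (all `k`
#' genes for a binary solution; the support, descending by weight, for an
#' LP solution), its weight, gene-level specificity `ss_l`, the best cell
#' type (`argmax_j ss_jl`) and every cell type assigned at the specificity
#' cutoff.  A JSON sidecar (same path with `.json` appended) records the
#' objective, parameters, solver status and — for binary panels — the
#' three accuracy criteria.
#'
#' @param solution a `panel_solution` or `lp_solution`.
#' @param spec a `specificity_table` over the same genes.
#' @param path output TSV path.
#' @param specificity_cutoff assignment cutoff (default 1.3).
#' @return `path`, invisibly.
#' @export
write_panel_report <- function(solution, spec, path, specificity_cutoff = 1.3) {
  stopifnot(inherits(spec, "specificity_table"))
  if (inherits(solution, "lp_solution")) {
    if (solution$status != "optimal") abort("cannot report an unsolved problem")
    w <- solution$w
    genes <- solution$selected     # already descending by weight
    params <- list(lambda = solution$model$lambda, mu = solution$model$mu,
                   model = "lp")
    criteria <- NULL
    objective <- solution$objective
    status <- solution$status
  } else if (inherits(solution, "panel_solution")) {
    if (!solution$status %in% c("optimal", "feasible")) {
      abort("cannot report an unsolved problem")
    }
    w <- solution$w
    genes <- solution$selected
    params <- list(k = solution$k, lambda = solution$lambda,
                   mu = solution$mu, model = "mip")
    cr <- panel_criteria(solution$problem$zt, solution$w)
    criteria <- list(C1 = cr$C1, C2 = cr$C2, C3 = cr$C3)
    objective <- solution$objective
    status <- solution$status
  } else {
    abort("solution must be a panel_solution or lp_solution")
  }
  idx <- match(genes, spec$genes)
  if (anyNA(idx)) abort("panel genes missing from the specificity table")
  best_ct <- spec$cell_types[apply(spec$ss[, idx, drop = FALSE], 2L, which.max)]
  assigned <- vapply(idx, function(l) {
    paste(spec$cell_types[spec$ss[, l] >= specificity_cutoff], collapse = ";")
  }, character(1))
  df <- data.frame(gene_id = genes, weight = unname(w[genes]),
                   ss_l = unname(spec$ss_gene[idx]), best_cell_type = best_ct,
                   assigned_cell_types = assigned, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(objective = objective, status = status, parameters = params,
                  specificity_cutoff = specificity_cutoff, criteria = criteria)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read back a panel report
#'
#' @param path TSV path written by [write_panel_report()].
#' @return list with `panel` (tibble) and `meta` (parsed JSON sidecar).
#' @export
read_panel_report <- function(path) {
  panel <- as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                       check.names = FALSE,
                                       stringsAsFactors = FALSE,
                                       colClasses = c(assigned_cell_types = "character")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(panel = panel, meta = meta)
}
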