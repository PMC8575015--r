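# Dense-simplex LPs occasionally hit a degenerate (singular) basis; a tiny
# deterministic objective perturbation resolves the tie without moving the
# optimum beyond ~1e-7 relative.  Internal helper shared by the LP paths.
linprog_robust <- function(cc, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                           maxiter = 1000L) {
  scale <- max(abs(cc), 1)
  for (eps in c(0, 1e-9, 1e-7)) {
    cc_try <- cc + eps * scale * seq_along(cc) / length(cc)
    res <- tryCatch(
      pracma::linprog(cc_try, A = A, b = b, Aeq = Aeq, beq = beq,
                      maxiter = maxiter),
      error = function(e) e
    )
    if (!inherits(res, "error") && !is.null(res$x) && all(is.finite(res$x))) {
      res$fval <- sum(cc * res$x)   # report the unperturbed objective
      return(res)
    }
  }
  res
}
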