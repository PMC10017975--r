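# Wald tests of fixed-effect terms from a fitted MET mixed model.

#' Wald tests for fixed-effect terms
#'
#' For each fixed term, tests the joint nullity of its coefficient
#' subvector conditional on all other terms (Type-III-like): the statistic
#' is \eqn{W = \hat b' C^{-1} \hat b} with \eqn{C} the corresponding block
#' of \eqn{(X'\hat V^{-1}X)^{-1}}, referred to a chi-square distribution
#' with df equal to the rank of the subvector.  A sequential mode refits
#' nested models term by term and tests each addition.
#'
#' @param fit a `met_fit` object from [reml_fit()].
#' @param terms character vector of term labels to test (default: all
#'   non-intercept fixed terms).
#' @param mode `"conditional"` (default) or `"sequential"`.
#' @return A `data.frame` with columns `term`, `wald`, `df`, `p`.  Terms
#'   whose columns were all aliased get `df = 0` and missing `p`.
#' @export
wald_tests <- function(fit, terms = NULL, mode = c("conditional",
                                                   "sequential")) {
  mode <- match.arg(mode)
  labels <- fit$term_labels
  terms <- terms %||% labels
  bad <- setdiff(terms, labels)
  if (length(bad) > 0)
    stop_metgxe("unknown term(s): ", paste(bad, collapse = ", "))
  if (mode == "sequential") return(wald_sequential(fit, terms))
  rows <- lapply(terms, function(tm) {
    j <- which(fit$assign == match(tm, labels))
    if (length(j) == 0)
      return(data.frame(term = tm, wald = NA_real_, df = 0L, p = NA_real_))
    b <- fit$beta[j]
    C <- fit$cov_beta[j, j, drop = FALSE]
    e <- eigen(C, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    rank <- sum(pos)
    if (rank == 0)
      return(data.frame(term = tm, wald = NA_real_, df = 0L, p = NA_real_))
    z <- crossprod(e$vectors[, pos, drop = FALSE], b)
    W <- sum(z^2 / e$values[pos])
    data.frame(term = tm, wald = W, df = rank,
               p = pchisq(W, rank, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Sequential (added-in-order) Wald tests: refit with terms added one at a
# time, each time testing the newly added term conditional on the previous.
wald_sequential <- function(fit, terms) {
  labels <- fit$term_labels
  pheno <- fit$design$data
  class(pheno) <- c("met_pheno", "data.frame")
  rows <- lapply(terms, function(tm) {
    upto <- labels[seq_len(match(tm, labels))]
    spec_k <- fit$spec
    spec_k$fixed <- upto
    fit_k <- reml_fit(build_design(pheno, spec_k))
    wald_tests(fit_k, terms = tm, mode = "conditional")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
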