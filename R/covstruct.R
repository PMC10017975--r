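# Parametrized covariance structures for the genetic interaction matrix
# (environment x environment) and the residual (season x season within
# location).  All structures are parametrized on an unconstrained scale
# (log-variances, Cholesky factors, logistic-mapped correlations) so that the
# materialized matrix is symmetric positive semi-definite by construction.

GXE_STRUCTURES <- c("none", "iid", "diag", "cs_het", "fa1", "us")
RESID_STRUCTURES <- c("iid", "diag_env", "us_season")

# Returns list(npar, init(vscale), mat(par) -> E x E matrix, par_names).
make_gxe_struct <- function(tag, E) {
  tag <- match.arg(tag, GXE_STRUCTURES)
  switch(tag,
    none = list(tag = tag, npar = 0L,
                init = function(v) numeric(0),
                mat = function(par) NULL,
                par_names = character(0)),
    iid = list(tag = tag, npar = 1L,
               init = function(v) log(v),
               mat = function(par) diag(rep(exp(par[1]), E)),
               par_names = "log_vge"),
    diag = list(tag = tag, npar = E,
                init = function(v) rep(log(v), E),
                mat = function(par) diag(exp(par), nrow = E),
                par_names = paste0("log_vge", seq_len(E))),
    cs_het = {
      # common correlation rho in (-1/(E-1), 1) ensures PSD of D R D
      lo <- -1 / (E - 1) + 1e-6
      list(tag = tag, npar = E + 1L,
           init = function(v) c(rep(log(v) / 2, E),
                                qlogis((0.3 - lo) / (1 - lo))),
           mat = function(par) {
             s <- exp(par[seq_len(E)])
             rho <- lo + (1 - lo) * plogis(par[E + 1L])
             R <- matrix(rho, E, E); diag(R) <- 1
             outer(s, s) * R
           },
           par_names = c(paste0("log_sd", seq_len(E)), "rho_raw"))
    },
    fa1 = list(tag = tag, npar = 2L * E,
               init = function(v) c(rep(sqrt(v / 2), E), rep(log(v / 2), E)),
               mat = function(par) {
                 lam <- par[seq_len(E)]
                 psi <- exp(par[E + seq_len(E)])
                 tcrossprod(lam) + diag(psi, nrow = E)
               },
               par_names = c(paste0("lambda", seq_len(E)),
                             paste0("log_psi", seq_len(E)))),
    us = {
      npar <- E * (E + 1L) / 2L
      idx <- which(lower.tri(diag(E), diag = TRUE), arr.ind = TRUE)
      diag_pos <- which(idx[, 1] == idx[, 2])
      list(tag = tag, npar = npar,
           init = function(v) {
             par <- numeric(npar)
             par[diag_pos] <- log(v) / 2
             par
           },
           mat = function(par) {
             L <- matrix(0, E, E)
             L[lower.tri(L, diag = TRUE)] <- par
             diag(L) <- exp(diag(L))
             tcrossprod(L)
           },
           par_names = paste0("chol", seq_len(npar)))
    })
}

# Residual structure.  `loc_seasons` is a named list: for each location the
# ordered vector of its environment indices (one per season).  Materializes
# to per-environment variances plus, for us_season, per-location season
# covariance matrices (NULL means zero covariance between seasons).
make_resid_struct <- function(tag, n_env, loc_seasons) {
  tag <- match.arg(tag, RESID_STRUCTURES)
  switch(tag,
    iid = list(tag = tag, npar = 1L,
               init = function(v) log(v),
               mat = function(par) list(vars = rep(exp(par[1]), n_env),
                                        loc_mats = NULL),
               par_names = "log_ve"),
    diag_env = list(tag = tag, npar = n_env,
                    init = function(v) rep(log(v), n_env),
                    mat = function(par) list(vars = exp(par),
                                             loc_mats = NULL),
                    par_names = paste0("log_ve", seq_len(n_env))),
    us_season = {
      sizes <- vapply(loc_seasons, length, integer(1))
      npars <- sizes * (sizes + 1L) / 2L
      offs <- cumsum(c(0L, npars))
      list(tag = tag, npar = sum(npars),
           init = function(v) {
             unlist(lapply(sizes, function(s) {
               par <- numeric(s * (s + 1L) / 2L)
               idx <- which(lower.tri(diag(s), diag = TRUE), arr.ind = TRUE)
               par[idx[, 1] == idx[, 2]] <- log(v) / 2
               par
             }), use.names = FALSE)
           },
           mat = function(par) {
             loc_mats <- vector("list", length(sizes))
             names(loc_mats) <- names(loc_seasons)
             vars <- numeric(n_env)
             for (k in seq_along(sizes)) {
               s <- sizes[k]
               L <- matrix(0, s, s)
               L[lower.tri(L, diag = TRUE)] <-
                 par[(offs[k] + 1L):offs[k + 1L]]
               diag(L) <- exp(diag(L))
               M <- tcrossprod(L)
               loc_mats[[k]] <- M
               vars[loc_seasons[[k]]] <- diag(M)
             }
             list(vars = vars, loc_mats = loc_mats)
           },
           par_names = paste0("rchol", seq_len(sum(npars))))
    })
}
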