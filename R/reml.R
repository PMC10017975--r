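# REML estimation.  The marginal covariance V of the observations is block
# diagonal by genotype: V_i = vg * J + Vge[env, env] + R_i, where R_i has
# season covariance within each individual tree.  The restricted
# log-likelihood is accumulated over genotype blocks; genotypes sharing an
# identical layout share one Cholesky factorization, and their fixed-matrix
# cross-products are evaluated as single BLAS calls on stacked matrices.

# Method-of-moments starting values (vg, interaction, residual) from the
# genotype x environment cell-mean decomposition: the pooled within-cell
# variance estimates the residual, the mean between-environment covariance
# of genotype deviations estimates vg, and the remainder of the deviation
# variance estimates the interaction.  Clipped away from zero so the
# log-parametrized search starts in the interior.
moment_start <- function(design) {
  df <- design$data
  y <- design$y
  vtot <- var(y)
  lo <- 0.02 * vtot
  cell <- interaction(df$genotype_id, df$env, drop = TRUE)
  cell_mean <- c(tapply(y, cell, mean))
  df_res <- length(y) - nlevels(cell)
  rss <- sum((y - cell_mean[cell])^2)
  ve0 <- if (df_res > 0 && rss > 0) rss / df_res else vtot / 3
  M <- tapply(y, list(df$genotype_id, df$env), mean)
  D <- sweep(M, 2, colMeans(M, na.rm = TRUE))
  r_bar <- max(1, length(y) / nlevels(cell))
  vg0 <- NA_real_
  if (ncol(D) > 1) {
    C <- suppressWarnings(cov(D, use = "pairwise.complete.obs"))
    vg0 <- mean(C[upper.tri(C)], na.rm = TRUE)
    vdiag <- mean(diag(C), na.rm = TRUE)
  } else {
    vdiag <- var(D[, 1], na.rm = TRUE)
  }
  if (!is.finite(vg0)) vg0 <- vdiag - ve0 / r_bar
  vge0 <- vdiag - max(vg0, 0) - ve0 / r_bar
  clip <- function(v) min(max(v, lo, na.rm = TRUE), vtot)
  c(g = clip(vg0), ge = clip(vge0), e = clip(ve0))
}

# Assemble the b x b covariance block for a layout pattern.
block_cov <- function(pat, vg, Vge, resid) {
  b <- pat$b
  Vb <- matrix(if (is.null(vg)) 0 else vg, b, b)
  if (!is.null(Vge)) Vb <- Vb + Vge[pat$env_b, pat$env_b, drop = FALSE]
  if (is.null(resid$loc_mats)) {
    diag(Vb) <- diag(Vb) + resid$vars[pat$env_b]
  } else {
    for (t in unique(pat$tree_b)) {
      idx <- which(pat$tree_b == t)
      M <- resid$loc_mats[[pat$loc_b[idx[1]]]]
      Vb[idx, idx] <- Vb[idx, idx] +
        M[pat$season_b[idx], pat$season_b[idx], drop = FALSE]
    }
  }
  Vb
}

# Core REML pass.  Returns the restricted log-likelihood (including the
# (n-p) log 2pi constant) together with the GLS quantities needed for
# estimates, Wald tests and BLUPs.
reml_core <- function(design, vg, Vge, resid, want_blups = FALSE) {
  p <- design$p
  XtViX <- matrix(0, p, p)
  XtViy <- numeric(p)
  ytViy <- 0
  logdetV <- 0
  chols <- if (want_blups) vector("list", length(design$patterns))
  for (k in seq_along(design$patterns)) {
    pat <- design$patterns[[k]]
    Vb <- block_cov(pat, vg, Vge, resid)
    R <- chol(Vb)
    if (want_blups) chols[[k]] <- R
    logdetV <- logdetV + 2 * pat$m * sum(log(diag(R)))
    U <- backsolve(R, pat$Bmat, transpose = TRUE)
    Umat <- matrix(aperm(array(U, c(pat$b, p, pat$m)), c(1, 3, 2)),
                   nrow = pat$b * pat$m)
    W <- backsolve(R, pat$Y, transpose = TRUE)
    XtViX <- XtViX + crossprod(Umat)
    XtViy <- XtViy + drop(crossprod(Umat, as.vector(W)))
    ytViy <- ytViy + sum(W * W)
  }
  RX <- tryCatch(chol(XtViX), error = function(e)
    stop_metgxe("singular X'V^-1X: the fixed part is rank deficient for ",
                "this covariance; reduce the fixed model"))
  logdetXtViX <- 2 * sum(log(diag(RX)))
  beta <- backsolve(RX, backsolve(RX, XtViy, transpose = TRUE))
  ytPy <- ytViy - sum(XtViy * beta)
  n <- design$n
  ll <- -0.5 * (logdetV + logdetXtViX + ytPy + (n - p) * log(2 * pi))
  out <- list(loglik = ll, beta = drop(beta), RX = RX,
              logdetV = logdetV, ytPy = ytPy)
  if (want_blups) {
    blup_g <- numeric(design$n_geno)
    blup_ge <- matrix(0, design$n_geno, design$n_env)
    for (k in seq_along(design$patterns)) {
      pat <- design$patterns[[k]]
      R <- chols[[k]]
      resm <- matrix(design$y[pat$obs_mat] -
                       design$X[as.vector(pat$obs_mat), , drop = FALSE] %*%
                       beta, nrow = pat$b)
      Wres <- backsolve(R, backsolve(R, resm, transpose = TRUE))
      if (!is.null(vg)) blup_g[pat$genotypes] <- vg * colSums(Wres)
      if (!is.null(Vge))
        blup_ge[pat$genotypes, ] <-
          t(Vge[, pat$env_b, drop = FALSE] %*% Wres)
    }
    out$blup_g <- blup_g
    out$blup_ge <- blup_ge
  }
  out
}

#' Restricted log-likelihood at given covariance components
#'
#' Evaluates the REML criterion
#' \deqn{-\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py + (n-p)\log 2\pi\right]}
#' with \eqn{V} assembled from the genotype main variance `vg`, the
#' environment x environment interaction covariance `Vge`, and the residual
#' specification, exploiting the block structure of \eqn{V} by genotype.
#'
#' @param design a [build_design()] bundle.
#' @param vg genotype main variance (scalar), or `NULL` if absent.
#' @param Vge E x E interaction covariance matrix, or `NULL` if absent.
#' @param resid_vars per-environment residual variances (length E or scalar,
#'   recycled).
#' @param resid_loc_mats optional named list of season x season residual
#'   covariance matrices per location (overrides `resid_vars` diagonals and
#'   adds season covariance within trees).
#' @return the restricted log-likelihood (numeric scalar).
#' @export
restricted_loglik <- function(design, vg = NULL, Vge = NULL,
                              resid_vars = 1, resid_loc_mats = NULL) {
  vars <- rep_len(resid_vars, design$n_env)
  if (!is.null(resid_loc_mats)) {
    for (l in seq_along(design$loc_levels))
      vars[design$loc_seasons[[l]]] <-
        diag(resid_loc_mats[[design$loc_levels[l]]])
  }
  reml_core(design, vg, Vge,
            list(vars = vars, loc_mats = resid_loc_mats))$loglik
}

#' Fit a MET mixed model by REML
#'
#' Maximizes the restricted log-likelihood over an unconstrained
#' parametrization of the covariance components (log-variances; Cholesky
#' factors for unstructured blocks) with quasi-Newton (BFGS) search.  Up to
#' three default initializations (different splits of the raw phenotypic
#' variance) are tried before non-convergence is declared.  Variance
#' components that collapse towards zero are reported with a boundary flag,
#' not an error.
#'
#' @param design a [build_design()] bundle (or a [met_pheno] table, in which
#'   case `spec` must be supplied and the design is built internally).
#' @param spec the [met_model_spec] (taken from the design when omitted).
#' @param control list: `tol` (relative log-likelihood convergence
#'   tolerance, default `1e-8`), `maxit` (default 400), `grad_tol` (gradient
#'   norm recorded at the optimum and compared against this for the
#'   convergence record, default `1e-4`).
#' @return A `met_fit` object with elements `beta` (fixed effects),
#'   `cov_beta`, `vg`, `Vge`, `resid`, `loglik`, `convergence`, `blup_g`,
#'   `blup_ge`, plus the design.
#' @export
reml_fit <- function(design, spec = NULL, control = list()) {
  if (inherits(design, "met_pheno")) {
    if (is.null(spec)) stop_metgxe("spec required when passing a table")
    design <- build_design(design, spec)
  }
  spec <- spec %||% design$spec
  ctl <- list(tol = 1e-8, maxit = 400, grad_tol = 1e-4)
  ctl[names(control)] <- control

  E <- design$n_env
  gxe_s <- make_gxe_struct(spec$gxe, E)
  res_s <- make_resid_struct(spec$residual, E, design$loc_seasons)
  n_g <- as.integer(spec$genotype)
  npar <- n_g + gxe_s$npar + res_s$npar
  i_g <- seq_len(n_g)
  i_ge <- n_g + seq_len(gxe_s$npar)
  i_r <- n_g + gxe_s$npar + seq_len(res_s$npar)

  materialize <- function(theta) {
    list(vg = if (n_g) exp(theta[i_g]) else NULL,
         Vge = gxe_s$mat(theta[i_ge]),
         resid = res_s$mat(theta[i_r]))
  }
  negll <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    comp <- materialize(theta)
    tryCatch(-reml_core(design, comp$vg, comp$Vge, comp$resid)$loglik,
             error = function(e) 1e10)
  }

  vtot <- var(design$y)
  starts <- c(list(moment_start(design)),
              lapply(list(c(g = 1, ge = 1, e = 1) / 3,
                          c(g = 0.5, ge = 0.1, e = 0.4),
                          c(g = 0.1, ge = 0.3, e = 0.6)),
                     function(sp) vtot * sp))
  make_init <- function(v) {
    if (!n_g) v["ge"] <- v["ge"] + v["g"]
    c(if (n_g) log(v["g"]),
      if (gxe_s$npar) gxe_s$init(v["ge"]),
      if (res_s$npar) res_s$init(v["e"]))
  }

  best <- NULL
  restarts <- 0L
  for (s in seq_along(starts)) {
    init <- unname(make_init(starts[[s]]))
    opt <- tryCatch(
      optim(init, negll, method = "BFGS",
            control = list(reltol = ctl$tol, maxit = ctl$maxit)),
      error = function(e) NULL)
    if (is.null(opt)) { restarts <- restarts + 1L; next }
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0 && opt$value < 1e9) { best <- opt; break }
    restarts <- restarts + 1L
  }
  if (is.null(best) || best$value >= 1e9)
    stop_metgxe("REML did not converge from any initialization")
  # polish: a short second quasi-Newton run at machine-precision tolerance
  # sharpens the parameter estimates beyond the loglik stopping rule
  polish <- tryCatch(
    optim(best$par, negll, method = "BFGS",
          control = list(reltol = 1e-15, maxit = 50)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    polish$convergence <- best$convergence
    polish$counts <- best$counts + polish$counts
    best <- polish
  }
  converged <- best$convergence == 0
  if (!converged)
    warning("REML iteration limit reached; returning best iterate",
            call. = FALSE)

  theta <- best$par
  comp <- materialize(theta)
  core <- reml_core(design, comp$vg, comp$Vge, comp$resid, want_blups = TRUE)
  grad <- num_grad(negll, theta)
  cov_beta <- chol2inv(core$RX)
  dimnames(cov_beta) <- list(colnames(design$X), colnames(design$X))

  # boundary detection on variance-scale parameters (log-parametrized)
  var_par <- c(if (n_g) i_g,
               if (spec$gxe %in% c("iid", "diag")) i_ge,
               if (spec$residual %in% c("iid", "diag_env")) i_r)
  boundary <- length(var_par) > 0 &&
    any(exp(theta[var_par]) < 1e-8 * max(vtot, 1e-12))

  fit <- structure(list(
    spec = spec, theta = theta,
    vg = if (n_g) unname(comp$vg) else NULL,
    Vge = comp$Vge, resid = c(comp$resid, list(tag = spec$residual)),
    loglik = core$loglik,
    beta = setNames(core$beta, colnames(design$X)),
    cov_beta = cov_beta,
    assign = design$assign, term_labels = design$term_labels,
    blup_g = setNames(core$blup_g, design$geno_levels),
    blup_ge = {
      bge <- core$blup_ge
      dimnames(bge) <- list(design$geno_levels, design$env_levels)
      bge
    },
    convergence = list(converged = converged, restarts = restarts,
                       iterations = best$counts[["function"]],
                       grad_norm = sqrt(sum(grad^2)),
                       grad_ok = sqrt(sum(grad^2)) <=
                         ctl$grad_tol * (1 + abs(core$loglik)),
                       boundary = boundary),
    design = design), class = "met_fit")
  fit
}

#' @export
logLik.met_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @export
coef.met_fit <- function(object, ...) object$beta

#' @export
vcov.met_fit <- function(object, ...) object$cov_beta

#' @export
print.met_fit <- function(x, ...) {
  cat("MET mixed model (REML), trait", x$spec$trait, "\n")
  cat("  observations:", x$design$n, " genotypes:", x$design$n_geno,
      " environments:", x$design$n_env, "\n")
  cat("  fixed terms:", paste(x$term_labels, collapse = ", "), "\n")
  cat("  genotype variance vg:",
      if (is.null(x$vg)) "(absorbed in G x E structure)"
      else format(x$vg, digits = 4), "\n")
  cat("  G x E structure:", x$spec$gxe,
      " residual:", x$spec$residual, "\n")
  cat("  restricted log-likelihood:", format(x$loglik, digits = 8), "\n")
  conv <- x$convergence
  cat("  converged:", conv$converged,
      " (", conv$iterations, "evaluations,", conv$restarts, "restarts)",
      if (conv$boundary) " [boundary estimate]", "\n")
  invisible(x)
}
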