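# Design construction for the mixed-model engine.  An observation is one
# scored tree in one environment; the random genetic terms link observations
# of the same genotype, so the marginal covariance of the data is block
# diagonal by genotype.  The design bundle pre-groups observations by
# genotype and by "pattern" (identical environment/tree layout), which lets
# the likelihood evaluate each distinct block factorization once.

#' Specify a mixed model for MET data
#'
#' @param trait `"BF"` or `"FF"`.
#' @param fixed character vector of fixed terms; available columns are
#'   `env` (environment factor), `block_in_env` (block nested in
#'   environment) plus any extra columns present in the phenotype table
#'   (e.g. a QTL class factor); interactions use `:` notation.
#' @param genotype logical; include the iid genotype main effect with
#'   variance `vg`.
#' @param gxe structure of the environment x environment covariance of the
#'   genotype-by-environment effect: `"none"`, `"iid"`, `"diag"`
#'   (heterogeneous per-environment variances, the default), `"cs_het"`,
#'   `"fa1"` or `"us"`.  The full-covariance structures (`cs_het`, `fa1`,
#'   `us`) already model genetic covariance between environments, so they
#'   are fitted without the separate genotype main effect (a constant shift
#'   between `vg` and the whole matrix would otherwise leave the likelihood
#'   unchanged).
#' @param residual residual structure: `"iid"`, `"diag_env"` (one variance
#'   per environment, the default) or `"us_season"` (unstructured
#'   season x season covariance within each location, shared by trees).
#' @return A `met_model_spec` list.
#' @export
met_model_spec <- function(trait = "BF",
                           fixed = c("env", "block_in_env"),
                           genotype = TRUE,
                           gxe = "diag",
                           residual = "diag_env") {
  gxe <- match.arg(gxe, GXE_STRUCTURES)
  residual <- match.arg(residual, RESID_STRUCTURES)
  if (genotype && gxe %in% c("cs_het", "fa1", "us")) {
    message("gxe structure '", gxe, "' models between-environment genetic ",
            "covariance itself; dropping the separate genotype main effect")
    genotype <- FALSE
  }
  structure(list(trait = trait, fixed = fixed, genotype = genotype,
                 gxe = gxe, residual = residual),
            class = "met_model_spec")
}

#' Build the design bundle for a mixed-model fit
#'
#' Constructs the response, the full-rank fixed-effect matrix (aliased
#' columns dropped deterministically in order of appearance and reported),
#' genotype/environment incidence, and the residual grouping by individual
#' tree (location x genotype x replicate) across seasons.
#'
#' @param pheno a [met_pheno] table (possibly carrying extra columns such as
#'   QTL class factors).
#' @param spec a [met_model_spec].
#' @return A `met_design` list consumed by [reml_fit()] and
#'   [restricted_loglik()].
#' @export
build_design <- function(pheno, spec) {
  df <- as.data.frame(pheno)
  df <- df[df$trait == spec$trait & !is.na(df$value), , drop = FALSE]
  if (nrow(df) == 0) stop_metgxe("no records for trait ", spec$trait)

  envs <- unique(df[, c("location", "season")])
  envs <- envs[order(envs$location, envs$season), ]
  env_levels <- paste(envs$location, envs$season, sep = ":")
  df$env <- factor(paste(df$location, df$season, sep = ":"),
                   levels = env_levels)
  df$block_in_env <- factor(paste(df$env, df$block, sep = "/"))
  df$genotype_id <- factor(df$genotype_id)

  vars <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  vars <- setdiff(vars, "1")  # "1" = intercept-only fixed part
  absent <- setdiff(vars, names(df))
  if (length(absent) > 0)
    stop_metgxe("fixed term variable(s) not in data: ",
                paste(absent, collapse = ", "))
  for (v in vars) {
    if (!is.numeric(df[[v]])) {
      df[[v]] <- factor(df[[v]])
      if (nlevels(df[[v]]) < 2)
        stop_metgxe("fixed term variable '", v, "' has a single level")
    }
  }

  form <- reformulate(spec$fixed)
  mf <- model.frame(form, df)
  trms <- attr(mf, "terms")
  # sum-to-zero contrasts so that conditional (Type-III-like) Wald tests of
  # main effects average over the levels of interacting factors
  factor_vars <- vars[!vapply(df[vars], is.numeric, logical(1))]
  contrasts_arg <- if (length(factor_vars) > 0)
    setNames(rep(list("contr.sum"), length(factor_vars)), factor_vars)
  X_full <- model.matrix(trms, mf, contrasts.arg = contrasts_arg)
  assign_full <- attr(X_full, "assign")

  qrX <- qr(X_full)
  rank <- qrX$rank
  keep <- sort(qrX$pivot[seq_len(rank)])
  drop_idx <- setdiff(seq_len(ncol(X_full)), keep)
  dropped <- colnames(X_full)[drop_idx]
  dropped_assign <- assign_full[drop_idx]
  X <- X_full[, keep, drop = FALSE]
  assign <- assign_full[keep]

  env_idx <- as.integer(df$env)
  n_env <- length(env_levels)
  env_loc <- envs$location
  env_season <- envs$season
  loc_levels <- unique(env_loc)
  loc_seasons <- lapply(loc_levels, function(l) which(env_loc == l))
  names(loc_seasons) <- loc_levels
  # season index within location, per environment
  season_in_loc <- integer(n_env)
  for (l in seq_along(loc_levels))
    season_in_loc[loc_seasons[[l]]] <- seq_along(loc_seasons[[l]])
  env_to_loc <- match(env_loc, loc_levels)

  tree <- as.integer(factor(paste(df$location, df$genotype_id,
                                  df$replicate, sep = "\r")))
  geno <- as.integer(df$genotype_id)
  n_geno <- nlevels(df$genotype_id)
  y <- df$value
  p <- ncol(X)

  # group observations by genotype, then genotypes by layout pattern
  by_geno <- split(seq_along(y), geno)
  keys <- character(n_geno)
  obs_sorted <- vector("list", n_geno)
  for (g in seq_len(n_geno)) {
    obs <- by_geno[[g]]
    ord <- order(env_idx[obs], tree[obs])
    obs <- obs[ord]
    tree_local <- match(tree[obs], unique(tree[obs]))
    obs_sorted[[g]] <- obs
    keys[g] <- paste(env_idx[obs], tree_local, sep = ".", collapse = ";")
  }
  patterns <- lapply(split(seq_len(n_geno), keys), function(gs) {
    obs1 <- obs_sorted[[gs[1]]]
    b <- length(obs1)
    m <- length(gs)
    obs_mat <- vapply(gs, function(g) obs_sorted[[g]], integer(b))
    obs_mat <- matrix(obs_mat, nrow = b)
    env_b <- env_idx[obs1]
    tree_b <- match(tree[obs1], unique(tree[obs1]))
    # pre-permute the stacked fixed matrix: b x (p*m), column (g-1)*p + j
    Xbig <- X[as.vector(obs_mat), , drop = FALSE]
    A <- aperm(array(Xbig, c(b, m, p)), c(1, 3, 2))
    list(genotypes = gs, b = b, m = m, obs_mat = obs_mat,
         env_b = env_b, tree_b = tree_b,
         loc_b = env_to_loc[env_b], season_b = season_in_loc[env_b],
         Bmat = matrix(A, nrow = b), Y = matrix(y[obs_mat], nrow = b))
  })

  structure(list(y = y, X = X, assign = assign,
                 term_labels = attr(trms, "term.labels"),
                 dropped = dropped, dropped_assign = dropped_assign,
                 terms = trms,
                 contrasts = attr(X_full, "contrasts"),
                 xlevels = lapply(mf[vars[!vapply(df[vars], is.numeric,
                                                  logical(1))]], levels),
                 data = df, n = length(y), p = p,
                 env_levels = env_levels, n_env = n_env,
                 env_loc = env_loc, env_season = env_season,
                 loc_levels = loc_levels, loc_seasons = loc_seasons,
                 geno_levels = levels(df$genotype_id), n_geno = n_geno,
                 patterns = patterns, spec = spec),
            class = "met_design")
}
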