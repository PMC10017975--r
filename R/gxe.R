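# The non-QTL G x E analysis: per-environment SD scaling, the MET mixed
# model, between-environment genetic correlations, variance fractions, and
# broad-sense heritabilities of clonal means.

#' Scale phenotypes by the raw standard deviation of their environment
#'
#' Divides each value by the sample SD (n-1 denominator) of its
#' environment, without centering, to curb variance heterogeneity between
#' environments before the G x E fit.  The per-environment SDs are stored
#' for back-transformation.
#'
#' @param pheno a [met_pheno] table.
#' @param trait `"BF"` or `"FF"` (other traits' records pass through
#'   unscaled).
#' @return the scaled table, with attribute `env_sds` (named vector).
#' @export
scale_by_env_sd <- function(pheno, trait = "BF") {
  sel <- pheno$trait == trait & !is.na(pheno$value)
  sds <- c(tapply(pheno$value[sel], pheno$env[sel], sd))
  bad <- names(sds)[is.na(sds) | sds == 0]
  if (length(bad) > 0)
    stop_metgxe("zero or undefined phenotypic SD in environment(s): ",
                paste(bad, collapse = ", "))
  scaled <- pheno
  scaled$value[sel] <- pheno$value[sel] / sds[as.character(pheno$env[sel])]
  attr(scaled, "env_sds") <- sds
  scaled
}

#' Fit the MET G x E mixed model
#'
#' The model \eqn{y = m + e_{lj} + eb_{ljk} + g_i + ge_{lji} + r_{ljki}}:
#' environment and block-within-environment fixed; genotype main effect
#' iid with variance `vg`; genotype-by-environment effects with the chosen
#' covariance structure; residuals with the chosen structure.  By default
#' observations are first scaled by their environment's raw phenotypic SD.
#'
#' @param pheno a [met_pheno] table.
#' @param trait `"BF"` or `"FF"`.
#' @param gxe,residual covariance structures, see [met_model_spec()].
#' @param scale logical; scale by environment SD first (default `TRUE`).
#' @param control passed to [reml_fit()].
#' @return a `met_fit`; when scaled, it carries attribute `env_sds`.
#' @export
fit_gxe_model <- function(pheno, trait = "BF", gxe = "diag",
                          residual = "diag_env", scale = TRUE,
                          control = list()) {
  val <- validate_met(pheno)
  if (length(val$errors) > 0)
    stop_metgxe("invalid MET: ", paste(val$errors, collapse = "; "))
  env_sds <- NULL
  if (scale) {
    pheno <- scale_by_env_sd(pheno, trait)
    env_sds <- attr(pheno, "env_sds")
  }
  has_blocks <- any(tapply(pheno$block, pheno$env,
                           function(b) length(unique(b))) > 1)
  fixed <- if (has_blocks) c("env", "block_in_env") else "env"
  spec <- met_model_spec(trait = trait, fixed = fixed, genotype = TRUE,
                         gxe = gxe, residual = residual)
  fit <- reml_fit(build_design(pheno, spec), control = control)
  attr(fit, "env_sds") <- env_sds
  fit
}

#' Between-environment total genetic correlations
#'
#' From the fitted components, the total genetic variance in environment
#' `lj` is `var_GEI(lj) = vg + Vge[lj, lj]`, the total genetic covariance
#' between environments is `cov_GEI = vg + Vge[lj, l'j']`, and their ratio
#' gives the genetic correlation.  Correlations below 1 indicate
#' genotype-ranking changes between environments.  Cells with non-positive
#' total genetic variance are set missing with a warning.
#'
#' @param fit a `met_fit` from [fit_gxe_model()] (or any fit providing `vg`
#'   and/or `Vge`).
#' @return a `met_gencor` list: `cor` (E x E, unit diagonal), `var_gei`,
#'   `cov_gei`, `mean_offdiag` (unweighted mean over off-diagonal pairs).
#' @export
genetic_correlations <- function(fit) {
  E <- fit$design$n_env
  vg <- fit$vg %||% 0
  Vge <- fit$Vge
  if (is.null(Vge)) Vge <- matrix(0, E, E)
  cov_gei <- vg + Vge
  var_gei <- diag(cov_gei)
  bad <- var_gei <= 0
  if (any(bad))
    warning("non-positive total genetic variance in environment(s): ",
            paste(fit$design$env_levels[bad], collapse = ", "),
            call. = FALSE)
  denom <- sqrt(pmax(var_gei, 0))
  cm <- cov_gei / outer(denom, denom)
  cm[bad, ] <- NA_real_; cm[, bad] <- NA_real_
  diag(cm)[!bad] <- 1
  dimnames(cm) <- dimnames(cov_gei) <-
    list(fit$design$env_levels, fit$design$env_levels)
  structure(list(cor = cm, var_gei = setNames(var_gei,
                                              fit$design$env_levels),
                 cov_gei = cov_gei,
                 mean_offdiag = mean(cm[upper.tri(cm)], na.rm = TRUE)),
            class = "met_gencor")
}

#' @export
print.met_gencor <- function(x, ...) {
  cat("Between-environment genetic correlations (",
      nrow(x$cor), " environments)\n", sep = "")
  cat("mean off-diagonal correlation:",
      format(x$mean_offdiag, digits = 3), "\n")
  invisible(x)
}

# Pooled MET model for heritability/fractions: genotype and genotype x
# environment random (iid), environment fixed; fitted with lme4.
met_pooled_fit <- function(pheno, trait) {
  df <- as.data.frame(pheno)
  df <- df[df$trait == trait & !is.na(df$value), ]
  if (length(unique(df$env)) < 2)
    stop_metgxe("pooled MET model needs >= 2 environments")
  df$genotype_id <- factor(df$genotype_id)
  df$env <- factor(df$env)
  lme4::lmer(value ~ env + (1 | genotype_id) + (1 | genotype_id:env),
             data = df, REML = TRUE,
             control = lme4::lmerControl(check.conv.singular = "ignore"))
}

lmer_vc <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  setNames(vc$vcov, vc$grp)
}

#' Broad-sense heritability formulas for clonal means
#'
#' `h2_clonal_mean()` is the single-location formula
#' \eqn{\sigma^2_g / (\sigma^2_g + \sigma^2_e/(nr))} (n seasons, r
#' replicates per genotype); `h2_met()` is the across-environments formula
#' \eqn{\sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/e + \sigma^2_e/(er))}
#' (e environments).  [location_h2()] and [met_h2()] plug estimated
#' components into these.
#'
#' @param sigma_g,sigma_ge,sigma_e variance components.
#' @param n,r,e design counts (seasons, replicates, environments).
#' @return heritability in `[0, 1]` for non-negative components.
#' @export
h2_clonal_mean <- function(sigma_g, sigma_e, n, r) {
  if (sigma_g <= 0) return(0)
  sigma_g / (sigma_g + sigma_e / (n * r))
}

#' @rdname h2_clonal_mean
#' @export
h2_met <- function(sigma_g, sigma_ge, sigma_e, e, r) {
  if (sigma_g <= 0) return(0)
  sigma_g / (sigma_g + sigma_ge / e + sigma_e / (e * r))
}

#' Broad-sense heritability of clonal means in one location
#'
#' Fits `y = mu + g + season + block + e` for the location (genotype
#' random, season and block fixed) and computes
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e / (n r))}
#' with `n` the number of seasons and `r` the median number of replicates
#' per genotype per season.
#'
#' @param pheno a [met_pheno] table.
#' @param location location label.
#' @param trait `"BF"` or `"FF"`.
#' @return list with `H2`, `sigma_g`, `sigma_e`, `n_seasons`, `r`,
#'   `location`.
#' @export
location_h2 <- function(pheno, location, trait = "BF") {
  df <- as.data.frame(pheno)
  df <- df[df$trait == trait & !is.na(df$value) &
             df$location == location, ]
  if (nrow(df) == 0) stop_metgxe("no records for location ", location)
  n_seasons <- length(unique(df$season))
  if (n_seasons < 2)
    warning("single season in ", location,
            "; H2 computed with n = 1", call. = FALSE)
  reps <- aggregate(replicate ~ genotype_id + season, df,
                    function(x) length(unique(x)))
  r <- median(reps$replicate)
  df$genotype_id <- factor(df$genotype_id)
  terms <- c(if (n_seasons > 1) "factor(season)",
             if (length(unique(df$block)) > 1) "factor(block)")
  form <- as.formula(paste("value ~",
                           paste(c(terms, "(1 | genotype_id)"),
                                 collapse = " + ")))
  fit <- lme4::lmer(form, data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  vc <- lmer_vc(fit)
  sigma_g <- unname(vc["genotype_id"])
  sigma_e <- unname(vc["Residual"])
  H2 <- h2_clonal_mean(sigma_g, sigma_e, n_seasons, r)
  list(H2 = H2, sigma_g = sigma_g, sigma_e = sigma_e,
       n_seasons = n_seasons, r = r, location = location)
}

#' MET broad-sense heritability of clonal means
#'
#' Fits the pooled model `y = mu + G + E + GE + e` (genotype and G x E
#' random, environment fixed) and computes
#' \deqn{H^2_{MET} = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/e +
#'   \sigma^2_e/(e r))}
#' with `e` the number of environments and `r` the median number of
#' replicates per genotype per environment.
#'
#' @param pheno a [met_pheno] table.
#' @param trait `"BF"` or `"FF"`.
#' @return list with `H2_MET`, `sigma_g`, `sigma_ge`, `sigma_e`, `e`, `r`.
#' @export
met_h2 <- function(pheno, trait = "BF") {
  fit <- met_pooled_fit(pheno, trait)
  vc <- lmer_vc(fit)
  df <- pheno[pheno$trait == trait & !is.na(pheno$value), ]
  e <- length(unique(df$env))
  reps <- aggregate(replicate ~ genotype_id + env, as.data.frame(df),
                    function(x) length(unique(x)))
  r <- median(reps$replicate)
  sigma_g <- unname(vc["genotype_id"])
  sigma_ge <- unname(vc["genotype_id:env"])
  sigma_e <- unname(vc["Residual"])
  H2 <- h2_met(sigma_g, sigma_ge, sigma_e, e, r)
  list(H2_MET = H2, sigma_g = sigma_g, sigma_ge = sigma_ge,
       sigma_e = sigma_e, e = e, r = r)
}

#' Phenotypic variance fractions from the pooled MET model
#'
#' Fractions of phenotypic variation attributed to genotype, environment,
#' G x E and residual.  Random-effect fractions come from the variance
#' components of the pooled model; the environment (fixed-effect) fraction
#' is the empirical variance of the fitted environment means across
#' observations.  Fractions are normalized to sum to one.
#'
#' @param pheno a [met_pheno] table.
#' @param trait `"BF"` or `"FF"`.
#' @return named numeric vector (genotype, environment, gxe, residual)
#'   with attribute `components`.
#' @export
variance_fractions <- function(pheno, trait = "BF") {
  fit <- met_pooled_fit(pheno, trait)
  vc <- lmer_vc(fit)
  X <- model.matrix(fit)
  env_pred <- drop(X %*% lme4::fixef(fit))
  v_env <- var(env_pred)
  comps <- c(genotype = unname(vc["genotype_id"]),
             environment = v_env,
             gxe = unname(vc["genotype_id:env"]),
             residual = unname(vc["Residual"]))
  frac <- comps / sum(comps)
  attr(frac, "components") <- comps
  frac
}
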