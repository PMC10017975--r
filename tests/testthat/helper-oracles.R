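# Shared fixtures and independent oracles for the test suite.

# Dense brute-force REML criterion: builds the full n x n covariance matrix
# explicitly and evaluates determinants directly.  Independent of the
# engine's block-structured path.
dense_reml_oracle <- function(design, vg, Vge, resid_vars,
                              loc_mats = NULL) {
  n <- design$n
  X <- design$X
  y <- design$y
  df <- design$data
  geno <- as.integer(factor(df$genotype_id))
  env <- as.integer(df$env)
  tree <- paste(df$location, df$genotype_id, df$replicate)
  loc <- as.character(df$location)
  season_in_loc <- integer(n)
  for (l in unique(loc)) {
    sel <- loc == l
    season_in_loc[sel] <- match(df$season[sel],
                                sort(unique(df$season[sel])))
  }
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- 0
    if (geno[i] == geno[j]) {
      if (!is.null(vg)) v <- v + vg
      if (!is.null(Vge)) v <- v + Vge[env[i], env[j]]
    }
    if (tree[i] == tree[j]) {
      if (is.null(loc_mats)) {
        if (i == j) v <- v + resid_vars[env[i]]
      } else {
        v <- v + loc_mats[[loc[i]]][season_in_loc[i], season_in_loc[j]]
      }
    }
    V[i, j] <- v
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r +
                       (n - ncol(X)) * log(2 * pi)))
}

# Small balanced phenotype table built by hand: g genotypes x e environments
# (one location per environment unless locations supplied) x r replicates.
make_pheno <- function(values, genotypes, locations, seasons, blocks = NULL,
                       replicates = NULL, trait = "BF") {
  n <- length(values)
  met_pheno(data.frame(
    genotype_id = rep_len(genotypes, n),
    location = rep_len(locations, n),
    season = rep_len(seasons, n),
    block = rep_len(blocks %||% "b1", n),
    replicate = rep_len(replicates %||% 1L, n),
    trait = trait, value = values))
}

# Deterministic grid phenotype table: all combinations of the supplied
# genotype/location/season/replicate labels, with values filled in order.
grid_pheno <- function(genotypes, locations, seasons, replicates = 1,
                       values, trait = "BF") {
  g <- expand.grid(genotype_id = genotypes, location = locations,
                   season = seasons, replicate = seq_len(replicates),
                   stringsAsFactors = FALSE)
  g$block <- paste0("b", g$replicate)
  g$trait <- trait
  g$value <- values
  met_pheno(g)
}

# Simulate data straight from the engine's model (no QTLs, no scaling):
# y = m + e_env + g_i + ge_ie + resid, balanced across environments and
# replicates.  Returns the met_pheno table and the generating components.
sim_engine_data <- function(n_geno, n_env, reps, vg, v_ge, ve, seed,
                            mean = 50) {
  set.seed(seed)
  v_ge <- rep_len(v_ge, n_env)
  e_env <- rnorm(n_env, 0, 2)
  g <- rnorm(n_geno, 0, sqrt(vg))
  ge <- matrix(rnorm(n_geno * n_env, 0, rep(sqrt(v_ge), each = n_geno)),
               n_geno, n_env)
  grid <- expand.grid(geno = seq_len(n_geno), env = seq_len(n_env),
                      rep = seq_len(reps))
  y <- mean + e_env[grid$env] + g[grid$geno] +
    ge[cbind(grid$geno, grid$env)] + rnorm(nrow(grid), 0, sqrt(ve))
  pheno <- met_pheno(data.frame(
    genotype_id = sprintf("g%03d", grid$geno),
    location = sprintf("L%02d", grid$env),
    season = 2020L,
    block = paste0("b", grid$rep),
    replicate = grid$rep,
    trait = "BF", value = y))
  list(pheno = pheno, vg = vg, v_ge = v_ge, ve = ve)
}

# Generator configuration with both QTL effects switched off (null QTLs),
# used by calibration studies.
null_qtl_config <- function(...) {
  cfg <- synth_config(...)
  cfg$qtls$cold$kappa <- 0
  cfg$qtls$warm$kappa <- 0
  cfg
}

# Scaled-down two/three-location configs for fast simulation studies.
small_met_config <- function(n_genotypes = 50, missing_frac = 0, ...) {
  synth_config(n_genotypes = n_genotypes,
               locations = c(A = 5, B = 8, C = 11),
               seasons = list(A = 2019:2020, B = 2019:2020, C = 2019:2020),
               missing_frac = missing_frac, ...)
}
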