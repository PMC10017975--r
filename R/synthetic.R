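# Synthetic full-sib MET generator.  Emulates the study design the package
# targets: an F1 full-sib family clonally replicated in two copies across
# five locations spanning cold to warm dormancy-season climates, scored for
# flowering date over 3-5 seasons per location (20 environments), with
# unbalanced genotype presence, two conditionally-neutral QTLs (a "cold"
# QTL expressed below a temperature threshold and a "warm" QTL expressed
# above one), a polygenic main effect, environment-specific genetic
# effects, and season-correlated residuals within each tree.

#' Default configuration for the synthetic MET generator
#'
#' Defaults define the emulated study conditions: 121 F1 genotypes, five
#' locations with Oct-Mar mean temperatures 4.5-12.5 degC, 3-5 seasons per
#' location (20 environments), two clonal replicates, 15% of genotypes
#' absent per environment.  Phenotypes are Julian days around a grand mean
#' of 90.  The QTL-temperature rules are piecewise-linear hinges: the cold
#' QTL has per-environment effect `kappa * max(0, t_ref - T)` (0.5 JD/degC
#' below 10 degC) and the warm QTL `kappa * max(0, T - t_ref)` (0.4 JD/degC
#' above 7 degC) - a minimal stand-in for the temperature dependence of
#' real dormancy loci, not an estimated relation.
#'
#' @param ... overrides of any default element.
#' @return A `synth_config` list.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_genotypes = 121L,
    locations = c(Maribor = 4.5, Forli = 7.5, Toulenne = 9.0,
                  Nimes = 9.5, Murcia = 12.5),
    seasons = list(Maribor = c(2017L, 2019L, 2021L),
                   Forli = 2018:2021,
                   Toulenne = c(2016:2019, 2021L),
                   Nimes = c(2017L, 2018L, 2019L, 2021L),
                   Murcia = 2017:2020),
    replicates = 2L,
    missing_frac = 0.15,
    trait = "BF",
    mean = 90,
    env_temp_slope = -2.5,   # JD per degC of environment Oct-Mar mean
    env_noise_sd = 1,        # JD, environment effect not tracking temperature
    season_offset_sd = 1.5,  # degC, season-level temperature offset
    daily_noise_sd = 2,      # degC, day-to-day temperature noise
    seasonal_amplitude = 6,  # degC, winter trough depth of the daily curve
    block_sd = 0.5,          # JD, block-within-environment effects
    vg = 4,                  # polygenic main variance (JD^2)
    v_ge = 1,                # per-environment interaction variance (scalar
                             # or one value per environment)
    residual_var = 3,        # JD^2
    residual_cor = 0.2,      # residual correlation among seasons in a tree
    qtls = list(
      cold = list(name = "qR4", linkage_group = "R4",
                  flanking = c("R4_m1", "R4_m2"), segregation = "ABxAA",
                  kappa = 0.5, t_ref = 10, side = "below"),
      warm = list(name = "qL1", linkage_group = "L1",
                  flanking = c("L1_m1", "L1_m2"), segregation = "ABxAB",
                  kappa = 0.4, t_ref = 7, side = "above")))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop_metgxe("unknown config element(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$vg >= 0, all(cfg$v_ge >= 0), cfg$residual_var >= 0,
            cfg$missing_frac >= 0, cfg$missing_frac < 1)
  class(cfg) <- "synth_config"
  cfg
}

#' Default genetic map for the generator
#'
#' Three linkage groups: the cold-QTL region (locus `qR4` with flanking
#' markers 1 cM away on either side, pseudo-testcross segregation), the
#' warm-QTL region (`qL1`, both parents heterozygous), and a neutral
#' background group.  The QTL loci are ordinary map loci; their genotypes
#' drive the simulated effects and their flanking markers are what the
#' analysis observes.
#'
#' @param config a [synth_config()].
#' @return A `met_map` data frame with columns `marker`, `linkage_group`,
#'   `position_cM`, `position_Mb`, `segregation`.
#' @export
default_genetic_map <- function(config = synth_config()) {
  cold <- config$qtls$cold; warm <- config$qtls$warm
  map <- data.frame(
    marker = c(cold$flanking[1], cold$name, cold$flanking[2],
               warm$flanking[1], warm$name, warm$flanking[2],
               "R2_m1", "R2_m2"),
    linkage_group = c(rep(cold$linkage_group, 3), rep(warm$linkage_group, 3),
                      "R2", "R2"),
    position_cM = c(28.5, 29.5, 30.5, 145, 146, 147, 10, 20),
    position_Mb = c(8.4, 9.9, 11.4, 47.4, 49.9, 52.3, 5.0, 9.0),
    segregation = c(rep(cold$segregation, 3), rep(warm$segregation, 3),
                    "ABxAA", "ABxAB"))
  map <- map[order(map$linkage_group, map$position_cM), ]
  rownames(map) <- NULL
  class(map) <- c("met_map", "data.frame")
  map
}

# Haldane map function: recombination fraction from a cM distance.
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Simulate marker classes for an F1 full-sib family
#'
#' Each parent transmits one of two homologs per linkage group, with
#' crossovers between adjacent loci at the Haldane recombination fraction
#' of their cM distance.  Both parents are assumed in coupling phase (one
#' homolog carries all A alleles, the other all B).  `ABxAA` loci are
#' heterozygous in the first parent only and segregate 1:1 AA:AB; `ABxAB`
#' loci segregate 1:2:1 AA:AB:BB.
#'
#' @param config a [synth_config()].
#' @param map a `met_map` with a `segregation` column (default:
#'   [default_genetic_map()]).
#' @param n number of individuals (default `config$n_genotypes`).
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @return A [met_markers] object covering all map loci (QTL loci included).
#' @export
simulate_fullsib_markers <- function(config = synth_config(),
                                     map = default_genetic_map(config),
                                     n = config$n_genotypes, seed = NULL) {
  with_seed(seed, {
    classes <- matrix(NA_character_, n, nrow(map),
                      dimnames = list(sprintf("RxL_%03d", seq_len(n)),
                                      map$marker))
    for (lg in unique(map$linkage_group)) {
      sub <- map[map$linkage_group == lg, , drop = FALSE]
      L <- nrow(sub)
      rfrac <- if (L > 1) haldane_r(diff(sub$position_cM)) else numeric(0)
      transmit <- function() {
        h <- matrix(0L, n, L)
        h[, 1] <- rbinom(n, 1, 0.5)
        for (k in seq_len(L - 1))
          h[, k + 1] <- (h[, k] + rbinom(n, 1, rfrac[k])) %% 2L
        h  # 0 = homolog carrying A, 1 = homolog carrying B
      }
      h1 <- transmit()
      h2 <- transmit()
      for (k in seq_len(L)) {
        a1 <- ifelse(h1[, k] == 1, "B", "A")
        a2 <- if (sub$segregation[k] == "ABxAA") rep("A", n)
              else ifelse(h2[, k] == 1, "B", "A")
        classes[, sub$marker[k]] <-
          ifelse(a1 == a2, paste0(a1, a2),
                 "AB")
      }
    }
    met_markers(classes, segregation = setNames(map$segregation, map$marker))
  })
}

#' Simulate daily temperature series and environment means
#'
#' For each location, builds a daily mean-temperature series over each
#' season's dormancy window (Oct 1 of the preceding year through May 31):
#' a smooth seasonal curve with its winter trough in mid-January, centred
#' so that the Oct-Mar mean equals the location's configured mean, plus a
#' season-level offset and day-to-day noise.
#'
#' @param config a [synth_config()].
#' @param seed integer seed, or `NULL`.
#' @return A `met_climate_profile` list: `climate` (a `met_climate` daily
#'   table), `env_means` (per environment: realized Oct-Mar mean `t_octmar`
#'   and the true season `offset`).
#' @export
simulate_environment_profile <- function(config = synth_config(),
                                         seed = NULL) {
  with_seed(seed, {
    clim <- list(); envrows <- list()
    for (loc in names(config$locations)) {
      lmean <- config$locations[[loc]]
      for (yr in config$seasons[[loc]]) {
        dates <- seq(as.Date(sprintf("%d-10-01", yr - 1)),
                     as.Date(sprintf("%d-05-31", yr)), by = "day")
        doy <- as.integer(dates - as.Date(sprintf("%d-10-01", yr - 1))) + 1L
        shape <- -config$seasonal_amplitude *
          cos(2 * pi * (doy - 107) / 365.25)
        octmar <- dates <= as.Date(sprintf("%d-03-31", yr))
        shape <- shape - mean(shape[octmar])
        offset <- rnorm(1, 0, config$season_offset_sd)
        tmean <- lmean + offset + shape +
          rnorm(length(dates), 0, config$daily_noise_sd)
        clim[[paste(loc, yr)]] <-
          data.frame(location = loc, date = dates, tmean = tmean)
        envrows[[paste(loc, yr)]] <-
          data.frame(location = loc, season = yr,
                     env = paste(loc, yr, sep = ":"),
                     t_octmar = mean(tmean[octmar]), offset = offset)
      }
    }
    climate <- do.call(rbind, clim)
    rownames(climate) <- NULL
    class(climate) <- c("met_climate", "data.frame")
    env_means <- do.call(rbind, envrows)
    rownames(env_means) <- NULL
    structure(list(climate = climate, env_means = env_means),
              class = "met_climate_profile")
  })
}

# True per-environment QTL effect: hinge below/above a temperature
# threshold, or a constant effect (side = "constant", kappa = the effect).
qtl_hinge_effect <- function(qtl, t_env) {
  switch(qtl$side,
         below = qtl$kappa * pmax(0, qtl$t_ref - t_env),
         above = qtl$kappa * pmax(0, t_env - qtl$t_ref),
         constant = rep(qtl$kappa, length(t_env)),
         stop_metgxe("unknown QTL rule side: ", qtl$side))
}

# QTL genotype coding: 0/1 for two-class (pseudo-testcross) loci,
# -1/0/+1 (count of B alleles - 1) for three-class loci.
qtl_z_coding <- function(classes, segregation) {
  if (segregation == "ABxAA") as.numeric(classes == "AB")
  else c(AA = -1, AB = 0, BB = 1)[classes]
}

#' Simulate MET phenotypes with a truth record
#'
#' Builds phenotype records according to
#' \deqn{y = m + e_{lj} + eb_{ljk} + \sum_q d_q(lj)\, z_{qi} + g_i +
#'   ge_{lji} + r_{ljki}}
#' with environment effects tracking the realized Oct-Mar temperatures
#' (`env_temp_slope`), hinge-rule QTL effects, iid polygenic effects
#' `g ~ N(0, vg)`, environment-specific genetic effects
#' `ge ~ N(0, v_ge(lj))` independent across environments, block effects,
#' and residuals correlated among seasons within each tree
#' (`residual_cor`).  Unbalance removes whole genotypes per environment.
#'
#' @param markers a [met_markers] object containing the QTL loci named in
#'   `config$qtls`.
#' @param profile a [simulate_environment_profile()] result.
#' @param config a [synth_config()].
#' @param seed integer seed, or `NULL`.
#' @return list with `pheno` (a [met_pheno] table) and `truth` (realized
#'   effects and the generating components).
#' @export
simulate_phenotypes <- function(markers, profile, config = synth_config(),
                                seed = NULL) {
  with_seed(seed, {
    env <- profile$env_means
    E <- nrow(env)
    nG <- config$n_genotypes
    genos <- markers$individuals[seq_len(nG)]
    if (length(markers$individuals) < nG)
      stop_metgxe("marker matrix has fewer individuals than n_genotypes")
    t_env <- env$t_octmar
    e_lj <- config$env_temp_slope * (t_env - mean(t_env)) +
      rnorm(E, 0, config$env_noise_sd)
    names(e_lj) <- env$env

    blocks <- paste0("b", seq_len(config$replicates))
    eb <- matrix(rnorm(E * length(blocks), 0, config$block_sd), E,
                 dimnames = list(env$env, blocks))

    qtl_d <- t(vapply(config$qtls, function(q) qtl_hinge_effect(q, t_env),
                      numeric(E)))
    colnames(qtl_d) <- env$env
    qtl_z <- vapply(config$qtls, function(q) {
      if (!q$name %in% markers$markers)
        stop_metgxe("QTL locus ", q$name, " absent from marker matrix")
      qtl_z_coding(markers$classes[genos, q$name],
                   markers$segregation[[q$name]])
    }, numeric(nG))
    rownames(qtl_z) <- genos

    g <- rnorm(nG, 0, sqrt(config$vg))
    names(g) <- genos
    v_ge <- rep_len(config$v_ge, E)
    ge <- matrix(rnorm(nG * E, 0, rep(sqrt(v_ge), each = nG)), nG, E,
                 dimnames = list(genos, env$env))

    # residuals: one season-correlated vector per tree within its location
    qtl_part <- t(qtl_z %*% qtl_d)  # E x nG
    rows <- list()
    for (l in names(config$locations)) {
      idx <- which(env$location == l)
      s <- length(idx)
      gi <- rep(seq_len(nG), times = config$replicates)
      rep_k <- rep(seq_len(config$replicates), each = nG)
      n_trees <- length(gi)
      resid <- if (config$residual_var > 0) {
        Sig <- config$residual_var *
          ((1 - config$residual_cor) * diag(s) +
             config$residual_cor * matrix(1, s, s))
        matrix(rnorm(n_trees * s), n_trees, s) %*% chol(Sig)
      } else matrix(0, n_trees, s)
      y_mat <- config$mean +
        matrix(e_lj[idx], n_trees, s, byrow = TRUE) +
        t(eb[idx, rep_k, drop = FALSE]) +
        t(qtl_part[idx, gi, drop = FALSE]) +
        g[gi] + ge[gi, idx, drop = FALSE] + resid
      rows[[l]] <- data.frame(
        genotype_id = rep(genos[gi], s),
        location = l,
        season = rep(env$season[idx], each = n_trees),
        block = rep(blocks[rep_k], s),
        replicate = rep(rep_k, s),
        trait = config$trait,
        value = as.vector(y_mat))
    }
    pheno <- do.call(rbind, rows)

    # unbalance: whole genotypes absent from an environment
    n_drop <- floor(config$missing_frac * nG)
    if (n_drop > 0) {
      drop_keys <- character(0)
      for (e in env$env)
        drop_keys <- c(drop_keys, paste(sample(genos, n_drop), e))
      pheno_env <- paste(pheno$location, pheno$season, sep = ":")
      pheno <- pheno[!(paste(pheno$genotype_id, pheno_env) %in% drop_keys), ]
    }
    rownames(pheno) <- NULL

    truth <- list(m = config$mean, env_effects = e_lj, block_effects = eb,
                  g = g, ge = ge, qtl_d = qtl_d, qtl_z = qtl_z,
                  t_env = setNames(t_env, env$env),
                  components = list(vg = config$vg,
                                    v_ge = setNames(v_ge, env$env),
                                    residual_var = config$residual_var,
                                    residual_cor = config$residual_cor,
                                    block_sd = config$block_sd))
    list(pheno = met_pheno(pheno), truth = truth)
  })
}

#' Simulate a complete synthetic MET
#'
#' Runs the marker, climate and phenotype generators in sequence under one
#' seed.  The same seed reproduces the output exactly.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (required: the generator is a study-conditions
#'   definition, and its runs must be reproducible).
#' @return list with `pheno`, `markers`, `map`, `climate`, `env_means`,
#'   `truth`, `config`, `seed`.
#' @export
simulate_met <- function(config = synth_config(), seed) {
  if (missing(seed) || !is_scalar_number(seed))
    stop_metgxe("an integer seed is required")
  with_seed(seed, {
    map <- default_genetic_map(config)
    markers <- simulate_fullsib_markers(config, map, seed = NULL)
    profile <- simulate_environment_profile(config, seed = NULL)
    ph <- simulate_phenotypes(markers, profile, config, seed = NULL)
    list(pheno = ph$pheno, markers = markers, map = map,
         climate = profile$climate, env_means = profile$env_means,
         truth = ph$truth, config = config, seed = seed)
  })
}

#' Write a simulated MET to a directory of canonical CSV files
#'
#' Writes `phenotypes.csv`, `markers.csv`, `map.csv`, `climate.csv` and
#' `truth.json`.
#'
#' @param sim a [simulate_met()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_met <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phenotypes(sim$pheno, file.path(dir, "phenotypes.csv"))
  mk <- data.frame(individual = sim$markers$individuals,
                   sim$markers$classes, check.names = FALSE)
  write.csv(mk, file.path(dir, "markers.csv"), row.names = FALSE, na = "NA")
  write.csv(as.data.frame(sim$map), file.path(dir, "map.csv"),
            row.names = FALSE, na = "NA")
  write.csv(as.data.frame(sim$climate), file.path(dir, "climate.csv"),
            row.names = FALSE, na = "NA")
  truth <- sim$truth
  truth$block_effects <- as.data.frame(truth$block_effects)
  truth$ge <- as.data.frame(truth$ge)
  truth$qtl_d <- as.data.frame(truth$qtl_d)
  truth$qtl_z <- as.data.frame(truth$qtl_z)
  jsonlite::write_json(list(seed = sim$seed, truth = truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
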