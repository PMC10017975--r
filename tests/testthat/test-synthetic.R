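# Synthetic MET generator: segregation, linkage, climate profile, phenotype
# skeleton, determinism and unbalance properties.

test_that("full-sib markers segregate 1:1 and 1:2:1", {
  map <- data.frame(marker = c("m_aa", "m_ab"),
                    linkage_group = c("LG1", "LG2"),
                    position_cM = c(0, 0), position_Mb = NA,
                    segregation = c("ABxAA", "ABxAB"))
  mk <- simulate_fullsib_markers(synth_config(), map, n = 10000, seed = 101)
  f1 <- table(mk$classes[, "m_aa"]) / 10000
  expect_lt(abs(f1[["AB"]] - 0.5), 0.02)
  expect_false("BB" %in% names(f1))
  f2 <- table(mk$classes[, "m_ab"]) / 10000
  expect_lt(abs(f2[["AA"]] - 0.25), 0.02)
  expect_lt(abs(f2[["AB"]] - 0.50), 0.02)
  expect_lt(abs(f2[["BB"]] - 0.25), 0.02)
})

test_that("linked markers recombine at the Haldane fraction", {
  # two pseudo-testcross markers 10 cM apart: r = (1 - exp(-0.2))/2
  map <- data.frame(marker = c("mk1", "mk2"), linkage_group = "LG1",
                    position_cM = c(0, 10), position_Mb = NA,
                    segregation = "ABxAA")
  mk <- simulate_fullsib_markers(synth_config(), map, n = 10000, seed = 202)
  r_expected <- (1 - exp(-0.2)) / 2
  rec <- mean(mk$classes[, "mk1"] != mk$classes[, "mk2"])
  expect_lt(abs(rec - r_expected), 0.01)
})

test_that("environment profile recovers configured Oct-Mar means", {
  # no noise, no season offsets: exact equality
  cfg0 <- small_met_config(daily_noise_sd = 0, season_offset_sd = 0)
  prof0 <- simulate_environment_profile(cfg0, seed = 1)
  expect_equal(prof0$env_means$t_octmar,
               unname(cfg0$locations[prof0$env_means$location]),
               tolerance = 1e-12)

  # offsets shift the realized mean one-for-one
  expect_equal(
    simulate_environment_profile(
      small_met_config(daily_noise_sd = 0), seed = 2)$env_means$t_octmar -
      unname(cfg0$locations[prof0$env_means$location]),
    simulate_environment_profile(
      small_met_config(daily_noise_sd = 0), seed = 2)$env_means$offset,
    tolerance = 1e-12)

  # default daily noise: realized means within 4 standard errors
  cfg <- small_met_config(season_offset_sd = 0)
  devs <- unlist(lapply(1:5, function(s) {
    p <- simulate_environment_profile(cfg, seed = s)
    p$env_means$t_octmar - unname(cfg$locations[p$env_means$location])
  }))
  se <- cfg$daily_noise_sd / sqrt(182)
  expect_true(all(abs(devs) < 4 * se))
})

test_that("phenotypes reduce to the deterministic skeleton and carry QTLs", {
  # all variances zero, QTL effects off: y is exactly m + e_lj + eb_ljk,
  # and with zero block SD and env noise, y = m + slope * (T - mean(T))
  cfg <- small_met_config(n_genotypes = 4, vg = 0, v_ge = 0,
                          residual_var = 0, block_sd = 0, env_noise_sd = 0,
                          daily_noise_sd = 0, season_offset_sd = 0)
  cfg$qtls$cold$kappa <- 0; cfg$qtls$warm$kappa <- 0
  sim <- simulate_met(cfg, seed = 9)
  t_env <- sim$truth$t_env[as.character(sim$pheno$env)]
  expected <- cfg$mean + cfg$env_temp_slope * (t_env - mean(sim$truth$t_env))
  expect_equal(sim$pheno$value, unname(expected), tolerance = 1e-10)

  # constant two-class QTL effect d: class mean difference estimates d
  d <- 2
  cfg2 <- small_met_config(n_genotypes = 2000, vg = 0, v_ge = 0,
                           residual_var = 1, block_sd = 0)
  cfg2$qtls$cold <- list(name = "qR4", linkage_group = "R4",
                         flanking = c("R4_m1", "R4_m2"),
                         segregation = "ABxAA", kappa = d, t_ref = 0,
                         side = "constant")
  cfg2$qtls$warm$kappa <- 0
  sim2 <- simulate_met(cfg2, seed = 10)
  z <- sim2$truth$qtl_z[as.character(sim2$pheno$genotype_id), "cold"]
  diff_means <- mean(sim2$pheno$value[z == 1]) -
    mean(sim2$pheno$value[z == 0])
  se <- sqrt(1 / sum(z == 1) + 1 / sum(z == 0))
  expect_lt(abs(diff_means - d), 3 * se)
})

test_that("same seed reproduces the simulation exactly", {
  a <- simulate_met(small_met_config(n_genotypes = 10), seed = 77)
  b <- simulate_met(small_met_config(n_genotypes = 10), seed = 77)
  expect_identical(a$pheno$value, b$pheno$value)
  expect_identical(a$markers$classes, b$markers$classes)
  expect_identical(a$climate$tmean, b$climate$tmean)
  expect_identical(a$truth, b$truth)
})

test_that("with no interaction and constant QTL effects the true genetic
           correlation between environments is 1", {
  cfg <- small_met_config(n_genotypes = 30, v_ge = 0)
  cfg$qtls$cold$side <- "constant"; cfg$qtls$cold$kappa <- 2
  cfg$qtls$warm$kappa <- 0
  sim <- simulate_met(cfg, seed = 13)
  # total genetic value of genotype i in env e: g_i + d_e * z_i + ge_ie
  gv <- sim$truth$g + outer(sim$truth$qtl_z[, "cold"],
                            sim$truth$qtl_d["cold", ]) + sim$truth$ge
  cors <- cor(gv)
  expect_equal(unname(cors[upper.tri(cors)]),
               rep(1, sum(upper.tri(cors))), tolerance = 1e-12)
})

test_that("unbalance deletes whole genotypes without altering the rest", {
  cfg_full <- small_met_config(n_genotypes = 20, missing_frac = 0)
  cfg_miss <- small_met_config(n_genotypes = 20, missing_frac = 0.2)
  full <- simulate_met(cfg_full, seed = 21)$pheno
  miss <- simulate_met(cfg_miss, seed = 21)$pheno
  expect_lt(nrow(miss), nrow(full))
  key <- function(p) paste(p$genotype_id, p$env, p$block, p$replicate)
  m <- match(key(miss), key(full))
  expect_false(anyNA(m))
  expect_identical(miss$value, full$value[m])
  # deletion is genotype-wise within environment
  cells <- table(miss$genotype_id, miss$env)
  expect_true(all(cells %in% c(0, cfg_miss$replicates)))
})

test_that("write_met produces the canonical files", {
  dir <- withr::local_tempdir()
  sim <- simulate_met(small_met_config(n_genotypes = 5), seed = 31)
  write_met(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("phenotypes.csv", "markers.csv", "map.csv", "climate.csv",
      "truth.json")))))
  back <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(back), nrow(sim$pheno))
})
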