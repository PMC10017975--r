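# Scaling, genetic correlations, heritabilities, variance fractions.

test_that("environment-SD scaling and back-transformation", {
  ph <- make_pheno(c(80, 90, 100), paste0("g", 1:3), "A", 2019)
  sc <- scale_by_env_sd(ph)
  expect_equal(sc$value, c(8, 9, 10))
  expect_equal(unname(attr(sc, "env_sds")), 10)

  sim <- simulate_met(small_met_config(n_genotypes = 10), seed = 2)
  sc2 <- scale_by_env_sd(sim$pheno)
  sds_after <- c(tapply(sc2$value, sc2$env, sd))
  expect_equal(unname(sds_after), rep(1, length(sds_after)),
               tolerance = 1e-12)
  # back-transformation recovers original SDs exactly
  back <- sc2
  back$value <- back$value * attr(sc2, "env_sds")[as.character(back$env)]
  expect_equal(back$value, sim$pheno$value, tolerance = 1e-12)

  const <- make_pheno(rep(90, 3), paste0("g", 1:3), "A", 2019)
  expect_error(scale_by_env_sd(const), "zero or undefined")
})

test_that("genetic correlations follow the component formula", {
  stub <- function(vg, Vge) {
    structure(list(vg = vg, Vge = Vge,
                   design = list(n_env = nrow(Vge),
                                 env_levels = paste0("e", seq_len(nrow(Vge))))),
              class = "met_fit")
  }
  gc1 <- genetic_correlations(stub(1, diag(c(1, 1))))
  expect_equal(gc1$cor[1, 2], 0.5)
  gc2 <- genetic_correlations(stub(1, matrix(0, 2, 2)))
  expect_equal(gc2$cor[1, 2], 1)
  gc3 <- genetic_correlations(stub(1, diag(c(1, 3))))
  expect_equal(gc3$cor[1, 2], 1 / sqrt(2 * 4), tolerance = 1e-12)
  # symmetric, unit diagonal, PSD when vg J + Vge is PSD
  gc4 <- genetic_correlations(stub(0.8, diag(c(0.5, 1, 2))))
  expect_identical(gc4$cor, t(gc4$cor))
  expect_equal(unname(diag(gc4$cor)), rep(1, 3))
  expect_gte(min(eigen(gc4$cor, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
})

test_that("heritability formulas match hand arithmetic", {
  expect_equal(h2_clonal_mean(9, 4, 2, 2), 9 / 10)
  expect_equal(h2_clonal_mean(9, 4, 2, 1), 9 / 11)
  expect_equal(h2_clonal_mean(0, 4, 2, 2), 0)
  expect_equal(h2_met(9, 3, 6, 3, 2), 9 / 11, tolerance = 1e-12)
  expect_equal(h2_met(9, 0, 0, 3, 2), 1)
  # monotone in sigma_g, decreasing in sigma_e
  grid_g <- seq(0.5, 8, by = 0.5)
  expect_true(all(diff(vapply(grid_g, h2_clonal_mean, numeric(1),
                              sigma_e = 4, n = 2, r = 2)) > 0))
  grid_e <- seq(0.5, 8, by = 0.5)
  expect_true(all(diff(vapply(grid_e, function(e)
    h2_met(4, 1, e, 5, 2), numeric(1))) < 0))
})

test_that("location and MET heritabilities recover simulated components", {
  cfg <- small_met_config(n_genotypes = 80, vg = 4, v_ge = 0.5,
                          residual_var = 2, residual_cor = 0)
  cfg$qtls$cold$kappa <- 0; cfg$qtls$warm$kappa <- 0
  sim <- simulate_met(cfg, seed = 6)
  h <- location_h2(sim$pheno, "A")
  # per-location truth: genetic variance vg + v_ge (interaction folds into
  # the genotype term within one location only partially; bounds are loose)
  expect_gt(h$H2, 0.7)
  expect_lte(h$H2, 1)
  expect_equal(h$n_seasons, 2)
  expect_equal(h$r, 2)

  mh <- met_h2(sim$pheno)
  plug <- h2_met(mh$sigma_g, mh$sigma_ge, mh$sigma_e, mh$e, mh$r)
  expect_equal(mh$H2_MET, plug)
  expect_gt(mh$H2_MET, 0.8)

  single <- sim$pheno[sim$pheno$season == 2019 &
                        sim$pheno$location == "A", ]
  class(single) <- c("met_pheno", "data.frame")
  expect_warning(h1 <- location_h2(single, "A"), "single season")
  expect_equal(h1$n_seasons, 1)
})

test_that("variance fractions: environment dominates, genotype exceeds GxE,
           and an all-zero genetic simulation gives near-zero shares", {
  sim <- simulate_met(small_met_config(n_genotypes = 60), seed = 7)
  vf <- variance_fractions(sim$pheno)
  expect_equal(sum(vf), 1, tolerance = 1e-9)
  expect_gt(vf[["environment"]], vf[["genotype"]])
  expect_gt(vf[["genotype"]], vf[["gxe"]])

  cfg0 <- small_met_config(n_genotypes = 60, vg = 0, v_ge = 0)
  cfg0$qtls$cold$kappa <- 0; cfg0$qtls$warm$kappa <- 0
  sim0 <- simulate_met(cfg0, seed = 8)
  vf0 <- variance_fractions(sim0$pheno)
  expect_lt(vf0[["genotype"]], 0.02)
  expect_lt(vf0[["gxe"]], 0.02)
})

test_that("GxE model recovers interaction structure", {
  # no interaction simulated: interaction variances shrink, vg recovered
  sims <- lapply(1:5, function(s) {
    sim <- sim_engine_data(100, 5, 2, vg = 1, v_ge = 0, ve = 0.5,
                           seed = 100 + s)
    fit <- reml_fit(build_design(sim$pheno, met_model_spec(fixed = "env")))
    c(vg = fit$vg, vge = mean(diag(fit$Vge)))
  })
  vg_hat <- vapply(sims, `[[`, numeric(1), "vg")
  vge_hat <- vapply(sims, `[[`, numeric(1), "vge")
  expect_lt(abs(median(vg_hat) - 1), 0.15)
  expect_lt(median(vge_hat), 0.1)

  # heterogeneous interaction variances rank-correlate with the truth
  v_truth <- c(0.1, 0.3, 0.6, 1.0, 1.5, 2.2, 0.05, 0.8)
  rhos <- vapply(1:5, function(s) {
    sim <- sim_engine_data(150, 8, 2, vg = 1, v_ge = v_truth, ve = 0.5,
                           seed = 200 + s)
    fit <- reml_fit(build_design(sim$pheno, met_model_spec(fixed = "env")))
    cor(diag(fit$Vge), v_truth, method = "spearman")
  }, numeric(1))
  expect_gte(median(rhos), 0.7)
})

test_that("environment effects test as overwhelmingly significant when
           simulated large", {
  sim <- simulate_met(small_met_config(n_genotypes = 40), seed = 9)
  fit <- fit_gxe_model(sim$pheno)
  w <- wald_tests(fit, "env")
  expect_lt(w$p, 1e-10)
})
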