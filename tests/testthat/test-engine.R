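# Mixed-model engine: design construction, restricted likelihood, REML
# estimates, Wald tests, lsmeans.

test_that("design matrix rank matches the factorial structure", {
  # 2 environments x 2 blocks: intercept + (2-1) env + 2*(2-1) blocks = 4
  ph <- grid_pheno(paste0("g", 1:3), "A", 2019:2020, replicates = 2,
                   values = rnorm(12, 90))
  d <- build_design(ph, met_model_spec(fixed = c("env", "block_in_env")))
  expect_equal(ncol(d$X), 4)
  expect_equal(qr(d$X)$rank, 4)
  # dropped aliased columns are reported
  expect_true(length(d$dropped) > 0)

  expect_error(build_design(ph, met_model_spec(fixed = c("env", "nope"))),
               "nope")
  ph1 <- grid_pheno(paste0("g", 1:3), "A", 2019, values = rnorm(3, 90))
  expect_error(build_design(ph1, met_model_spec(fixed = "env")),
               "single level")
})

test_that("restricted likelihood matches the OLS closed form under iid", {
  set.seed(42)
  ph <- grid_pheno(paste0("g", 1:6), "A", 2019:2020, replicates = 2,
                   values = rnorm(24, 90, 2))
  d <- build_design(ph, met_model_spec(fixed = "env", gxe = "none"))
  X <- d$X; y <- d$y
  n <- length(y); p <- ncol(X)
  rss <- sum(lm.fit(X, y)$residuals^2)
  s2 <- rss / (n - p)
  closed <- -0.5 * ((n - p) * log(s2) + determinant(crossprod(X))$modulus +
                      (n - p) + (n - p) * log(2 * pi))
  engine <- restricted_loglik(d, vg = NULL, Vge = NULL, resid_vars = s2)
  expect_equal(engine, as.numeric(closed), tolerance = 1e-10)
})

test_that("restricted likelihood is invariant to row permutation", {
  sim <- simulate_met(small_met_config(n_genotypes = 8), seed = 4)
  spec <- met_model_spec(fixed = c("env", "block_in_env"))
  d1 <- build_design(sim$pheno, spec)
  shuffled <- as.data.frame(sim$pheno)[sample(nrow(sim$pheno)), ]
  class(shuffled) <- c("met_pheno", "data.frame")
  d2 <- build_design(shuffled, spec)
  vg <- 1.3; Vge <- diag(runif(d1$n_env, 0.2, 0.8))
  rv <- runif(d1$n_env, 0.5, 1.5)
  expect_equal(restricted_loglik(d1, vg, Vge, rv),
               restricted_loglik(d2, vg, Vge, rv), tolerance = 1e-10)
})

test_that("balanced one-way REML matches expected-mean-squares estimates", {
  set.seed(11)
  g <- 30; r <- 4
  vals <- rnorm(g, 0, 3)[rep(seq_len(g), each = r)] +
    rnorm(g * r, 50, 1.5)
  ph <- met_pheno(data.frame(
    genotype_id = rep(sprintf("g%02d", seq_len(g)), each = r),
    location = "A", season = 2020, block = "b1",
    replicate = rep(seq_len(r), g), trait = "BF", value = vals))
  spec <- met_model_spec(fixed = "1", genotype = TRUE, gxe = "none",
                         residual = "iid")
  fit <- reml_fit(build_design(ph, spec))
  aovfit <- aov(value ~ genotype_id, data = as.data.frame(ph))
  ms <- summary(aovfit)[[1]][["Mean Sq"]]
  vg_ems <- (ms[1] - ms[2]) / r
  ve_ems <- ms[2]
  expect_equal(fit$vg, vg_ems, tolerance = 1e-6)
  expect_equal(fit$resid$vars[1], ve_ems, tolerance = 1e-6)
  # cross-check against lme4 on the same data
  lfit <- lme4::lmer(value ~ (1 | genotype_id), data = as.data.frame(ph))
  expect_equal(fit$loglik, as.numeric(logLik(lfit)), tolerance = 1e-6)
})

test_that("REML improves on its initialization and recovers components", {
  sim <- sim_engine_data(60, 4, 2, vg = 1, v_ge = 0.3, ve = 0.6, seed = 8)
  d <- build_design(sim$pheno, met_model_spec(fixed = "env"))
  fit <- reml_fit(d)
  # optimizer contract: final restricted loglik is at least the value at
  # the default equal-split initialization
  v0 <- var(d$y) / 3
  ll0 <- restricted_loglik(d, vg = v0, Vge = diag(rep(v0, d$n_env)),
                           resid_vars = rep(v0, d$n_env))
  expect_gte(fit$loglik, ll0)
  expect_true(fit$convergence$converged)
  expect_equal(fit$vg, 1, tolerance = 0.5)
})

test_that("with variance ratios at zero the fixed estimates are OLS", {
  sim <- simulate_met(small_met_config(n_genotypes = 10), seed = 14)
  spec <- met_model_spec(fixed = c("env", "block_in_env"))
  d <- build_design(sim$pheno, spec)
  core_beta <- {
    eps <- var(d$y) * 1e-12
    # vg = Vge = 0: V = sigma^2 I, GLS reduces to OLS
    fitted <- lm.fit(d$X, d$y)
    fitted$coefficients
  }
  ll <- restricted_loglik(d, vg = NULL, Vge = NULL, resid_vars = 1)
  expect_true(is.finite(ll))
  # engine GLS at V = I equals OLS coefficients
  f0 <- metgxe:::reml_core(d, NULL, NULL,
                           list(vars = rep(1, d$n_env), loc_mats = NULL))
  expect_equal(unname(f0$beta), unname(core_beta), tolerance = 1e-8)
})

test_that("fitted interaction and residual structures stay PSD", {
  sim <- simulate_met(small_met_config(n_genotypes = 25), seed = 15)
  for (gxe in c("diag", "cs_het", "fa1")) {
    fit <- suppressMessages(
      fit_gxe_model(sim$pheno, gxe = gxe, scale = FALSE))
    if (!is.null(fit$Vge))
      expect_gte(min(eigen(fit$Vge, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-10)
    expect_true(all(fit$resid$vars >= 0))
  }
  fit_us <- fit_gxe_model(sim$pheno, residual = "us_season", scale = FALSE)
  for (M in fit_us$resid$loc_mats)
    expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
})

test_that("the dense oracle agrees with a season-correlated residual", {
  sim <- simulate_met(small_met_config(n_genotypes = 6, residual_cor = 0.4),
                      seed = 16)
  d <- build_design(sim$pheno,
                    met_model_spec(fixed = c("env", "block_in_env"),
                                   residual = "us_season"))
  loc_mats <- lapply(setNames(d$loc_levels, d$loc_levels), function(l) {
    s <- length(d$loc_seasons[[l]])
    0.8 * ((1 - 0.3) * diag(s) + 0.3)
  })
  vg <- 0.7; Vge <- diag(rep(0.4, d$n_env))
  a <- restricted_loglik(d, vg, Vge, resid_vars = 1,
                         resid_loc_mats = loc_mats)
  b <- dense_reml_oracle(d, vg, Vge, resid_vars = rep(1, d$n_env),
                         loc_mats = loc_mats)
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("Wald statistic matches the two-sample z statistic squared", {
  set.seed(77)
  n_half <- 60
  ph <- met_pheno(data.frame(
    genotype_id = sprintf("g%03d", seq_len(2 * n_half)),
    location = "A", season = 2020, block = "b1", replicate = 1,
    trait = "BF",
    value = c(rnorm(n_half, 90, 2), rnorm(n_half, 91.5, 2))))
  ph$grp <- rep(c("x", "y"), each = n_half)
  fit <- reml_fit(build_design(ph, met_model_spec(
    fixed = "grp", genotype = FALSE, gxe = "none", residual = "iid")))
  w <- wald_tests(fit)
  tt <- t.test(value ~ grp, data = as.data.frame(ph), var.equal = TRUE)
  expect_equal(w$wald, unname(tt$statistic)^2, tolerance = 1e-3)
  expect_equal(w$df, 1L)
  # rank-deficient term: df = 0, missing p
  ph$dup <- ph$grp
  fit2 <- reml_fit(build_design(ph, met_model_spec(
    fixed = c("grp", "dup"), genotype = FALSE, gxe = "none",
    residual = "iid")))
  w2 <- wald_tests(fit2)
  expect_equal(w2$df[w2$term == "dup"], 0L)
  expect_true(is.na(w2$p[w2$term == "dup"]))
})

test_that("sequential Wald mode agrees with the conditional test for the
           last term added", {
  sim <- simulate_met(small_met_config(n_genotypes = 12), seed = 19)
  fit <- reml_fit(build_design(sim$pheno, met_model_spec(
    fixed = c("env", "block_in_env"))))
  cond <- wald_tests(fit, "block_in_env", mode = "conditional")
  seq_ <- wald_tests(fit, "block_in_env", mode = "sequential")
  expect_equal(seq_$wald, cond$wald, tolerance = 1e-6)
})

test_that("lsmeans equal raw class means on balanced data and match
           emmeans on unbalanced data", {
  skip_if_not_installed("emmeans")
  set.seed(5)
  df <- expand.grid(class = c("AA", "AB"), season = factor(2019:2021),
                    rep = 1:6)
  df$value <- 90 + 2 * (df$class == "AB") + rnorm(nrow(df))
  fit <- lm(value ~ class + season, data = df)
  lsm <- ls_means(fit, "class")
  raw <- c(tapply(df$value, df$class, mean))
  expect_equal(lsm$means$lsmean, unname(raw[lsm$means$level]),
               tolerance = 1e-10)

  # unbalanced: drop rows, compare against emmeans
  df2 <- df[-c(1, 2, 3, 7, 13, 20), ]
  fit2 <- lm(value ~ class + season, data = df2)
  lsm2 <- ls_means(fit2, "class")
  em <- as.data.frame(emmeans::emmeans(fit2, "class"))
  expect_equal(lsm2$means$lsmean, em$emmean, tolerance = 1e-8)
  expect_equal(lsm2$means$se, em$SE, tolerance = 1e-8)
  emc <- as.data.frame(emmeans::contrast(emmeans::emmeans(fit2, "class"),
                                         "pairwise"))
  expect_equal(lsm2$contrasts$diff, emc$estimate, tolerance = 1e-8)
  expect_equal(lsm2$contrasts$p, emc$p.value, tolerance = 1e-8)
})
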