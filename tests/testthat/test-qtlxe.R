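# QTL class encoding, selection rule, single/complete models, effect sizes,
# PVE, temperature correlation, marker contrasts.

test_that("QTL classes concatenate flanking-marker genotypes", {
  mat <- matrix(c("AB", "AA", NA, "AB", "AB", "AA"), ncol = 2,
                dimnames = list(paste0("i", 1:3), c("mkA", "mkB")))
  mk <- met_markers(mat)
  q <- encode_qtl_classes(mk, "Q1", c("mkA", "mkB"))
  expect_equal(unname(q$classes["i1"]), "AB/AB")
  expect_equal(unname(q$classes["i2"]), "AA/AB")
  expect_true(is.na(q$classes["i3"]))
  expect_error(encode_qtl_classes(mk, "Q1", c("mkA", "missing")), "absent")
})

test_that("flanking-marker class frequencies reflect Haldane linkage", {
  map <- data.frame(marker = c("mk1", "mk2"), linkage_group = "LG1",
                    position_cM = c(0, 5), position_Mb = NA,
                    segregation = "ABxAA")
  mk <- simulate_fullsib_markers(synth_config(), map, n = 10000, seed = 55)
  q <- encode_qtl_classes(mk, "Q", c("mk1", "mk2"))
  nonparental <- mean(q$classes %in% c("AA/AB", "AB/AA"))
  expect_lt(abs(nonparental - haldane_r(5)), 0.01)
})

test_that("QTL selection applies the significance rule exactly", {
  fake <- function(qtl, p_main, p_int)
    structure(list(qtl = qtl,
                   wald = data.frame(term = c("q", "q:env"),
                                     wald = c(1, 1), df = c(1, 1),
                                     p = c(p_main, p_int))),
              class = "met_qtl_fit")
  sel <- select_qtls(list(fake("a", 0.03, 0.20), fake("b", 0.20, 0.04),
                          fake("c", 0.20, 0.20)))
  expect_equal(sel$selected, c(TRUE, TRUE, FALSE))
  sel_b <- select_qtls(list(fake("a", 0.03, 0.20), fake("b", 0.20, 0.04),
                            fake("c", 0.20, 0.20)), adjust = "bonferroni")
  expect_equal(sel_b$selected, c(FALSE, FALSE, FALSE))
})

test_that("single-QTL model detects a conditionally neutral QTL and the
           complete model with one QTL reproduces it exactly", {
  sim <- simulate_met(small_met_config(n_genotypes = 80), seed = 33)
  q <- encode_qtl_classes(sim$markers, "qR4", c("R4_m1", "R4_m2"))
  f <- suppressWarnings(
    fit_single_qtl(sim$pheno, q, gxe = "iid", residual = "iid"))
  expect_true(all(f$wald$df >= 1))
  expect_true(all(f$wald$p > 0 & f$wald$p <= 1))
  # interaction significant: effect ranges from 0 (warm) to large (cold)
  expect_lt(f$wald$p[f$wald$effect == "interaction"], 0.05)

  cf <- suppressWarnings(
    fit_complete_model(sim$pheno, list(q), gxe = "iid", residual = "iid"))
  expect_equal(cf$wald$wald, f$wald$wald, tolerance = 1e-8)
  expect_equal(cf$wald$p, f$wald$p, tolerance = 1e-8)
  expect_equal(cf$per_qtl$qR4$d_by_env, f$d_by_env, tolerance = 1e-8)
})

test_that("two independent QTLs keep significant effects in the complete
           model", {
  sim <- simulate_met(small_met_config(n_genotypes = 100), seed = 44)
  q1 <- encode_qtl_classes(sim$markers, "qR4", c("R4_m1", "R4_m2"))
  q2 <- encode_qtl_classes(sim$markers, "qL1", c("L1_m1", "L1_m2"))
  cf <- suppressWarnings(
    fit_complete_model(sim$pheno, list(q1, q2), gxe = "iid",
                       residual = "iid"))
  expect_equal(nrow(cf$wald), 4)
  # each QTL significant (main or interaction) conditional on the other
  for (q in c("qR4", "qL1")) {
    ps <- cf$wald$p[cf$wald$qtl == q]
    expect_lt(min(ps, na.rm = TRUE), 0.05)
  }
  # aliased QTL pair is refused
  expect_error(suppressWarnings(
    fit_complete_model(sim$pheno, list(q1, q1))), "aliased")
})

test_that("estimated per-environment effects track the simulated rule", {
  sim <- simulate_met(small_met_config(n_genotypes = 120), seed = 51)
  q <- encode_qtl_classes(sim$markers, "qR4", c("R4_m1", "R4_m2"))
  f <- suppressWarnings(
    fit_single_qtl(sim$pheno, q, gxe = "iid", residual = "iid"))
  pv <- qtl_pve_by_env(f, sim$pheno)
  d_true <- sim$truth$qtl_d["cold", pv$env]
  ok <- !is.na(pv$d)
  expect_gte(cor(pv$d[ok], d_true[ok]), 0.8)
  # PVE arithmetic: p(1-p) d^2 / var * 100
  expect_equal(pv$pve,
               100 * pv$p_high * (1 - pv$p_high) * pv$d^2 / pv$var_pheno,
               tolerance = 1e-12)
})

test_that("consistent allele relabeling only flips contrast signs", {
  sim <- simulate_met(small_met_config(n_genotypes = 60), seed = 61)
  q <- encode_qtl_classes(sim$markers, "qR4", c("R4_m1", "R4_m2"))
  swapped <- q
  swapped$classes <- chartr("AB", "BA", q$classes)
  # class frequencies are preserved under the swap; per-location contrasts
  # flip sign only
  loc <- "A"
  a <- class_contrasts_by_location(sim$pheno, q, loc)
  b <- class_contrasts_by_location(sim$pheno, swapped, loc)
  merged <- merge(a$contrasts, b$contrasts,
                  by.x = c("a", "b"), by.y = c("b", "a"),
                  suffixes = c("_orig", "_swap"))
  relabel <- function(x) chartr("AB", "BA", x)
  m2 <- a$contrasts
  m2$a <- relabel(m2$a); m2$b <- relabel(m2$b)
  for (k in seq_len(nrow(m2))) {
    hit <- which(b$contrasts$a == m2$a[k] & b$contrasts$b == m2$b[k])
    rev <- which(b$contrasts$a == m2$b[k] & b$contrasts$b == m2$a[k])
    if (length(hit) == 1)
      expect_equal(b$contrasts$diff[hit], m2$diff[k], tolerance = 1e-10)
    else
      expect_equal(b$contrasts$diff[rev], -m2$diff[k], tolerance = 1e-10)
  }
})

test_that("effect-temperature correlation handles clean and degenerate
           inputs", {
  eff <- c(e1 = 1, e2 = 2, e3 = 3, e4 = 4)
  temp <- c(e1 = 10, e2 = 8, e3 = 6, e4 = 4)
  ec <- effect_temperature_correlation(eff, temp)
  expect_equal(ec$r, -1, tolerance = 1e-12)
  expect_warning(
    ec0 <- effect_temperature_correlation(
      c(e1 = 1, e2 = 1, e3 = 1, e4 = 1), temp), "zero variance")
  expect_true(is.na(ec0$r))
  expect_error(effect_temperature_correlation(eff[1:3], temp[1:3]),
               ">= 4")
})

test_that("per-location class contrasts: balanced lsmeans equal raw means
           and degenerate classes are refused", {
  set.seed(3)
  g <- sprintf("g%02d", 1:20)
  cls <- setNames(rep(c("AA", "AB"), each = 10), g)
  ph <- grid_pheno(g, "A", 2019:2020, replicates = 2,
                   values = 90 + 2 * (rep(cls, 4) == "AB") + rnorm(80))
  lsm <- class_contrasts_by_location(ph, cls, "A")
  raw <- c(tapply(ph$value, cls[as.character(ph$genotype_id)], mean))
  expect_equal(lsm$means$lsmean, unname(raw[lsm$means$level]),
               tolerance = 1e-10)
  expect_equal(lsm$means$n_genotypes, c(10L, 10L))

  mono <- setNames(rep("AA", 20), g)
  expect_error(class_contrasts_by_location(ph, mono, "A"),
               "single marker class")
})

test_that("pairwise contrasts reproduce directed mean differences", {
  means <- c("A:A" = 91.6, "G:A" = 95.1)
  expect_equal(class_contrast(means, "G:A", "A:A"), 3.5, tolerance = 1e-9)
  pc <- pairwise_contrasts(c(x = 1, y = 3, z = 6))
  expect_equal(pc$diff, c(-2, -5, -3))
  expect_error(class_contrast(means, "G:G", "A:A"), "not found")
})
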