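# QTL x E inference: QTL class encoding from flanking markers, single-QTL
# and complete multi-QTL mixed models with Wald tests, per-environment QTL
# effect sizes and PVE, the effect-temperature correlation, and per-location
# marker-class contrasts.

#' Encode a QTL class variable from two flanking markers
#'
#' Each individual's value is the concatenated genotype of the two closest
#' flanking markers of the QTL (e.g. `"AB/AA"`); individuals with either
#' marker missing are missing.
#'
#' @param markers a [met_markers] object.
#' @param qtl QTL label (e.g. `"R4"`).
#' @param marker_pair character vector of the two flanking marker names.
#' @return a `met_qtl_classes` list: `qtl`, `markers`, `classes` (named
#'   character vector per individual).
#' @export
encode_qtl_classes <- function(markers, qtl, marker_pair) {
  absent <- setdiff(marker_pair, markers$markers)
  if (length(absent) > 0)
    stop_metgxe("marker(s) absent from matrix: ",
                paste(absent, collapse = ", "))
  m1 <- markers$classes[, marker_pair[1]]
  m2 <- markers$classes[, marker_pair[2]]
  cls <- ifelse(is.na(m1) | is.na(m2), NA_character_,
                paste(m1, m2, sep = "/"))
  names(cls) <- markers$individuals
  structure(list(qtl = qtl, markers = marker_pair, classes = cls),
            class = "met_qtl_classes")
}

# Merge QTL class variables into the phenotype table as factor columns
# named by QTL; records with any missing class are dropped (fixed-effect
# factors cannot carry missing levels).
merge_qtl_classes <- function(pheno, qtls, min_class_n = 5) {
  df <- as.data.frame(pheno)
  cols <- character(0)
  for (q in qtls) {
    cname <- make.names(q$qtl)
    cls <- q$classes[as.character(df$genotype_id)]
    counts <- table(cls[!duplicated(df$genotype_id)])
    keep_classes <- names(counts)[counts >= min_class_n]
    if (length(keep_classes) < 2)
      stop_metgxe("QTL ", q$qtl, " has fewer than 2 classes with >= ",
                  min_class_n, " individuals")
    if (length(keep_classes) < length(counts))
      warning("QTL ", q$qtl, ": rare class(es) dropped: ",
              paste(setdiff(names(counts), keep_classes), collapse = ", "),
              call. = FALSE)
    cls[!cls %in% keep_classes] <- NA
    df[[cname]] <- cls
    cols <- c(cols, cname)
  }
  df <- df[complete.cases(df[, cols, drop = FALSE]), ]
  for (cname in cols) df[[cname]] <- factor(df[[cname]])
  if (length(cols) > 1) {
    for (i in seq_len(length(cols) - 1)) for (j in (i + 1):length(cols)) {
      if (identical(as.integer(df[[cols[i]]]), as.integer(df[[cols[j]]])))
        stop_metgxe("QTL class variables are aliased (identical classes): ",
                    cols[i], " and ", cols[j])
    }
  }
  class(df) <- c("met_pheno", "data.frame")
  attr(df, "qtl_cols") <- cols
  df
}

# Resolve a term label irrespective of the variable order used by the
# formula machinery (e.g. "qR4:env" may be recorded as "env:qR4").
resolve_term <- function(labels, term) {
  want <- sort(strsplit(term, ":", fixed = TRUE)[[1]])
  hit <- which(vapply(labels, function(l)
    identical(sort(strsplit(l, ":", fixed = TRUE)[[1]]), want), logical(1)))
  if (length(hit) == 0) stop_metgxe("term not in model: ", term)
  labels[hit[1]]
}

# Per-class, per-environment fixed-effect predictions for a QTL term, the
# extreme classes in overall mean order, and the per-environment contrast
# d between them (defined only where both extreme classes are observed).
qtl_class_env_effects <- function(fit, qname, data) {
  design <- fit$design
  if (length(design$dropped_assign) > 0) {
    hit <- design$term_labels[design$dropped_assign] |>
      vapply(function(l) qname %in% strsplit(l, ":", fixed = TRUE)[[1]],
             logical(1))
    if (any(hit))
      warning("aliased column(s) in the ", qname, " terms (empty class x ",
              "environment cell?); per-environment effects may be ",
              "inaccurate where data are sparse", call. = FALSE)
  }
  vars <- unique(unlist(strsplit(design$term_labels, ":", fixed = TRUE)))
  grid_parts <- list()
  for (v in vars) {
    grid_parts[[v]] <- if (v %in% names(design$xlevels))
      design$xlevels[[v]] else mean(design$data[[v]])
  }
  # average over nuisance factors not involved in the QTL-by-environment
  # surface is unnecessary: their contribution cancels in contrasts, so fix
  # them at their first level
  for (v in setdiff(names(grid_parts), c(qname, "env")))
    if (v %in% names(design$xlevels)) grid_parts[[v]] <- grid_parts[[v]][1]
  grid <- expand.grid(grid_parts, stringsAsFactors = TRUE)
  for (v in names(design$xlevels))
    grid[[v]] <- factor(grid[[v]], levels = design$xlevels[[v]])
  Xg <- model.matrix(design$terms, grid, contrasts.arg = design$contrasts)
  Xg <- Xg[, colnames(design$X), drop = FALSE]
  pred <- drop(Xg %*% fit$beta)
  classes <- design$xlevels[[qname]]
  envs <- design$env_levels
  eff <- matrix(NA_real_, length(classes), length(envs),
                dimnames = list(classes, envs))
  eff[cbind(match(grid[[qname]], classes), match(grid$env, envs))] <- pred
  observed <- table(design$data[[qname]], design$data$env) > 0
  overall <- rowMeans(eff)
  hi <- classes[which.max(overall)]
  lo <- classes[which.min(overall)]
  d <- ifelse(observed[hi, envs] & observed[lo, envs],
              eff[hi, ] - eff[lo, ], NA_real_)
  list(effects = eff, extreme = c(high = hi, low = lo),
       d_by_env = setNames(d, envs), observed = observed)
}

#' Fit a single-QTL mixed model with QTL x E terms
#'
#' Extends the G x E model by entering the QTL class variable and its
#' interaction with environment as fixed effects, with the background
#' genotype main effect and background-by-environment effects random:
#' \eqn{y = m + e_{lj} + eb_{ljk} + q_i + qe_{lji} + x_i + xe_{lji} +
#' r_{ljki}}.  Wald tests are reported for the QTL main and QTL x E terms.
#' The per-environment effect size `d` is the contrast between the two
#' classes most extreme in overall adjusted mean.
#'
#' @param pheno a [met_pheno] table (raw scale).
#' @param qtl a [encode_qtl_classes()] variable.
#' @param trait,gxe,residual,scale,control as in [fit_gxe_model()].
#' @return a `met_qtl_fit`: `qtl`, `fit`, `wald` (main and interaction
#'   rows), `class_env_effects`, `extreme_classes`, `d_by_env` (on the
#'   analysis scale), `env_sds` (when scaled).
#' @export
fit_single_qtl <- function(pheno, qtl, trait = "BF", gxe = "diag",
                           residual = "diag_env", scale = TRUE,
                           control = list()) {
  df <- merge_qtl_classes(pheno, list(qtl))
  qname <- attr(df, "qtl_cols")
  env_sds <- NULL
  if (scale) {
    df <- scale_by_env_sd(df, trait)
    env_sds <- attr(df, "env_sds")
  }
  has_blocks <- any(tapply(df$block, df$env,
                           function(b) length(unique(b))) > 1)
  fixed <- c("env", if (has_blocks) "block_in_env",
             qname, paste0(qname, ":env"))
  spec <- met_model_spec(trait = trait, fixed = fixed, genotype = TRUE,
                         gxe = gxe, residual = residual)
  fit <- reml_fit(build_design(df, spec), control = control)
  int_term <- resolve_term(fit$term_labels, paste0(qname, ":env"))
  wald <- wald_tests(fit, terms = c(qname, int_term))
  wald$effect <- c("main", "interaction")
  ce <- qtl_class_env_effects(fit, qname, df)
  structure(list(qtl = qtl$qtl, qname = qname, fit = fit, wald = wald,
                 class_env_effects = ce$effects,
                 extreme_classes = ce$extreme,
                 d_by_env = ce$d_by_env, observed = ce$observed,
                 env_sds = env_sds),
            class = "met_qtl_fit")
}

#' @export
print.met_qtl_fit <- function(x, ...) {
  cat("Single-QTL mixed model for QTL", x$qtl, "\n")
  print(x$wald, digits = 4)
  cat("extreme classes:", x$extreme_classes["high"], "-",
      x$extreme_classes["low"], "\n")
  invisible(x)
}

#' Select QTLs from single-QTL fits
#'
#' A candidate is selected when its main effect or its environment
#' interaction (or both) is significant at `alpha`.
#'
#' @param fits list of `met_qtl_fit` objects.
#' @param alpha significance level (default 0.05; no multiple-testing
#'   adjustment by default, `adjust = "bonferroni"` applies one across
#'   candidates).
#' @param adjust `"none"` or `"bonferroni"`.
#' @return data frame with `qtl`, `p_main`, `p_interaction`, `selected`.
#' @export
select_qtls <- function(fits, alpha = 0.05, adjust = c("none",
                                                       "bonferroni")) {
  adjust <- match.arg(adjust)
  out <- do.call(rbind, lapply(fits, function(f)
    data.frame(qtl = f$qtl, p_main = f$wald$p[1],
               p_interaction = f$wald$p[2])))
  thr <- if (adjust == "bonferroni") alpha / nrow(out) else alpha
  out$selected <- (!is.na(out$p_main) & out$p_main < thr) |
    (!is.na(out$p_interaction) & out$p_interaction < thr)
  rownames(out) <- NULL
  out
}

#' Fit the complete multi-QTL model
#'
#' All selected QTLs enter jointly as fixed class and class-by-environment
#' terms over a common random background, so each QTL's Wald test is
#' conditional on the others.
#'
#' @param pheno a [met_pheno] table (raw scale).
#' @param qtls list of [encode_qtl_classes()] variables.
#' @param trait,gxe,residual,scale,control as in [fit_gxe_model()].
#' @return a `met_complete_fit`: the joint `fit`, per-QTL `wald` table, and
#'   per-QTL class-environment effects as in [fit_single_qtl()].
#' @export
fit_complete_model <- function(pheno, qtls, trait = "BF", gxe = "diag",
                               residual = "diag_env", scale = TRUE,
                               control = list()) {
  if (length(qtls) == 0) stop_metgxe("no QTLs supplied")
  df <- merge_qtl_classes(pheno, qtls)
  qnames <- attr(df, "qtl_cols")
  env_sds <- NULL
  if (scale) {
    df <- scale_by_env_sd(df, trait)
    env_sds <- attr(df, "env_sds")
  }
  has_blocks <- any(tapply(df$block, df$env,
                           function(b) length(unique(b))) > 1)
  fixed <- c("env", if (has_blocks) "block_in_env",
             as.vector(rbind(qnames, paste0(qnames, ":env"))))
  spec <- met_model_spec(trait = trait, fixed = fixed, genotype = TRUE,
                         gxe = gxe, residual = residual)
  fit <- reml_fit(build_design(df, spec), control = control)
  test_terms <- as.vector(rbind(
    qnames, vapply(qnames, function(q)
      resolve_term(fit$term_labels, paste0(q, ":env")), character(1))))
  wald <- wald_tests(fit, terms = test_terms)
  wald$qtl <- rep(vapply(qtls, function(q) q$qtl, character(1)), each = 2)
  wald$effect <- rep(c("main", "interaction"), length(qnames))
  per_qtl <- lapply(seq_along(qtls), function(k) {
    ce <- qtl_class_env_effects(fit, qnames[k], df)
    list(qtl = qtls[[k]]$qtl, qname = qnames[k],
         class_env_effects = ce$effects, extreme_classes = ce$extreme,
         d_by_env = ce$d_by_env, observed = ce$observed)
  })
  names(per_qtl) <- vapply(qtls, function(q) q$qtl, character(1))
  structure(list(fit = fit, wald = wald, per_qtl = per_qtl,
                 env_sds = env_sds),
            class = "met_complete_fit")
}

#' Per-environment phenotypic variance explained by a QTL
#'
#' An estimator of the QTL's PVE in each environment from the fitted
#' extreme-class contrast and observed class frequencies:
#' \deqn{PVE_{lj} = 100\, p_{lj}(1 - p_{lj})\, d_{lj}^2 /
#'   \widehat{var}_{pheno}(lj)}
#' where `p` is the observed frequency of the later-flowering extreme class
#' among scored individuals carrying either extreme class, `d` the fitted
#' contrast (back-transformed to the raw scale when the model was fitted on
#' environment-scaled data) and the denominator the raw phenotypic variance
#' of the environment.
#'
#' @param qfit a `met_qtl_fit` (or one element of a complete fit's
#'   `per_qtl` plus its `env_sds`).
#' @param pheno the raw-scale [met_pheno] table used for the fit.
#' @param trait `"BF"` or `"FF"`.
#' @return data frame with `env`, `d` (raw scale), `p_high`, `var_pheno`,
#'   `pve` (percent); environments lacking both extreme classes are `NA`.
#' @export
qtl_pve_by_env <- function(qfit, pheno, trait = "BF") {
  df <- as.data.frame(pheno)
  df <- df[df$trait == trait & !is.na(df$value), ]
  envs <- names(qfit$d_by_env)
  hi <- qfit$extreme_classes["high"]
  lo <- qfit$extreme_classes["low"]
  data_fit <- qfit$fit$design$data
  rows <- lapply(envs, function(e) {
    d <- qfit$d_by_env[[e]]
    if (!is.na(d) && !is.null(qfit$env_sds)) d <- d * qfit$env_sds[[e]]
    sub <- data_fit[data_fit$env == e, ]
    cls <- sub[[qfit$qname]][!duplicated(sub$genotype_id)]
    n_hi <- sum(cls == hi); n_lo <- sum(cls == lo)
    p <- if (n_hi + n_lo > 0) n_hi / (n_hi + n_lo) else NA_real_
    vp <- var(df$value[df$env == e])
    pve <- if (is.na(d) || is.na(p) || !is.finite(vp) || vp <= 0) NA_real_
           else 100 * p * (1 - p) * d^2 / vp
    data.frame(env = e, d = d, p_high = p, var_pheno = vp, pve = pve)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between per-environment QTL effect and temperature
#'
#' Pearson correlation (with two-sided p-value) between a per-environment
#' QTL quantity (effect size `d` or PVE) and the environments' Oct-Mar
#' mean temperatures.
#'
#' @param effect named numeric vector (names = environment labels).
#' @param temperature named numeric vector of Oct-Mar mean temperatures.
#' @return list with `r`, `p`, `n`.
#' @export
effect_temperature_correlation <- function(effect, temperature) {
  shared <- intersect(names(effect), names(temperature))
  x <- effect[shared]; y <- temperature[shared]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4)
    stop_metgxe("need >= 4 environments with both quantities")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in effect or temperature; correlation undefined",
            call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Marker-class least-squares means and contrasts within a location
#'
#' Per-location analysis of a single marker: a fixed-effect linear model
#' with marker class, season and block, from which adjusted class means and
#' all pairwise contrasts (t-based p-values) are computed.
#'
#' @param pheno a [met_pheno] table.
#' @param classes a [encode_qtl_classes()] variable, or a named character
#'   vector of per-individual classes at a single marker.
#' @param location location label.
#' @param trait `"BF"` or `"FF"`.
#' @return a `met_lsmeans` with an extra `n_genotypes` column in `means`.
#' @export
class_contrasts_by_location <- function(pheno, classes, location,
                                        trait = "BF") {
  cls <- if (inherits(classes, "met_qtl_classes")) classes$classes
         else classes
  df <- as.data.frame(pheno)
  df <- df[df$trait == trait & !is.na(df$value) &
             df$location == location, ]
  if (nrow(df) == 0) stop_metgxe("no records for location ", location)
  df$class <- cls[as.character(df$genotype_id)]
  df <- df[!is.na(df$class), ]
  df$class <- factor(df$class)
  if (nlevels(df$class) < 2)
    stop_metgxe("single marker class observed in ", location)
  df$season <- factor(df$season)
  df$block <- factor(df$block)
  terms <- c("class",
             if (nlevels(df$season) > 1) "season",
             if (nlevels(df$block) > 1) "block")
  fit <- lm(reformulate(terms, response = "value"), data = df)
  lsm <- ls_means(fit, "class")
  ng <- tapply(df$genotype_id, df$class,
               function(g) length(unique(g)))
  lsm$means$n_genotypes <- as.integer(ng[lsm$means$level])
  lsm
}
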