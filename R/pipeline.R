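# Pipeline orchestration: simulate -> describe -> fit-gxe -> fit-qtlxe ->
# marker-effects, with CSV outputs and a JSON run manifest.  Stages run in
# dependency order; a stage failure stops its dependents and is recorded.

PIPELINE_STAGES <- c("simulate", "describe", "fit-gxe", "fit-qtlxe",
                     "marker-effects")

#' Run the MET analysis pipeline
#'
#' Simulates (or loads) a MET, runs descriptives, the G x E model with
#' genetic correlations and heritabilities, the QTL x E models, and the
#' per-location marker-effect analyses, writing CSV outputs plus a
#' `manifest.json` recording the seed, configuration, stage status and
#' output inventory.  Re-running with the same seed and inputs reproduces
#' identical outputs.
#'
#' @param out_dir output directory.
#' @param seed integer seed driving all randomness.
#' @param config a [synth_config()] for the simulate stage.
#' @param stages subset of `c("simulate", "describe", "fit-gxe",
#'   "fit-qtlxe", "marker-effects")`.
#' @param pheno,markers,map,climate optional pre-loaded inputs; required
#'   (from files or a previous simulate) when `"simulate"` is not among
#'   `stages`.
#' @param trait `"BF"` or `"FF"`.
#' @param gxe,residual covariance structure tags for the model stages.
#' @param scale logical, scale by environment SD before mixed-model fits.
#' @return the manifest, invisibly.  Errors if any stage failed.
#' @export
run_pipeline <- function(out_dir, seed, config = synth_config(),
                         stages = PIPELINE_STAGES,
                         pheno = NULL, markers = NULL, map = NULL,
                         climate = NULL, trait = "BF", gxe = "diag",
                         residual = "diag_env", scale = TRUE) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0)
    stop_metgxe("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!gxe %in% GXE_STRUCTURES)
    stop_metgxe("invalid gxe structure tag: ", gxe)
  if (!residual %in% RESID_STRUCTURES)
    stop_metgxe("invalid residual structure tag: ", residual)
  if (!is_scalar_number(seed)) stop_metgxe("an integer seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, package_version =
                     as.character(packageVersion("metgxe")),
                   stages = list(), outputs = character(0))
  record <- function(stage, status, secs)
    manifest$stages[[stage]] <<- list(status = status,
                                      wall_time_s = round(secs, 3))
  emit <- function(name, df) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE, na = "NA")
    manifest$outputs <<- c(manifest$outputs, name)
  }
  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             message = conditionMessage(e)))
    record(stage, if (res$ok) "ok" else paste("failed:", res$message),
           proc.time()[["elapsed"]] - t0)
    res
  }
  failed <- FALSE
  sim <- NULL

  if ("simulate" %in% stages) {
    res <- run_stage("simulate", function() {
      sim <- simulate_met(config, seed)
      write_met(sim, out_dir)
      manifest$outputs <<- c(manifest$outputs, "phenotypes.csv",
                             "markers.csv", "map.csv", "climate.csv",
                             "truth.json")
      sim
    })
    if (res$ok) {
      sim <- res$value
      pheno <- sim$pheno; markers <- sim$markers
      map <- sim$map; climate <- sim$climate
    } else failed <- TRUE
  }
  if (is.null(pheno) && !failed)
    stop_metgxe("no phenotype input: supply `pheno` or include 'simulate'")

  if ("describe" %in% stages && !failed) {
    res <- run_stage("describe", function() {
      emit("env_summary.csv", env_summary(pheno, trait))
      sp <- spearman_matrices(pheno, "years_within_location", trait)
      sp_long <- do.call(rbind, lapply(names(sp), function(g) {
        cm <- sp[[g]]$cor
        idx <- which(upper.tri(cm), arr.ind = TRUE)
        data.frame(group = g, env_a = rownames(cm)[idx[, 1]],
                   env_b = colnames(cm)[idx[, 2]], spearman = cm[idx])
      }))
      emit("spearman_years_within_location.csv", sp_long)
      rn <- reaction_norms(pheno, "by_location", trait)
      emit("reaction_norms.csv",
           data.frame(genotype_id = rownames(rn$matrix), rn$matrix,
                      check.names = FALSE))
      if (!is.null(climate)) {
        envs <- unique(as.data.frame(pheno)[, c("location", "season")])
        cc <- characterize_climate(climate, envs)
        emit("climate_deviations.csv", cc$deviations)
        emit("env_temperature.csv", cc$env_temperature)
      } else {
        warning("no climate input; climate characterization skipped",
                call. = FALSE)
      }
      NULL
    })
    if (!res$ok) failed <- TRUE
  }

  gfit <- NULL
  if ("fit-gxe" %in% stages && !failed) {
    res <- run_stage("fit-gxe", function() {
      gfit <- fit_gxe_model(pheno, trait, gxe = gxe, residual = residual,
                            scale = scale)
      gc_ <- genetic_correlations(gfit)
      emit("genetic_correlations.csv",
           data.frame(env = rownames(gc_$cor), gc_$cor,
                      check.names = FALSE))
      h2 <- do.call(rbind, lapply(unique(pheno$location), function(l)
        as.data.frame(location_h2(pheno, l, trait))))
      emit("heritability.csv", h2)
      mh <- met_h2(pheno, trait)
      emit("met_heritability.csv", as.data.frame(mh))
      vf <- variance_fractions(pheno, trait)
      emit("variance_fractions.csv",
           data.frame(component = names(vf), fraction = as.numeric(vf)))
      jsonlite::write_json(
        list(seed = seed, vg = gfit$vg, v_ge = diag(gfit$Vge),
             resid_vars = gfit$resid$vars, loglik = gfit$loglik,
             mean_genetic_correlation = gc_$mean_offdiag),
        file.path(out_dir, "components.json"), auto_unbox = TRUE,
        digits = NA)
      manifest$outputs <<- c(manifest$outputs, "components.json")
      gfit
    })
    if (res$ok) gfit <- res$value else failed <- TRUE
  }

  if ("fit-qtlxe" %in% stages && !failed) {
    res <- run_stage("fit-qtlxe", function() {
      if (is.null(markers)) stop_metgxe("no marker input for fit-qtlxe")
      qtls <- lapply(config$qtls, function(q)
        encode_qtl_classes(markers, q$name, q$flanking))
      sfits <- lapply(qtls, function(q)
        fit_single_qtl(pheno, q, trait, gxe = gxe, residual = residual,
                       scale = scale))
      emit("wald_single.csv",
           do.call(rbind, lapply(sfits, function(f)
             data.frame(qtl = f$qtl, f$wald))))
      sel <- select_qtls(sfits)
      emit("qtl_selection.csv", sel)
      if (any(sel$selected)) {
        cfit <- fit_complete_model(pheno, qtls[sel$selected], trait,
                                   gxe = gxe, residual = residual,
                                   scale = scale)
        emit("wald_complete.csv", cfit$wald)
      }
      pve <- do.call(rbind, lapply(sfits, function(f)
        data.frame(qtl = f$qtl, qtl_pve_by_env(f, pheno, trait))))
      emit("pve_by_env.csv", pve)
      if (!is.null(climate)) {
        envs <- unique(as.data.frame(pheno)[, c("location", "season")])
        tt <- characterize_climate(climate, envs)$env_temperature
        temp <- setNames(tt$t_octmar, tt$env)
        tc <- do.call(rbind, lapply(sfits, function(f) {
          pv <- qtl_pve_by_env(f, pheno, trait)
          ec <- effect_temperature_correlation(setNames(pv$pve, pv$env),
                                               temp)
          data.frame(qtl = f$qtl, r = ec$r, p = ec$p, n = ec$n)
        }))
        emit("temperature_correlation.csv", tc)
      }
      NULL
    })
    if (!res$ok) failed <- TRUE
  }

  if ("marker-effects" %in% stages && !failed) {
    res <- run_stage("marker-effects", function() {
      if (is.null(markers)) stop_metgxe("no marker input")
      qtl_loci <- vapply(config$qtls, function(q) q$name, character(1))
      rows <- list()
      for (mk in intersect(qtl_loci, markers$markers)) {
        cls <- setNames(markers$classes[, mk], markers$individuals)
        for (l in unique(pheno$location)) {
          lsm <- tryCatch(class_contrasts_by_location(pheno, cls, l, trait),
                          error = function(e) NULL)
          if (is.null(lsm)) next
          rows[[paste(mk, l)]] <-
            data.frame(marker = mk, location = l, lsm$contrasts)
        }
      }
      emit("marker_contrasts.csv", do.call(rbind, rows))
      NULL
    })
    if (!res$ok) failed <- TRUE
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  if (failed) {
    msgs <- vapply(manifest$stages, function(s) s$status, character(1))
    stop_metgxe("pipeline failed; stage status: ",
                paste(names(msgs), msgs, sep = "=", collapse = "; "))
  }
  invisible(manifest)
}
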