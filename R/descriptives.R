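# Phenotype summaries, Spearman correlation matrices among environments,
# reaction norms with a rank-change (crossover) statistic, and climate
# characterization over the dormancy window.

#' Per-environment phenotype summary
#'
#' Mean, minimum, maximum and count of non-missing values per environment.
#' Environments with no scored values are omitted with a warning.
#'
#' @param pheno a [met_pheno] table.
#' @param trait `"BF"` or `"FF"`.
#' @return data frame with columns `env`, `location`, `season`, `n`,
#'   `mean`, `min`, `max`.
#' @export
env_summary <- function(pheno, trait = "BF") {
  df <- pheno[pheno$trait == trait, ]
  envs <- unique(df[, c("env", "location", "season")])
  envs <- envs[order(envs$location, envs$season), ]
  rows <- lapply(seq_len(nrow(envs)), function(i) {
    v <- df$value[df$env == envs$env[i]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    data.frame(envs[i, ], n = length(v), mean = mean(v), min = min(v),
               max = max(v))
  })
  omitted <- envs$env[vapply(rows, is.null, logical(1))]
  if (length(omitted) > 0)
    warning("environment(s) with no scored values omitted: ",
            paste(omitted, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Replicate-averaged genotype x environment means as a matrix.
genotype_env_means <- function(pheno, trait = "BF") {
  df <- pheno[pheno$trait == trait & !is.na(pheno$value), ]
  if (nrow(df) == 0) stop_metgxe("no records for trait ", trait)
  agg <- aggregate(value ~ genotype_id + env, data = df, FUN = mean)
  genos <- sort(unique(as.character(df$genotype_id)))
  envs <- unique(df[, c("env", "location", "season")])
  envs <- envs[order(envs$location, envs$season), ]
  M <- matrix(NA_real_, length(genos), nrow(envs),
              dimnames = list(genos, envs$env))
  M[cbind(match(agg$genotype_id, genos), match(agg$env, envs$env))] <-
    agg$value
  attr(M, "env_info") <- envs
  M
}

#' Spearman correlation matrices among environments
#'
#' Rank correlations of genotype means (replicates averaged first) between
#' environments, computed within families: either among the seasons of each
#' location, or among the locations of each season.  Cells with fewer than
#' three shared genotypes are set missing with a warning.
#'
#' @param pheno a [met_pheno] table.
#' @param family `"years_within_location"` or `"locations_within_year"`.
#' @param trait `"BF"` or `"FF"`.
#' @return named list of `met_spearman` objects, one per location (or
#'   season): each holds `cor` (symmetric, unit diagonal) and `n` (shared
#'   genotypes per cell).
#' @export
spearman_matrices <- function(pheno,
                              family = c("years_within_location",
                                         "locations_within_year"),
                              trait = "BF") {
  family <- match.arg(family)
  M <- genotype_env_means(pheno, trait)
  info <- attr(M, "env_info")
  groups <- if (family == "years_within_location")
    split(seq_len(nrow(info)), info$location)
  else split(seq_len(nrow(info)), info$season)
  lapply(groups, function(cols) {
    sub <- M[, cols, drop = FALSE]
    k <- ncol(sub)
    cm <- diag(k)
    nm <- matrix(0L, k, k)
    dimnames(cm) <- dimnames(nm) <- list(colnames(sub), colnames(sub))
    diag(nm) <- colSums(!is.na(sub))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i >= j) next
      ok <- complete.cases(sub[, c(i, j)])
      nm[i, j] <- nm[j, i] <- sum(ok)
      if (sum(ok) < 3) {
        warning("fewer than 3 shared genotypes for ", colnames(sub)[i],
                " vs ", colnames(sub)[j], "; cell set missing",
                call. = FALSE)
        cm[i, j] <- cm[j, i] <- NA_real_
      } else {
        cm[i, j] <- cm[j, i] <- cor(sub[ok, i], sub[ok, j],
                                    method = "spearman")
      }
    }
    structure(list(cor = cm, n = nm), class = "met_spearman")
  })
}

#' Reaction norms and rank-change (crossover) count
#'
#' Returns the genotype x environment matrix of replicate-averaged means,
#' environments ordered either by location within each year or by year
#' within each location, together with a crossover statistic: the number of
#' genotype pairs whose order inverts between at least one pair of adjacent
#' environments in the ordering.  The statistic is invariant to adding a
#' constant to all phenotypes.
#'
#' @param pheno a [met_pheno] table.
#' @param ordering `"by_location"` (environments sorted location-major) or
#'   `"by_year"` (season-major).
#' @param trait `"BF"` or `"FF"`.
#' @return list with `matrix` (genotypes x environments) and `crossovers`
#'   (integer count of inverting genotype pairs).
#' @export
reaction_norms <- function(pheno, ordering = c("by_location", "by_year"),
                           trait = "BF") {
  ordering <- match.arg(ordering)
  M <- genotype_env_means(pheno, trait)
  info <- attr(M, "env_info")
  ord <- if (ordering == "by_location") order(info$location, info$season)
         else order(info$season, info$location)
  M <- M[, ord, drop = FALSE]
  if (ncol(M) < 2) stop_metgxe("need >= 2 environments for reaction norms")
  inverted <- matrix(FALSE, nrow(M), nrow(M))
  for (k in seq_len(ncol(M) - 1)) {
    a <- M[, k]; b <- M[, k + 1]
    ok <- which(!is.na(a) & !is.na(b))
    if (length(ok) < 2) next
    da <- outer(a[ok], a[ok], "-")
    db <- outer(b[ok], b[ok], "-")
    inverted[ok, ok] <- inverted[ok, ok] | (da * db < 0)
  }
  list(matrix = M, crossovers = sum(inverted[upper.tri(inverted)]))
}

#' Characterize environments from daily temperatures
#'
#' For each location, computes a daily reference mean over all available
#' years of the dormancy window (Oct 1 through May 31, indexed by day of
#' window), represents each studied season as a deviation series from that
#' reference, and computes each environment's Oct-Mar mean temperature
#' (Oct 1 of the year preceding the season through Mar 31 of the season
#' year).  Missing days are tolerated; a coverage fraction below 80% of the
#' window draws a warning.
#'
#' @param climate a [read_climate()] table.
#' @param environments data frame with columns `location`, `season` (one
#'   row per environment to characterize).
#' @return list with `reference` (location, day_of_window, ref_tmean),
#'   `deviations` (location, season, date, day_of_window, deviation) and
#'   `env_temperature` (location, season, env, t_octmar, coverage).
#' @export
characterize_climate <- function(climate, environments) {
  ref_rows <- list(); dev_rows <- list(); env_rows <- list()
  for (loc in unique(environments$location)) {
    cl <- climate[climate$location == loc, ]
    if (nrow(cl) == 0) stop_metgxe("no climate data for location ", loc)
    # window membership: Oct-Dec belongs to the following season's window
    yr <- as.integer(format(cl$date, "%Y"))
    mo <- as.integer(format(cl$date, "%m"))
    season <- ifelse(mo >= 10, yr + 1L, yr)
    start <- as.Date(sprintf("%d-10-01", season - 1L))
    dow <- as.integer(cl$date - start) + 1L
    in_window <- mo >= 10 | mo <= 5
    cl <- cl[in_window, ]; season <- season[in_window]; dow <- dow[in_window]
    ref <- tapply(cl$tmean, dow, mean)
    ref_rows[[loc]] <- data.frame(location = loc,
                                  day_of_window = as.integer(names(ref)),
                                  ref_tmean = as.numeric(ref))
    for (sn in sort(unique(environments$season[environments$location ==
                                               loc]))) {
      sel <- season == sn
      if (!any(sel)) stop_metgxe("no climate data for ", loc, " season ", sn)
      dev_rows[[paste(loc, sn)]] <- data.frame(
        location = loc, season = sn, date = cl$date[sel],
        day_of_window = dow[sel],
        deviation = cl$tmean[sel] - as.numeric(ref[as.character(dow[sel])]))
      octmar <- sel & (cl$date <= as.Date(sprintf("%d-03-31", sn))) &
        (cl$date >= as.Date(sprintf("%d-10-01", sn - 1L)))
      n_days <- as.integer(as.Date(sprintf("%d-03-31", sn)) -
                             as.Date(sprintf("%d-10-01", sn - 1L))) + 1L
      coverage <- sum(octmar) / n_days
      if (coverage < 0.8)
        warning(sprintf("Oct-Mar coverage %.0f%% for %s %d", 100 * coverage,
                        loc, sn), call. = FALSE)
      env_rows[[paste(loc, sn)]] <- data.frame(
        location = loc, season = sn, env = paste(loc, sn, sep = ":"),
        t_octmar = mean(cl$tmean[octmar]), coverage = coverage)
    }
  }
  list(reference = do.call(rbind, c(ref_rows, make.row.names = FALSE)),
       deviations = do.call(rbind, c(dev_rows, make.row.names = FALSE)),
       env_temperature = do.call(rbind, c(env_rows,
                                          make.row.names = FALSE)))
}
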