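# Domain types and file readers for MET data: long-format phenotypes,
# marker-class matrices from an F1 full-sib cross, genetic maps, and daily
# climate tables.  Environments are location x season combinations.

PHENO_COLS <- c("genotype_id", "location", "season", "block", "replicate",
                "trait", "value")

#' Construct a MET phenotype table
#'
#' Builds a validated long-format phenotype table.  Each record is one
#' scoring of one tree: a genotype in a block/replicate of one environment
#' (location x season), for one trait, with the value in Julian days
#' (day of year) or `NA` when the tree was not scored.
#'
#' @param df data frame with columns `genotype_id`, `location`, `season`
#'   (integer calendar year), `block`, `replicate`, `trait` (`"BF"` or
#'   `"FF"`), `value` (Julian day or `NA`).
#' @return A `met_pheno` object: the data frame with an added `env` column
#'   (`location:season` label).
#' @export
met_pheno <- function(df) {
  missing_cols <- setdiff(PHENO_COLS, names(df))
  if (length(missing_cols) > 0)
    stop_metgxe("phenotype table lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, union(PHENO_COLS, names(df))]
  df$season <- as.integer(df$season)
  df$value <- as.numeric(df$value)
  bad_trait <- !df$trait %in% c("BF", "FF")
  if (any(bad_trait))
    stop_metgxe("trait must be 'BF' or 'FF'; offending rows: ",
                paste(head(which(bad_trait), 5), collapse = ", "))
  out_of_range <- !is.na(df$value) & (df$value < 1 | df$value > 200)
  if (any(out_of_range))
    stop_metgxe("Julian-day values must lie in [1, 200]; offending rows: ",
                paste(head(which(out_of_range), 5), collapse = ", "))
  key <- do.call(paste, c(df[c("genotype_id", "location", "season", "block",
                               "replicate", "trait")], sep = "\r"))
  if (anyDuplicated(key))
    stop_metgxe("duplicate (genotype, environment, block, replicate, trait) ",
                "key(s), first at row ", which(duplicated(key))[1])
  df$env <- paste(df$location, df$season, sep = ":")
  class(df) <- c("met_pheno", "data.frame")
  df
}

#' Read a long-format phenotype table from CSV
#'
#' The canonical dialect is a comma-separated file with header
#' `genotype_id,location,season,block,replicate,trait,value` and missing
#' token `NA`.  Other dialects are accommodated through `dialect`, a named
#' character vector mapping canonical names to the file's column names.
#'
#' @param path path to a CSV file.
#' @param dialect optional named character vector, e.g.
#'   `c(genotype_id = "geno", value = "jd")`.
#' @return A [met_pheno] table.
#' @export
read_phenotypes <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_metgxe("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                  colClasses = "character")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      hit <- match(dialect[[canon]], names(raw))
      if (!is.na(hit)) names(raw)[hit] <- canon
    }
  }
  missing_cols <- setdiff(PHENO_COLS, names(raw))
  if (length(missing_cols) > 0)
    stop_metgxe("phenotype file lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  val_chr <- raw$value
  val_num <- suppressWarnings(as.numeric(val_chr))
  bad <- !is.na(val_chr) & is.na(val_num)
  if (any(bad))
    stop_metgxe("unparseable phenotype value(s) at line(s) ",
                paste(head(which(bad) + 1L, 5), collapse = ", "),
                " of ", path)
  raw$value <- val_num
  met_pheno(raw)
}

#' Write a phenotype table in the canonical CSV dialect
#'
#' @param pheno a [met_pheno] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  df <- as.data.frame(pheno)[, PHENO_COLS]
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Construct a marker-class matrix
#'
#' Marker genotypes of an F1 full-sib family, coded `AA`/`AB`/`BB` (unphased;
#' parental origin is not tracked).  The segregation type of each marker is
#' either `ABxAA` (pseudo-testcross: one parent heterozygous, expected 1:1
#' AA:AB) or `ABxAB` (both parents heterozygous, expected 1:2:1 AA:AB:BB).
#' Unless declared, segregation is inferred from the observed classes: a
#' marker with no `BB` class is taken as `ABxAA`.
#'
#' @param classes character matrix, rows = individuals (rownames), columns =
#'   markers (colnames), cells in `AA`, `AB`, `BB` or `NA`.
#' @param segregation optional named character vector (`ABxAA`/`ABxAB`) that
#'   overrides inference per marker.
#' @return A `met_markers` object: list with `classes`, `individuals`,
#'   `markers`, `segregation` and per-marker observed class `frequencies`.
#' @export
met_markers <- function(classes, segregation = NULL) {
  classes <- as.matrix(classes)
  if (is.null(rownames(classes)))
    rownames(classes) <- paste0("ind", seq_len(nrow(classes)))
  if (is.null(colnames(classes)))
    colnames(classes) <- paste0("mk", seq_len(ncol(classes)))
  ok <- is.na(classes) | classes %in% c("AA", "AB", "BB")
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop_metgxe("marker class outside {AA, AB, BB, NA} at (",
                rownames(classes)[idx[1]], ", ", colnames(classes)[idx[2]],
                "): '", classes[idx[1], idx[2]], "'")
  }
  seg <- vapply(seq_len(ncol(classes)), function(j) {
    if (any(classes[, j] == "BB", na.rm = TRUE)) "ABxAB" else "ABxAA"
  }, character(1))
  names(seg) <- colnames(classes)
  if (!is.null(segregation)) {
    bad <- setdiff(names(segregation), colnames(classes))
    if (length(bad) > 0)
      stop_metgxe("segregation declared for unknown marker(s): ",
                  paste(bad, collapse = ", "))
    has_bb <- vapply(names(segregation), function(m)
      any(classes[, m] == "BB", na.rm = TRUE), logical(1))
    if (any(segregation == "ABxAA" & has_bb))
      stop_metgxe("marker(s) declared ABxAA but contain BB classes: ",
                  paste(names(segregation)[segregation == "ABxAA" & has_bb],
                        collapse = ", "))
    seg[names(segregation)] <- segregation
  }
  freq <- lapply(seq_len(ncol(classes)), function(j)
    table(factor(classes[, j], levels = c("AA", "AB", "BB"))))
  names(freq) <- colnames(classes)
  structure(list(classes = classes, individuals = rownames(classes),
                 markers = colnames(classes), segregation = seg,
                 frequencies = freq),
            class = "met_markers")
}

#' Read a marker-class matrix from CSV
#'
#' Expects rows = individuals (first column holds individual labels),
#' columns = markers, cells in `AA`/`AB`/`BB`/`NA`.
#'
#' @inheritParams met_markers
#' @param path path to a CSV file.
#' @return A [met_markers] object.
#' @export
read_marker_classes <- function(path, segregation = NULL) {
  if (!file.exists(path)) stop_metgxe("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                  colClasses = "character")
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- raw[[1]]
  met_markers(mat, segregation = segregation)
}

#' Read a genetic map table from CSV
#'
#' Expects columns `marker`, `linkage_group`, `position_cM` and optionally
#' `position_Mb`.  Markers are sorted by position within linkage group.
#'
#' @param path path to a CSV file.
#' @return data frame of class `met_map`.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop_metgxe("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  req <- c("marker", "linkage_group", "position_cM")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0)
    stop_metgxe("map file lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  if (!"position_Mb" %in% names(raw)) raw$position_Mb <- NA_real_
  if (any(raw$position_cM < 0, na.rm = TRUE))
    stop_metgxe("negative cM positions in map")
  raw <- raw[order(raw$linkage_group, raw$position_cM), ]
  rownames(raw) <- NULL
  class(raw) <- c("met_map", "data.frame")
  raw
}

#' Read a daily climate table from CSV
#'
#' Expects columns `location`, `date` (ISO-8601) and either `tmean` or the
#' pair `tmin`/`tmax`, from which `tmean` is derived as their midpoint.
#'
#' @param path path to a CSV file.
#' @return data frame of class `met_climate` with columns `location`,
#'   `date` (`Date`), `tmean`.
#' @export
read_climate <- function(path) {
  if (!file.exists(path)) stop_metgxe("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (!all(c("location", "date") %in% names(raw)))
    stop_metgxe("climate file needs columns location, date")
  if (!"tmean" %in% names(raw)) {
    if (!all(c("tmin", "tmax") %in% names(raw)))
      stop_metgxe("climate file needs tmean, or both tmin and tmax")
    raw$tmean <- (as.numeric(raw$tmin) + as.numeric(raw$tmax)) / 2
  }
  raw$date <- as.Date(raw$date)
  if (anyNA(raw$date)) stop_metgxe("unparseable date(s) in climate file")
  key <- paste(raw$location, raw$date)
  if (anyDuplicated(key))
    stop_metgxe("duplicate (location, date) record(s), first: ",
                key[which(duplicated(key))[1]])
  out <- raw[, c("location", "date", "tmean")]
  class(out) <- c("met_climate", "data.frame")
  out
}

#' Validate the design of a MET phenotype table
#'
#' Reports per-environment genotype and record counts and an unbalance
#' summary.  Genotypes present in a single environment carry no
#' between-environment information and are flagged as warnings; duplicate
#' observation keys are errors.  The check is side-effect-free.
#'
#' @param pheno a [met_pheno] table.
#' @return A `met_validation` list with elements `per_env` (data frame),
#'   `warnings`, `errors`, and `unbalance` (fraction of genotype x
#'   environment cells that are filled).
#' @export
validate_met <- function(pheno) {
  if (nrow(pheno) == 0) stop_metgxe("empty phenotype table")
  errors <- character(0)
  warnings <- character(0)
  key <- do.call(paste, c(pheno[c("genotype_id", "env", "block", "replicate",
                                  "trait")], sep = "\r"))
  dups <- unique(key[duplicated(key)])
  if (length(dups) > 0)
    errors <- c(errors, paste0("duplicate record key(s): ",
                               paste(gsub("\r", "/", head(dups, 5)),
                                     collapse = "; ")))
  envs <- sort(unique(pheno$env))
  per_env <- do.call(rbind, lapply(envs, function(e) {
    sub <- pheno[pheno$env == e, ]
    reps <- table(sub$genotype_id[!duplicated(paste(sub$genotype_id,
                                                    sub$replicate))])
    data.frame(env = e,
               n_genotypes = length(unique(sub$genotype_id)),
               n_records = nrow(sub),
               median_replicates = as.numeric(median(reps)))
  }))
  singletons <- names(which(tapply(pheno$env, pheno$genotype_id,
                                   function(e) length(unique(e))) == 1))
  if (length(singletons) > 0 && length(envs) > 1)
    warnings <- c(warnings, paste0(
      "genotype(s) present in a single environment (no between-environment ",
      "information): ", paste(head(singletons, 10), collapse = ", "),
      if (length(singletons) > 10) " ..."))
  low <- per_env$env[per_env$n_genotypes < 2]
  if (length(low) > 0)
    errors <- c(errors, paste0("environment(s) with < 2 genotypes: ",
                               paste(low, collapse = ", ")))
  cells <- table(pheno$genotype_id, pheno$env)
  unbalance <- mean(cells > 0)
  structure(list(per_env = per_env, warnings = warnings, errors = errors,
                 unbalance = unbalance),
            class = "met_validation")
}

#' @export
print.met_validation <- function(x, ...) {
  cat("MET validation:", nrow(x$per_env), "environments,",
      sum(x$per_env$n_records), "records\n")
  cat(sprintf("filled genotype x environment cells: %.1f%%\n",
              100 * x$unbalance))
  if (length(x$errors)) cat("errors:\n", paste(" -", x$errors, "\n"))
  if (length(x$warnings)) cat("warnings:\n", paste(" -", x$warnings, "\n"))
  if (!length(x$errors) && !length(x$warnings)) cat("no problems found\n")
  invisible(x)
}

#' Read a flat key = value analysis configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values that parse as numbers are converted.
#'
#' @param path path to the configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_metgxe("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop_metgxe("unparseable config line: ", ln)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
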