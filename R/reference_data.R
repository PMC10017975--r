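# Published reference values shipped with the package.

#' Published KASP marker-class mean flowering dates
#'
#' Per-location least-squares mean flowering dates (beginning of flowering,
#' Julian days) for the genotype classes of four KASP markers scored in a
#' 'Regina' x 'Lapins' sweet cherry F1 population across five European
#' locations, as published for that trial.  Two markers sit in the
#' flowering-date QTL region on linkage group 1 (three classes each) and
#' two in the region on linkage group 4 (two classes each).  These are the
#' worked-example inputs for [pairwise_contrasts()] and [class_contrast()]:
#' differences of these means reproduce the published allele-effect sizes,
#' e.g. 3.5 days between the KASP_9.936 classes in Maribor.
#'
#' @param marker optional marker name to filter on.
#' @return data frame with columns `marker`, `class`, `n_individuals` and
#'   one mean column per location (Forli, Maribor, Murcia, Nimes,
#'   Toulenne).
#' @export
kasp_reference_means <- function(marker = NULL) {
  path <- system.file("extdata", "kasp_class_means.csv",
                      package = "metgxe", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(marker)) {
    df <- df[df$marker %in% marker, ]
    if (nrow(df) == 0) stop_metgxe("unknown marker: ", marker)
  }
  df
}
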