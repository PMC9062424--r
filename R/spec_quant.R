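# Beer-Lambert conversions for the colorimetric/UV quantifications used
# around iron-sulfur enzyme reconstitution: ferrozine-iron (562 nm, eps 27.9
# mM^-1 cm^-1), methylene-blue sulfide (670 nm, eps 34.5), and peptide A280
# (eps 5.6). Units are mM and cm throughout.

#' Define an absorbance assay sample
#'
#' @param absorbance absorbance (AU, >= 0).
#' @param epsilon molar extinction coefficient in mM^-1 cm^-1 (> 0).
#' @param path_cm optical path length in cm (default 1).
#' @param dilution_factor dilution applied before reading (>= 1).
#' @param reference_conc optional reference concentration in mM (e.g. protein
#'   monomer) for molar-equivalents reporting.
#' @return An `assay_sample`.
#' @export
assay_sample <- function(absorbance, epsilon, path_cm = 1,
                         dilution_factor = 1, reference_conc = NULL) {
  if (any(absorbance < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (any(epsilon <= 0)) stop("epsilon must be > 0", call. = FALSE)
  if (any(path_cm <= 0)) stop("path_cm must be > 0", call. = FALSE)
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1", call. = FALSE)
  structure(list(absorbance = absorbance, epsilon = epsilon, path_cm = path_cm,
                 dilution_factor = dilution_factor,
                 reference_conc = reference_conc),
            class = "assay_sample")
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' `A / (epsilon * l) * dilution_factor`, in mM.
#'
#' @param sample an [assay_sample].
#' @return Concentration in mM.
#' @export
concentration <- function(sample) {
  sample$absorbance / (sample$epsilon * sample$path_cm) * sample$dilution_factor
}

#' Molar equivalents of an analyte relative to a reference
#'
#' @param analyte_mM analyte concentration (mM).
#' @param reference_mM reference concentration (mM, > 0).
#' @return Dimensionless equivalents.
#' @export
equivalents <- function(analyte_mM, reference_mM) {
  if (any(reference_mM <= 0)) stop("reference concentration must be > 0", call. = FALSE)
  analyte_mM / reference_mM
}

#' Apply Beer-Lambert arithmetic to an assay table
#'
#' @param df data frame with columns `sample_id`, `absorbance`, `epsilon`,
#'   and optionally `path_cm`, `dilution_factor`, `reference_mM`.
#' @return The table with `conc_mM` (and `equivalents` when a reference is
#'   given) appended.
#' @export
assay_concentrations <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$path_cm)) df$path_cm <- 1
  if (is.null(df$dilution_factor)) df$dilution_factor <- 1
  df$conc_mM <- df$absorbance / (df$epsilon * df$path_cm) * df$dilution_factor
  if (!is.null(df$reference_mM)) {
    ok <- !is.na(df$reference_mM)
    df$equivalents <- NA_real_
    df$equivalents[ok] <- equivalents(df$conc_mM[ok], df$reference_mM[ok])
  }
  df
}
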