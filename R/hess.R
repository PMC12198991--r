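#' Entropy of formation from absolute entropy (Hess's law)
#'
#' The formation reaction of CmHnOpNo(g) from the elements in their standard
#' states has an entropy change equal to the species' absolute entropy minus
#' the absolute entropies of the stoichiometric elements.
#'
#' @param S_abs absolute entropy of the species, J mol^-1 K^-1.
#' @param f an [elemental_formula()] or formula string.
#' @param constants a [thermo_constants()] object.
#' @return Entropy of formation, J mol^-1 K^-1.
#' @examples
#' formation_entropy(836.9, "C25H12N2O10")  # a diimidetricarboxylic acid
#' @export
formation_entropy <- function(S_abs, f, constants = thermo_constants()) {
  stopifnot(is.numeric(S_abs), S_abs > 0)
  S_abs - element_entropy_sum(f, constants)
}

#' Gibbs energy of formation from enthalpy and entropy of formation
#'
#' The Gibbs relation dfG = dfH - T*dfS, with the unit convention of
#' thermochemical tables: enthalpy and Gibbs energy in kJ mol^-1, entropy in
#' J mol^-1 K^-1.  The factor 1000 lives here and in
#' [enthalpy_from_gibbs()] only.
#'
#' @param dfH enthalpy of formation, kJ mol^-1.
#' @param dfS entropy of formation, J mol^-1 K^-1.
#' @param T temperature, K (default 298.15).
#' @return Gibbs energy of formation, kJ mol^-1.
#' @examples
#' gibbs_of_formation(-1406.6, -1303.8)
#' @export
gibbs_of_formation <- function(dfH, dfS, T = 298.15) {
  stopifnot(T > 0)
  dfH - T * dfS / 1000
}

#' Enthalpy of formation from Gibbs energy and entropy of formation
#'
#' Exact inverse of [gibbs_of_formation()]: dfH = dfG + T*dfS.  Used to chain
#' a regression-predicted Gibbs energy with a quantum-chemical entropy into an
#' enthalpy of formation.
#'
#' @param dfG Gibbs energy of formation, kJ mol^-1.
#' @param dfS entropy of formation, J mol^-1 K^-1.
#' @param T temperature, K.
#' @return Enthalpy of formation, kJ mol^-1.
#' @examples
#' enthalpy_from_gibbs(-1017.9, -1306.7)
#' @export
enthalpy_from_gibbs <- function(dfG, dfS, T = 298.15) {
  stopifnot(T > 0)
  dfG + T * dfS / 1000
}

#' Enthalpic-difference estimate of a formation enthalpy
#'
#' Estimates the formation enthalpy of a substituted parent compound by
#' transferring the enthalpy increment between a substituted analog and its
#' reference skeleton: `parent + (analog - reference)`.  E.g. the enthalpy of
#' a diaminobenzoic acid from benzoic acid plus the
#' phenylenediamine-vs-benzene increment.
#'
#' @param parent_dfH formation enthalpy of the parent, kJ mol^-1.
#' @param analog_dfH formation enthalpy of the substituted analog, kJ mol^-1.
#' @param reference_dfH formation enthalpy of the analog's unsubstituted
#'   reference, kJ mol^-1.
#' @return Estimated formation enthalpy, kJ mol^-1.
#' @examples
#' enthalpic_difference_estimate(-295.7, 86.6, 82.9)
#' @export
enthalpic_difference_estimate <- function(parent_dfH, analog_dfH,
                                          reference_dfH) {
  parent_dfH + (analog_dfH - reference_dfH)
}

#' Isomerization enthalpy
#'
#' @param dfH_a,dfH_b formation enthalpies of the two isomers, kJ mol^-1.
#' @return `dfH_a - dfH_b`, kJ mol^-1.
#' @export
isomerization_enthalpy <- function(dfH_a, dfH_b) dfH_a - dfH_b

#' Root-sum-square combination of standard uncertainties
#'
#' @param u numeric vector of nonnegative standard uncertainties.
#' @return The combined standard uncertainty `sqrt(sum(u^2))`.
#' @examples
#' combine_rss(c(1.6, 0.9))
#' @export
combine_rss <- function(u) {
  if (!length(u)) stop("empty uncertainty list")
  if (any(is.na(u)) || any(u < 0)) stop("uncertainties must be nonnegative")
  sqrt(sum(u^2))
}

#' Round half away from zero
#'
#' Rounding convention used when comparing computed values against printed
#' table entries (R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# ---- species thermochemistry tables ----------------------------------------

.species_cols <- c("name", "formula", "dfH_kJ_mol", "u_dfH",
                   "dfS_J_molK", "S_abs_J_molK")

#' Assemble a species thermochemistry table
#'
#' A `species_thermo` table is a data frame with one row per species and
#' columns `name`, `formula` (Hill string, may be `NA`), `dfH_kJ_mol`,
#' `u_dfH`, `dfS_J_molK`, `S_abs_J_molK`; missing quantities are `NA`.  When
#' a row carries all of `dfS_J_molK`, `S_abs_J_molK` and `formula`, internal
#' consistency with Hess's law is enforced to 0.05 J mol^-1 K^-1.
#'
#' @param df data frame with at least `name` and one thermochemical column.
#' @param constants a [thermo_constants()] object, used for the consistency
#'   check.
#' @return The validated data frame, classed `species_thermo`.
#' @export
species_thermo <- function(df, constants = thermo_constants()) {
  if (!"name" %in% names(df)) stop("species table needs a 'name' column")
  for (col in .species_cols)
    if (!col %in% names(df)) df[[col]] <- NA
  df <- df[, .species_cols]
  df$name <- as.character(df$name)
  if (anyDuplicated(df$name)) stop("duplicate species names")
  has_any <- rowSums(!is.na(df[, c("dfH_kJ_mol", "dfS_J_molK",
                                   "S_abs_J_molK")])) > 0
  if (any(!has_any))
    stop("species with no thermochemical data: ",
         paste(df$name[!has_any], collapse = ", "))
  chk <- !is.na(df$dfS_J_molK) & !is.na(df$S_abs_J_molK) & !is.na(df$formula)
  for (i in which(chk)) {
    implied <- formation_entropy(df$S_abs_J_molK[i], df$formula[i], constants)
    if (abs(implied - df$dfS_J_molK[i]) > 0.05)
      stop(sprintf(
        "species %s: dfS (%.3f) inconsistent with S_abs - element sum (%.3f)",
        df$name[i], df$dfS_J_molK[i], implied))
  }
  class(df) <- c("species_thermo", "data.frame")
  df
}

#' Read / write species thermochemistry tables
#'
#' CSV columns: `name, formula, dfH_kJ_mol, u_dfH, dfS_J_molK, S_abs_J_molK`.
#' JSON holds the same records as an array of objects.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @param constants a [thermo_constants()] for validation.
#' @return A [species_thermo()] table.
#' @export
read_species_thermo <- function(path, constants = thermo_constants()) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  species_thermo(df, constants)
}

#' @rdname read_species_thermo
#' @param x a [species_thermo()] table.
#' @export
write_species_thermo <- function(x, path) {
  stopifnot(inherits(x, "species_thermo"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  }
  invisible(path)
}
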