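#' Stoichiometric gas-phase reaction
#'
#' Stoichiometry is a named numeric vector of signed coefficients, reactants
#' negative and products positive, e.g. the condensation
#' `2 TMA + DABA -> DITA + 2 H2O` is
#' `c(TMA = -2, DABA = -1, DITA = 1, H2O = 2)`.
#'
#' @param stoichiometry named numeric vector of nonzero signed coefficients.
#' @param T temperature, K.
#' @return An object of class `reaction`.
#' @export
reaction <- function(stoichiometry, T = 298.15) {
  stoichiometry <- unlist(stoichiometry)
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry must be named by species")
  if (any(stoichiometry == 0)) stop("stoichiometric coefficients must be nonzero")
  if (!any(stoichiometry < 0) || !any(stoichiometry > 0))
    stop("reaction needs at least one reactant and one product")
  if (anyDuplicated(names(stoichiometry))) stop("duplicate species")
  stopifnot(T > 0)
  structure(list(stoichiometry = stoichiometry, T = T), class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  s <- x$stoichiometry
  side <- function(v) paste(paste0(ifelse(abs(v) != 1, abs(v), ""),
                                   names(v)), collapse = " + ")
  cat("<reaction> ", side(s[s < 0]), " -> ", side(s[s > 0]),
      "  (T = ", x$T, " K)\n", sep = "")
  invisible(x)
}

#' Read a reaction from JSON
#'
#' `{"stoichiometry": {"TMA": -2, ...}, "T": 298.15}`; an optional
#' `drS_J_molK` field carries a literature reaction entropy for use when
#' per-species formation entropies are not all available, and is attached
#' as the attribute `drS`.
#'
#' @param path JSON file path.
#' @return A [reaction()].
#' @export
read_reaction <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rx <- reaction(unlist(j$stoichiometry),
                 T = if (!is.null(j$T)) j$T else 298.15)
  if (!is.null(j$drS_J_molK)) attr(rx, "drS") <- j$drS_J_molK
  rx
}

.species_value <- function(rxn, thermo, col, what) {
  if (inherits(thermo, "species_thermo")) {
    idx <- match(names(rxn$stoichiometry), thermo$name)
    if (anyNA(idx))
      stop("species missing from thermo table: ",
           paste(names(rxn$stoichiometry)[is.na(idx)], collapse = ", "))
    v <- thermo[[col]][idx]
  } else {
    v <- unlist(thermo)[names(rxn$stoichiometry)]
  }
  if (anyNA(v))
    stop("missing ", what, " for species: ",
         paste(names(rxn$stoichiometry)[is.na(v)], collapse = ", "))
  v
}

#' Reaction enthalpy from species formation enthalpies
#'
#' `sum(nu_i * dfH_i)` over the stoichiometry.  If the table carries
#' standard uncertainties, the combined standard uncertainty
#' `combine_rss(|nu_i| * u_i)` is attached as attribute `"u"` (species
#' without a printed uncertainty contribute zero).
#'
#' @param rxn a [reaction()].
#' @param thermo a [species_thermo()] table, or a named vector of dfH values
#'   (kJ mol^-1).
#' @return Reaction enthalpy, kJ mol^-1.
#' @export
reaction_enthalpy <- function(rxn, thermo) {
  stopifnot(inherits(rxn, "reaction"))
  v <- .species_value(rxn, thermo, "dfH_kJ_mol", "dfH")
  out <- sum(rxn$stoichiometry * v)
  if (inherits(thermo, "species_thermo")) {
    u <- thermo$u_dfH[match(names(rxn$stoichiometry), thermo$name)]
    u[is.na(u)] <- 0
    attr(out, "u") <- combine_rss(abs(rxn$stoichiometry) * u)
  }
  out
}

#' Reaction entropy from species formation entropies
#'
#' `sum(nu_i * dfS_i)`, J mol^-1 K^-1.
#'
#' @param rxn a [reaction()].
#' @param thermo a [species_thermo()] table or named vector of dfS values.
#' @return Reaction entropy, J mol^-1 K^-1.
#' @export
reaction_entropy <- function(rxn, thermo) {
  stopifnot(inherits(rxn, "reaction"))
  sum(rxn$stoichiometry * .species_value(rxn, thermo, "dfS_J_molK", "dfS"))
}

#' Reaction Gibbs energy from reaction enthalpy and entropy
#'
#' `drG = drH - T*drS/1000` (enthalpy in kJ mol^-1, entropy in
#' J mol^-1 K^-1).
#'
#' @param drH reaction enthalpy, kJ mol^-1.
#' @param drS reaction entropy, J mol^-1 K^-1.
#' @param T temperature, K.
#' @return Reaction Gibbs energy, kJ mol^-1.
#' @examples
#' reaction_gibbs(-82.86, -47.92)
#' @export
reaction_gibbs <- function(drH, drS, T = 298.15) {
  stopifnot(T > 0)
  drH - T * drS / 1000
}

#' Equilibrium constant from the reaction Gibbs energy
#'
#' `Keq = exp(-1000 * drG / (R*T))`, dimensionless at standard state.
#' Exponents beyond ~700 overflow double precision; these return `Inf`
#' (or 0) with a warning.
#'
#' @param drG reaction Gibbs energy, kJ mol^-1.
#' @param T temperature, K.
#' @param constants a [thermo_constants()] supplying R.
#' @return The equilibrium constant.
#' @examples
#' equilibrium_constant(-68.57)
#' @export
equilibrium_constant <- function(drG, T = 298.15,
                                 constants = thermo_constants()) {
  stopifnot(T > 0)
  expo <- -1000 * drG / (constants$R * T)
  if (abs(expo) > 700)
    warning("exponent beyond double-precision range; returning ",
            if (expo > 0) "Inf" else "0")
  exp(expo)
}

#' Full reaction thermochemistry report
#'
#' Computes drH (with RSS-combined uncertainty when available), drS, drG and
#' Keq at the reaction temperature.  `drS` may be supplied directly (e.g. a
#' literature value, or the `drS` attribute of a reaction read from JSON)
#' when formation entropies are not available for every species.
#'
#' @param rxn a [reaction()].
#' @param thermo a [species_thermo()] table.
#' @param drS optional reaction entropy override, J mol^-1 K^-1.
#' @param constants a [thermo_constants()].
#' @return List with `drH_kJ_mol`, `u_drH`, `drS_J_molK`, `drG_kJ_mol`,
#'   `u_drG`, `Keq`, `T`.
#' @export
reaction_report <- function(rxn, thermo, drS = NULL,
                            constants = thermo_constants()) {
  stopifnot(inherits(rxn, "reaction"))
  drH <- reaction_enthalpy(rxn, thermo)
  u_drH <- attr(drH, "u")
  drH <- as.numeric(drH)
  if (is.null(drS)) drS <- attr(rxn, "drS")
  if (is.null(drS)) drS <- reaction_entropy(rxn, thermo)
  drG <- reaction_gibbs(drH, drS, rxn$T)
  list(drH_kJ_mol = drH, u_drH = u_drH, drS_J_molK = drS,
       drG_kJ_mol = drG, u_drG = u_drH, Keq = equilibrium_constant(
         drG, rxn$T, constants), T = rxn$T)
}
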