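#' Elemental formulas
#'
#' An `elemental_formula` is a named integer vector mapping element symbols to
#' nonnegative atom counts.  It is the bookkeeping unit behind Hess's-law
#' formation reactions: for a species CmHnOpNo the formation reaction from the
#' elements in their standard states is
#' `m C(s) + n/2 H2(g) + p/2 O2(g) + o/2 N2(g) -> CmHnOpNo(g)`.
#'
#' @param counts named numeric vector or list of nonnegative integer atom
#'   counts, e.g. `c(C = 7, H = 6, O = 2)`.
#' @return An object of class `elemental_formula`.
#' @examples
#' elemental_formula(c(C = 25, H = 12, N = 2, O = 10))
#' @export
elemental_formula <- function(counts = numeric()) {
  counts <- unlist(counts)
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("all counts must be named by element symbol")
    if (any(!names(counts) %in% .known_elements))
      stop("unknown element symbol(s): ",
           paste(setdiff(names(counts), .known_elements), collapse = ", "))
    if (any(counts < 0) || any(counts != round(counts)))
      stop("atom counts must be nonnegative integers")
    counts <- tapply(counts, names(counts), sum)   # merge duplicates
    counts <- counts[counts > 0]
  }
  out <- as.integer(counts[order(match(names(counts), .hill_order))])
  names(out) <- names(counts)[order(match(names(counts), .hill_order))]
  structure(out, class = "elemental_formula")
}

# Hill convention ordering: C, H, then alphabetical
.known_elements <- c(
  "C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si"
)
.hill_order <- c("C", "H", sort(setdiff(.known_elements, c("C", "H"))))

#' Parse a Hill-style formula string
#'
#' Accepts element symbols each followed by an optional positive count, e.g.
#' `"C25H12N2O10"`.  Parentheses, charges and isotopes are not supported.
#'
#' @param text a single formula string.
#' @return An [elemental_formula()].
#' @examples
#' parse_formula("C7H6O2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single string")
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula string: ", sQuote(text))
  elems <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Za-z]+", "", tokens)
  bad <- setdiff(elems, .known_elements)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  if (any(nums == "0"))
    stop("zero atom count in formula string")
  counts <- ifelse(nzchar(nums), as.numeric(nums), 1)
  names(counts) <- elems
  elemental_formula(counts)
}

#' @export
format.elemental_formula <- function(x, ...) {
  if (!length(x)) return("")
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  stopifnot(inherits(e1, "elemental_formula"), inherits(e2, "elemental_formula"))
  all_el <- union(names(e1), names(e2))
  counts <- vapply(all_el, function(el) {
    sum(c(unclass(e1)[el], unclass(e2)[el]), na.rm = TRUE)
  }, numeric(1))
  elemental_formula(counts)
}

#' Scale a formula by an integer multiplier
#' @param f an [elemental_formula()].
#' @param k nonnegative integer.
#' @return An [elemental_formula()].
#' @export
formula_scale <- function(f, k) {
  stopifnot(inherits(f, "elemental_formula"), k >= 0, k == round(k))
  elemental_formula(unclass(f) * k)
}

#' Physical constants and element reference entropies
#'
#' Bundles the molar gas constant, the reference temperature, and the absolute
#' entropies of the elements in their standard reference states (graphite and
#' the diatomic gases) used in Hess's-law formation-entropy calculations.
#'
#' Default entropies (J mol^-1 K^-1, with standard uncertainties): C(s)
#' 5.74 +/- 0.10, H2(g) 130.571 +/- 0.003, O2(g) 205.043 +/- 0.005, N2(g)
#' 191.500 +/- 0.004.  R is the CODATA value 8.314462618 J mol^-1 K^-1.
#'
#' @param R molar gas constant, J mol^-1 K^-1.
#' @param T_ref reference temperature, K.
#' @param element_entropies data frame with columns `species`, `element`,
#'   `atoms` (atoms of the element per molecule of reference species), `S`
#'   (absolute entropy, J mol^-1 K^-1) and `u` (standard uncertainty).
#' @return An object of class `thermo_constants`.
#' @examples
#' k <- thermo_constants()
#' k$T_ref
#' @export
thermo_constants <- function(R = 8.314462618, T_ref = 298.15,
                             element_entropies = NULL) {
  if (is.null(element_entropies)) {
    element_entropies <- data.frame(
      species = c("C(s)", "H2(g)", "O2(g)", "N2(g)"),
      element = c("C", "H", "O", "N"),
      atoms   = c(1L, 2L, 2L, 2L),
      S       = c(5.74, 130.571, 205.043, 191.500),
      u       = c(0.10, 0.003, 0.005, 0.004),
      stringsAsFactors = FALSE
    )
  }
  req <- c("species", "element", "atoms", "S", "u")
  if (!all(req %in% names(element_entropies)))
    stop("element_entropies must have columns: ", paste(req, collapse = ", "))
  if (any(element_entropies$S <= 0)) stop("element entropies must be > 0")
  if (anyDuplicated(element_entropies$element))
    stop("duplicate element in element_entropies")
  if (R <= 0 || T_ref <= 0) stop("R and T_ref must be positive")
  structure(list(R = R, T_ref = T_ref,
                 element_entropies = element_entropies),
            class = "thermo_constants")
}

#' Read a constants override block from JSON
#'
#' The JSON may contain any of `R`, `T_ref`, and `element_entropies` (an array
#' of objects with fields species/element/atoms/S/u); omitted fields keep
#' their defaults.
#'
#' @param path path to a JSON file.
#' @return A [thermo_constants()] object.
#' @export
read_constants <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- thermo_constants()
  thermo_constants(
    R = if (!is.null(cfg$R)) cfg$R else base$R,
    T_ref = if (!is.null(cfg$T_ref)) cfg$T_ref else base$T_ref,
    element_entropies = if (!is.null(cfg$element_entropies))
      as.data.frame(cfg$element_entropies) else base$element_entropies
  )
}

#' Absolute entropy of the stoichiometric elements
#'
#' For a formula CmHnOpNo, returns
#' `m*S(C,s) + (n/2)*S(H2,g) + (p/2)*S(O2,g) + (o/2)*S(N2,g)`:
#' the total absolute entropy of the elements, in their standard reference
#' states, needed to form one mole of the species.  Subtracting this from a
#' species' absolute entropy gives its entropy of formation (Hess's law).
#'
#' @param f an [elemental_formula()] (or formula string).
#' @param constants a [thermo_constants()] object.
#' @param uncertainty if `TRUE`, return a list with elements `S` and `u`
#'   (root-sum-square propagation of the tabulated element uncertainties);
#'   otherwise a bare number.
#' @return Entropy in J mol^-1 K^-1 (or a list when `uncertainty = TRUE`).
#' @examples
#' element_entropy_sum(parse_formula("C25H12N2O10"))
#' @export
element_entropy_sum <- function(f, constants = thermo_constants(),
                                uncertainty = FALSE) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "elemental_formula"),
            inherits(constants, "thermo_constants"))
  ee <- constants$element_entropies
  if (!length(f)) {
    return(if (uncertainty) list(S = 0, u = 0) else 0)
  }
  idx <- match(names(f), ee$element)
  if (anyNA(idx))
    stop("no reference-entropy entry for element(s): ",
         paste(names(f)[is.na(idx)], collapse = ", "))
  mult <- unclass(f) / ee$atoms[idx]
  S <- sum(mult * ee$S[idx])
  if (!uncertainty) return(S)
  list(S = S, u = combine_rss(mult * ee$u[idx]))
}
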