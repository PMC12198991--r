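#' Group-count vector for a molecule
#'
#' A named numeric vector of nonnegative Benson group counts (correction
#' terms included, under the labels of [correction_labels()]).  Labels are
#' canonicalized and duplicate spellings merged.
#'
#' @param counts named numeric vector/list of group counts.
#' @param corrections named numeric vector/list of correction-term counts
#'   (merged with `counts`; split out for readability only).
#' @return An object of class `group_vector`.
#' @examples
#' group_vector(c("C_B-(H)(C_B)2" = 6))  # benzene
#' @export
group_vector <- function(counts = numeric(), corrections = numeric()) {
  counts <- c(unlist(counts), unlist(corrections))
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("all group counts must be named")
    if (any(counts < 0)) stop("group counts must be nonnegative")
    names(counts) <- canonical_label(names(counts))
    counts <- tapply(counts, names(counts), sum)
    counts <- counts[counts > 0]
    counts <- counts[order(names(counts))]
  }
  structure(as.numeric(counts), names = names(counts),
            class = "group_vector")
}

#' @export
print.group_vector <- function(x, ...) {
  cat("<group_vector>", if (!length(x)) " (empty)", "\n", sep = "")
  for (i in seq_along(x))
    cat(sprintf("  %-20s %g\n", names(x)[i], unclass(x)[i]))
  invisible(x)
}

#' @export
`+.group_vector` <- function(e1, e2) {
  stopifnot(inherits(e1, "group_vector"), inherits(e2, "group_vector"))
  group_vector(c(stats::setNames(as.numeric(e1), names(e1)),
                 stats::setNames(as.numeric(e2), names(e2))))
}

#' Group-additivity property estimate
#'
#' Computes `intercept(property) + sum(count * value(label, property))` over
#' all groups and corrections in the vector.  This is the manual-estimation
#' use of regression-derived group values: the intercept is added exactly
#' once per molecule, mirroring a linear fit with intercept.
#'
#' @param gv a [group_vector()] (or named numeric vector of counts).
#' @param table a [gav_table()]; defaults to the packaged one.
#' @param property `"S"` (absolute entropy, J mol^-1 K^-1), `"dfS"` (entropy
#'   of formation, J mol^-1 K^-1) or `"dfG"` (Gibbs energy of formation,
#'   kJ mol^-1).
#' @return The estimated property value.
#' @examples
#' benzene <- group_vector(c("C_B-(H)(C_B)2" = 6))
#' gav_estimate(benzene, property = "S")
#' @export
gav_estimate <- function(gv, table = builtin_gav_table(),
                         property = c("S", "dfS", "dfG")) {
  property <- match.arg(property)
  if (!inherits(gv, "group_vector")) gv <- group_vector(gv)
  stopifnot(inherits(table, "gav_table"))
  idx <- match(names(gv), table$values$label)
  if (anyNA(idx))
    stop("group label(s) not in parameter table: ",
         paste(sQuote(names(gv)[is.na(idx)]), collapse = ", "))
  unname(table$intercept[property]) +
    sum(as.numeric(gv) * table$values[[property]][idx])
}

#' Atom contributions of each group label
#'
#' Maps every label of the packaged table to the elemental formula it
#' contributes: the center heavy atom, the carbonyl oxygen for CO centers,
#' hydrogen ligands, and the absorbed NO2 atoms for the nitro-substituted
#' aromatic carbon.  Correction labels contribute no atoms.  Derived from
#' the canonical label grammar itself.
#'
#' @param labels labels to map; defaults to the packaged table's labels.
#' @return Named list of [elemental_formula()] objects.
#' @export
builtin_atom_map <- function(labels = builtin_gav_table()$values$label) {
  out <- lapply(labels, function(lb) {
    lb <- canonical_label(lb)
    if (lb %in% correction_labels()) return(elemental_formula())
    if (lb == "CH3(qua)") return(elemental_formula(c(C = 1, H = 3)))
    p <- .parse_group_label(lb)
    if (is.null(p)) stop("no atom-map rule for label: ", sQuote(lb))
    counts <- c(C = 0, H = 0, N = 0, O = 0)
    counts[substr(p$center, 1, 1)] <- 1          # C_B/C_D/CO/C -> C; N; O
    if (p$center == "CO") counts["O"] <- counts["O"] + 1
    counts["H"] <- counts["H"] + sum(p$ligands == "H")
    n_no2 <- sum(p$ligands == "NO2")
    counts["N"] <- counts["N"] + n_no2
    counts["O"] <- counts["O"] + 2 * n_no2
    elemental_formula(counts)
  })
  stats::setNames(out, canonical_label(labels))
}

#' Elemental formula implied by a group vector
#'
#' Sums the per-group atom contributions times counts; used to validate
#' proposed decompositions against a molecule's known formula (atom
#' conservation).
#'
#' @param gv a [group_vector()].
#' @param atom_map named list of [elemental_formula()] contributions; defaults
#'   to [builtin_atom_map()] extended over the labels present in `gv`.
#' @return An [elemental_formula()].
#' @examples
#' formula_from_groups(group_vector(c("C_B-(H)(C_B)2" = 6)))  # C6H6
#' @export
formula_from_groups <- function(gv, atom_map = NULL) {
  if (!inherits(gv, "group_vector")) gv <- group_vector(gv)
  if (!length(gv)) return(elemental_formula())
  if (is.null(atom_map)) {
    atom_map <- builtin_atom_map(names(gv))
  } else {
    names(atom_map) <- canonical_label(names(atom_map))
    missing <- setdiff(names(gv), names(atom_map))
    if (length(missing))
      stop("no atom-map entry for label(s): ",
           paste(sQuote(missing), collapse = ", "))
  }
  total <- c(C = 0, H = 0, N = 0, O = 0)
  for (i in seq_along(gv)) {
    contrib <- unclass(atom_map[[names(gv)[i]]])
    for (el in names(contrib)) {
      total[el] <- (if (el %in% names(total)) total[el] else 0) +
        contrib[[el]] * as.numeric(gv)[i]
    }
  }
  elemental_formula(total)
}

#' Read / write group vectors as JSON
#'
#' JSON form is a flat object `{label: count, ...}`.
#'
#' @param path file path.
#' @return A [group_vector()].
#' @export
read_group_vector <- function(path) {
  group_vector(unlist(jsonlite::read_json(path, simplifyVector = TRUE)))
}

#' @rdname read_group_vector
#' @param gv a [group_vector()].
#' @export
write_group_vector <- function(gv, path) {
  stopifnot(inherits(gv, "group_vector"))
  jsonlite::write_json(as.list(stats::setNames(as.numeric(gv), names(gv))),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
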