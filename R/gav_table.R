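# Benson group labels and the group-value parameter table.
#
# Canonical label grammar: CENTER-(LIG1)(LIG2)..., center one of
# {C, C_D, C_B, CO, O, N}; H ligands come first and carry their multiplicity
# ("(H)3"); remaining ligands are sorted by the fixed priority
# CO > C_B > C_D > C > N > O (unknown tokens such as NO2 go last); repeated
# ligands collapse to a numeric suffix, "(C_B)2".  Printed-table spellings
# like "CO-(O)(C_B)" or "C_B-(N)(C_B)_2_" are accepted anywhere a label is
# and resolve to canonical form.

.center_types <- c("C_B", "C_D", "CO", "C", "N", "O")
.ligand_priority <- c("CO", "C_B", "C_D", "C", "N", "O")

# labels that do not follow the CENTER-(LIG) grammar
.special_labels <- c("rsc", paste("radical", 1:4),
                     "correction o-", "correction m-", "correction p-",
                     "CH3(qua)")

#' Labels treated as correction terms rather than atom-bearing groups
#'
#' Ring-strain ("rsc"), radical, and ortho/meta/para substitution-pattern
#' corrections enter the group sum additively but contribute no atoms.
#'
#' @return Character vector of correction labels.
#' @export
correction_labels <- function() {
  c("rsc", paste("radical", 1:4),
    "correction o-", "correction m-", "correction p-")
}

.clean_label <- function(x) {
  x <- gsub("\\*", "", x)
  x <- gsub("–|−", "-", x)     # en-dash/minus
  x <- trimws(x)
  x <- gsub("_\\s", " ", x)
  x <- gsub("\\)_([0-9]+)_?", ")\\1", x) # (C_B)_2_ -> (C_B)2
  x <- gsub("C_B_", "C_B", x, fixed = TRUE)
  x <- gsub("C_D_", "C_D", x, fixed = TRUE)
  x <- gsub("NO_2_?", "NO2", x)
  x <- gsub("CH_3_?", "CH3", x)
  x <- gsub("^CB([-(])", "C_B\\1", x)
  x <- gsub("^CD([-(])", "C_D\\1", x)
  x <- gsub("\\(CB\\)", "(C_B)", x)
  x <- gsub("\\(CD\\)", "(C_D)", x)
  gsub("\\s+", " ", x)
}

.parse_group_label <- function(x) {
  m <- regexec("^(C_B|C_D|CO|C|N|O)-\\((.+)$", x)[[1]]
  if (m[1] == -1) return(NULL)
  center <- regmatches(x, list(m))[[1]][2]
  rest <- paste0("(", regmatches(x, list(m))[[1]][3])
  lm <- gregexpr("\\(([A-Za-z_0-9]+)\\)([0-9]*)", rest)[[1]]
  toks <- regmatches(rest, list(lm))[[1]]
  if (sum(attr(lm, "match.length")) != nchar(rest)) return(NULL)
  ligs <- character(0)
  for (tk in toks) {
    lig <- sub("^\\(([A-Za-z_0-9]+)\\)[0-9]*$", "\\1", tk)
    n <- sub("^\\([A-Za-z_0-9]+\\)", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    ligs <- c(ligs, rep(lig, n))
  }
  list(center = center, ligands = ligs)
}

.build_label <- function(center, ligands) {
  h <- sum(ligands == "H")
  rest <- ligands[ligands != "H"]
  pr <- match(rest, .ligand_priority)
  pr[is.na(pr)] <- length(.ligand_priority) + 1L
  rest <- rest[order(pr, rest)]
  parts <- character(0)
  if (h > 0) parts <- paste0("(H)", if (h > 1) h else "")
  if (length(rest)) {
    r <- rle(rest)
    parts <- c(parts, paste0("(", r$values, ")",
                             ifelse(r$lengths > 1, r$lengths, "")))
  }
  paste0(center, "-", paste(parts, collapse = ""))
}

#' Canonicalize a Benson group label
#'
#' Normalizes spelling variants (printed subscripts, ligand order) onto the
#' canonical grammar.  Correction labels (`rsc`, `radical n`,
#' `correction o-/m-/p-`) and `CH3(qua)` pass through unchanged.
#'
#' @param label character vector of labels.
#' @return Character vector of canonical labels.
#' @examples
#' canonical_label("CO-(O)(C_B)")   # "CO-(C_B)(O)"
#' canonical_label("C_B-(H)(C_B)_2_")
#' @export
canonical_label <- function(label) {
  vapply(label, function(x) {
    x <- .clean_label(x)
    if (x %in% .special_labels) return(x)
    p <- .parse_group_label(x)
    if (is.null(p)) stop("malformed group label: ", sQuote(x))
    .build_label(p$center, p$ligands)
  }, character(1), USE.NAMES = FALSE)
}

#' Group-additivity parameter table
#'
#' Holds, for every group and correction label, its additive contribution to
#' absolute entropy `S` (J mol^-1 K^-1), entropy of formation `dfS`
#' (J mol^-1 K^-1) and Gibbs energy of formation `dfG` (kJ mol^-1), plus the
#' regression intercept triple that is added exactly once per molecule.
#'
#' @param values data frame with columns `label`, `S`, `dfS`, `dfG`.
#' @param intercept named numeric triple `c(S=, dfS=, dfG=)`.
#' @param provenance free-text description of where the values come from.
#' @param version version string for the parameter set.
#' @return An object of class `gav_table`.
#' @export
gav_table <- function(values, intercept, provenance = "", version = "") {
  stopifnot(is.data.frame(values),
            all(c("label", "S", "dfS", "dfG") %in% names(values)))
  values$label <- canonical_label(values$label)
  if (anyDuplicated(values$label))
    stop("duplicate group labels: ",
         paste(values$label[duplicated(values$label)], collapse = ", "))
  intercept <- intercept[c("S", "dfS", "dfG")]
  if (anyNA(names(intercept))) stop("intercept must name S, dfS, dfG")
  structure(list(values = values[, c("label", "S", "dfS", "dfG")],
                 intercept = unlist(intercept),
                 provenance = provenance, version = version),
            class = "gav_table")
}

#' @export
print.gav_table <- function(x, ...) {
  cat("<gav_table> ", nrow(x$values), " groups",
      if (nzchar(x$version)) paste0(", version ", x$version), "\n", sep = "")
  cat("intercept: S=", x$intercept["S"], " dfS=", x$intercept["dfS"],
      " dfG=", x$intercept["dfG"], "\n", sep = "")
  if (nzchar(x$provenance)) cat(strwrap(x$provenance, 78), sep = "\n")
  invisible(x)
}

.gav_cache <- new.env(parent = emptyenv())

#' The packaged group-value table
#'
#' Loads (and caches) the MLR-derived group values shipped with the package:
#' 41 group and correction rows plus the intercept, for gas-phase S, dfS and
#' dfG at 298.15 K.
#'
#' @return A [gav_table()].
#' @examples
#' tab <- builtin_gav_table()
#' gav_lookup(tab, "CO-(O)(CO)")
#' @export
builtin_gav_table <- function() {
  if (is.null(.gav_cache$table)) {
    path <- system.file("extdata", "gav_groups_v1.json",
                        package = "gavthermo", mustWork = TRUE)
    .gav_cache$table <- load_gav_table(path)
  }
  .gav_cache$table
}

#' Load / write a group-value table as JSON
#'
#' Schema: `{"groups": {label: {"S": x, "dfS": y, "dfG": z}, ...},
#' "intercept": {"S": ..., "dfS": ..., "dfG": ...}, "provenance": "...",
#' "version": "..."}`.
#'
#' @param path JSON file path.
#' @return A [gav_table()].
#' @export
load_gav_table <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$groups) || is.null(j$intercept))
    stop("parameter table must contain 'groups' and 'intercept'")
  rows <- lapply(names(j$groups), function(lb) {
    v <- j$groups[[lb]]
    if (!all(c("S", "dfS", "dfG") %in% names(v)))
      stop("group ", sQuote(lb), " missing one of S/dfS/dfG")
    data.frame(label = lb, S = v$S, dfS = v$dfS, dfG = v$dfG)
  })
  gav_table(do.call(rbind, rows),
            unlist(j$intercept[c("S", "dfS", "dfG")]),
            provenance = if (!is.null(j$provenance)) j$provenance else "",
            version = if (!is.null(j$version)) j$version else "")
}

#' @rdname load_gav_table
#' @param table a [gav_table()].
#' @export
write_gav_table <- function(table, path) {
  stopifnot(inherits(table, "gav_table"))
  groups <- stats::setNames(lapply(seq_len(nrow(table$values)), function(i) {
    as.list(table$values[i, c("S", "dfS", "dfG")])
  }), table$values$label)
  jsonlite::write_json(
    list(schema = "gavthermo-parameter-table", version = table$version,
         provenance = table$provenance, groups = groups,
         intercept = as.list(table$intercept)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Look up one label's value triple
#'
#' @param table a [gav_table()].
#' @param label a group label in any accepted spelling.
#' @return Named numeric triple `c(S=, dfS=, dfG=)`.
#' @export
gav_lookup <- function(table, label) {
  stopifnot(inherits(table, "gav_table"))
  lb <- canonical_label(label)
  i <- match(lb, table$values$label)
  if (is.na(i)) stop("label not in table: ", sQuote(label))
  unlist(table$values[i, c("S", "dfS", "dfG")])
}
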