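# Molecular graphs and Benson-group perception for closed-shell C/H/N/O
# molecules.  The library-level contract is the JSON graph (atoms/bonds
# lists); SMILES enters through an established reader (Open Babel via
# ChemmineOB) whose aromaticity model is taken as-is.

#' Molecular graph
#'
#' Heavy-atom graph: `atoms` is a data frame with columns `element`
#' (`C`/`N`/`O`), `hcount` (implicit hydrogens) and `aromatic` (logical);
#' `bonds` has 1-based atom indices `i`, `j` and `order` in
#' `{"1","2","3","ar"}`.  Explicit hydrogen atoms, if supplied, are collapsed
#' into the `hcount` of their heavy neighbor.  Valences are checked against
#' C=4, N=3, O=2 with aromatic bonds counted as 1.5.
#'
#' @param atoms data frame (`element`, `hcount`, `aromatic`).
#' @param bonds data frame (`i`, `j`, `order`).
#' @return An object of class `molecular_graph`.
#' @export
molecular_graph <- function(atoms, bonds) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  if (!"hcount" %in% names(atoms)) atoms$hcount <- 0L
  if (!"aromatic" %in% names(atoms)) atoms$aromatic <- FALSE
  atoms$hcount[is.na(atoms$hcount)] <- 0L
  atoms$aromatic[is.na(atoms$aromatic)] <- FALSE
  if (nrow(bonds)) {
    bonds$order <- as.character(bonds$order)
    if (!all(bonds$order %in% c("1", "2", "3", "ar")))
      stop("bond orders must be 1, 2, 3 or 'ar'")
    if (any(bonds$i == bonds$j) ||
        any(bonds$i < 1 | bonds$j < 1 |
            bonds$i > nrow(atoms) | bonds$j > nrow(atoms)))
      stop("bond endpoints out of range")
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = character())
  }
  # collapse explicit hydrogens
  is_h <- atoms$element == "H"
  if (any(is_h)) {
    keep <- which(!is_h)
    remap <- match(seq_len(nrow(atoms)), keep)
    for (b in seq_len(nrow(bonds))) {
      hi <- c(bonds$i[b], bonds$j[b])
      hflag <- is_h[hi]
      if (any(hflag)) {
        if (all(hflag)) stop("H-H bond unsupported")
        heavy <- hi[!hflag]
        atoms$hcount[heavy] <- atoms$hcount[heavy] + 1L
      }
    }
    hb <- is_h[bonds$i] | is_h[bonds$j]
    bonds <- bonds[!hb, , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  if (!nrow(atoms)) stop("molecule has no heavy atoms")
  if (!all(atoms$element %in% c("C", "N", "O")))
    stop("unsupported element(s): ",
         paste(setdiff(atoms$element, c("C", "N", "O")), collapse = ", "))
  g <- structure(list(atoms = atoms, bonds = bonds),
                 class = "molecular_graph")
  .check_valences(g)
  g
}

.bond_value <- function(order) {
  c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5)[order]
}

.check_valences <- function(g) {
  target <- c(C = 4, N = 3, O = 2)
  tot <- g$atoms$hcount
  for (b in seq_len(nrow(g$bonds))) {
    v <- .bond_value(g$bonds$order[b])
    tot[g$bonds$i[b]] <- tot[g$bonds$i[b]] + v
    tot[g$bonds$j[b]] <- tot[g$bonds$j[b]] + v
  }
  exp_v <- target[g$atoms$element]
  # aromatic bookkeeping (1.5 per ar bond) allows a half-unit slack
  bad <- ifelse(g$atoms$aromatic, abs(tot - exp_v) > 0.51, tot != exp_v)
  if (any(bad))
    stop("valence inconsistency at atom(s) ",
         paste(which(bad), collapse = ", "),
         " (element ", paste(g$atoms$element[bad], collapse = ", "), ")")
  n_ar_bond <- integer(nrow(g$atoms))
  for (b in which(g$bonds$order == "ar")) {
    n_ar_bond[g$bonds$i[b]] <- n_ar_bond[g$bonds$i[b]] + 1L
    n_ar_bond[g$bonds$j[b]] <- n_ar_bond[g$bonds$j[b]] + 1L
  }
  if (any(g$atoms$aromatic & n_ar_bond == 0))
    stop("aromatic flag on atom without aromatic bonds")
  invisible(g)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, formula ",
      format(graph_formula(x)), "\n", sep = "")
  invisible(x)
}

#' Elemental formula of a molecular graph
#' @param g a [molecular_graph()].
#' @return An [elemental_formula()] including implicit hydrogens.
#' @export
graph_formula <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  counts <- table(g$atoms$element)
  f <- stats::setNames(as.numeric(counts), names(counts))
  f["H"] <- sum(g$atoms$hcount)
  elemental_formula(f[f > 0])
}

#' Read / write the JSON graph format
#'
#' `{"atoms": [{"element": "C", "hcount": 1, "aromatic": true}, ...],
#'   "bonds": [{"i": 1, "j": 2, "order": "ar"}, ...]}` with 1-based indices.
#'
#' @param path file path.
#' @return A [molecular_graph()].
#' @export
read_graph_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  molecular_graph(as.data.frame(j$atoms), as.data.frame(j$bonds))
}

#' @rdname read_graph_json
#' @param g a [molecular_graph()].
#' @export
write_graph_json <- function(g, path) {
  stopifnot(inherits(g, "molecular_graph"))
  jsonlite::write_json(list(atoms = g$atoms, bonds = g$bonds), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Parse a SMILES string into a molecular graph
#'
#' Uses Open Babel (through the ChemmineOB package) to interpret the SMILES,
#' add explicit hydrogens and assign its aromaticity model; the resulting
#' MOL2 block is then converted to a [molecular_graph()].  No independent
#' aromaticity perception is performed.
#'
#' @param smiles a single SMILES string (C/H/N/O, closed-shell, uncharged).
#' @return A [molecular_graph()].
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("parse_smiles requires the ChemmineOB package")
  mol2 <- ChemmineOB::convertFormat(
    "SMI", "MOL2", source = paste0(smiles, "\n"),
    options = data.frame(names = "h", args = ""))
  .parse_mol2(mol2)
}

# Minimal reader for the MOL2 text Open Babel emits: ATOM records give the
# element via the atom type ("C.ar", "O.2", ...), BOND records give orders
# ("1","2","3","ar","am"); amide is treated as a single bond.
.parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  a0 <- grep("^@<TRIPOS>ATOM", lines)
  b0 <- grep("^@<TRIPOS>BOND", lines)
  if (!length(a0) || !length(b0)) stop("malformed MOL2 block")
  sec_end <- function(start) {
    nxt <- grep("^@<TRIPOS>", lines)
    nxt <- nxt[nxt > start]
    if (length(nxt)) min(nxt) - 1L else length(lines)
  }
  atom_lines <- lines[(a0 + 1):sec_end(a0)]
  bond_lines <- lines[(b0 + 1):sec_end(b0)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
  af <- do.call(rbind, lapply(strsplit(trimws(atom_lines), "\\s+"),
                              function(x) x[1:6]))
  type <- af[, 6]
  atoms <- data.frame(
    element = sub("\\..*$", "", type),
    hcount = 0L,
    aromatic = grepl("\\.ar$", type),
    stringsAsFactors = FALSE
  )
  bf <- do.call(rbind, lapply(strsplit(trimws(bond_lines), "\\s+"),
                              function(x) x[1:4]))
  order <- bf[, 4]
  order[order == "am"] <- "1"
  bonds <- data.frame(i = as.integer(bf[, 2]), j = as.integer(bf[, 3]),
                      order = order, stringsAsFactors = FALSE)
  molecular_graph(atoms, bonds)
}

# ---- ring perception --------------------------------------------------------

.adjacency <- function(g) {
  adj <- vector("list", nrow(g$atoms))
  for (b in seq_len(nrow(g$bonds))) {
    adj[[g$bonds$i[b]]] <- c(adj[[g$bonds$i[b]]], g$bonds$j[b])
    adj[[g$bonds$j[b]]] <- c(adj[[g$bonds$j[b]]], g$bonds$i[b])
  }
  adj
}

# all simple cycles of exactly length L, as ordered atom vectors,
# deduplicated by atom set; exhaustive DFS, fine for molecule-sized graphs
.cycles_of_length <- function(g, L) {
  adj <- .adjacency(g)
  found <- list()
  seen <- character(0)
  dfs <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (length(path) == L && nb == path[1]) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          found[[length(found) + 1L]] <<- path
        }
      } else if (length(path) < L && !(nb %in% path) && nb > path[1]) {
        dfs(c(path, nb))
      }
    }
  }
  for (v in seq_len(nrow(g$atoms))) dfs(v)
  found
}

# ---- group perception -------------------------------------------------------

.center_type <- function(g) {
  n <- nrow(g$atoms)
  dbl_to_O <- logical(n); has_dbl <- logical(n); dbl_partner_C <- logical(n)
  for (b in which(g$bonds$order == "2")) {
    i <- g$bonds$i[b]; j <- g$bonds$j[b]
    has_dbl[i] <- has_dbl[j] <- TRUE
    if (g$atoms$element[j] == "O") dbl_to_O[i] <- TRUE
    if (g$atoms$element[i] == "O") dbl_to_O[j] <- TRUE
    if (g$atoms$element[j] == "C") dbl_partner_C[i] <- TRUE
    if (g$atoms$element[i] == "C") dbl_partner_C[j] <- TRUE
  }
  has_triple <- logical(n)
  for (b in which(g$bonds$order == "3")) {
    has_triple[g$bonds$i[b]] <- TRUE
    has_triple[g$bonds$j[b]] <- TRUE
  }
  vapply(seq_len(n), function(a) {
    el <- g$atoms$element[a]
    if (el == "O") {
      if (has_dbl[a] && dbl_partner_C[a]) "O_carbonyl" else "O"
    } else if (el == "N") {
      "N"
    } else {                      # carbon
      if (has_triple[a])
        stop("no canonical label for sp carbon (atom ", a, ")")
      if (g$atoms$aromatic[a]) "C_B"
      else if (dbl_to_O[a]) "CO"
      else if (has_dbl[a]) "C_D"
      else "C"
    }
  }, character(1))
}

#' Decompose a molecule into Benson groups
#'
#' Assigns exactly one group per heavy atom -- except carbonyl oxygens, which
#' are absorbed into their CO center -- and emits a ring-strain correction
#' (`rsc`) once per five-membered ring containing the CO-N-CO imide motif.
#' Center typing: `CO` = carbon double-bonded to oxygen, `C_B` = aromatic
#' carbon, `C_D` = other sp2 carbon, `C` = sp3 carbon, `O`/`N` = heteroatom
#' centers.  Each center's ligand list is its neighbors' center types plus
#' its hydrogen count.  Atom conservation against the molecular formula is
#' checked before returning.
#'
#' Substitution-pattern (ortho/meta/para) corrections are not assigned here;
#' see [annotate_substitution_corrections()].
#'
#' @param mol a [molecular_graph()] or a SMILES string.
#' @return A [group_vector()].
#' @examples
#' \dontrun{
#' perceive_groups("c1ccccc1")        # 6 x C_B-(H)(C_B)2
#' }
#' @export
perceive_groups <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "molecular_graph"))
  types <- .center_type(mol)
  adj <- .adjacency(mol)
  labels <- character(0)
  for (a in seq_len(nrow(mol$atoms))) {
    if (types[a] == "O_carbonyl") next
    nb <- adj[[a]]
    lig_types <- types[nb]
    if (types[a] == "CO") {
      # drop the absorbed carbonyl oxygen(s)
      drop <- nb[types[nb] == "O_carbonyl" &
                   vapply(nb, function(x) {
                     any((mol$bonds$i == a & mol$bonds$j == x |
                            mol$bonds$j == a & mol$bonds$i == x) &
                           mol$bonds$order == "2")
                   }, logical(1))]
      lig_types <- types[setdiff(nb, drop)]
    }
    lig_types[lig_types == "O_carbonyl"] <- "O"  # e.g. ester O seen from C
    ligands <- c(rep("H", mol$atoms$hcount[a]), lig_types)
    labels <- c(labels, .build_label(types[a], ligands))
  }
  counts <- table(labels)
  gv <- stats::setNames(as.numeric(counts), names(counts))
  # ring strain: one rsc per 5-ring with an in-ring CO-N-CO motif
  n_rsc <- 0L
  for (ring in .cycles_of_length(mol, 5L)) {
    rt <- types[ring]
    hit <- FALSE
    for (k in seq_along(ring)) {
      prv <- ring[if (k == 1) 5 else k - 1]
      nxt <- ring[if (k == 5) 1 else k + 1]
      if (rt[k] == "N" && types[prv] == "CO" && types[nxt] == "CO")
        hit <- TRUE
    }
    if (hit) n_rsc <- n_rsc + 1L
  }
  if (n_rsc > 0) gv <- c(gv, rsc = n_rsc)
  out <- group_vector(gv)
  implied <- formula_from_groups(out, atom_map = .perception_atom_map(out))
  if (format(implied) != format(graph_formula(mol)))
    stop("internal error: perceived groups do not conserve atoms (",
         format(implied), " vs ", format(graph_formula(mol)), ")")
  out
}

# atom map derived from the label grammar, covering any perceived label
.perception_atom_map <- function(gv) {
  stats::setNames(lapply(names(gv), function(lb) {
    if (lb %in% correction_labels()) return(elemental_formula())
    p <- .parse_group_label(lb)
    counts <- c(C = 0, H = 0, N = 0, O = 0)
    counts[substr(p$center, 1, 1)] <- 1
    if (p$center == "CO") counts["O"] <- counts["O"] + 1
    counts["H"] <- counts["H"] + sum(p$ligands == "H")
    elemental_formula(counts)
  }), names(gv))
}

#' Add ortho/meta/para substitution corrections
#'
#' For every aromatic six-membered ring, counts unordered pairs of
#' substituent-bearing positions: pairs at ring distance 1, 2 and 3 add to
#' `correction o-`, `correction m-` and `correction p-` respectively.  A
#' substituent is any non-hydrogen neighbor outside the ring (so a fused
#' carbonyl counts); multiple substituents on one position multiply the
#' pair count.
#'
#' @param mol the [molecular_graph()] the vector came from (or SMILES).
#' @param gv the [group_vector()] from [perceive_groups()].
#' @return The group vector with correction counts added.
#' @export
annotate_substitution_corrections <- function(mol, gv) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "molecular_graph"), inherits(gv, "group_vector"))
  adj <- .adjacency(mol)
  extra <- c("correction o-" = 0, "correction m-" = 0, "correction p-" = 0)
  for (ring in .cycles_of_length(mol, 6L)) {
    if (!all(mol$atoms$aromatic[ring])) next
    subs <- vapply(seq_along(ring), function(k) {
      length(setdiff(adj[[ring[k]]], ring))
    }, integer(1))
    for (k1 in 1:5) for (k2 in (k1 + 1):6) {
      if (subs[k1] > 0 && subs[k2] > 0) {
        d <- min(abs(k1 - k2), 6 - abs(k1 - k2))
        lab <- c("correction o-", "correction m-", "correction p-")[d]
        extra[lab] <- extra[lab] + subs[k1] * subs[k2]
      }
    }
  }
  gv + group_vector(extra[extra > 0])
}
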