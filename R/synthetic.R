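#' Generate a synthetic group-count regression dataset
#'
#' Emulates the statistical structure a group-additivity regression assumes:
#' a sparse nonnegative integer design over a group vocabulary, a linear
#' response with intercept, and homoscedastic Gaussian noise.  Group counts
#' are drawn from a Poisson(`lambda`) truncated at `max_count`, with one
#' guaranteed occurrence of every group somewhere in the dataset so all
#' coefficients are identifiable.  Entropy-of-formation observations are
#' derived exactly as the absolute-entropy observation minus the
#' element-entropy sum of the formula implied by the group counts, which
#' preserves the exact linear relation real data has between the two
#' properties.
#'
#' @param n_molecules number of rows; default 77.
#' @param group_universe character vector of group labels; defaults to all
#'   labels of the packaged table.
#' @param truth a [gav_table()] providing the true coefficients; defaults to
#'   the packaged table.
#' @param lambda mean occupancy of the (truncated) Poisson counts.
#' @param max_count truncation cap on any single count.
#' @param noise_sd named vector `c(S = ..., dfG = ...)`: observation noise,
#'   in J mol^-1 K^-1 for S and kJ mol^-1 for dfG (dfS inherits the S
#'   noise through the exact linear relation).
#' @param seed integer seed; the draw is deterministic given it.
#' @param constants a [thermo_constants()] for the element-entropy sums.
#' @return List with `dataset` (a [thermo_dataset()]) and `truth` (the
#'   [gav_table()] used).
#' @examples
#' sim <- generate_thermo_dataset(n_molecules = 50, seed = 1)
#' nrow(sim$dataset)
#' @export
generate_thermo_dataset <- function(n_molecules = 77L,
                                    group_universe = NULL,
                                    truth = builtin_gav_table(),
                                    lambda = 0.6, max_count = 6L,
                                    noise_sd = c(S = 5, dfG = 5),
                                    seed = 42L,
                                    constants = thermo_constants()) {
  stopifnot(n_molecules >= 1, lambda > 0, all(noise_sd >= 0))
  if (is.null(group_universe)) group_universe <- truth$values$label
  group_universe <- canonical_label(group_universe)
  p <- length(group_universe)
  if (n_molecules < p + 1)
    warning("fewer rows than coefficients; the design cannot be full rank")
  atom_map <- builtin_atom_map(group_universe)
  res <- .with_seed(seed, {
    counts <- matrix(pmin(stats::rpois(n_molecules * p, lambda), max_count),
                     nrow = n_molecules, ncol = p,
                     dimnames = list(NULL, group_universe))
    for (g in which(colSums(counts) == 0))
      counts[sample.int(n_molecules, 1L), g] <- 1L
    eps_S <- stats::rnorm(n_molecules, 0, noise_sd[["S"]])
    eps_G <- stats::rnorm(n_molecules, 0, noise_sd[["dfG"]])
    list(counts = counts, eps_S = eps_S, eps_G = eps_G)
  })
  counts <- res$counts
  idx <- match(group_universe, truth$values$label)
  if (anyNA(idx))
    stop("truth table lacks group(s): ",
         paste(group_universe[is.na(idx)], collapse = ", "))
  S_true <- as.numeric(counts %*% truth$values$S[idx]) +
    truth$intercept["S"]
  G_true <- as.numeric(counts %*% truth$values$dfG[idx]) +
    truth$intercept["dfG"]
  # per-group element contributions as a matrix: row = group, col = element
  elems <- c("C", "H", "N", "O")
  E <- t(vapply(atom_map[group_universe], function(f) {
    v <- stats::setNames(rep(0, 4), elems)
    v[names(f)] <- unclass(f)
    v
  }, numeric(4)))
  atom_totals <- counts %*% E              # rows x elements
  per_elem_S <- vapply(elems, function(el) {
    element_entropy_sum(elemental_formula(stats::setNames(1, el)), constants)
  }, numeric(1))
  elem_sum <- as.numeric(atom_totals %*% per_elem_S)
  formulas <- apply(atom_totals, 1, function(v) {
    format(elemental_formula(v))
  })
  S_obs <- S_true + res$eps_S
  df <- data.frame(molecule_id = sprintf("mol%03d", seq_len(n_molecules)),
                   formula = formulas,
                   S_J_molK = S_obs,
                   dfS_J_molK = S_obs - elem_sum,
                   dfG_kJ_mol = G_true + res$eps_G,
                   check.names = FALSE)
  gdf <- as.data.frame(counts)
  names(gdf) <- paste0("group:", group_universe)
  list(dataset = thermo_dataset(cbind(df, gdf)), truth = truth)
}
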