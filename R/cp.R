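#' Cubic gas-phase heat-capacity polynomial
#'
#' `Cp(T) = a3*T^3 + a2*T^2 + a1*T + a0`, Cp in J mol^-1 K^-1, T in K.
#'
#' @param a3,a2,a1,a0 polynomial coefficients.
#' @param valid_range numeric length-2 `(T_min, T_max)` in K; evaluation
#'   outside it warns.
#' @param label optional name.
#' @return An object of class `cp_polynomial`.
#' @export
cp_polynomial <- function(a3, a2, a1, a0,
                          valid_range = c(298.15, 613.15), label = "") {
  stopifnot(length(valid_range) == 2, valid_range[1] < valid_range[2])
  structure(list(a3 = a3, a2 = a2, a1 = a1, a0 = a0,
                 valid_range = valid_range, label = label),
            class = "cp_polynomial")
}

#' @export
print.cp_polynomial <- function(x, ...) {
  cat(sprintf(
    "<cp_polynomial>%s Cp(T) = %g T^3 + %g T^2 + %g T + %g  [%g, %g] K\n",
    if (nzchar(x$label)) paste0(" ", x$label, ":") else "",
    x$a3, x$a2, x$a1, x$a0, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Evaluate a heat-capacity polynomial
#'
#' @param p a [cp_polynomial()].
#' @param T temperature(s), K.
#' @return Cp in J mol^-1 K^-1.
#' @examples
#' cp_eval(cp_polynomial(-2.29e-7, -1.54e-4, 0.63, 0.59), 298.15)
#' @export
cp_eval <- function(p, T) {
  stopifnot(inherits(p, "cp_polynomial"))
  out_of_range <- T < p$valid_range[1] | T > p$valid_range[2]
  if (any(out_of_range))
    warning("evaluating ", if (nzchar(p$label)) paste0(p$label, " "),
            "outside its fitted range [", p$valid_range[1], ", ",
            p$valid_range[2], "] K")
  p$a3 * T^3 + p$a2 * T^2 + p$a1 * T + p$a0
}

#' Fit a cubic polynomial to (T, Cp) samples
#'
#' Ordinary least squares on the raw cubic basis; needs at least four
#' distinct temperatures.
#'
#' @param T temperatures, K.
#' @param Cp heat capacities, J mol^-1 K^-1.
#' @param label passed to the resulting polynomial.
#' @return List with `polynomial` (a [cp_polynomial()], valid over the
#'   sampled range) and `R2`.
#' @export
fit_cp_cubic <- function(T, Cp, label = "") {
  stopifnot(length(T) == length(Cp))
  if (length(unique(T)) < 4)
    stop("need at least 4 samples with distinct temperatures")
  fit <- stats::lm(Cp ~ stats::poly(T, 3, raw = TRUE))
  b <- unname(stats::coef(fit))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((Cp - mean(Cp))^2)
  list(polynomial = cp_polynomial(b[4], b[3], b[2], b[1],
                                  valid_range = range(T), label = label),
       R2 = r2)
}

#' Packaged heat-capacity polynomials
#'
#' Cubic Cp,m(g) polynomials for the two diaminobenzoic acids and the two
#' diimidetricarboxylic acids, from third-order fits of quantum-chemical
#' heat capacities.  For the two DITA polynomials the source prints the T^2
#' coefficient as "0.0014 x 10^-4", which is dimensionally out of line with
#' the ~1e-4-magnitude T^2 coefficients of the DABA polynomials (and is
#' printed identically for both isomers); `t2_variant = "printed"` (the
#' default) stores the literal value -1.4e-7 and warns, while `"amended"`
#' selects the alternative reading -1.4e-3.  The validity range 298.15 to
#' 613.15 K is the calorimetric scan range, adopted here as a convention.
#'
#' @param t2_variant `"printed"` or `"amended"` T^2 coefficient for the two
#'   DITA polynomials.
#' @return Named list of [cp_polynomial()] objects: `34daba`, `35daba`,
#'   `34dita`, `35dita`.
#' @export
builtin_cp_polynomials <- function(t2_variant = c("printed", "amended")) {
  t2_variant <- match.arg(t2_variant)
  dita_t2 <- if (t2_variant == "printed") -1.4e-7 else -1.4e-3
  if (t2_variant == "printed")
    warning("DITA T^2 coefficient uses the literal printed value -1.4e-7, ",
            "which is dimensionally suspect; see ?builtin_cp_polynomials")
  list(
    `34daba` = cp_polynomial(-2.29e-7, -1.54e-4, 0.63, 0.59,
                             label = "Cp,m(3,4-DABA, g)"),
    `35daba` = cp_polynomial(-1.11e-7, -2.89e-4, 0.68, 1.10,
                             label = "Cp,m(3,5-DABA, g)"),
    `34dita` = cp_polynomial(2.36e-7, dita_t2, 2.16, -40.24,
                             label = "Cp,m(3,4-DITA, g)"),
    `35dita` = cp_polynomial(2.28e-7, dita_t2, 2.15, -38.07,
                             label = "Cp,m(3,5-DITA, g)")
  )
}

#' Read / write a polynomial as JSON
#' @param path JSON file path.
#' @return A [cp_polynomial()].
#' @export
read_cp_polynomial <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp_polynomial(j$a3, j$a2, j$a1, j$a0,
                valid_range = unlist(j$valid_range),
                label = if (!is.null(j$label)) j$label else "")
}

#' @rdname read_cp_polynomial
#' @param p a [cp_polynomial()].
#' @export
write_cp_polynomial <- function(p, path) {
  stopifnot(inherits(p, "cp_polynomial"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
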