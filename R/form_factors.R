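# Atomic form factors: four-Gaussian-plus-constant parameterization
#   f(s) = sum_i a_i * exp(-b_i * s^2) + c,   s = sin(theta)/lambda = |q| / (4*pi)
# a_i, c in electrons; b_i in A^2. Coefficients from the standard crystallographic
# tabulation (International Tables for Crystallography Vol. C, Table 6.1.1.4).

.ff_table <- list(
  H  = list(a = c(0.493002, 0.322912, 0.140191, 0.040810),
            b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038, z = 1),
  C  = list(a = c(2.3100, 1.0200, 1.5886, 0.8650),
            b = c(20.8439, 10.2075, 0.5687, 51.6512), c = 0.2156, z = 6),
  N  = list(a = c(12.2126, 3.1322, 2.0125, 1.1663),
            b = c(0.0057, 9.8933, 28.9975, 0.5826), c = -11.5290, z = 7),
  O  = list(a = c(3.0485, 2.2868, 1.5463, 0.8670),
            b = c(13.2771, 5.7011, 0.3239, 32.9089), c = 0.2508, z = 8),
  P  = list(a = c(6.4345, 4.1791, 1.7800, 1.4908),
            b = c(1.9067, 27.1570, 0.5260, 68.1645), c = 1.1149, z = 15),
  S  = list(a = c(6.9053, 5.2034, 1.4379, 1.5863),
            b = c(1.4679, 22.2151, 0.2536, 56.1720), c = 0.8669, z = 16),
  FE = list(a = c(11.7695, 7.3573, 3.5222, 2.3045),
            b = c(4.7611, 0.3072, 15.3535, 76.8805), c = 1.0369, z = 26),
  AU = list(a = c(16.8819, 18.5913, 25.5582, 5.8600),
            b = c(0.4611, 8.6216, 1.4826, 36.3956), c = 12.0658, z = 79)
)

#' Elements with built-in form-factor coefficients
#'
#' @return Character vector of element symbols for which a four-Gaussian
#'   form-factor record is built in.
#' @export
ff_elements <- function() names(.ff_table)

#' Look up the form-factor record for an element
#'
#' @param element Element symbol (case-insensitive), e.g. `"C"` or `"Au"`.
#' @return A `form_factor_record`: list with Gaussian amplitudes `a`
#'   (electrons), widths `b` (squared Angstrom) and constant term `c`.
#' @export
ff_record <- function(element) {
  key <- toupper(trimws(element))
  rec <- .ff_table[[key]]
  if (is.null(rec))
    stop("no form-factor record for element '", element,
         "'; known: ", paste(ff_elements(), collapse = ", "))
  structure(rec[c("a", "b", "c")], class = "form_factor_record")
}

#' Evaluate an atomic form factor
#'
#' Evaluates `f(q) = sum_i a_i exp(-b_i s^2) + c` with `s = q/(4*pi)`, the
#' Fourier transform of the atomic electron density in the independent-atom
#' approximation. `f(0)` equals the electron count of the species.
#'
#' @param kind Element symbol, or a `form_factor_record` (list with `a`, `b`,
#'   `c`), allowing user-defined coarse-grained scatterers.
#' @param q_mag Scattering-vector magnitudes in inverse Angstrom
#'   (`|q| = 4 pi sin(theta) / lambda`); vectorized.
#' @return Form-factor values in electrons, same length as `q_mag`.
#' @examples
#' form_factor("C", 0)            # ~6 electrons
#' form_factor("C", seq(0, 2, 0.5))
#' @export
form_factor <- function(kind, q_mag) {
  stopifnot(is.numeric(q_mag), all(is.finite(q_mag)), all(q_mag >= 0))
  rec <- if (is.character(kind)) ff_record(kind) else kind
  if (!is.list(rec) || is.null(rec$a) || is.null(rec$b) || is.null(rec$c))
    stop("'kind' must be an element symbol or a list with fields a, b, c")
  s2 <- (q_mag / (4 * pi))^2
  f <- rep(rec$c, length(q_mag))
  for (i in seq_along(rec$a)) f <- f + rec$a[i] * exp(-rec$b[i] * s2)
  f
}

# Evaluate form factors for every scatterer of a particle at the given |q|
# values. Returns an n_scatterer x n_q matrix is avoided: instead callers get
# a list keyed by scatterer group (see .ff_groups) for linear-cost summation.
.ff_groups <- function(particle) {
  # group scatterers sharing a form-factor evaluator
  if (!is.null(particle$ff_records)) {
    # explicit per-scatterer records: group by identical coefficient rows
    key <- vapply(particle$ff_records, function(r)
      paste(signif(c(r$a, r$b, r$c), 12), collapse = ","), character(1))
  } else {
    key <- toupper(particle$element)
  }
  idx <- split(seq_along(key), key)
  lapply(idx, function(i) {
    rec <- if (!is.null(particle$ff_records)) particle$ff_records[[i[1]]]
           else ff_record(particle$element[i[1]])
    list(indices = i, record = rec)
  })
}
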