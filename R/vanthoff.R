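# Van't Hoff conversion between NaCl molarity and osmotic potential.
# R in MPa L mol^-1 K^-1; psi = -c * i * R * (T + 273.15)

.R_MPA <- 0.008314

#' Osmotic potential of a NaCl solution (Van't Hoff)
#'
#' Converts a solute concentration to its osmotic potential
#' \eqn{\psi = -c \, i \, R \, (T + 273.15)} with
#' \eqn{R = 0.008314} MPa L mol\eqn{^{-1}} K\eqn{^{-1}}. For NaCl the
#' dissociation number `ions` defaults to 2 (full dissociation).
#'
#' @param conc solute concentration, mol/L (non-negative).
#' @param temperature solution temperature, degrees Celsius.
#' @param ions dissociation number (osmotically active particles per
#'   formula unit); 2 for NaCl.
#' @return Osmotic potential in MPa (always \eqn{\le 0}).
#' @seealso [vant_hoff_conc()] for the exact inverse.
#' @examples
#' vant_hoff_psi(0.1, 25)   # -0.4958 MPa
#' @export
vant_hoff_psi <- function(conc, temperature, ions = 2) {
  if (any(conc < 0)) stop("'conc' must be non-negative")
  if (any(temperature <= -273.15)) stop("'temperature' must exceed absolute zero")
  -conc * ions * .R_MPA * (temperature + 273.15)
}

#' NaCl molarity producing a given osmotic potential
#'
#' Exact algebraic inverse of [vant_hoff_psi()].
#'
#' @param psi osmotic potential, MPa (non-positive).
#' @inheritParams vant_hoff_psi
#' @return Concentration in mol/L.
#' @examples
#' vant_hoff_conc(-0.4958, 25)  # ~0.1 M
#' @export
vant_hoff_conc <- function(psi, temperature, ions = 2) {
  if (any(psi > 0)) stop("'psi' must be non-positive")
  if (any(temperature <= -273.15)) stop("'temperature' must exceed absolute zero")
  -psi / (ions * .R_MPA * (temperature + 273.15))
}
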