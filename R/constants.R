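## CODATA 2018 exact/recommended values (SI)
.dh_constants <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  kB   = 1.380649e-23       # Boltzmann constant, J/K
)

#' Debye screening length of a symmetric 1:1 electrolyte
#'
#' \eqn{l_D = [\epsilon_w \epsilon_0 k_B T / (2 e^2 n_0)]^{1/2}}.
#'
#' @param eps_w relative dielectric constant of the electrolyte
#'   (about 80 for water).
#' @param temperature absolute temperature in K.
#' @param n0 bulk number density of each ionic species in m^-3
#'   (1 mM corresponds to about 6.022e23 m^-3).
#' @return Debye length in metres.
#' @examples
#' ## physiological-ish salt: ~0.96 nm
#' debye_length(80, 298, 0.1 * 6.02214076e26)
#' @export
debye_length <- function(eps_w, temperature, n0) {
  if (!(is.numeric(eps_w) && eps_w > 0)) stop("'eps_w' must be positive")
  if (!(is.numeric(temperature) && temperature > 0)) {
    stop("'temperature' must be positive")
  }
  if (!(is.numeric(n0) && n0 > 0)) stop("'n0' must be positive")
  sqrt(eps_w * .dh_constants$eps0 * .dh_constants$kB * temperature /
         (2 * .dh_constants$e^2 * n0))
}
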