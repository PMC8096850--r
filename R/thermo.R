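#' Thermodynamic state for free-energy bookkeeping
#'
#' Converts a temperature into the thermal energy kT in kcal/mol via the
#' Boltzmann constant (1.38064852e-23 J/K) and the Avogadro constant.
#' At 310 K, kT is about 0.616 kcal/mol. `beta` is the inverse thermal energy
#' 1/(kT) in mol/kcal, the factor that appears in Boltzmann weights
#' exp(-beta U).
#'
#' @param temperature temperature in K.
#' @return A `thermo_state` list: `temperature`, `k_B` (J/K), `kT`
#'   (kcal/mol), `beta` (mol/kcal).
#' @export
thermo_state <- function(temperature = 310) {
  if (temperature < 0) abort("temperature must be >= 0")
  k_B <- 1.38064852e-23
  avogadro <- 6.02214076e23
  kT <- k_B * temperature * avogadro / 4184
  structure(
    list(temperature = temperature, k_B = k_B, kT = kT,
         beta = if (kT > 0) 1 / kT else Inf),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %g K, kT = %.6g kcal/mol\n",
              x$temperature, x$kT))
  invisible(x)
}
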