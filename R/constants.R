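#' Physical constants used throughout the package
#'
#' Gas constant `R` (J mol-1 K-1), Boltzmann constant `kB` (J K-1) and
#' Planck constant `h` (J s). `t_ref` is the reference temperature (K) at
#' which binding enthalpy and entropy are defined in the van't Hoff model;
#' it is fixed and not user-configurable so that fitted (dH, dS) are always
#' comparable across variants.
#'
#' @format A named list with elements `R`, `kB`, `h`, `t_ref`.
#' @export
#' @examples
#' phys_const$R * 298.15
phys_const <- list(
  R     = 8.314,
  kB    = 1.380649e-23,
  h     = 6.62607015e-34,
  t_ref = 293.15
)
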