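#' Physical constants used throughout the package
#'
#' A single table of the physical constants the analysis relies on, so that
#' every module (resonance arithmetic, dose conversion, sinc correction)
#' draws from one source.
#'
#' @format A named list:
#' \describe{
#'   \item{planck_J_s}{Planck constant h (J s), 2019 SI exact value.}
#'   \item{bohr_magneton_J_T}{Bohr magneton mu_B (J/T), CODATA 2018.}
#'   \item{avogadro_per_mol}{Avogadro constant (1/mol), 2019 SI exact value.}
#'   \item{gyromagnetic_ratio_rad_s_T}{Proton gyromagnetic ratio gamma
#'     (rad s^-1 T^-1).}
#'   \item{iron_molar_mass_g_mol}{Molar mass of iron (g/mol).}
#' }
#' @export
spio_constants <- list(
  planck_J_s               = 6.62607015e-34,
  bohr_magneton_J_T        = 9.2740100783e-24,
  avogadro_per_mol         = 6.02214076e23,
  gyromagnetic_ratio_rad_s_T = 2.6752218744e8,
  iron_molar_mass_g_mol    = 55.845
)

# unnormalized sinc: sin(x)/x, sinc(0) = 1
sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
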