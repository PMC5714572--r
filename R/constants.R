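# Physical constants used across the package. Energies in MeV, lengths in
# mm, times in hours unless a function documents otherwise.

.const <- list(
  me_mev        = 0.510999,    # electron rest energy
  alpha_fs      = 1 / 137.036, # fine-structure constant
  avogadro      = 6.02214076e23,
  barn_cm2      = 1e-24,
  bq_per_mci    = 3.7e7,
  mev_to_j      = 1.602176634e-13,
  decays_per_uci_h = 3.7e4 * 3600, # 1 uCi for 1 h
  water_za      = 0.5542,      # Z/A of water
  water_i_ev    = 75,          # mean excitation energy of water
  water_x0_mm   = 360.8,       # radiation length of water, mm
  csda_e_max    = 2.5          # upper end of the range-energy table, MeV
)

# daughter atomic number and mass number per beta emitter, for the Coulomb
# factor of the Fermi spectrum shape
.daughters <- list(
  "90Y"   = c(z = 40, a = 90),
  "90Sr"  = c(z = 39, a = 90),
  "32P"   = c(z = 16, a = 32),
  "186Re" = c(z = 76, a = 186),
  "188Re" = c(z = 76, a = 188),
  "153Sm" = c(z = 63, a = 153),
  "142Pr" = c(z = 60, a = 142),
  "177Lu" = c(z = 72, a = 177),
  "166Ho" = c(z = 68, a = 166),
  "31Si"  = c(z = 15, a = 31),
  "28Al"  = c(z = 14, a = 28),
  "19O"   = c(z = 9,  a = 19)
)

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "yasdose")
  if (!nzchar(path)) stop("packaged fixture not found: ", file, call. = FALSE)
  path
}
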