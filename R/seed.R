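#' YAS glass composition
#'
#' Per-element weight fractions, masses, molar masses and the isotopic
#' abundance of the activatable parent for one seed, from the packaged
#' composition table (total mass 8.618 mg). The samarium is enriched
#' \eqn{^{152}}Sm and is treated as isotopically pure for activation;
#' silicon uses the 3.09% natural abundance of \eqn{^{30}}Si.
#'
#' @return A data frame of class `material_composition`.
#' @export
yas_composition <- function() {
  comp <- utils::read.csv(.extdata("table3_composition.csv"), stringsAsFactors = FALSE)
  material_composition(comp)
}

#' Construct a material composition
#'
#' @param comp Data frame with columns `element`, `weight_pct`, `mass_mg`,
#'   `molar_mass_g_mol`, `z`, `i_ev` and (for activation) `parent_isotope`,
#'   `parent_abundance`, `product_nuclide`.
#' @return The validated data frame with class `material_composition`.
#' @export
material_composition <- function(comp) {
  needed <- c("element", "weight_pct", "mass_mg", "molar_mass_g_mol", "z", "i_ev")
  missing_cols <- setdiff(needed, names(comp))
  if (length(missing_cols)) {
    stop("composition lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(comp$weight_pct) - 100) > 0.01) {
    stop("weight fractions must sum to 100 +/- 0.01 (got ",
         sum(comp$weight_pct), ")", call. = FALSE)
  }
  total <- sum(comp$mass_mg)
  # masses must be consistent with the weight fractions within print rounding
  dev <- abs(comp$mass_mg - comp$weight_pct / 100 * total)
  if (any(dev > 0.005 + 1e-9)) {
    stop("per-element masses inconsistent with weight fractions", call. = FALSE)
  }
  class(comp) <- c("material_composition", "data.frame")
  comp
}

#' Seed geometry and material
#'
#' The default is the YAS glass seed: a cylinder 4.5 mm long and 0.8 mm in
#' diameter with density 3.8 g/cm^3.
#'
#' @param length_mm,diameter_mm Cylinder dimensions in mm.
#' @param density_g_cm3 Glass density in g/cm^3.
#' @param composition A [material_composition()].
#' @return An object of class `seed_spec`.
#' @export
#' @examples
#' yas_seed()
seed_spec <- function(length_mm = 4.5, diameter_mm = 0.8,
                      density_g_cm3 = 3.8, composition = yas_composition()) {
  stopifnot(length_mm > 0, diameter_mm > 0, density_g_cm3 > 0)
  structure(list(length_mm = length_mm, diameter_mm = diameter_mm,
                 density_g_cm3 = density_g_cm3, composition = composition),
            class = "seed_spec")
}

#' @rdname seed_spec
#' @export
yas_seed <- function() seed_spec()

#' @export
print.seed_spec <- function(x, ...) {
  cat(sprintf("<seed> cylinder %g mm x %g mm diameter, %g g/cm3, %g mg\n",
              x$length_mm, x$diameter_mm, x$density_g_cm3,
              sum(x$composition$mass_mg)))
  invisible(x)
}

#' Activatable parent atoms of one element in the seed
#'
#' \eqn{N = m / M \times N_A \times f}, with \eqn{m} the element mass in
#' the seed, \eqn{M} its molar mass and \eqn{f} the isotopic abundance of
#' the activatable parent.
#'
#' @param composition A [material_composition()].
#' @param element Element label as it appears in the composition
#'   (e.g. `"Y"`, `"Si"`, `"152Sm"`).
#' @param abundance Override for the parent isotopic fraction; defaults to
#'   the packaged value.
#' @return Number of parent atoms.
#' @export
#' @examples
#' atom_inventory(yas_composition(), "152Sm")  # ~7.93e16
#' atom_inventory(yas_composition(), "Y")      # ~2.52e19
atom_inventory <- function(composition, element, abundance = NULL) {
  i <- match(element, composition$element)
  if (is.na(i)) {
    stop("element '", element, "' not in composition", call. = FALSE)
  }
  m <- composition$mass_mg[i]
  M <- composition$molar_mass_g_mol[i]
  f <- if (is.null(abundance)) composition$parent_abundance[i] else abundance
  if (is.na(M) || M <= 0) stop("missing molar mass for ", element, call. = FALSE)
  if (is.na(f) || f < 0 || f > 1) {
    stop("missing or invalid parent abundance for ", element, call. = FALSE)
  }
  (m * 1e-3) / M * .const$avogadro * f
}

# Bethe mass collision stopping power (MeV cm^2/g), point-Coulomb, no
# density-effect correction; used only through the glass/water ratio where
# the omitted terms largely cancel.
.mass_stopping_power <- function(energy_mev, za, i_ev) {
  me <- .const$me_mev
  tau <- energy_mev / me
  beta2 <- 1 - 1 / (1 + tau)^2
  fterm <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
  0.153536 / beta2 * za * (log(tau^2 * (tau + 2) / 2 / (i_ev * 1e-6 / me)^2) + fterm)
}

#' Glass-to-water mass collision stopping power ratio
#'
#' Computed from the composition by Bragg additivity: the glass Z/A and
#' log-mean excitation energy are weight-fraction averages of elemental
#' values, and the ratio of Bethe collision stopping powers to water
#' (Z/A = 0.5542, I = 75 eV) is evaluated at the given electron energy.
#' For the YAS glass the ratio is nearly energy-independent (~0.77).
#'
#' @param composition A [material_composition()].
#' @param energy_mev Electron kinetic energy at which to evaluate.
#' @return Dimensionless mass stopping power ratio (glass / water).
#' @export
stopping_power_ratio <- function(composition, energy_mev) {
  w <- composition$weight_pct / 100
  za_el <- composition$z / composition$molar_mass_g_mol
  za <- sum(w * za_el)
  i_glass <- exp(sum(w * za_el * log(composition$i_ev)) / za)
  .mass_stopping_power(energy_mev, za, i_glass) /
    .mass_stopping_power(energy_mev, .const$water_za, .const$water_i_ev)
}

#' Water-equivalent path scaling of the seed glass
#'
#' The factor converting a geometric path length in the glass to the
#' water-equivalent length used by the dose-point kernel:
#' density times the glass/water mass collision stopping power ratio.
#'
#' @param seed A [seed_spec()].
#' @param energy_mev Electron energy at which the ratio is taken; the
#'   default is the mean \eqn{^{90}}Y beta energy.
#' @return Dimensionless scaling (~2.92 for the YAS seed).
#' @export
water_equivalent_scaling <- function(seed, energy_mev = 0.934) {
  seed$density_g_cm3 * stopping_power_ratio(seed$composition, energy_mev)
}
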