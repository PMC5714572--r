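#' Activity produced by thermal neutron activation
#'
#' Thin-target, thermal-only (2200 m/s) activation without parent
#' burn-up or flux depression:
#' \eqn{A(t) = N \sigma \phi\, (1 - e^{-\lambda t})}, converted from Bq
#' to mCi. The saturation activity \eqn{N \sigma \phi} is the
#' \eqn{t \to \infty} limit.
#'
#' @param n_atoms Activatable parent atoms.
#' @param sigma_barns Thermal capture cross-section in barns.
#' @param flux Neutron flux in cm^-2 s^-1.
#' @param lambda_per_h Product decay constant in 1/h.
#' @param time_h Irradiation time in hours (may be `Inf`).
#' @return End-of-bombardment activity in mCi.
#' @export
#' @examples
#' # 152Sm(n,g)153Sm, 0.02 mg enriched 152Sm, 5 h at 3e13: ~0.95 mCi
#' n <- atom_inventory(yas_composition(), "152Sm")
#' activation_activity(n, 206, 3e13, decay_constant(46.7), 5)
activation_activity <- function(n_atoms, sigma_barns, flux, lambda_per_h, time_h) {
  if (any(c(n_atoms, sigma_barns, flux, lambda_per_h, time_h) < 0)) {
    stop("activation inputs must be nonnegative", call. = FALSE)
  }
  sat_bq <- n_atoms * sigma_barns * .const$barn_cm2 * flux
  sat_bq * (1 - exp(-lambda_per_h * time_h)) / .const$bq_per_mci
}

#' Radioactive decay of an activity
#'
#' @param activity_mci Activity in mCi.
#' @param lambda_per_h Decay constant in 1/h.
#' @param time_h Elapsed (cooling) time in hours.
#' @return \eqn{A e^{-\lambda t}} in mCi.
#' @export
#' @examples
#' decay_activity(5.750, decay_constant(64.1), 13)   # ~5 mCi
#' decay_activity(0.95, decay_constant(46.7), 13)    # ~0.8 mCi
decay_activity <- function(activity_mci, lambda_per_h, time_h) {
  if (any(time_h < 0)) stop("cooling time must be nonnegative", call. = FALSE)
  activity_mci * exp(-lambda_per_h * time_h)
}

#' Time for a permanent implant to deliver a dose fraction
#'
#' For a permanently implanted source the cumulated dose fraction after
#' time \eqn{t} is \eqn{1 - e^{-\lambda t}}; the time to reach fraction
#' \eqn{f} is \eqn{t = -\ln(1-f)/\lambda}.
#'
#' @param lambda_per_h Decay constant in 1/h.
#' @param fraction Dose fraction in (0, 1).
#' @return Time in hours.
#' @export
#' @examples
#' time_to_dose_fraction(decay_constant(64.0), 0.9) / 24  # 8.86 days
time_to_dose_fraction <- function(lambda_per_h, fraction) {
  if (any(fraction <= 0 | fraction >= 1)) {
    stop("fraction must be strictly inside (0, 1)", call. = FALSE)
  }
  -log(1 - fraction) / lambda_per_h
}

#' Cumulated decays of a decaying source
#'
#' \eqn{\tilde A(T) = A_0 (1 - e^{-\lambda T})/\lambda}; for
#' \eqn{T = \infty} this is \eqn{A_0/\lambda = A_0 T_{1/2}/\ln 2} (the
#' mean-lifetime integral).
#'
#' @param a0 Initial activity (any activity unit).
#' @param lambda_per_h Decay constant in 1/h.
#' @param time_h Integration horizon in hours, may be `Inf`.
#' @return Cumulated activity in (activity unit) x hours.
#' @export
cumulated_decays <- function(a0, lambda_per_h, time_h) {
  if (any(time_h < 0)) stop("time must be nonnegative", call. = FALSE)
  ifelse(is.infinite(time_h), a0 / lambda_per_h,
         a0 * (1 - exp(-lambda_per_h * time_h)) / lambda_per_h)
}

#' Activation scenario
#'
#' The default reproduces the reference irradiation: thermal flux
#' 3e13 cm^-2 s^-1 for 5 hours, then 13 hours of cooling.
#'
#' @param flux Thermal neutron flux, cm^-2 s^-1.
#' @param irradiation_h,cooling_h Times in hours.
#' @param seed A [seed_spec()].
#' @return Object of class `activation_scenario`.
#' @export
activation_scenario <- function(flux = 3e13, irradiation_h = 5,
                                cooling_h = 13, seed = yas_seed()) {
  stopifnot(flux >= 0, irradiation_h >= 0, cooling_h >= 0)
  structure(list(flux = flux, irradiation_h = irradiation_h,
                 cooling_h = cooling_h, seed = seed),
            class = "activation_scenario")
}

#' Activation and cooling plan for a seed
#'
#' End-of-bombardment and post-cooling activities for every activatable
#' parent in the seed composition (89Y, 30Si, 27Al, 152Sm), using the
#' activation-table half-lives (64.1 h for 90Y). Short-lived products
#' whose post-cooling activity has dropped below 1% of the seed total --
#' 31Si and 28Al after the 13 h cooling, roughly five of their
#' half-lives -- are flagged negligible.
#'
#' @param scenario An [activation_scenario()].
#' @return Data frame with one row per product nuclide plus a `Total`
#'   row: `eob_mci`, `cooled_mci`, `negligible`.
#' @export
#' @examples
#' irradiation_plan(activation_scenario())
irradiation_plan <- function(scenario) {
  comp <- scenario$seed$composition
  act <- comp[!is.na(comp$product_nuclide) & comp$product_nuclide != "19O", ]
  if (!nrow(act)) stop("composition has no activatable parents", call. = FALSE)
  rows <- lapply(seq_len(nrow(act)), function(i) {
    nuc <- get_nuclide(act$product_nuclide[i])
    lam <- nuc$lambda_activation_per_h
    n <- atom_inventory(comp, act$element[i])
    eob <- activation_activity(n, nuc$sigma_parent_b, scenario$flux, lam,
                               scenario$irradiation_h)
    data.frame(
      nuclide = nuc$name,
      parent = act$parent_isotope[i],
      half_life_h = nuc$half_life_activation_h,
      eob_mci = eob,
      cooled_mci = decay_activity(eob, lam, scenario$cooling_h)
    )
  })
  out <- do.call(rbind, rows)
  total_cooled <- sum(out$cooled_mci)
  out$negligible <- if (total_cooled > 0) {
    out$cooled_mci < 0.01 * total_cooled
  } else {
    rep(FALSE, nrow(out))
  }
  total <- data.frame(nuclide = "Total", parent = "", half_life_h = NA,
                      eob_mci = sum(out$eob_mci),
                      cooled_mci = sum(out$cooled_mci), negligible = FALSE)
  rbind(out, total)
}
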