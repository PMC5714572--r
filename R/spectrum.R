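#' Beta emission spectrum from Fermi theory
#'
#' Builds the binned \eqn{\beta^-} kinetic-energy spectrum
#' \deqn{N(E) \propto p\,W\,(E_{max}-E)^2\,F(Z,E)\,S(E)}
#' with \eqn{p, W} the electron momentum and total energy, \eqn{F(Z,E)}
#' the relativistic point-charge Fermi Coulomb function of the daughter
#' (screening neglected), and \eqn{S(E)} the shape factor: 1 for allowed
#' transitions and \eqn{p^2 + q^2} for the unique first-forbidden decay of
#' \eqn{^{90}}Y (\eqn{q} the neutrino momentum). The density is normalized
#' to unit area over \eqn{[0, E_{max}]}.
#'
#' @param nuclide A [get_nuclide()] record (or an isotope label).
#' @param n_bins Number of uniform energy bins (at least 100).
#' @param shape `"auto"` uses the registry transition type; `"allowed"`
#'   or `"forbidden-unique"` force a shape factor.
#' @return An object of class `beta_spectrum`: list with `nuclide`,
#'   `energy_mev` (bin edges, length `n_bins + 1`), `density_per_mev` at
#'   the edges, and the realized `mean_mev`.
#' @export
#' @examples
#' sp <- beta_spectrum("90Y")
#' sp$mean_mev                  # within 2% of 0.934 MeV
#' range(sp$energy_mev)         # 0 .. 2.284
beta_spectrum <- function(nuclide, n_bins = 1000, shape = c("auto", "allowed", "forbidden-unique")) {
  if (is.character(nuclide)) nuclide <- get_nuclide(nuclide)
  shape <- match.arg(shape)
  if (is.na(nuclide$emax_mev)) {
    stop("nuclide '", nuclide$name, "' has no beta endpoint energy", call. = FALSE)
  }
  stopifnot(n_bins >= 100)
  forbidden <- switch(shape,
    auto = identical(nuclide$transition, "first-forbidden-unique"),
    allowed = FALSE,
    `forbidden-unique` = TRUE
  )
  emax <- nuclide$emax_mev
  me <- .const$me_mev
  E <- seq(0, emax, length.out = n_bins + 1)
  W <- 1 + E / me
  p <- sqrt(pmax(W^2 - 1, 0))
  q <- (emax - E) / me
  dens <- p * W * q^2 * .fermi_function(nuclide$z_daughter, nuclide$a_mass, E)
  if (forbidden) dens <- dens * (p^2 + q^2)
  dens[!is.finite(dens)] <- 0
  dens[c(1, n_bins + 1)] <- 0       # p = 0 at E = 0, q = 0 at Emax
  area <- pracma::trapz(E, dens)
  dens <- dens / area
  sp <- list(
    nuclide = nuclide$name,
    energy_mev = E,
    density_per_mev = dens,
    mean_mev = pracma::trapz(E, E * dens),
    shape = if (forbidden) "forbidden-unique" else "allowed"
  )
  class(sp) <- "beta_spectrum"
  sp
}

# relativistic point-charge Fermi Coulomb correction for beta-minus decay;
# z is the daughter charge, a the mass number (nuclear radius)
.fermi_function <- function(z, a, energy_mev) {
  if (is.na(z)) return(rep(1, length(energy_mev)))
  me <- .const$me_mev
  alpha <- .const$alpha_fs
  W <- 1 + energy_mev / me
  p <- sqrt(pmax(W^2 - 1, 0))
  gam <- sqrt(1 - (alpha * z)^2)
  rn <- 0.426 * alpha * a^(1 / 3)   # nuclear radius in hbar/(me c)
  out <- numeric(length(W))
  ok <- p > 0
  eta <- alpha * z * W[ok] / p[ok]
  g2 <- abs(pracma::gammaz(complex(real = gam, imaginary = eta)))^2
  out[ok] <- 2 * (1 + gam) * (2 * p[ok] * rn)^(2 * (gam - 1)) *
    exp(pi * eta) * g2 / gamma(2 * gam + 1)^2
  out
}

#' @export
print.beta_spectrum <- function(x, ...) {
  cat(sprintf("<beta spectrum %s (%s)>  Emax = %g MeV, mean = %.4f MeV, %d bins\n",
              x$nuclide, x$shape, max(x$energy_mev), x$mean_mev,
              length(x$energy_mev) - 1L))
  invisible(x)
}

#' Mean energy of a spectrum
#' @param spectrum A [beta_spectrum()].
#' @return Mean kinetic energy in MeV.
#' @export
spectrum_mean <- function(spectrum) {
  pracma::trapz(spectrum$energy_mev, spectrum$energy_mev * spectrum$density_per_mev)
}

# cumulative distribution at the spectrum's energy grid
.spectrum_cdf <- function(spectrum) {
  E <- spectrum$energy_mev
  d <- spectrum$density_per_mev
  cdf <- cumsum(c(0, diff(E) * (utils::head(d, -1) + utils::tail(d, -1)) / 2))
  cdf / cdf[length(cdf)]
}

#' Sample emission energies
#'
#' Inverse-CDF draws over the binned density; bit-identical for a fixed
#' seed.
#'
#' @param spectrum A [beta_spectrum()].
#' @param n Number of draws (at least 1).
#' @param rng_seed Optional integer seed set before drawing.
#' @return Numeric vector of kinetic energies in MeV.
#' @export
sample_energies <- function(spectrum, n, rng_seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  cdf <- .spectrum_cdf(spectrum)
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], spectrum$energy_mev[keep], runif(n),
                rule = 2, ties = "ordered")$y
}

#' Write / read a spectrum as a two-column CSV
#'
#' @param spectrum A [beta_spectrum()].
#' @param path CSV path (columns `E_MeV`, `density`).
#' @return `write_spectrum_csv` returns `path` invisibly;
#'   `read_spectrum_csv` returns a `beta_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(
    data.frame(E_MeV = spectrum$energy_mev, density = spectrum$density_per_mev),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param nuclide Label to attach to the re-read spectrum.
#' @export
read_spectrum_csv <- function(path, nuclide = NA_character_) {
  df <- utils::read.csv(path)
  sp <- list(nuclide = nuclide, energy_mev = df$E_MeV,
             density_per_mev = df$density,
             mean_mev = pracma::trapz(df$E_MeV, df$E_MeV * df$density),
             shape = "imported")
  class(sp) <- "beta_spectrum"
  sp
}
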