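#' Nuclide registry
#'
#' The registry merges the packaged tables of beta-emitter properties and
#' of activation products of the YAS glass. For \eqn{^{90}}Y two printed
#' half-lives exist (64.0 h in the emitter comparison table, 64.1 h in the
#' activation table); both are kept, with `half_life_h` holding the
#' emitter-table value and `half_life_activation_h` the activation-table
#' value. Dose and decay-planning operations default to 64.0 h, activation
#' and cooling arithmetic to 64.1 h; either is overridable.
#'
#' @return A data frame with one row per nuclide: half-lives (h), beta
#'   endpoint and mean energies (MeV), beta transition type, thermal
#'   capture cross-section of the activatable parent (barns) and gamma
#'   line data where printed.
#' @export
#' @examples
#' nuclide_registry()[, c("nuclide", "half_life_h", "emax_mev")]
nuclide_registry <- function() {
  t1 <- utils::read.csv(.extdata("table1_nuclides.csv"), stringsAsFactors = FALSE)
  t2 <- utils::read.csv(.extdata("table2_activation.csv"), stringsAsFactors = FALSE)
  reg <- merge(t1, t2[, c("nuclide", "half_life_h", "sigma_parent_b")],
               by = "nuclide", all = TRUE, suffixes = c("", "_act"))
  names(reg)[names(reg) == "half_life_h_act"] <- "half_life_activation_h"
  names(reg)[names(reg) == "sigma_parent_b_act"] <- "sigma_parent_b_activation"
  # activation-only nuclides carry their table-2 data in the main columns
  only2 <- is.na(reg$half_life_h)
  reg$half_life_h[only2] <- reg$half_life_activation_h[only2]
  reg$sigma_parent_b[only2] <- reg$sigma_parent_b_activation[only2]
  i2 <- match(reg$nuclide, t2$nuclide)
  reg$emax_mev[only2] <- t2$beta_emax_mev[i2[only2]]
  # fall back to the single printed half-life where only one table lists it
  noact <- is.na(reg$half_life_activation_h)
  reg$half_life_activation_h[noact] <- reg$half_life_h[noact]
  reg$transition <- ifelse(reg$nuclide == "90Y", "first-forbidden-unique", "allowed")
  reg[order(reg$nuclide), ]
}

#' Look up one nuclide
#'
#' @param name Isotope label, e.g. `"90Y"`, `"153Sm"`, `"31Si"`.
#' @return An object of class `nuclide_record`: a list with `name`,
#'   `half_life_h` (emitter-table value), `half_life_activation_h`,
#'   the decay constants `lambda_per_h` / `lambda_activation_per_h`
#'   (\eqn{\ln 2 / T_{1/2}}), `emax_mev`, `emean_mev`, `transition`,
#'   `sigma_parent_b`, `gamma_lines` and the daughter charge/mass numbers
#'   used by the spectrum generator.
#' @export
#' @examples
#' y90 <- get_nuclide("90Y")
#' y90$half_life_h            # 64.0
#' y90$lambda_per_h           # ln(2)/64.0
get_nuclide <- function(name) {
  reg <- nuclide_registry()
  i <- match(name, reg$nuclide)
  if (is.na(i)) {
    stop("unknown isotope '", name, "'; available: ",
         paste(reg$nuclide, collapse = ", "), call. = FALSE)
  }
  row <- reg[i, ]
  d <- .daughters[[name]]
  gamma_lines <- if (!is.na(row$gamma_kev)) {
    list(c(kev = row$gamma_kev, yield = row$gamma_yield_pct / 100))
  } else {
    list()
  }
  rec <- list(
    name = name,
    half_life_h = row$half_life_h,
    half_life_activation_h = row$half_life_activation_h,
    lambda_per_h = log(2) / row$half_life_h,
    lambda_activation_per_h = log(2) / row$half_life_activation_h,
    emax_mev = row$emax_mev,
    emean_mev = row$emean_mev,
    beta_yield = if (!is.na(row$beta_yield_pct)) row$beta_yield_pct / 100 else NA_real_,
    transition = row$transition,
    sigma_parent_b = row$sigma_parent_b,
    gamma_lines = gamma_lines,
    z_daughter = if (!is.null(d)) unname(d["z"]) else NA_real_,
    a_mass = if (!is.null(d)) unname(d["a"]) else NA_real_
  )
  class(rec) <- "nuclide_record"
  rec
}

#' @export
print.nuclide_record <- function(x, ...) {
  cat(sprintf("<nuclide %s>  T1/2 = %g h", x$name, x$half_life_h))
  if (!isTRUE(all.equal(x$half_life_h, x$half_life_activation_h))) {
    cat(sprintf(" (activation: %g h)", x$half_life_activation_h))
  }
  if (!is.na(x$emax_mev)) cat(sprintf("  Emax = %g MeV", x$emax_mev))
  if (!is.na(x$emean_mev)) cat(sprintf("  Emean = %g MeV", x$emean_mev))
  cat("\n")
  if (!is.na(x$sigma_parent_b)) {
    cat(sprintf("  parent capture cross-section: %g b\n", x$sigma_parent_b))
  }
  invisible(x)
}

#' Decay constant from a half-life
#'
#' @param half_life_h Half-life in hours.
#' @return \eqn{\lambda = \ln 2 / T_{1/2}} in 1/h.
#' @export
decay_constant <- function(half_life_h) {
  stopifnot(is.numeric(half_life_h), all(half_life_h > 0))
  log(2) / half_life_h
}

#' Export the nuclide registry as JSON
#'
#' @param path File to write; defaults to returning the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
registry_to_json <- function(path = NULL) {
  js <- jsonlite::toJSON(nuclide_registry(), dataframe = "rows",
                         na = "null", digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
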