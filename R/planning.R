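#' Total dose of a permanently implanted decaying source
#'
#' \eqn{D(T) = \dot D_0 (1 - e^{-\lambda T}) / \lambda}, converted from
#' cGy to Gy. With \eqn{T = \infty} the integral is the initial dose
#' rate times the mean lifetime \eqn{T_{1/2}/\ln 2}.
#'
#' @param dose_rate_cgy_h Initial dose rate in cGy/h.
#' @param half_life_h Half-life in hours.
#' @param duration_h Integration horizon in hours (default `Inf`,
#'   permanent implant).
#' @return Dose in Gy.
#' @export
#' @examples
#' # 0.0003 cGy/h/uCi at 10 mm x 5 mCi, full decay of 90Y: 1.38 Gy
#' permanent_implant_dose(0.0003 * 5000, 64.0)
permanent_implant_dose <- function(dose_rate_cgy_h, half_life_h,
                                   duration_h = Inf) {
  stopifnot(all(dose_rate_cgy_h >= 0), all(half_life_h > 0), all(duration_h >= 0))
  lam <- decay_constant(half_life_h)
  cumulated_decays(dose_rate_cgy_h, lam, duration_h) / 100
}

#' Contained-to-apparent activity ratio
#'
#' A fraction `f_self` of the emitted beta energy never leaves the glass,
#' so the activity inferred from the external dose field (apparent) is
#' smaller than the activity contained in the seed by
#' \eqn{1/(1 - f_{self})}.
#'
#' @param f_self Self-absorbed energy fraction in `[0, 1)`.
#' @return The contained/apparent ratio.
#' @export
#' @examples
#' contained_to_apparent(0.3051)   # ~1.44
contained_to_apparent <- function(f_self) {
  if (any(f_self < 0 | f_self >= 1)) {
    stop("f_self must be in [0, 1)", call. = FALSE)
  }
  1 / (1 - f_self)
}

#' Isodose contours of a scored grid
#'
#' Interpolates the polar dose grid onto a Cartesian half-plane
#' (transverse distance y >= 0, axial coordinate z) and extracts closed
#' contour polylines at the requested dose-rate levels, mirrored to the
#' full (y, z) plane by cylindrical symmetry.
#'
#' @param grid_obj A `dose_grid`.
#' @param levels Dose-rate levels in cGy/h/uCi.
#' @param res_mm Cartesian interpolation pitch (default 0.1 mm).
#' @return Named list (one element per level) of data frames with
#'   `y_mm`, `z_mm`; empty (with a warning) for levels outside the grid's
#'   dynamic range.
#' @export
isodose_contours <- function(grid_obj, levels, res_mm = 0.1) {
  g <- grid_obj$grid
  d <- .mirror_symmetrize(grid_obj)$dose_cgy_uci_h
  rmid <- (seq_len(g$n_r) - 0.5) * g$shell_mm
  thmid <- ((seq_len(g$n_theta) - 0.5) * g$aperture_deg) * pi / 180
  ld <- suppressWarnings(log(d))
  ld[!is.finite(ld)] <- NA
  y <- seq(res_mm / 2, g$r_max_mm, by = res_mm)
  z <- seq(-g$r_max_mm, g$r_max_mm, by = res_mm)
  pts <- expand.grid(y = y, z = z)
  rr <- sqrt(pts$y^2 + pts$z^2)
  tt <- acos(pmax(pmin(pts$z / pmax(rr, 1e-12), 1), -1))
  ir <- pmin(pmax(findInterval(rr, rmid), 1), g$n_r - 1)
  it <- pmin(pmax(findInterval(tt, thmid), 1), g$n_theta - 1)
  wr <- pmin(pmax((rr - rmid[ir]) / (rmid[ir + 1] - rmid[ir]), 0), 1)
  wt <- pmin(pmax((tt - thmid[it]) / (thmid[it + 1] - thmid[it]), 0), 1)
  idx <- function(i, j) cbind(i, j)
  v <- (1 - wr) * (1 - wt) * ld[idx(ir, it)] +
    wr * (1 - wt) * ld[idx(ir + 1, it)] +
    (1 - wr) * wt * ld[idx(ir, it + 1)] +
    wr * wt * ld[idx(ir + 1, it + 1)]
  zmat <- matrix(v, length(y), length(z))
  rng <- range(exp(zmat), na.rm = TRUE)
  out <- vector("list", length(levels))
  names(out) <- as.character(levels)
  for (k in seq_along(levels)) {
    if (levels[k] < rng[1] || levels[k] > rng[2]) {
      warning("isodose level ", levels[k], " outside the grid dynamic range")
      out[[k]] <- data.frame(y_mm = numeric(), z_mm = numeric())
      next
    }
    cl <- grDevices::contourLines(y, z, zmat, levels = log(levels[k]))
    if (!length(cl)) {
      out[[k]] <- data.frame(y_mm = numeric(), z_mm = numeric())
      next
    }
    # keep the longest polyline, close it through the mirror half-plane
    ln <- cl[[which.max(vapply(cl, function(p) length(p$x), numeric(1)))]]
    half <- data.frame(y_mm = ln$x, z_mm = ln$y)
    mirrored <- data.frame(y_mm = -rev(ln$x), z_mm = rev(ln$y))
    out[[k]] <- rbind(half, mirrored)
  }
  out
}

#' Implant plan
#'
#' @param seeds Data frame with seed positions `x_mm`, `y_mm`, `z_mm`,
#'   orientation components `ux`, `uy`, `uz` (normalized) and
#'   `activity_mci` (apparent initial activity).
#' @param params A [tg60_parameter_set()].
#' @param nuclide A [get_nuclide()] record (decay during the implant).
#' @return Object of class `implant_plan`.
#' @export
implant_plan <- function(seeds, params, nuclide = get_nuclide("90Y")) {
  needed <- c("x_mm", "y_mm", "z_mm", "ux", "uy", "uz", "activity_mci")
  if (!all(needed %in% names(seeds))) {
    stop("seeds need columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  nrm <- sqrt(seeds$ux^2 + seeds$uy^2 + seeds$uz^2)
  if (any(abs(nrm - 1) > 1e-6)) stop("orientations must be unit vectors", call. = FALSE)
  if (any(seeds$activity_mci < 0)) stop("activities must be nonnegative", call. = FALSE)
  structure(list(seeds = seeds, params = params, nuclide = nuclide),
            class = "implant_plan")
}

#' Cumulative dose of a multi-seed implant at a point
#'
#' Superposes the TG-60 dose rate of every seed, each evaluated in its
#' own local frame (distance from the seed center and polar angle to its
#' axis), then integrates the common exponential decay to `time_h`.
#' Seeds are transparent to each other's radiation (no interseed
#' attenuation).
#'
#' @param plan An [implant_plan()].
#' @param point Numeric length-3, mm.
#' @param time_h Horizon in hours (default `Inf`).
#' @return Cumulative dose in Gy.
#' @export
multi_seed_dose <- function(plan, point, time_h = Inf) {
  stopifnot(length(point) == 3)
  s <- plan$seeds
  total_rate <- 0
  for (i in seq_len(nrow(s))) {
    v <- point - c(s$x_mm[i], s$y_mm[i], s$z_mm[i])
    r <- sqrt(sum(v^2))
    L <- plan$params$L_mm
    axial <- abs(sum(v * c(s$ux[i], s$uy[i], s$uz[i])))
    radial <- sqrt(max(r^2 - axial^2, 0))
    if (axial <= L / 2 && radial <= 0.5) {
      stop("point lies inside seed ", i, call. = FALSE)
    }
    th <- acos(pmin(pmax(axial / max(r, 1e-12), -1), 1)) * 180 / pi
    # beyond the tabulated 10 mm the beta dose is negligible: count zero
    rate <- suppressWarnings(dose_rate_tg60(plan$params, r, th)) # cGy/h/uCi
    if (is.na(rate)) rate <- 0
    total_rate <- total_rate + rate * s$activity_mci[i] * 1000
  }
  permanent_implant_dose(total_rate, plan$nuclide$half_life_h, time_h)
}
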