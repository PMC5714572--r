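#' Line-source geometry function
#'
#' \eqn{G_L(r,\theta) = \beta / (L\,r\,\sin\theta)}, with \eqn{\beta} the
#' angle subtended at the point \eqn{(r,\theta)} by the active line of
#' length \eqn{L}; on the long axis the limit is
#' \eqn{G_L = 1/(r^2 - L^2/4)}. The polar angle is measured from the
#' seed's long axis.
#'
#' @param r_mm Radial distance(s) from the seed center, mm.
#' @param theta_deg Polar angle(s) in degrees.
#' @param L_mm Active (effective) length, default the physical 4.5 mm.
#' @return Geometry function in mm^-2 (vectorized; inputs recycled).
#' @export
#' @examples
#' geometry_function_line(2, 90)   # 0.18759 mm^-2
#' geometry_function_line(5, 0)    # 1/(25 - 5.0625)
geometry_function_line <- function(r_mm, theta_deg, L_mm = 4.5) {
  n <- max(length(r_mm), length(theta_deg))
  r <- rep_len(r_mm, n)
  th <- rep_len(theta_deg, n) * pi / 180
  st <- sin(th)
  ct <- cos(th)
  on_axis <- abs(st) < 1e-9
  if (any(r[on_axis] <= L_mm / 2)) {
    stop("point on the source line within the active length", call. = FALSE)
  }
  out <- numeric(n)
  if (any(on_axis)) out[on_axis] <- 1 / (r[on_axis]^2 - L_mm^2 / 4)
  off <- !on_axis
  if (any(off)) {
    beta <- atan2(r[off] * ct[off] + L_mm / 2, r[off] * st[off]) -
      atan2(r[off] * ct[off] - L_mm / 2, r[off] * st[off])
    out[off] <- beta / (L_mm * r[off] * st[off])
  }
  out
}

#' Radial dose function from a transverse profile
#'
#' \eqn{g_L(r) = [\dot D(r)/\dot D(r_0)] \cdot [G_L(r_0,\theta_0)/G_L(r,\theta_0)]}
#' with the reference point at \eqn{r_0 = 2} mm on the transverse axis.
#'
#' @param transverse Data frame with columns `r_mm` and a dose-rate
#'   column (the second column, or named `dose_rate`).
#' @param L_mm Effective line length.
#' @param r0_mm Reference radius (2 mm).
#' @return Data frame `r_mm`, `gL`.
#' @export
#' @examples
#' t4 <- load_reference_table("table4_radial_dose_rate")
#' gl <- radial_dose_function(data.frame(r_mm = t4$data$r_mm,
#'                                       dose_rate = t4$data$MCNP5))
#' gl$gL[gl$r_mm == 5.0]   # 0.374 to three decimals
radial_dose_function <- function(transverse, L_mm = 4.5, r0_mm = 2.0) {
  dcol <- if ("dose_rate" %in% names(transverse)) "dose_rate" else names(transverse)[2]
  r <- transverse$r_mm
  d <- transverse[[dcol]]
  i0 <- which(abs(r - r0_mm) < 1e-9)
  if (!length(i0)) stop("transverse table lacks the reference radius ", r0_mm, " mm",
                        call. = FALSE)
  g0 <- geometry_function_line(r0_mm, 90, L_mm)
  data.frame(r_mm = r, gL = d / d[i0[1]] * g0 / geometry_function_line(r, 90, L_mm))
}

# dose rate at an exact (r, theta) point of a scored polar grid: average
# of the cells adjacent to the point (points on shell/band edges get the
# mean of both neighbors); NA if any contributing cell touches the seed
.grid_point_dose <- function(grid_obj, r_mm, theta_deg) {
  g <- grid_obj$grid
  eps <- 1e-9
  ir <- r_mm / g$shell_mm
  it <- theta_deg / g$aperture_deg
  irs <- if (abs(ir - round(ir)) < eps) c(round(ir) - 1, round(ir)) else floor(ir)
  its <- if (abs(it - round(it)) < eps) c(round(it) - 1, round(it)) else floor(it)
  irs <- irs[irs >= 0 & irs < g$n_r] + 1L
  its <- its[its >= 0 & its < g$n_theta] + 1L
  if (!length(irs) || !length(its)) return(NA_real_)
  cells <- grid_obj$dose_cgy_uci_h[irs, its, drop = FALSE]
  masks <- grid_obj$seed_mask[irs, its, drop = FALSE]
  if (any(masks != 0L)) return(NA_real_)
  mean(cells)
}

#' 2D anisotropy function from a scored grid
#'
#' \eqn{F(r,\theta) = [\dot D(r,\theta)/\dot D(r,\theta_0)] \cdot
#' [G_L(r,\theta_0)/G_L(r,\theta)]}. Cells inside or cut by the physical
#' seed are reported as missing, never zero. The grid is first
#' symmetrized about the transverse plane (the geometry is mirror
#' symmetric; this halves the variance).
#'
#' @param grid_obj A `dose_grid`.
#' @param radii_mm,theta_deg Output lattice (defaults match the packaged
#'   anisotropy table: 1-10 mm, 0-90 degrees in 10-degree steps).
#' @param L_mm Effective line length.
#' @return Matrix of F values, radii in columns (dimnames set), `NA`
#'   where undefined.
#' @export
anisotropy_2d <- function(grid_obj, radii_mm = seq(1, 10, by = 0.5),
                          theta_deg = seq(0, 90, by = 10), L_mm = 4.5) {
  sym <- .mirror_symmetrize(grid_obj)
  out <- matrix(NA_real_, length(theta_deg), length(radii_mm),
                dimnames = list(theta_deg, radii_mm))
  for (ic in seq_along(radii_mm)) {
    d90 <- .grid_point_dose(sym, radii_mm[ic], 90)
    if (is.na(d90) || d90 <= 0) next
    g90 <- geometry_function_line(radii_mm[ic], 90, L_mm)
    for (ith in seq_along(theta_deg)) {
      th <- max(theta_deg[ith], 1e-6)
      d <- .grid_point_dose(sym, radii_mm[ic], theta_deg[ith])
      if (is.na(d) || d <= 0) next
      out[ith, ic] <- d / d90 * g90 / geometry_function_line(radii_mm[ic], th, L_mm)
    }
  }
  out
}

# average each cell with its mirror about the transverse plane
.mirror_symmetrize <- function(grid_obj) {
  d <- grid_obj$dose_cgy_uci_h
  m <- grid_obj$seed_mask
  dm <- (d + d[, rev(seq_len(ncol(d)))]) / 2
  grid_obj$dose_cgy_uci_h <- dm
  grid_obj$seed_mask <- pmax(m, m[, rev(seq_len(ncol(m)))])
  grid_obj
}

#' 1D anisotropy factor from a scored grid
#'
#' \eqn{\varphi_{an}(r) = \int \dot D(r,\theta) \sin\theta\, d\theta \,/\,
#' [2 \dot D(r,\theta_0)]}: the solid-angle-weighted mean dose rate over
#' the full polar range divided by the transverse dose rate, by exact
#' quadrature over the cone bands.
#'
#' @param grid_obj A `dose_grid` covering the full polar range.
#' @param radii_mm Radii to evaluate.
#' @return Data frame `r_mm`, `phi_an`.
#' @export
anisotropy_1d <- function(grid_obj, radii_mm = seq(1, 10, by = 0.5)) {
  g <- grid_obj$grid
  if (g$n_theta * g$aperture_deg < 180 - 1e-9) {
    stop("grid does not cover the full polar range", call. = FALSE)
  }
  th_edges <- seq(0, pi, length.out = g$n_theta + 1)
  w <- -diff(cos(th_edges)) # integrates sin(theta) over each band
  phi <- vapply(radii_mm, function(r) {
    ir <- r / g$shell_mm
    irs <- if (abs(ir - round(ir)) < 1e-9) c(round(ir) - 1, round(ir)) else floor(ir)
    irs <- irs[irs >= 0 & irs < g$n_r] + 1L
    rows <- grid_obj$dose_cgy_uci_h[irs, , drop = FALSE]
    if (anyNA(rows)) return(NA_real_)
    d90 <- .grid_point_dose(grid_obj, r, 90)
    sum(colMeans(rows) * w) / (2 * d90)
  }, numeric(1))
  data.frame(r_mm = radii_mm, phi_an = phi)
}

#' 1D anisotropy factor from an anisotropy-function table
#'
#' Reconstructs \eqn{\varphi_{an}(r)} by quadrature over a tabulated
#' \eqn{F(r,\theta)} hemisphere:
#' \eqn{\varphi_{an}(r) = \int_0^{90^\circ} F\, G_L \sin\theta\, d\theta
#' / G_L(r, 90^\circ)} (mirror symmetry doubles the hemisphere and
#' cancels the factor 2). Missing near-axis entries are extended from the
#' smallest tabulated angle.
#'
#' @param F_row Numeric vector of F values at `theta_deg` for one radius
#'   (NAs allowed near the axis).
#' @param r_mm The radius of the row.
#' @param theta_deg Angles of the entries, degrees from the long axis.
#' @param L_mm Effective line length.
#' @return The quadrature estimate of \eqn{\varphi_{an}(r)}.
#' @export
phi_an_from_F <- function(F_row, r_mm, theta_deg = seq(0, 90, by = 10),
                          L_mm = 4.5) {
  ok <- !is.na(F_row)
  if (!any(ok)) return(NA_real_)
  thmin <- min(theta_deg[ok])
  Fful <- F_row
  Fful[!ok] <- F_row[which(theta_deg == thmin)]
  th <- theta_deg * pi / 180
  gl <- geometry_function_line(r_mm, pmax(theta_deg, 1e-6), L_mm)
  pracma::trapz(th, Fful * gl * sin(th)) /
    geometry_function_line(r_mm, 90, L_mm)
}

#' Fifth-order polynomial fit of a radial dose function
#'
#' Unweighted least squares of \eqn{g_L(r)} on powers of \eqn{r}; the fit
#' quality is summarized by the Pearson correlation between fitted and
#' tabulated values.
#'
#' @param gl_table Data frame `r_mm`, `gL`.
#' @param order Polynomial order (default 5).
#' @return Object of class `radial_poly_fit`: coefficients `a0..a5`,
#'   correlation `R`, and `predict(fit, r)` support.
#' @export
fit_radial_polynomial <- function(gl_table, order = 5) {
  if (nrow(gl_table) < order + 2) {
    stop("need at least order + 2 points", call. = FALSE)
  }
  X <- outer(gl_table$r_mm, 0:order, `^`)
  qr_x <- qr(X)
  if (qr_x$rank < order + 1) stop("rank-deficient design", call. = FALSE)
  fit <- stats::lm.fit(X, gl_table$gL)
  coefs <- fit$coefficients
  names(coefs) <- paste0("a", 0:order)
  fitted <- drop(X %*% coefs)
  structure(list(coefficients = coefs,
                 R = stats::cor(fitted, gl_table$gL),
                 order = order, r_mm = gl_table$r_mm, fitted = fitted),
            class = "radial_poly_fit")
}

#' @export
predict.radial_poly_fit <- function(object, r_mm, ...) {
  drop(outer(r_mm, 0:object$order, `^`) %*% object$coefficients)
}

#' @export
print.radial_poly_fit <- function(x, ...) {
  cat(sprintf("<order-%d radial dose function fit>  R = %.5f\n", x$order, x$R))
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Reference absorbed dose rate
#'
#' Dose rate at the TG-60 reference point \eqn{(r_0 = 2\,\mathrm{mm},
#' \theta_0 = 90^\circ)}. For a scored `dose_grid` this is the mean of
#' the cells adjacent to the reference point; for a transverse-profile
#' data frame it is the tabulated value at 2 mm.
#'
#' @param x A `dose_grid` or a data frame with `r_mm` and a dose column.
#' @return Dose rate in cGy/h per uCi.
#' @export
#' @examples
#' t4 <- load_reference_table("table4_radial_dose_rate")
#' reference_dose_rate(data.frame(r_mm = t4$data$r_mm,
#'                                dose_rate = t4$data$MCNP5))  # 5.0542
reference_dose_rate <- function(x) {
  if (inherits(x, "dose_grid")) {
    d <- .grid_point_dose(x, 2.0, 90)
    if (is.na(d)) stop("reference cell unavailable", call. = FALSE)
    return(d)
  }
  dcol <- if ("dose_rate" %in% names(x)) "dose_rate" else names(x)[2]
  i <- which(abs(x$r_mm - 2.0) < 1e-9)
  if (!length(i)) stop("no entry at the 2 mm reference radius", call. = FALSE)
  x[[dcol]][i[1]]
}

#' TG-60 parameter set
#'
#' Bundles the reference dose rate, radial dose function table, 2D
#' anisotropy table, 1D anisotropy factors, line length and polynomial
#' fit. Validates the protocol normalizations
#' (\eqn{g_L(2\,\mathrm{mm}) = 1}, \eqn{F(r, 90^\circ) = 1}).
#'
#' @param ref_dose_rate Reference dose rate, cGy/h/uCi.
#' @param gl_table Data frame `r_mm`, `gL`.
#' @param F_table Matrix as returned by [anisotropy_2d()] (angles in
#'   rows, radii in columns, dimnames set).
#' @param phi_an Data frame `r_mm`, `phi_an` (optional).
#' @param L_mm Effective length.
#' @param fit Optional [fit_radial_polynomial()] result; computed from
#'   `gl_table` when missing.
#' @return Object of class `tg60_parameters`.
#' @export
tg60_parameter_set <- function(ref_dose_rate, gl_table, F_table,
                               phi_an = NULL, L_mm = 4.5, fit = NULL) {
  stopifnot(ref_dose_rate > 0)
  g2 <- gl_table$gL[abs(gl_table$r_mm - 2.0) < 1e-9]
  if (!length(g2) || abs(g2 - 1) > 1e-6) {
    stop("gL table is not normalized to 1 at the 2 mm reference radius",
         call. = FALSE)
  }
  f90 <- F_table[rownames(F_table) == "90", ]
  if (any(abs(f90[!is.na(f90)] - 1) > 1e-6)) {
    stop("F table is not 1 on the transverse plane", call. = FALSE)
  }
  if (any(gl_table$gL <= 0)) stop("gL entries must be positive", call. = FALSE)
  if (is.null(fit)) fit <- fit_radial_polynomial(gl_table)
  structure(list(ref_dose_rate = ref_dose_rate, gl_table = gl_table,
                 F_table = F_table, phi_an = phi_an, L_mm = L_mm, fit = fit),
            class = "tg60_parameters")
}

#' @export
print.tg60_parameters <- function(x, ...) {
  cat(sprintf("<TG-60 parameters>  ref dose rate %.4f cGy/h/uCi, L = %g mm\n",
              x$ref_dose_rate, x$L_mm))
  cat(sprintf("  gL over %g-%g mm (%d pts), F %d angles x %d radii, fit R = %.5f\n",
              min(x$gl_table$r_mm), max(x$gl_table$r_mm), nrow(x$gl_table),
              nrow(x$F_table), ncol(x$F_table), x$fit$R))
  invisible(x)
}

#' Extract the TG-60 parameters from a scored grid
#'
#' Runs the full extraction chain: transverse profile, reference dose
#' rate, radial dose function, 2D/1D anisotropy and the polynomial fit.
#'
#' @param grid_obj A `dose_grid`.
#' @param radii_mm Radii for the tables.
#' @param theta_deg Angles for the anisotropy table.
#' @param L_mm Effective length; defaults to the seed's physical length.
#' @return A [tg60_parameter_set()].
#' @export
extract_tg60 <- function(grid_obj, radii_mm = seq(1, 10, by = 0.5),
                         theta_deg = seq(0, 90, by = 10), L_mm = NULL) {
  if (is.null(L_mm)) L_mm <- grid_obj$seed$length_mm
  tr <- transverse_profile(grid_obj, radii_mm)
  gl <- radial_dose_function(tr, L_mm)
  Ftab <- anisotropy_2d(grid_obj, radii_mm, theta_deg, L_mm)
  phi <- anisotropy_1d(grid_obj, radii_mm)
  tg60_parameter_set(reference_dose_rate(grid_obj), gl, Ftab, phi, L_mm)
}

#' TG-60 parameters from the packaged reference tables
#'
#' Builds a parameter set from the printed MCNP5 data: the transverse
#' dose-rate table (for the reference dose rate and radial dose
#' function) and the anisotropy table.
#'
#' @param code Which transport code's column to use (`"MCNP5"`,
#'   `"EGSnrc"` or `"FLUKA"`; the anisotropy table is MCNP5-only).
#' @return A [tg60_parameter_set()].
#' @export
tg60_reference_params <- function(code = "MCNP5") {
  t4 <- load_reference_table("table4_radial_dose_rate")$data
  if (!code %in% names(t4)) stop("unknown code column: ", code, call. = FALSE)
  tr <- data.frame(r_mm = t4$r_mm, dose_rate = t4[[code]])
  gl <- radial_dose_function(tr)
  # re-normalize exactly at r0 (printed tables round to three decimals)
  t7 <- load_reference_table("table7_F")$data
  Fm <- as.matrix(t7[, -1])
  dimnames(Fm) <- list(t7$theta_deg,
                       sub("^r", "", colnames(t7)[-1]))
  phi <- load_reference_table("table7_phi_an")$data
  tg60_parameter_set(reference_dose_rate(tr), gl, Fm,
                     data.frame(r_mm = phi$r_mm, phi_an = phi$phi_an))
}

#' TG-60 dose-rate reconstruction
#'
#' \eqn{\dot D(r,\theta) = \dot D_w(r_0,\theta_0)\,
#' [G_L(r,\theta)/G_L(r_0,\theta_0)]\, g_L(r)\, F(r,\theta)}, with
#' log-linear interpolation of \eqn{g_L} in \eqn{r} (the falloff spans
#' five decades) and bilinear interpolation of \eqn{F} in
#' \eqn{(r,\theta)}; angles beyond the tabulated hemisphere are mirrored
#' about the transverse plane.
#'
#' @param params A [tg60_parameter_set()].
#' @param r_mm,theta_deg Evaluation point(s), recycled.
#' @return Dose rate(s) in cGy/h/uCi; `NA` with a warning outside the
#'   table's radial validity range.
#' @export
#' @examples
#' p <- tg60_reference_params()
#' dose_rate_tg60(p, 2, 90)    # the reference dose rate
#' dose_rate_tg60(p, 5, 90)    # ~0.378
dose_rate_tg60 <- function(params, r_mm, theta_deg) {
  n <- max(length(r_mm), length(theta_deg))
  r <- rep_len(r_mm, n)
  th <- rep_len(theta_deg, n)
  rmin <- min(params$gl_table$r_mm)
  rmax <- max(params$gl_table$r_mm)
  out <- rep(NA_real_, n)
  bad <- r < rmin - 1e-9 | r > rmax + 1e-9
  if (any(bad)) {
    warning("dose requested outside the table range ", rmin, "-", rmax,
            " mm; returning NA")
  }
  ok <- !bad
  if (!any(ok)) return(out)
  gl <- exp(stats::approx(params$gl_table$r_mm, log(params$gl_table$gL),
                          pmin(pmax(r[ok], rmin), rmax), rule = 2,
                          ties = "ordered")$y)
  Fv <- .interp_F(params$F_table, r[ok], th[ok])
  g0 <- geometry_function_line(2.0, 90, params$L_mm)
  gq <- geometry_function_line(r[ok], pmax(pmin(th[ok], 180 - 1e-9), 1e-9),
                               params$L_mm)
  out[ok] <- params$ref_dose_rate * gq / g0 * gl * Fv
  out
}

# bilinear interpolation of the F table, mirroring theta about 90 deg and
# extending missing near-axis values from the nearest defined angle
.interp_F <- function(F_table, r_mm, theta_deg) {
  thg <- as.numeric(rownames(F_table))
  rg <- as.numeric(colnames(F_table))
  th <- ifelse(theta_deg > 90, 180 - theta_deg, theta_deg)
  vapply(seq_along(r_mm), function(i) {
    col <- pmin(pmax(r_mm[i], rg[1]), rg[length(rg)])
    jc <- findInterval(col, rg, rightmost.closed = TRUE)
    jc <- min(jc, length(rg) - 1)
    wr <- (col - rg[jc]) / (rg[jc + 1] - rg[jc])
    f1 <- .interp_F_col(F_table[, jc], thg, th[i])
    f2 <- .interp_F_col(F_table[, jc + 1], thg, th[i])
    (1 - wr) * f1 + wr * f2
  }, numeric(1))
}

.interp_F_col <- function(col, thg, th) {
  ok <- !is.na(col)
  if (!any(ok)) return(NA_real_)
  if (th <= min(thg[ok])) return(col[ok][which.min(thg[ok])])
  stats::approx(thg[ok], col[ok], th, rule = 2, ties = "ordered")$y
}

#' Serialize a TG-60 parameter set to JSON
#'
#' @param params A [tg60_parameter_set()].
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
tg60_to_json <- function(params, path = NULL) {
  payload <- list(
    ref_dose_rate_cgy_h_uci = params$ref_dose_rate,
    L_mm = params$L_mm,
    gL = params$gl_table,
    F = list(theta_deg = as.numeric(rownames(params$F_table)),
             r_mm = as.numeric(colnames(params$F_table)),
             values = unname(apply(params$F_table, 1, as.numeric, simplify = FALSE))),
    phi_an = params$phi_an,
    fit = list(coefficients = as.list(params$fit$coefficients), R = params$fit$R)
  )
  js <- jsonlite::toJSON(payload, na = "null", digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
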