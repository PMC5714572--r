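#' Load a packaged reference table
#'
#' The printed tables the package is validated against, transcribed as
#' plain CSV with a YAML sidecar carrying units and provenance. Blank
#' cells of the anisotropy table (points inside or behind the seed) are
#' read as missing values.
#'
#' @param name One of `"table1_nuclides"`, `"table2_activation"`,
#'   `"table3_composition"`, `"table4_radial_dose_rate"`,
#'   `"table5_reference_dose_rate"`, `"table6_gL"`, `"table7_F"`,
#'   `"table7_phi_an"`, `"eq1_coefficients"`.
#' @return Object of class `reference_table`: list with `name`, `data`
#'   (data frame), `units` and `provenance`.
#' @export
#' @examples
#' load_reference_table("table5_reference_dose_rate")$data
load_reference_table <- function(name) {
  meta <- yaml::read_yaml(.extdata("tables.yaml"))
  known <- names(meta)
  if (!name %in% known) {
    stop("unknown reference table '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  df <- utils::read.csv(.extdata(paste0(name, ".csv")),
                        stringsAsFactors = FALSE)
  structure(list(name = name, data = df,
                 units = meta[[name]]$units,
                 provenance = meta[[name]]$provenance,
                 notes = meta[[name]]$notes),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("<reference table %s>  %d x %d\n", x$name,
              nrow(x$data), ncol(x$data)))
  if (!is.null(x$provenance)) cat(" ", x$provenance, "\n")
  print(utils::head(x$data, 4))
  if (nrow(x$data) > 4) cat("  ...\n")
  invisible(x)
}

#' Compare a computed table against a reference
#'
#' Aligns the two tables on a key column and reports per-cell absolute
#' and relative deviations with pass/fail flags against a tolerance.
#'
#' @param computed,reference Data frames sharing the key column and a
#'   value column, or a `reference_table` for `reference`.
#' @param value_col Name of the value column in each (length 1 or 2).
#' @param key Key column name (default the first column of `computed`).
#' @param tolerance Tolerance for the pass flag.
#' @param relative Compare relative (default) or absolute deviations.
#' @return Object of class `reference_comparison`: the per-row table plus
#'   summary statistics (`max_abs`, `max_rel`, `n_fail`, `pass`).
#' @export
compare_to_reference <- function(computed, reference, value_col,
                                 key = names(computed)[1],
                                 tolerance = 0.01, relative = TRUE) {
  if (inherits(reference, "reference_table")) reference <- reference$data
  vc <- rep_len(value_col, 2)
  if (!key %in% names(reference)) {
    stop("key column '", key, "' missing from the reference", call. = FALSE)
  }
  m <- match(computed[[key]], reference[[key]])
  if (anyNA(m)) {
    stop("keys not found in reference: ",
         paste(utils::head(computed[[key]][is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  ref <- reference[[vc[2]]][m]
  val <- computed[[vc[1]]]
  dev <- val - ref
  rel <- ifelse(ref != 0, dev / ref, NA_real_)
  crit <- if (relative) abs(rel) else abs(dev)
  tab <- data.frame(key = computed[[key]], computed = val, reference = ref,
                    deviation = dev, relative = rel,
                    pass = crit <= tolerance)
  names(tab)[1] <- key
  structure(list(table = tab,
                 max_abs = max(abs(dev)),
                 max_rel = max(abs(rel), na.rm = TRUE),
                 n_fail = sum(!tab$pass, na.rm = TRUE),
                 pass = all(tab$pass, na.rm = TRUE),
                 tolerance = tolerance, relative = relative),
            class = "reference_comparison")
}

#' @export
print.reference_comparison <- function(x, ...) {
  cat(sprintf("<comparison>  %s at %s tolerance %g: max |dev| = %.3g, max rel = %.3g, %d failing\n",
              if (x$pass) "PASS" else "FAIL",
              if (x$relative) "relative" else "absolute",
              x$tolerance, x$max_abs, x$max_rel, x$n_fail))
  invisible(x)
}

#' Persist a dose grid as CSV plus JSON metadata
#'
#' Long-format CSV (`r_mm`, `theta_deg`, `dose`, `rel_unc`) with a JSON
#' sidecar recording the seed geometry, history count and RNG seed.
#'
#' @param grid_obj A `dose_grid`.
#' @param path CSV path; metadata goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid_obj, path) {
  g <- grid_obj$grid
  rmid <- (seq_len(g$n_r) - 0.5) * g$shell_mm
  thmid <- (seq_len(g$n_theta) - 0.5) * g$aperture_deg
  df <- data.frame(
    r_mm = rep(rmid, times = g$n_theta),
    theta_deg = rep(thmid, each = g$n_r),
    dose = as.vector(grid_obj$dose_cgy_uci_h),
    rel_unc = as.vector(grid_obj$rel_unc)
  )
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(nuclide = grid_obj$nuclide,
               seed_length_mm = grid_obj$seed$length_mm,
               seed_diameter_mm = grid_obj$seed$diameter_mm,
               seed_density_g_cm3 = grid_obj$seed$density_g_cm3,
               shell_mm = g$shell_mm, aperture_deg = g$aperture_deg,
               r_max_mm = g$r_max_mm,
               n_histories = grid_obj$n_histories,
               n_batches = grid_obj$n_batches,
               rng_seed = as.integer(grid_obj$rng_seed),
               rho_eff = grid_obj$rho_eff,
               dose_units = "cGy/h per uCi contained activity")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
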