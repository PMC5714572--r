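# Shared, lazily built fixtures. The full-statistics simulation is built
# once and reused by the engine, TG-60 and acceptance tests.
.fx <- new.env(parent = emptyenv())

shared_spectrum <- function() {
  if (is.null(.fx$sp)) .fx$sp <- beta_spectrum("90Y")
  .fx$sp
}

shared_kernel <- function() {
  if (is.null(.fx$kern)) .fx$kern <- point_kernel(shared_spectrum())
  .fx$kern
}

# 1e6-history run of the YAS seed under the study conditions
shared_sim <- function() {
  if (is.null(.fx$sim)) {
    .fx$sim <- simulate_seed_dose(yas_seed(), shared_spectrum(),
                                  n_histories = 1e6, rng_seed = 20130906,
                                  kernel = shared_kernel())
  }
  .fx$sim
}

# quick run for shape-insensitive checks
small_sim <- function(n = 1e5, rng_seed = 42) {
  simulate_seed_dose(yas_seed(), shared_spectrum(), n_histories = n,
                     rng_seed = rng_seed, kernel = shared_kernel())
}

# a synthetic spherically symmetric dose grid (no seed shadow), for
# isotropy-driven checks
synthetic_grid <- function(profile = function(r) exp(-r), r_max = 12) {
  g <- grid_spec(r_max_mm = r_max)
  rmid <- (seq_len(g$n_r) - 0.5) * g$shell_mm
  dose <- matrix(rep(profile(rmid), g$n_theta), g$n_r, g$n_theta)
  structure(list(grid = g, seed = yas_seed(), nuclide = "synthetic",
                 dose_cgy_uci_h = dose,
                 rel_unc = matrix(1e-4, g$n_r, g$n_theta),
                 seed_mask = matrix(0L, g$n_r, g$n_theta),
                 n_histories = NA, rng_seed = NA, n_batches = NA),
            class = "dose_grid")
}

# brute-force line-source geometry function: numerical integral of
# 1/d^2 along the active line, independent of the closed form
gl_brute_force <- function(r_mm, theta_deg, L_mm = 4.5, n = 4000) {
  th <- theta_deg * pi / 180
  y <- r_mm * sin(th)
  z <- r_mm * cos(th)
  t <- seq(-L_mm / 2, L_mm / 2, length.out = n + 1)
  f <- 1 / (y^2 + (z - t)^2)
  pracma::trapz(t, f) / L_mm
}
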