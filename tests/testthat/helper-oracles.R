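# Independent oracles used across the suite. Everything here is written
# directly from the mass-action reaction scheme, deliberately not through the
# package's own rate or equilibrium functions.

# Integrate the two binding reactions P + T <-> PT, P + D <-> PD to (near)
# steady state from a fully dissociated start. Rates hand-written.
kinetic_equilibrium_oracle <- function(T_tot, D_tot, P_tot, K_T, K_D,
                                       k_on = 1e8, t_end = 50) {
  konT <- k_on * 1e-6
  konD <- k_on * 1e-6
  koffT <- if (K_T > 0) k_on / K_T else 0
  koffD <- if (K_D > 0) k_on / K_D else 0
  if (K_T == 0) konT <- 0
  if (K_D == 0) konD <- 0
  rhs <- function(t, y, p) {
    vT <- konT * y[3] * y[1] - koffT * y[4]
    vD <- konD * y[3] * y[2] - koffD * y[5]
    list(c(-vT, -vD, -vT - vD, vT, vD))
  }
  y0 <- c(T_tot, D_tot, P_tot, 0, 0)
  out <- deSolve::lsoda(y0, c(0, t_end), rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-12)
  stats::setNames(out[nrow(out), -1], c("T", "D", "P", "PT", "PD"))
}

# Hand-written mass-action net rates for one species vector.
binding_rates_oracle <- function(s, konT, koffT, konD, koffD) {
  vT <- konT * s[["P"]] * s[["T"]] - koffT * s[["PT"]]
  vD <- konD * s[["P"]] * s[["D"]] - koffD * s[["PD"]]
  c(T = -vT, D = -vD, P = -vT - vD, PT = vT, PD = vD)
}

# Small, fast scenario used by structural session tests: coarse grids and a
# weakly bound, short-half-life tracer-like drug so sessions integrate in
# well under a second.
quick_scenario <- function(with_infusion = FALSE, K_A = 5e3,
                           initial_conc = 50, n_tube = 6, n_dz = 16) {
  tox <- drug_params("toxquick", mw = 250, site = "SudlowI", K_A = K_A,
                     t_half_total = 10 * 60,
                     therapeutic_range = c(5, 15), lambda_free = 1e-3,
                     calibration_peak = initial_conc)
  inf <- if (with_infusion) {
    comp <- drug_params("compquick", mw = 200, site = "SudlowI",
                        K_A = 1.9e5, t_half_total = 20,
                        lambda_free = 0.05, calibration_peak = 20)
    infusion_spec(comp, dose = 1000, diluent_volume = 400)
  }
  scenario(tox, initial_conc = initial_conc, infusion = inf,
           n_tube = n_tube, n_dz = n_dz)
}
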