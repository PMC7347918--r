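#' Peclet correction factor for transmembrane diffusion
#'
#' In the presence of ultrafiltration, the diffusive solute exchange across
#' the membrane is attenuated by the factor `Pe / (exp(Pe) - 1)`, where the
#' Peclet number `Pe` is the ratio of convective to diffusive transmembrane
#' mass-transfer rates. The removable singularity at `Pe = 0` evaluates to 1
#' (series expansion below |Pe| < 1e-6).
#'
#' @param Pe Peclet number (any real value; vectorised).
#' @return The dimensionless multiplier.
#' @examples
#' peclet_factor(0)  # 1
#' peclet_factor(1)  # 1 / (e - 1)
#' @export
peclet_factor <- function(Pe) {
  out <- numeric(length(Pe))
  small <- abs(Pe) < 1e-6
  out[small] <- 1 - Pe[small] / 2 + Pe[small]^2 / 12
  out[!small] <- Pe[!small] / (exp(Pe[!small]) - 1)
  out
}

#' Closed-form counter-current dialyzer clearance
#'
#' Steady-state clearance of a freely diffusing solute in an ideal
#' counter-current exchanger:
#' `K = Q_p (exp(theta) - 1) / (exp(theta) - Q_p/Q_d)` with
#' `theta = KoA (1/Q_p - 1/Q_d)`. Used as the independent oracle against
#' which the discretized dialyzer model is validated; the equal-flow limit
#' `Q_p = Q_d` reduces to `K = KoA Q_p / (KoA + Q_p)`.
#'
#' @param KoA Overall mass-transfer-area coefficient, mL/min.
#' @param Q_p,Q_d Plasma and dialysate flow rates, mL/min.
#' @return Clearance, mL/min.
#' @export
closed_form_clearance <- function(KoA, Q_p, Q_d) {
  stopifnot(KoA >= 0, Q_p > 0, Q_d > 0)
  if (KoA == 0) return(0)
  theta <- KoA * (1 / Q_p - 1 / Q_d)
  if (abs(theta) < 1e-10) return(KoA * Q_p / (KoA + Q_p))
  # flow-limited asymptotes before exp() overflows
  if (theta > 500) return(Q_p)
  if (theta < -500) return(Q_d)
  Q_p * (exp(theta) - 1) / (exp(theta) - Q_p / Q_d)
}

#' Flow-weighted mixing at the infusion port
#'
#' Boundary concentrations at the head of the arterial tube segment:
#' `C(0) = (Q_pl C_pl + Q_D C_inf) / (Q_pl + Q_D)`. The infusion stream
#' contains only free competitor drug, so every other species is simply
#' diluted.
#'
#' @param C_pl Plasma species vector entering the circuit, uM.
#' @param infusion An [infusion_spec()], or `NULL` (then `Q_D` must be 0).
#' @param Q_pl Plasma flow rate, mL/min.
#' @param Q_D Infusion rate, mL/min (diluent volume / session duration).
#' @return Boundary species vector, uM.
#' @export
tube_inlet_mixing <- function(C_pl, infusion, Q_pl, Q_D) {
  stopifnot(Q_pl > 0, Q_D >= 0)
  if (Q_D == 0) return(C_pl)
  if (is.null(infusion)) stop("Q_D > 0 requires an infusion spec")
  C_inf <- c(0, infusion$C_inf, 0, 0, 0)
  out <- (Q_pl * unname(C_pl) + Q_D * C_inf) / (Q_pl + Q_D)
  stats::setNames(out, .species_names)
}

#' Axial flow profiles in the dialyzer
#'
#' The volume infused upstream is ultrafiltered uniformly along the fiber:
#' the plasma-side flow decreases linearly from `Q_pl + Q_D` at the blood
#' inlet to `Q_pl` at the outlet, while the counter-current dialysate flow
#' picks the filtrate up, growing from `Q_di` at its inlet (x = L) to
#' `Q_di + Q_D` at its outlet (x = 0).
#'
#' @param Q_pl Plasma flow from the patient, mL/min.
#' @param Q_di Fresh dialysate inflow, mL/min.
#' @param Q_D Infusion (= ultrafiltration) rate, mL/min.
#' @param n_dz Number of axial grid cells.
#' @return A list of class `hd_flow_profile` with face flows `Qp_face` and
#'   `Qd_face` (length `n_dz + 1`, mL/min) and `Q_tube`.
#' @export
flow_profile <- function(Q_pl, Q_di, Q_D = 0, n_dz = 64) {
  stopifnot(Q_pl > 0, Q_di > 0, Q_D >= 0, n_dz >= 2)
  xi <- (0:n_dz) / n_dz
  structure(list(
    Q_tube = Q_pl + Q_D,
    Qp_face = Q_pl + Q_D - xi * Q_D,
    Qd_face = Q_di + (1 - xi) * Q_D,
    Q_D = Q_D, Q_di = Q_di, Q_pl = Q_pl, n_dz = n_dz
  ), class = "hd_flow_profile")
}

#' Zero-initialised extracorporeal field state
#'
#' Spatially discretised species concentrations along the arterial tube
#' segment and along both sides of the dialyzer. Fields start empty
#' (saline-primed circuit) and fill from the patient within the first
#' circuit transit.
#'
#' @param n_tube,n_dz Grid cells for the tube segment and the dialyzer.
#' @return A list of class `hd_field_state` with matrices `tube`
#'   (`n_tube x 5`), `dz_plasma` and `dz_dialysate` (`n_dz x 5`), uM.
#' @export
field_state <- function(n_tube = 16, n_dz = 64) {
  z <- function(n) matrix(0, n, 5, dimnames = list(NULL, .species_names))
  structure(list(tube = z(n_tube), dz_plasma = z(n_dz),
                 dz_dialysate = z(n_dz)),
            class = "hd_field_state")
}

# Precomputed constants for the extracorporeal right-hand side. Flows in
# mL/min, cell volumes in mL, concentrations uM.
.extracorporeal_consts <- function(dialyzer, tube, Q_pl, Q_di, Q_D,
                                   n_tube, n_dz, toxic, competitor,
                                   C_inf = 0) {
  kT <- .kinetic_constants(toxic)
  kD <- .kinetic_constants(competitor)
  sigma <- c(dialyzer$sigma_free, dialyzer$sigma_free,
             rep(dialyzer$sigma_protein, 3))
  KoA <- c(dialyzer$KoA_free, dialyzer$KoA_free, 0, 0, 0)
  # segment Peclet number: per-cell ultrafiltration over per-cell KoA
  Pe <- ifelse(KoA > 0, Q_D * (1 - sigma) / KoA, 0)
  pef <- peclet_factor(Pe)
  flows <- flow_profile(Q_pl, Q_di, Q_D, n_dz)
  v_t <- tube$cross_section * tube$length / n_tube
  v_p <- dialyzer$n_fibers * dialyzer$area_lumen * dialyzer$fiber_length / n_dz
  v_d <- dialyzer$n_fibers * dialyzer$area_dialysate *
    dialyzer$fiber_length / n_dz
  expand <- function(v, n) matrix(v, n, 5, byrow = TRUE)
  list(
    n_t = n_tube, n_d = n_dz,
    konT = kT$kon, koffT = kT$koff, konD = kD$kon, koffD = kD$koff,
    Q_tube = flows$Q_tube, Q_pl = Q_pl, Q_D = Q_D,
    Qpf_in = flows$Qp_face[1:n_dz], Qpf_out = flows$Qp_face[2:(n_dz + 1)],
    Qdf_in = flows$Qd_face[2:(n_dz + 1)], Qdf_out = flows$Qd_face[1:n_dz],
    Qd_exit = flows$Qd_face[1],
    v_t = v_t, v_p = v_p, v_d = v_d,
    conv_p = expand(Q_D / n_dz * (1 - sigma) / v_p, n_dz),
    diff_p = expand(pef * KoA / n_dz / v_p, n_dz),
    conv_d = expand(Q_D / n_dz * (1 - sigma) / v_d, n_dz),
    diff_d = expand(pef * KoA / n_dz / v_d, n_dz),
    C_inf_vec = c(0, C_inf, 0, 0, 0)
  )
}

# Derivatives of all extracorporeal fields given the tube inlet boundary
# concentration `bc` (numeric 5). Returns the field derivatives, the
# dialysate outlet mass flux (umol/min per species) and the blood-side
# return concentration.
.field_deriv <- function(Tb, Cp, Cd, bc, cc) {
  rTb <- .binding_rates_mat(Tb, cc$konT, cc$koffT, cc$konD, cc$koffD)
  up_t <- rbind(bc, Tb[-cc$n_t, , drop = FALSE], deparse.level = 0)
  dTb <- cc$Q_tube * (up_t - Tb) / cc$v_t + rTb

  rCp <- .binding_rates_mat(Cp, cc$konT, cc$koffT, cc$konD, cc$koffD)
  rCd <- .binding_rates_mat(Cd, cc$konT, cc$koffT, cc$konD, cc$koffD)
  up_p <- rbind(Tb[cc$n_t, ], Cp[-cc$n_d, , drop = FALSE],
                deparse.level = 0)
  gradd <- Cp - Cd
  dCp <- (cc$Qpf_in * up_p - cc$Qpf_out * Cp) / cc$v_p -
    cc$conv_p * Cp - cc$diff_p * gradd + rCp
  down_d <- rbind(Cd[-1L, , drop = FALSE], rep(0, 5), deparse.level = 0)
  dCd <- (cc$Qdf_in * down_d - cc$Qdf_out * Cd) / cc$v_d +
    cc$conv_d * Cp + cc$diff_d * gradd + rCd

  list(dTb = dTb, dCp = dCp, dCd = dCd,
       out_flux = cc$Qd_exit * Cd[1L, ] / 1000, # umol/min
       C_out = Cp[cc$n_d, ])
}

#' Tube-segment right-hand side
#'
#' First-order upwind advection of all five species along the arterial
#' segment plus mass-action binding in every cell; axial diffusion is
#' neglected. The inlet boundary comes from [tube_inlet_mixing()].
#'
#' @param field An `hd_field_state` (only `$tube` is used).
#' @param inlet Boundary species vector at x = 0, uM.
#' @param Q_tube Tube flow rate `Q_pl + Q_D`, mL/min.
#' @param tube A [tube_params()].
#' @param toxic,competitor [drug_params()] objects.
#' @return Matrix of time derivatives, uM/min, same shape as `field$tube`.
#' @export
tube_rhs <- function(field, inlet, Q_tube, tube, toxic, competitor = NULL) {
  Tb <- field$tube
  n_t <- nrow(Tb)
  kT <- .kinetic_constants(toxic)
  kD <- .kinetic_constants(competitor)
  v_t <- tube$cross_section * tube$length / n_t
  up <- rbind(unname(inlet), Tb[-n_t, , drop = FALSE], deparse.level = 0)
  Q_tube * (up - Tb) / v_t +
    .binding_rates_mat(Tb, kT$kon, kT$koff, kD$kon, kD$koff)
}

#' Dialyzer right-hand side
#'
#' Counter-current method-of-lines model of one representative fiber scaled
#' to the full bundle: plasma-side upwind advection with the linearly
#' decreasing flow, convective transmembrane transport
#' `(1 - sigma) dQ_p/dx C_p`, Peclet-corrected diffusive exchange
#' `KoA (C_p - C_d)` (free solutes only; KoA = 0 for albumin and its
#' complexes), binding reactions in every cell, and the mirrored dialysate
#' balance. The dialysate enters solute-free at x = L (single pass).
#'
#' @param field An `hd_field_state` (`$dz_plasma`, `$dz_dialysate`).
#' @param flows A [flow_profile()] with `n_dz` matching the field.
#' @param dialyzer A [dialyzer_params()].
#' @param toxic,competitor [drug_params()] objects.
#' @param inlet Blood-side inlet species vector (tube outlet), uM.
#' @param tube A [tube_params()] (only used for consistency of the shared
#'   constant bundle).
#' @return A list with derivative matrices `dz_plasma` and `dz_dialysate`
#'   (uM/min), the dialysate outlet mass flux `out_flux` (umol/min per
#'   species) and the blood return concentrations `C_out` (uM).
#' @export
dialyzer_rhs <- function(field, flows, dialyzer, toxic, competitor = NULL,
                         inlet, tube = tube_params()) {
  n_dz <- nrow(field$dz_plasma)
  stopifnot(flows$n_dz == n_dz)
  cc <- .extracorporeal_consts(dialyzer, tube, flows$Q_pl, flows$Q_di,
                               flows$Q_D, n_tube = 2, n_dz = n_dz,
                               toxic = toxic, competitor = competitor)
  # reuse the field derivative with a 2-cell tube held at the inlet value
  Tb <- rbind(unname(inlet), unname(inlet), deparse.level = 0)
  d <- .field_deriv(Tb, field$dz_plasma, field$dz_dialysate,
                    bc = unname(inlet), cc = cc)
  list(dz_plasma = d$dCp, dz_dialysate = d$dCd, out_flux = d$out_flux,
       C_out = d$C_out)
}

#' Simulated steady-state dialyzer clearance of an unbound tracer
#'
#' Runs the discretized tube + dialyzer model with a fixed blood-side inlet
#' concentration of a non-binding, non-reacting tracer until steady state
#' and returns the clearance `removal rate / inlet concentration`. Serves
#' as the numerical counterpart of [closed_form_clearance()].
#'
#' @param KoA Membrane mass-transfer coefficient, mL/min.
#' @param Q_p,Q_d Plasma and dialysate flow rates, mL/min.
#' @param Q_D Ultrafiltration (infusion) rate, mL/min.
#' @param n_dz Dialyzer grid cells.
#' @param dialyzer,tube Geometry parameter objects; KoA overrides the
#'   dialyzer's value.
#' @param settle Integration time allowed to reach steady state, minutes.
#' @return Clearance, mL/min.
#' @export
dialyzer_clearance <- function(KoA = 800, Q_p = 162.5, Q_d = 500, Q_D = 0,
                               n_dz = 64, dialyzer = dialyzer_params(),
                               tube = tube_params(), settle = 15) {
  dialyzer$KoA_free <- KoA
  tracer <- drug_params("tracer", mw = 100, K_A = 0, t_half_total = 1,
                        lambda_free = 0)
  cc <- .extracorporeal_consts(dialyzer, tube, Q_p, Q_d, Q_D,
                               n_tube = 4, n_dz = n_dz, toxic = tracer,
                               competitor = NULL)
  C_in <- 100
  bc <- c(C_in, 0, 0, 0, 0)
  nt <- 4L
  y0 <- numeric((nt + 2 * n_dz) * 5)
  deriv <- function(t, y, parms) {
    Tb <- matrix(y[1:(nt * 5)], nt, 5)
    Cp <- matrix(y[nt * 5 + 1:(n_dz * 5)], n_dz, 5)
    Cd <- matrix(y[(nt + n_dz) * 5 + 1:(n_dz * 5)], n_dz, 5)
    d <- .field_deriv(Tb, Cp, Cd, bc, cc)
    list(c(d$dTb, d$dCp, d$dCd))
  }
  out <- deSolve::lsodes(y0, c(0, settle), deriv, parms = NULL,
                         rtol = 1e-10, atol = 1e-10, maxsteps = 100000)
  .check_solver(out, c(0, settle))
  yT <- out[nrow(out), -1]
  Cd1 <- yT[(nt + n_dz) * 5 + 1]
  Cp_out <- yT[nt * 5 + n_dz]
  # removal = dialysate outlet + net ultrafiltrate carried out of plasma
  removal <- cc$Qd_exit * Cd1 # (uM * mL/min) / 1000 umol/min; ratio cancels
  removal / C_in
}
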