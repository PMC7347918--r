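#' Three-compartment patient state
#'
#' Plasma and interstitial pools carry all five species (free toxic drug,
#' free competitor, free albumin, and the two complexes); the intracellular
#' pool has no binding protein and therefore carries free drug only.
#'
#' @param plasma,interstitial Species vectors ([species_vector()]), uM.
#' @param intracellular Named numeric `c(T = , D = )`, uM.
#' @return An object of class `hd_patient_state`.
#' @export
patient_state <- function(plasma = species_vector(),
                          interstitial = species_vector(),
                          intracellular = c(T = 0, D = 0)) {
  stopifnot(all(intracellular >= 0), length(intracellular) == 2L)
  structure(list(plasma = plasma, interstitial = interstitial,
                 intracellular = c(T = unname(intracellular[1]),
                                   D = unname(intracellular[2]))),
            class = "hd_patient_state")
}

# flat packing order used by all integrators:
# [T,D,P,PT,PD]_pl, [T,D,P,PT,PD]_is, [T,D]_ic  (12 states, uM)
.pack_patient <- function(st) {
  c(unname(st$plasma), unname(st$interstitial), unname(st$intracellular))
}

.unpack_patient <- function(y) {
  patient_state(
    plasma = species_vector(y[1], y[2], y[3], y[4], y[5]),
    interstitial = species_vector(y[6], y[7], y[8], y[9], y[10]),
    intracellular = c(T = y[11], D = y[12])
  )
}

#' Extracorporeal exchange terms for the patient model
#'
#' Describes the flow leaving the patient for the extracorporeal circuit and
#' the post-dialyzer return concentrations. When inactive (no dialysis) all
#' exchange terms vanish.
#'
#' @param Q_pl Plasma flow rate, mL/min.
#' @param C_out Return (post-dialyzer) concentrations, a species vector, uM.
#' @param active Logical flag.
#' @return An object of class `hd_exchange`.
#' @export
external_exchange <- function(Q_pl, C_out = species_vector(), active = TRUE) {
  structure(list(Q_pl = Q_pl, C_out = C_out, active = active),
            class = "hd_exchange")
}

#' @rdname external_exchange
#' @export
exchange_none <- function() external_exchange(Q_pl = 0, active = FALSE)

# Parameter bundle shared by every right-hand side. Rates in 1/min, kon in
# 1/(uM min), flows in L/min, volumes in L.
.kin_bundle <- function(patient, toxic, competitor) {
  kT <- .kinetic_constants(toxic)
  kD <- .kinetic_constants(competitor)
  lamT <- toxic$lambda_free
  lamD <- if (is.null(competitor)) 0 else competitor$lambda_free
  if (is.na(lamT)) stop("toxic drug has no calibrated lambda_free; run ",
                        "calibrate_free_half_life() first or set it to 0")
  if (is.na(lamD)) stop("competitor drug has no calibrated lambda_free")
  list(konT = kT$kon, koffT = kT$koff, konD = kD$kon, koffD = kD$koff,
       lamT = lamT, lamD = lamD,
       Kip = patient$K_ip / 1000, Kic = patient$K_ic / 1000,
       Vpl = patient$V_pl, Vis = patient$V_is, Vic = patient$V_ic)
}

# Core patient derivative on the flat 12-vector. `exch` is NULL or
# list(Qpl = L/min, C_out = numeric(5)). Returns list(dy = numeric(12),
# elim = c(T, D) umol/min) so callers can integrate cumulative elimination.
.patient_deriv <- function(y, p, exch = NULL) {
  pl <- y[1:5]; is_ <- y[6:10]; ic <- y[11:12]
  rpl <- {
    rT <- -p$konT * pl[3] * pl[1] + p$koffT * pl[4]
    rD <- -p$konD * pl[3] * pl[2] + p$koffD * pl[5]
    c(rT, rD, rT + rD, -rT, -rD)
  }
  ris <- {
    rT <- -p$konT * is_[3] * is_[1] + p$koffT * is_[4]
    rD <- -p$konD * is_[3] * is_[2] + p$koffD * is_[5]
    c(rT, rD, rT + rD, -rT, -rD)
  }
  free <- c(1, 1, 0, 0, 0)  # (1 - indicator) gate: exchange/elimination
  dpl <- free * p$Kip * (is_ - pl) / p$Vpl + rpl -
    free * c(p$lamT, p$lamD, 0, 0, 0) * pl
  if (!is.null(exch)) {
    dpl <- dpl + exch$Qpl * (exch$C_out - pl) / p$Vpl
  }
  dis <- (-free * p$Kip * (is_ - pl) +
            free * p$Kic * (c(ic, 0, 0, 0) - is_)) / p$Vis + ris
  dic <- -p$Kic * (ic - is_[1:2]) / p$Vic
  list(dy = c(dpl, dis, dic),
       elim = c(p$lamT * pl[1], p$lamD * pl[2]) * p$Vpl)
}

#' Patient model right-hand side
#'
#' Time derivative of the three-compartment patient state: plasma exchanges
#' with the extracorporeal circuit (all species travel with the flow) and
#' with the interstitium (free drugs only, coefficient `K_ip`); the
#' interstitium exchanges free drug with the intracellular pool (`K_ic`);
#' mass-action binding runs in both albumin-containing pools; first-order
#' elimination removes free drug from plasma at rate `lambda_free`.
#' Compartment volumes are constant.
#'
#' @param state An `hd_patient_state`.
#' @param exchange An [external_exchange()]; use [exchange_none()] off
#'   dialysis.
#' @param patient A [patient_params()].
#' @param toxic,competitor [drug_params()] objects (competitor may be
#'   `NULL`).
#' @return An `hd_patient_state`-shaped list of derivatives, uM/min.
#' @export
patient_rhs <- function(state, exchange, patient, toxic, competitor = NULL) {
  p <- .kin_bundle(patient, toxic, competitor)
  exch <- if (exchange$active) {
    list(Qpl = exchange$Q_pl / 1000, C_out = unname(exchange$C_out))
  }
  d <- .patient_deriv(.pack_patient(state), p, exch)$dy
  structure(list(
    plasma = stats::setNames(d[1:5], .species_names),
    interstitial = stats::setNames(d[6:10], .species_names),
    intracellular = c(T = d[11], D = d[12])
  ), class = "hd_patient_state_deriv")
}

#' Equilibrated patient initialization
#'
#' At the peak, drug is assumed equilibrated across plasma, interstitial and
#' intracellular pools: the free concentration is equal everywhere, each
#' albumin-containing pool sits at binding equilibrium with its own albumin
#' level, and total plasma concentration equals the requested serum value.
#' Because the plasma totals are prescribed, the state follows in closed
#' form: the plasma competitive equilibrium fixes the free levels and the
#' other pools are slaved to them.
#'
#' @param conc_toxic Total serum (plasma) concentration of the toxic drug,
#'   mg/L.
#' @param conc_competitor Total serum concentration of the competitor, mg/L.
#' @param patient A [patient_params()].
#' @param toxic,competitor [drug_params()] objects.
#' @return An `hd_patient_state`.
#' @examples
#' st <- initialize_equilibrated(70, patient = patient_params(),
#'                               toxic = drug_phenytoin())
#' # plasma bound fraction ~0.86
#' st$plasma[["PT"]] / (st$plasma[["T"]] + st$plasma[["PT"]])
#' @export
initialize_equilibrated <- function(conc_toxic, conc_competitor = 0,
                                    patient, toxic, competitor = NULL) {
  stopifnot(conc_toxic >= 0, conc_competitor >= 0)
  T_tot <- mgL_to_uM(conc_toxic, toxic$mw)
  D_tot <- if (conc_competitor > 0) {
    if (is.null(competitor)) stop("competitor concentration given without ",
                                  "competitor drug parameters")
    mgL_to_uM(conc_competitor, competitor$mw)
  } else 0
  K_D <- if (is.null(competitor)) 0 else competitor$K_A
  pl <- equilibrate_competitive(T_tot, D_tot, patient$albumin_plasma,
                                toxic$K_A, K_D)
  Tf <- pl[["T"]]; Df <- pl[["D"]]
  kT <- toxic$K_A * 1e-6
  kD <- K_D * 1e-6
  P_free_is <- patient$albumin_interstitial / (1 + kT * Tf + kD * Df)
  is_ <- species_vector(T_free = Tf, D_free = Df, P_free = P_free_is,
                        PT = kT * Tf * P_free_is, PD = kD * Df * P_free_is)
  patient_state(plasma = pl, interstitial = is_,
                intracellular = c(T = Tf, D = Df))
}

#' Simulate the patient off dialysis
#'
#' Stiff integration of the three-compartment model with the extracorporeal
#' exchange inactive; used for free half-life calibration and for the
#' post-dialytic rebound phase.
#'
#' @param state0 Initial `hd_patient_state`.
#' @param duration Simulated time, minutes.
#' @param patient A [patient_params()].
#' @param toxic,competitor [drug_params()] with finite `lambda_free`.
#' @param dt_out Output sampling interval, minutes (at most 1).
#' @param rtol,atol Solver tolerances (relative; absolute in uM).
#' @return An `hd_timecourse` tibble; the final patient state is attached as
#'   attribute `"final_state"`.
#' @export
simulate_patient_only <- function(state0, duration, patient, toxic,
                                  competitor = NULL, dt_out = 1,
                                  rtol = 1e-8, atol = 1e-10) {
  p <- .kin_bundle(patient, toxic, competitor)
  y0 <- c(.pack_patient(state0), 0, 0) # + cumulative eliminated (umol)
  deriv <- function(t, y, parms) {
    d <- .patient_deriv(y[1:12], p)
    list(c(d$dy, d$elim))
  }
  times <- seq(0, duration, by = min(dt_out, 1))
  if (times[length(times)] < duration) times <- c(times, duration)
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 100000)
  .check_solver(out, times)
  .assert_nonneg(out[, 2:13], "patient-only simulation")
  tc <- .patient_timecourse(out, toxic, competitor)
  attr(tc, "final_state") <- .unpack_patient(out[nrow(out), 2:13])
  tc
}

.check_solver <- function(out, times) {
  if (nrow(out) < length(times)) {
    stop("stiff solver failed at t = ", out[nrow(out), 1],
         " min (", attr(out, "istate")[1], "); see deSolve diagnostics")
  }
}

# tolerance-level negative excursions are a solver failure, not something to
# clip away silently
.assert_nonneg <- function(m, what, floor = -1e-7) {
  mn <- min(m)
  if (mn < floor) {
    stop("negative concentration (", format(mn), " uM) in ", what,
         "; tighten solver tolerances")
  }
}

# columns shared by every timecourse flavour
.patient_timecourse <- function(out, toxic, competitor) {
  cn <- c("time_min",
          paste0("pl_", .species_names, "_uM"),
          paste0("is_", .species_names, "_uM"),
          "ic_T_uM", "ic_D_uM", "cum_elim_T_umol", "cum_elim_D_umol")
  df <- tibble::as_tibble(as.data.frame(out[, seq_along(cn)]))
  names(df) <- cn
  .finish_timecourse(df, toxic, competitor)
}

.finish_timecourse <- function(df, toxic, competitor) {
  df$plasma_total_toxic_mgL <- uM_to_mgL(df$pl_T_uM + df$pl_PT_uM, toxic$mw)
  df$plasma_free_toxic_mgL <- uM_to_mgL(df$pl_T_uM, toxic$mw)
  df$cum_eliminated_toxic_mg <- df$cum_elim_T_umol * toxic$mw / 1000
  if (!is.null(competitor)) {
    df$plasma_total_comp_mgL <- uM_to_mgL(df$pl_D_uM + df$pl_PD_uM,
                                          competitor$mw)
    df$plasma_free_comp_mgL <- uM_to_mgL(df$pl_D_uM, competitor$mw)
    df$cum_eliminated_comp_mg <- df$cum_elim_D_umol * competitor$mw / 1000
  }
  class(df) <- c("hd_timecourse", class(df))
  df
}

#' Write a timecourse table to delimited text
#'
#' @param tc An `hd_timecourse` tibble.
#' @param path Output path; tab-separated with a header row.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.table(as.data.frame(tc), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
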