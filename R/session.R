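#' Simulate a full hemodialysis session
#'
#' Closed-loop integration of the coupled patient-tube-dialyzer system:
#' plasma leaves the patient at `Q_pl = Q_blood (1 - hematocrit)`, receives
#' the competitor infusion at the head of the arterial segment, traverses
#' the tube (advection + re-equilibration), passes the counter-current
#' dialyzer where free solute is removed by diffusion and convection, and
#' returns to the patient plasma pool. The infusion runs at the constant
#' rate `diluent_volume / duration`, so the full dose is delivered over the
#' session; the infused volume is ultrafiltered uniformly along the fiber
#' and the patient's compartment volumes stay constant. The extracorporeal
#' circuit starts solute-free (saline primed).
#'
#' The whole stiff system (binding kinetics with `k_on` around 1e8 1/(M min)
#' against hours-long patient dynamics) is integrated monolithically with a
#' sparse-Jacobian BDF solver.
#'
#' @param sc A validated `hd_scenario` with calibrated drugs.
#' @param duration Session length, minutes.
#' @param dt_out Output sampling interval, minutes (at most 1).
#' @param rtol,atol Solver tolerances (absolute tolerance in uM). The
#'   defaults are validated against a 100-fold tighter reference run in the
#'   test suite; the mass-balance audit provides an independent accuracy
#'   check at every output time.
#' @param engine `"compiled"` (default) evaluates the right-hand side in C;
#'   `"r"` uses the pure-R implementation. Both compute the same model and
#'   are cross-checked in the test suite.
#' @return An object of class `hd_session`: the timecourse tibble, the end
#'   patient state, cumulative dialysate removal and endogenous elimination
#'   (mg per drug), the extracorporeal holdup at session end, and the mass
#'   audit residuals.
#' @export
simulate_session <- function(sc, duration, dt_out = 1,
                             rtol = 1e-6, atol = 1e-6,
                             engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  validate_scenario(sc)
  n_t <- sc$n_tube
  n_d <- sc$n_dz
  competitor <- if (!is.null(sc$infusion)) sc$infusion$drug
  Q_pl <- sc$session$Q_blood * (1 - sc$patient$hematocrit)
  Q_D <- if (!is.null(sc$infusion)) sc$infusion$diluent_volume / duration
         else 0
  C_inf <- if (!is.null(sc$infusion)) sc$infusion$C_inf else 0
  cc <- .extracorporeal_consts(sc$dialyzer, sc$tube, Q_pl,
                               sc$session$Q_dialysate, Q_D, n_t, n_d,
                               sc$toxic, competitor, C_inf)
  pk <- .kin_bundle(sc$patient, sc$toxic, competitor)
  Qpl_L <- Q_pl / 1000

  st0 <- initialize_equilibrated(sc$initial_conc, patient = sc$patient,
                                 toxic = sc$toxic)
  i_pat <- 1:12
  i_tube <- 12 + 1:(n_t * 5)
  i_cp <- 12 + n_t * 5 + 1:(n_d * 5)
  i_cd <- 12 + (n_t + n_d) * 5 + 1:(n_d * 5)
  i_aux <- 12 + (n_t + 2 * n_d) * 5 + 1:7 # elim T, elim D, out x5 (umol)
  y0 <- c(.pack_patient(st0), numeric((n_t + 2 * n_d) * 5), numeric(7))

  times <- seq(0, duration, by = min(dt_out, 1))
  if (times[length(times)] < duration) times <- c(times, duration)
  if (engine == "compiled") {
    sigma <- c(sc$dialyzer$sigma_free, sc$dialyzer$sigma_free,
               rep(sc$dialyzer$sigma_protein, 3))
    KoA <- c(sc$dialyzer$KoA_free, sc$dialyzer$KoA_free, 0, 0, 0)
    pef <- peclet_factor(ifelse(KoA > 0, Q_D * (1 - sigma) / KoA, 0))
    pv <- c(n_t, n_d, pk$konT, pk$koffT, pk$konD, pk$koffD,
            pk$lamT, pk$lamD, pk$Kip, pk$Kic, pk$Vpl, pk$Vis, pk$Vic,
            Q_pl, cc$Q_tube, Q_D, sc$session$Q_dialysate,
            cc$v_t, cc$v_p, cc$v_d, C_inf, sigma, KoA, pef)
    out <- deSolve::lsodes(y0, times, func = "hdbind_derivs_session",
                           dllname = "hdbind",
                           initfunc = "hdbind_init_session", parms = pv,
                           rtol = rtol, atol = atol, maxsteps = 200000)
  } else {
    deriv <- function(t, y, parms) {
      pl <- y[1:5]
      bc <- (Q_pl * pl + Q_D * cc$C_inf_vec) / cc$Q_tube
      Tb <- matrix(y[i_tube], n_t, 5)
      Cp <- matrix(y[i_cp], n_d, 5)
      Cd <- matrix(y[i_cd], n_d, 5)
      fd <- .field_deriv(Tb, Cp, Cd, bc, cc)
      pd <- .patient_deriv(y[i_pat], pk,
                           exch = list(Qpl = Qpl_L, C_out = fd$C_out))
      list(c(pd$dy, fd$dTb, fd$dCp, fd$dCd, pd$elim, fd$out_flux))
    }
    out <- deSolve::lsodes(y0, times, deriv, parms = NULL, rtol = rtol,
                           atol = atol, maxsteps = 200000)
  }
  .check_solver(out, times)
  .assert_nonneg(out[, 1 + c(i_pat, i_tube, i_cp, i_cd)], "session")

  tc <- .patient_timecourse(out, sc$toxic, competitor)
  ycols <- out[, -1, drop = FALSE]
  # cumulative dialysate removal per drug entity (free + complexed), mg
  outT <- ycols[, i_aux[3]] + ycols[, i_aux[6]]
  tc$cum_removed_toxic_mg <- outT * sc$toxic$mw / 1000
  if (!is.null(competitor)) {
    outD <- ycols[, i_aux[4]] + ycols[, i_aux[7]]
    tc$cum_removed_comp_mg <- outD * competitor$mw / 1000
    tc$infused_comp_mg <- Q_D * C_inf * tc$time_min / 1000 *
      competitor$mw / 1000
  }

  audit <- .session_mass_audit(ycols, tc$time_min, sc, cc, competitor,
                               i_pat, i_tube, i_cp, i_cd, i_aux, Q_D, C_inf)
  tc$mass_residual_toxic <- audit$res_T
  end_state <- .unpack_patient(ycols[nrow(ycols), i_pat])

  free0 <- tc$pl_T_uM[1]
  cap_margin <- max(tc$pl_T_uM) / free0 - 1
  if (cap_margin > 1e-6) {
    warning("free toxic drug exceeded its initial plasma concentration by ",
            format(cap_margin * 100, digits = 3), "%")
  }

  n <- nrow(tc)
  structure(list(
    timecourse = tc, scenario = sc, duration = duration, Q_D = Q_D,
    end_state = end_state,
    removed_dialysate = c(toxic = unname(tc$cum_removed_toxic_mg[n]),
                          competitor = if (!is.null(competitor))
                            unname(tc$cum_removed_comp_mg[n]) else NA_real_),
    eliminated_endogenous = c(
      toxic = unname(tc$cum_eliminated_toxic_mg[n]),
      competitor = if (!is.null(competitor))
        unname(tc$cum_eliminated_comp_mg[n]) else NA_real_),
    holdup_mg = audit$holdup_mg,
    mass_residual = audit$max_residual,
    residuals = audit$residuals,
    free_cap_margin = cap_margin
  ), class = "hd_session")
}

# Relative mass-balance residuals per conserved entity (toxic drug,
# competitor drug, albumin): initial + infused must equal patient + circuit
# holdup + dialysate removal + endogenous elimination at every output time.
# `species` picks the state-vector species slots that carry the entity
# (drug T: free 1 + complex 4; drug D: 2 + 5; albumin: 3 + 4 + 5).
.session_mass_audit <- function(ycols, times, sc, cc, competitor,
                                i_pat, i_tube, i_cp, i_cd, i_aux, Q_D,
                                C_inf) {
  p <- sc$patient
  n_t <- sc$n_tube
  n_d <- sc$n_dz
  tmax <- nrow(ycols)
  field_mass <- function(idx, v_cell, species) {
    n <- length(idx) %/% 5L
    m <- 0
    for (s in species) {
      m <- m + rowSums(ycols[, idx[(s - 1L) * n + seq_len(n)],
                             drop = FALSE])
    }
    m * v_cell / 1000 # uM * mL -> umol (after /1000)
  }
  entity_mass <- function(species) {
    pat <- 0
    for (s in species) {
      pat <- pat + ycols[, i_pat[s]] * p$V_pl +
        ycols[, i_pat[5L + s]] * p$V_is +
        (if (s <= 2) ycols[, i_pat[10L + s]] * p$V_ic else 0)
    }
    pat + field_mass(i_tube, cc$v_t, species) +
      field_mass(i_cp, cc$v_p, species) +
      field_mass(i_cd, cc$v_d, species)
  }
  mass_T <- entity_mass(c(1L, 4L)) + ycols[, i_aux[1]] +
    ycols[, i_aux[3]] + ycols[, i_aux[6]]
  res_T <- abs(mass_T - mass_T[1]) / mass_T[1]
  residuals <- c(toxic = max(res_T))
  if (!is.null(competitor)) {
    infused_umol <- Q_D * C_inf / 1000 * times
    mass_D <- entity_mass(c(2L, 5L)) + ycols[, i_aux[2]] +
      ycols[, i_aux[4]] + ycols[, i_aux[7]] - infused_umol
    denom <- max(abs(mass_D[1]), max(infused_umol))
    res_D <- abs(mass_D - mass_D[1]) / denom
    residuals <- c(residuals, competitor = max(res_D))
  }
  mass_P <- entity_mass(c(3L, 4L, 5L)) + ycols[, i_aux[5]] +
    ycols[, i_aux[6]] + ycols[, i_aux[7]]
  res_P <- abs(mass_P - mass_P[1]) / mass_P[1]
  residuals <- c(residuals, albumin = max(res_P))
  holdup_T_umol <- (field_mass(i_tube, cc$v_t, c(1L, 4L)) +
                      field_mass(i_cp, cc$v_p, c(1L, 4L)) +
                      field_mass(i_cd, cc$v_d, c(1L, 4L)))[tmax]
  list(res_T = res_T, residuals = residuals,
       max_residual = max(residuals),
       holdup_mg = c(toxic = holdup_T_umol * sc$toxic$mw / 1000))
}

#' Post-dialytic rebound trajectory
#'
#' After the session ends, free drug redistributes from the interstitial and
#' intracellular pools back into plasma, transiently raising the total serum
#' concentration. Simulates the patient off dialysis (elimination active)
#' and reports the trajectory and its plasma peak.
#'
#' @param end_state Patient state at the end of the session.
#' @param horizon Observation window, minutes.
#' @param patient A [patient_params()].
#' @param toxic,competitor Calibrated [drug_params()] objects.
#' @return A list of class `hd_rebound`: `timecourse`, `peak_mgL` (maximum
#'   total plasma toxic-drug concentration over the horizon, including
#'   t = 0) and `t_peak_min`.
#' @export
rebound_trajectory <- function(end_state, horizon = 720, patient, toxic,
                               competitor = NULL) {
  tc <- simulate_patient_only(end_state, horizon, patient, toxic, competitor)
  i <- which.max(tc$plasma_total_toxic_mgL)
  structure(list(timecourse = tc,
                 peak_mgL = tc$plasma_total_toxic_mgL[i],
                 t_peak_min = tc$time_min[i]),
            class = "hd_rebound")
}

# One duration candidate: end concentration and rebound peak vs the MTC.
.try_duration <- function(sc, duration, mtc, competitor, ...) {
  ses <- simulate_session(sc, duration, ...)
  n <- nrow(ses$timecourse)
  end_conc <- ses$timecourse$plasma_total_toxic_mgL[n]
  reb <- rebound_trajectory(ses$end_state, sc$session$rebound_horizon,
                            sc$patient, sc$toxic, competitor)
  list(session = ses, rebound = reb, end_conc = end_conc,
       ok = end_conc <= mtc && reb$peak_mgL <= mtc)
}

#' Minimal treatment duration with rebound accounting
#'
#' Finds the smallest session length on a fixed time grid such that both the
#' end-of-session total plasma concentration and the post-dialytic rebound
#' peak stay at or below the maximum therapeutic concentration (MTC). The
#' lower bound of the therapeutic window is reported but not enforced
#' (ongoing elimination keeps the concentration falling after the rebound).
#' The infusion rate is recomputed for every candidate duration so the full
#' competitor dose is always delivered. The search brackets coarsely (60-min
#' strides) and then bisects on the 5-min grid; the pass/fail criterion is
#' monotone in duration, making the result deterministic.
#'
#' @param sc A calibrated `hd_scenario`.
#' @param step Duration grid, minutes.
#' @param coarse Coarse bracketing stride, minutes (multiple of `step`).
#' @param ... Passed to [simulate_session()].
#' @return An object of class `hd_min_duration`: `min_duration` (min, `NA`
#'   when censored at `max_duration`), `censored`, the passing `session` and
#'   its `rebound`, and a `trace` tibble of every duration evaluated.
#' @export
find_min_duration <- function(sc, step = 5, coarse = 60, ...) {
  validate_scenario(sc)
  mtc <- sc$toxic$therapeutic_range[2]
  if (!is.finite(mtc)) stop("toxic drug has no therapeutic maximum")
  competitor <- if (!is.null(sc$infusion)) sc$infusion$drug
  trace <- list()
  note <- function(d, r) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(
      duration_min = d, end_conc_mgL = r$end_conc,
      rebound_peak_mgL = r$rebound$peak_mgL, ok = r$ok)
  }
  best <- NULL
  # coarse upward bracketing
  lo <- 0 # duration 0 always fails (initial conc above MTC)
  hi <- NA
  d <- coarse
  while (d <= sc$session$max_duration) {
    r <- .try_duration(sc, d, mtc, competitor, ...)
    note(d, r)
    if (r$ok) { hi <- d; best <- r; break }
    lo <- d
    d <- d + coarse
  }
  if (is.na(hi)) {
    return(structure(list(min_duration = NA_real_, censored = TRUE,
                          session = NULL, rebound = NULL,
                          trace = dplyr::bind_rows(trace), step = step,
                          scenario = sc),
                     class = "hd_min_duration"))
  }
  while (hi - lo > step) {
    mid <- lo + step * floor((hi - lo) / (2 * step))
    mid <- max(lo + step, min(mid, hi - step))
    r <- .try_duration(sc, mid, mtc, competitor, ...)
    note(mid, r)
    if (r$ok) { hi <- mid; best <- r } else lo <- mid
  }
  structure(list(min_duration = hi, censored = FALSE,
                 session = best$session, rebound = best$rebound,
                 trace = dplyr::bind_rows(trace), step = step,
                 scenario = sc),
            class = "hd_min_duration")
}

#' @export
print.hd_min_duration <- function(x, ...) {
  if (x$censored) {
    cat("<hd_min_duration> censored at max_duration\n")
  } else {
    cat("<hd_min_duration> ", x$min_duration, " min (rebound peak ",
        format(x$rebound$peak_mgL, digits = 4), " mg/L)\n", sep = "")
  }
  invisible(x)
}

#' Sweep the competitor drug half-life
#'
#' Re-runs the minimal-duration search for a family of hypothetical
#' competitor drugs identical in binding affinity and dosage but with
#' different conventional half-lives; each half-life is recalibrated to its
#' own free elimination rate first. Longer-lived competitors persist in the
#' patient's compartments and keep displacing toxic drug there, shortening
#' the required treatment; beyond a couple of hours the effect saturates.
#'
#' @param sc A calibrated `hd_scenario` with an infusion.
#' @param half_lives Conventional competitor half-lives to test, minutes.
#' @param step Duration grid, minutes.
#' @param ... Passed to [simulate_session()].
#' @return A tibble: `t_half_total_min`, `t_half_free_min`,
#'   `min_duration_min`, `censored`.
#' @export
sweep_competitor_half_life <- function(sc, half_lives, step = 5, ...) {
  stopifnot(!is.null(sc$infusion))
  purrr::map_dfr(half_lives, function(th) {
    sc2 <- sc
    sc2$infusion$drug$t_half_total <- th
    sc2$infusion$drug$lambda_free <- NA_real_
    cal <- calibrate_free_half_life(sc2$infusion$drug, sc2$patient)
    sc2$infusion$drug <- cal$drug
    md <- find_min_duration(sc2, step = step, ...)
    tibble::tibble(t_half_total_min = th,
                   t_half_free_min = cal$t_half_free,
                   min_duration_min = md$min_duration,
                   censored = md$censored)
  })
}

#' Sweep the initial toxicity level
#'
#' Runs sessions of fixed duration and fixed competitor dose across a range
#' of initial toxic-drug concentrations and reports the end-of-session
#' concentration and the post-dialytic rebound peak for each.
#'
#' @param sc A calibrated `hd_scenario`.
#' @param initial_concs Initial total serum concentrations, mg/L.
#' @param duration Fixed session length, minutes.
#' @param ... Passed to [simulate_session()].
#' @return A tibble: `initial_conc_mgL`, `end_conc_mgL`,
#'   `rebound_peak_mgL`, `within_window` (end concentration at or below the
#'   MTC), `rebound_above_mtc`.
#' @export
sweep_toxicity <- function(sc, initial_concs, duration, ...) {
  mtc <- sc$toxic$therapeutic_range[2]
  competitor <- if (!is.null(sc$infusion)) sc$infusion$drug
  purrr::map_dfr(initial_concs, function(c0) {
    sc2 <- sc
    sc2$initial_conc <- c0
    r <- .try_duration(sc2, duration, mtc, competitor, ...)
    tibble::tibble(initial_conc_mgL = c0, end_conc_mgL = r$end_conc,
                   rebound_peak_mgL = r$rebound$peak_mgL,
                   within_window = r$end_conc <= mtc,
                   rebound_above_mtc = r$rebound$peak_mgL > mtc)
  })
}

#' Mass-balance audit of a session
#'
#' Checks, for every conserved entity (toxic drug, competitor drug,
#' albumin), that the initial mass plus everything infused equals the mass
#' still in the patient and circuit plus cumulative dialysate removal plus
#' cumulative endogenous elimination, at every output time.
#'
#' @param x An `hd_session`.
#' @param tol Acceptable relative residual.
#' @return A tibble with one row per entity (`entity`, `residual`); errors
#'   when the worst residual exceeds `tol`, naming the largest contributor.
#' @export
mass_audit <- function(x, tol = 1e-6) {
  stopifnot(inherits(x, "hd_session"))
  res <- x$residuals
  out <- tibble::tibble(entity = names(res), residual = unname(res))
  if (max(res) > tol) {
    stop("mass audit failed: ", names(res)[which.max(res)], " residual ",
         format(max(res)), " exceeds ", tol)
  }
  out
}
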