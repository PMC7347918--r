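#' Drug binding and elimination parameters
#'
#' Bundles one drug's albumin binding, endogenous elimination, and
#' therapeutic-range parameters. The dissociation rate constant is derived
#' from the association constant and the binding affinity,
#' `k_off = k_on / K_A`, so the pair always satisfies `K_A = k_on / k_off`.
#'
#' @param name Drug name.
#' @param mw Molecular weight, g/mol.
#' @param site Albumin binding site, `"SudlowI"` or `"SudlowII"`. Two drugs
#'   compete only when they share a site.
#' @param K_A Association (binding affinity) constant, 1/M. `K_A = 0`
#'   describes an unbound tracer (both rate constants zero).
#' @param t_half_total Conventional half-life defined on total serum
#'   concentration, minutes.
#' @param therapeutic_range Length-2 numeric, total serum concentration
#'   (mg/L), or `NULL` when the drug is only used as a displacer.
#' @param k_on Association rate constant, 1/(M min). Default 1e8.
#' @param lambda_free First-order elimination rate applied to free plasma
#'   drug, 1/min. Usually left `NA` and filled in by
#'   [calibrate_free_half_life()].
#' @param calibration_peak Peak total serum concentration (mg/L) at which the
#'   free half-life calibration equilibrates the patient.
#' @return An object of class `hd_drug`.
#' @seealso [drug_phenytoin()], [drug_carbamazepine()], [drug_aspirin()],
#'   [drug_ibuprofen()]
#' @export
drug_params <- function(name, mw, site = c("SudlowI", "SudlowII"), K_A,
                        t_half_total, therapeutic_range = NULL,
                        k_on = 1e8, lambda_free = NA_real_,
                        calibration_peak = NA_real_) {
  site <- match.arg(site)
  k_off <- if (K_A > 0) k_on / K_A else 0
  x <- structure(
    list(name = name, mw = mw, site = site, K_A = K_A, k_on = k_on,
         k_off = k_off, t_half_total = t_half_total,
         therapeutic_range = therapeutic_range,
         lambda_free = lambda_free, calibration_peak = calibration_peak),
    class = "hd_drug"
  )
  x
}

#' @export
print.hd_drug <- function(x, ...) {
  cat("<hd_drug> ", x$name, " (", x$site, ")\n", sep = "")
  cat("  MW ", x$mw, " g/mol; K_A ", format(x$K_A, digits = 4),
      " 1/M; t1/2(total) ", x$t_half_total, " min\n", sep = "")
  if (is.finite(x$lambda_free)) {
    cat("  lambda_free ", format(x$lambda_free, digits = 4),
        " 1/min (t1/2 free ", format(log(2) / x$lambda_free, digits = 3),
        " min)\n", sep = "")
  }
  invisible(x)
}

#' Three-compartment patient parameters
#'
#' Plasma, interstitial, and intracellular fluid pools. Free drug exchanges
#' between plasma and interstitium (coefficient `K_ip`) and between
#' interstitium and cells (`K_ic`); albumin and complexes are confined to the
#' extracellular pools. The capillary endothelium is more permeable than
#' cell walls, so `K_ip > K_ic` is enforced.
#'
#' @param V_pl,V_is,V_ic Plasma, interstitial, intracellular volumes, L.
#' @param hematocrit Blood hematocrit fraction, in (0, 1).
#' @param albumin_plasma,albumin_interstitial Total albumin, uM. The
#'   interstitial concentration defaults to 40% of the plasma level: with a
#'   14 L interstitial space this places about 1.5 times the intravascular
#'   albumin mass extravascularly, the standard whole-body distribution.
#' @param K_ip,K_ic Free-solute mass-transfer coefficients, mL/min.
#' @return An object of class `hd_patient`.
#' @export
patient_params <- function(V_pl = 3.5, V_is = 14, V_ic = 28,
                           hematocrit = 0.35,
                           albumin_plasma = 650,
                           albumin_interstitial = 0.4 * albumin_plasma,
                           K_ip = 1200, K_ic = 100) {
  structure(
    list(V_pl = V_pl, V_is = V_is, V_ic = V_ic, hematocrit = hematocrit,
         albumin_plasma = albumin_plasma,
         albumin_interstitial = albumin_interstitial,
         K_ip = K_ip, K_ic = K_ic),
    class = "hd_patient"
  )
}

#' Hollow-fiber dialyzer parameters
#'
#' Transport across the membrane is governed by the overall mass-transfer
#' coefficient `KoA_free` (free solutes only; protein species have KoA = 0)
#' and the reflection coefficients (`sigma_free` = 0 for free drugs,
#' `sigma_protein` = 0.999 for albumin and its complexes). Fiber geometry
#' only sets residence times; unspecified dimensions default to a
#' high-flux 1.8 m^2 dialyzer with 200 um inner-diameter, 23 cm fibers.
#'
#' @param KoA_free Diffusive mass-transfer-area coefficient for free
#'   solutes, mL/min.
#' @param sigma_free,sigma_protein Membrane reflection coefficients.
#' @param membrane_area Total membrane area, m^2.
#' @param fiber_inner_diameter Fiber lumen diameter, cm.
#' @param fiber_length Fiber length, cm.
#' @param n_fibers Number of fibers; by default derived from the membrane
#'   area and fiber dimensions.
#' @param area_dialysate Dialysate-side cross-section per fiber, cm^2;
#'   defaults to twice the lumen cross-section.
#' @return An object of class `hd_dialyzer`.
#' @export
dialyzer_params <- function(KoA_free = 800, sigma_free = 0,
                            sigma_protein = 0.999, membrane_area = 1.8,
                            fiber_inner_diameter = 0.02, fiber_length = 23,
                            n_fibers = NULL, area_dialysate = NULL) {
  area_lumen <- pi * (fiber_inner_diameter / 2)^2
  if (is.null(n_fibers)) {
    n_fibers <- membrane_area * 1e4 / (pi * fiber_inner_diameter * fiber_length)
  }
  if (is.null(area_dialysate)) area_dialysate <- 2 * area_lumen
  structure(
    list(KoA_free = KoA_free, sigma_free = sigma_free,
         sigma_protein = sigma_protein, membrane_area = membrane_area,
         fiber_inner_diameter = fiber_inner_diameter,
         fiber_length = fiber_length, n_fibers = n_fibers,
         area_lumen = area_lumen, area_dialysate = area_dialysate),
    class = "hd_dialyzer"
  )
}

#' Arterial tube-segment parameters
#'
#' The segment of the extracorporeal line between the infusion port and the
#' dialyzer blood inlet, where the infused competitor mixes with plasma and
#' the binding equilibrium shifts in transit.
#'
#' @param length Segment length, cm.
#' @param inner_diameter Line inner diameter, cm.
#' @return An object of class `hd_tube`.
#' @export
tube_params <- function(length = 150, inner_diameter = 0.4) {
  structure(
    list(length = length, inner_diameter = inner_diameter,
         cross_section = pi * (inner_diameter / 2)^2),
    class = "hd_tube"
  )
}

#' Competitor-drug infusion prescription
#'
#' A dose dissolved in a diluent bag, infused at constant rate into the
#' arterial line over the whole treatment session; the infusion rate is
#' therefore `diluent_volume / duration` and the full dose is always
#' delivered. Only free drug exists in the infusion stream.
#'
#' @param drug A [drug_params()] object for the competitor.
#' @param dose Total dose, mg.
#' @param diluent_volume Diluent volume, mL.
#' @return An object of class `hd_infusion` with the bag concentration
#'   `C_inf` (uM) precomputed.
#' @export
infusion_spec <- function(drug, dose, diluent_volume) {
  structure(
    list(drug = drug, dose = dose, diluent_volume = diluent_volume,
         C_inf = 1e6 * dose / (drug$mw * diluent_volume)),
    class = "hd_infusion"
  )
}

#' Dialysis session settings
#'
#' @param Q_blood Blood flow rate, mL/min. The plasma flow rate is
#'   `Q_blood * (1 - hematocrit)`.
#' @param Q_dialysate Fresh dialysate inflow rate, mL/min (single pass).
#' @param max_duration Longest session considered by the duration search,
#'   minutes.
#' @param rebound_horizon Post-dialysis observation window for the rebound
#'   peak, minutes.
#' @return An object of class `hd_session_params`.
#' @export
session_params <- function(Q_blood = 250, Q_dialysate = 500,
                           max_duration = 1440, rebound_horizon = 720) {
  structure(
    list(Q_blood = Q_blood, Q_dialysate = Q_dialysate,
         max_duration = max_duration, rebound_horizon = rebound_horizon),
    class = "hd_session_params"
  )
}

#' Assemble a treatment scenario
#'
#' @param toxic [drug_params()] for the intoxicating drug.
#' @param initial_conc Initial total serum concentration of the toxic drug,
#'   mg/L.
#' @param patient,dialyzer,tube,session Component parameter objects.
#' @param infusion An [infusion_spec()] for the competitor, or `NULL` for
#'   conventional hemodialysis.
#' @param n_tube,n_dz Method-of-lines grid cells for the tube segment and
#'   the dialyzer.
#' @return An object of class `hd_scenario`.
#' @export
scenario <- function(toxic, initial_conc,
                     patient = patient_params(),
                     dialyzer = dialyzer_params(),
                     tube = tube_params(),
                     session = session_params(),
                     infusion = NULL,
                     n_tube = 16, n_dz = 64) {
  structure(
    list(toxic = toxic, initial_conc = initial_conc, patient = patient,
         dialyzer = dialyzer, tube = tube, session = session,
         infusion = infusion, n_tube = n_tube, n_dz = n_dz),
    class = "hd_scenario"
  )
}

#' @export
print.hd_scenario <- function(x, ...) {
  cat("<hd_scenario> ", x$toxic$name, " ", x$initial_conc, " mg/L",
      if (!is.null(x$infusion)) {
        paste0(" + ", x$infusion$drug$name, " ", x$infusion$dose, " mg in ",
               x$infusion$diluent_volume, " mL")
      } else " (conventional HD)",
      "\n", sep = "")
  cat("  Qb ", x$session$Q_blood, " mL/min, Qd ", x$session$Q_dialysate,
      " mL/min, KoA ", x$dialyzer$KoA_free, " mL/min\n", sep = "")
  invisible(x)
}

# ---- presets ----------------------------------------------------------------

#' Drug presets
#'
#' Reference parameter sets for the two intoxication drugs and their binding
#' competitors. Phenytoin and aspirin bind Sudlow site I; carbamazepine and
#' ibuprofen bind Sudlow site II. Affinities of the toxic drugs are derived
#' from their therapeutic binding fractions (90% bound at 20 mg/L for
#' phenytoin, 75% bound at 12 mg/L for carbamazepine, against 650 uM
#' albumin) via [affinity_from_binding()]; competitor affinities are
#' literature constants. Conventional half-lives: phenytoin 35 h,
#' carbamazepine 25 h, aspirin 20 min, ibuprofen 2 h.
#'
#' @param albumin Total albumin used to derive the affinity, uM.
#' @return An `hd_drug` object.
#' @name drug_presets
NULL

#' @rdname drug_presets
#' @export
drug_phenytoin <- function(albumin = 650) {
  drug_params("phenytoin", mw = 252.27, site = "SudlowI",
              K_A = affinity_from_binding(20, 0.90, albumin, 252.27),
              t_half_total = 35 * 60, therapeutic_range = c(10, 20),
              calibration_peak = 70)
}

#' @rdname drug_presets
#' @export
drug_carbamazepine <- function(albumin = 650) {
  drug_params("carbamazepine", mw = 236.27, site = "SudlowII",
              K_A = affinity_from_binding(12, 0.75, albumin, 236.27),
              t_half_total = 25 * 60, therapeutic_range = c(4, 12),
              calibration_peak = 35)
}

#' @rdname drug_presets
#' @export
drug_aspirin <- function() {
  drug_params("aspirin", mw = 180.16, site = "SudlowI", K_A = 1.90e5,
              t_half_total = 20, calibration_peak = 20)
}

#' @rdname drug_presets
#' @export
drug_ibuprofen <- function() {
  drug_params("ibuprofen", mw = 206.28, site = "SudlowII", K_A = 1.76e5,
              t_half_total = 2 * 60, calibration_peak = 25)
}

#' Scenario presets
#'
#' The two reference intoxication scenarios: (A) phenytoin toxicity at
#' 70 mg/L treated with 2000 mg aspirin in 500 mL saline, and (B)
#' carbamazepine toxicity at 35 mg/L treated with 800 mg ibuprofen in
#' 200 mL saline. Blood and dialysate flow rates 250 and 500 mL/min,
#' KoA 800 mL/min for free solutes, 1.8 m^2 high-flux dialyzer.
#'
#' @param with_infusion If `FALSE`, drop the competitor infusion
#'   (conventional hemodialysis).
#' @param calibrate If `TRUE` (default), calibrate the free elimination
#'   rates of both drugs before returning.
#' @return An `hd_scenario` object.
#' @name scenario_presets
NULL

#' @rdname scenario_presets
#' @export
scenario_phenytoin_aspirin <- function(with_infusion = TRUE,
                                       calibrate = TRUE) {
  sc <- scenario(
    toxic = drug_phenytoin(), initial_conc = 70,
    infusion = if (with_infusion) infusion_spec(drug_aspirin(), 2000, 500)
  )
  if (calibrate) sc <- calibrate_scenario(sc)
  sc
}

#' @rdname scenario_presets
#' @export
scenario_carbamazepine_ibuprofen <- function(with_infusion = TRUE,
                                             calibrate = TRUE) {
  sc <- scenario(
    toxic = drug_carbamazepine(), initial_conc = 35,
    infusion = if (with_infusion) infusion_spec(drug_ibuprofen(), 800, 200)
  )
  if (calibrate) sc <- calibrate_scenario(sc)
  sc
}

# ---- validation -------------------------------------------------------------

#' List invariant violations of a scenario
#'
#' Checks every physical invariant of the assembled scenario and returns all
#' violations at once (never just the first), each with the field path that
#' failed.
#'
#' @param x An `hd_scenario`.
#' @return A tibble with columns `field` and `message`; zero rows when the
#'   scenario is valid.
#' @export
scenario_violations <- function(x) {
  v <- list()
  bad <- function(field, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(field = field, message = message)
  }
  chk_drug <- function(d, path) {
    if (is.null(d)) return()
    for (f in c("mw", "k_on", "t_half_total")) {
      if (!is.finite(d[[f]]) || d[[f]] <= 0) {
        bad(paste0(path, ".", f), "must be strictly positive")
      }
    }
    if (!is.finite(d$K_A) || d$K_A < 0) bad(paste0(path, ".K_A"),
                                            "must be non-negative")
    if (d$K_A > 0) {
      rel <- abs(d$k_off - d$k_on / d$K_A) / (d$k_on / d$K_A)
      if (!is.finite(rel) || rel > 1e-12) {
        bad(paste0(path, ".k_off"),
            paste0("inconsistent with ", path, ".K_A: k_off must equal ",
                   "k_on / K_A"))
      }
    }
    tr <- d$therapeutic_range
    if (!is.null(tr) && all(is.finite(tr)) && !(tr[1] < tr[2])) {
      bad(paste0(path, ".therapeutic_range"), "must satisfy min < max")
    }
  }
  chk_drug(x$toxic, "toxic")
  p <- x$patient
  for (f in c("V_pl", "V_is", "V_ic", "albumin_plasma",
              "albumin_interstitial")) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      bad(paste0("patient.", f), "must be strictly positive")
    }
  }
  if (!is.finite(p$hematocrit) || p$hematocrit <= 0 || p$hematocrit >= 1) {
    bad("patient.hematocrit", "must lie strictly between 0 and 1")
  }
  if (!(is.finite(p$K_ip) && is.finite(p$K_ic) && p$K_ip > p$K_ic &&
        p$K_ic > 0)) {
    bad("patient.K_ip", "must satisfy K_ip > K_ic > 0")
  }
  dz <- x$dialyzer
  for (f in c("KoA_free", "membrane_area", "fiber_length", "n_fibers",
              "area_lumen", "area_dialysate")) {
    if (!is.finite(dz[[f]]) || dz[[f]] <= 0) {
      bad(paste0("dialyzer.", f), "must be strictly positive")
    }
  }
  for (f in c("sigma_free", "sigma_protein")) {
    if (!is.finite(dz[[f]]) || dz[[f]] < 0 || dz[[f]] > 1) {
      bad(paste0("dialyzer.", f), "must lie in [0, 1]")
    }
  }
  for (f in c("length", "cross_section")) {
    if (!is.finite(x$tube[[f]]) || x$tube[[f]] <= 0) {
      bad(paste0("tube.", f), "must be strictly positive")
    }
  }
  s <- x$session
  for (f in c("Q_blood", "Q_dialysate", "max_duration", "rebound_horizon")) {
    if (!is.finite(s[[f]]) || s[[f]] <= 0) {
      bad(paste0("session.", f), "must be strictly positive")
    }
  }
  if (!is.finite(x$initial_conc) || x$initial_conc < 0) {
    bad("initial_conc", "must be non-negative")
  }
  inf <- x$infusion
  if (!is.null(inf)) {
    chk_drug(inf$drug, "infusion.drug")
    if (!is.finite(inf$dose) || inf$dose <= 0) {
      bad("infusion.dose", "must be strictly positive")
    }
    if (!is.finite(inf$diluent_volume) || inf$diluent_volume <= 0) {
      bad("infusion.diluent_volume", "must be strictly positive")
    }
    cexp <- 1e6 * inf$dose / (inf$drug$mw * inf$diluent_volume)
    if (is.finite(cexp) && abs(inf$C_inf - cexp) / cexp > 1e-9) {
      bad("infusion.C_inf", "inconsistent with dose and diluent_volume")
    }
    if (!is.null(x$toxic) && inf$drug$site != x$toxic$site) {
      bad("infusion.drug.site",
          "competitor must share the toxic drug's albumin site")
    }
  }
  if (x$n_tube < 2 || x$n_dz < 2) bad("n_tube", "grids need at least 2 cells")
  if (length(v) == 0) {
    tibble::tibble(field = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Validate a scenario, aggregating all violations
#'
#' @param x An `hd_scenario`.
#' @return `x` invisibly when valid; otherwise an error listing every
#'   violation with its field path.
#' @export
validate_scenario <- function(x) {
  stopifnot(inherits(x, "hd_scenario"))
  v <- scenario_violations(x)
  if (nrow(v) > 0) {
    stop("invalid scenario:\n",
         paste0("  - ", v$field, ": ", v$message, collapse = "\n"),
         call. = FALSE)
  }
  invisible(x)
}

# ---- scenario config files --------------------------------------------------

.drug_to_list <- function(d) {
  if (is.null(d)) return(NULL)
  list(name = d$name, mw = d$mw, site = d$site, K_A = d$K_A, k_on = d$k_on,
       t_half_total = d$t_half_total,
       therapeutic_range = d$therapeutic_range,
       lambda_free = d$lambda_free, calibration_peak = d$calibration_peak)
}

.drug_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  drug_params(l$name, l$mw, l$site, l$K_A, l$t_half_total,
              therapeutic_range = unlist(l$therapeutic_range),
              k_on = l$k_on,
              lambda_free = l$lambda_free %||% NA_real_,
              calibration_peak = l$calibration_peak %||% NA_real_)
}

#' Write a scenario to a YAML config file
#'
#' @param x An `hd_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "hd_scenario"))
  cfg <- list(
    drug_toxic = .drug_to_list(x$toxic),
    initial_conc = x$initial_conc,
    patient = unclass(x$patient),
    dialyzer = unclass(x$dialyzer),
    tube = x$tube[c("length", "inner_diameter")],
    session = unclass(x$session),
    infusion = if (!is.null(x$infusion)) {
      list(drug = .drug_to_list(x$infusion$drug), dose = x$infusion$dose,
           diluent_volume = x$infusion$diluent_volume)
    },
    grid = list(n_tube = x$n_tube, n_dz = x$n_dz)
  )
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Read a scenario from a YAML config file
#'
#' @param path Config file path (as written by [write_scenario()]).
#' @return An `hd_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  sc <- scenario(
    toxic = .drug_from_list(cfg$drug_toxic),
    initial_conc = cfg$initial_conc,
    patient = do.call(patient_params, cfg$patient),
    dialyzer = do.call(dialyzer_params, cfg$dialyzer[
      c("KoA_free", "sigma_free", "sigma_protein", "membrane_area",
        "fiber_inner_diameter", "fiber_length", "n_fibers",
        "area_dialysate")]),
    tube = do.call(tube_params, cfg$tube),
    session = do.call(session_params, cfg$session),
    infusion = if (!is.null(cfg$infusion)) {
      infusion_spec(.drug_from_list(cfg$infusion$drug), cfg$infusion$dose,
                    cfg$infusion$diluent_volume)
    },
    n_tube = cfg$grid$n_tube, n_dz = cfg$grid$n_dz
  )
  validate_scenario(sc)
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
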