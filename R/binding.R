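#' Species vector for the competitive binding system
#'
#' The model tracks five chemical species per well-mixed pool or grid cell:
#' free toxic drug `T`, free competitor drug `D`, free albumin `P`, and the
#' two albumin complexes `PT` and `PD`. All concentrations are in uM.
#'
#' @param T_free,D_free,P_free,PT,PD Concentrations in uM (non-negative).
#' @return A named numeric vector of length 5 with names
#'   `c("T", "D", "P", "PT", "PD")`.
#' @export
species_vector <- function(T_free = 0, D_free = 0, P_free = 0, PT = 0, PD = 0) {
  s <- c(T = unname(T_free), D = unname(D_free), P = unname(P_free),
         PT = unname(PT), PD = unname(PD))
  if (any(!is.finite(s))) stop("species concentrations must be finite")
  if (any(s < 0)) stop("species concentrations must be non-negative")
  s
}

.species_names <- c("T", "D", "P", "PT", "PD")

#' Net mass-action reaction rates for competitive albumin binding
#'
#' Both drugs bind reversibly to the same albumin site:
#' `P + T <-> PT` and `P + D <-> PD`. The net production rate of free toxic
#' drug is `-k_on,T * P * T + k_off,T * PT`, symmetrically for the
#' competitor; complex rates are the negatives and free albumin consumes
#' both associations and gains both dissociations.
#'
#' @param s A species vector from [species_vector()] (uM).
#' @param toxic,competitor [drug_params()] objects supplying the rate
#'   constants. `competitor` may be `NULL` when no displacer is present.
#' @return Named numeric vector of net rates, uM/min, same names as `s`.
#' @export
binding_rates <- function(s, toxic, competitor = NULL) {
  kT <- .kinetic_constants(toxic)
  kD <- .kinetic_constants(competitor)
  rT <- -kT$kon * s[["P"]] * s[["T"]] + kT$koff * s[["PT"]]
  rD <- -kD$kon * s[["P"]] * s[["D"]] + kD$koff * s[["PD"]]
  c(T = rT, D = rD, P = rT + rD, PT = -rT, PD = -rD)
}

# kon in 1/(uM*min), koff in 1/min; zero when no drug / no binding (K_A = 0)
.kinetic_constants <- function(drug) {
  if (is.null(drug)) return(list(kon = 0, koff = 0))
  if (drug$K_A <= 0) return(list(kon = 0, koff = 0))
  list(kon = drug$k_on * 1e-6, koff = drug$k_off)
}

# Vectorised binding rates over a matrix of cells (rows) x species (cols),
# used by the tube and dialyzer method-of-lines right-hand sides.
.binding_rates_mat <- function(M, konT, koffT, konD, koffD) {
  rT <- -konT * M[, 3L] * M[, 1L] + koffT * M[, 4L]
  rD <- -konD * M[, 3L] * M[, 2L] + koffD * M[, 5L]
  cbind(rT, rD, rT + rD, -rT, -rD, deparse.level = 0)
}

#' Single-drug albumin binding equilibrium
#'
#' Solves the one-ligand, one-site equilibrium
#' `T_free * (1 + K_A * P_free) = T_tot` with
#' `P_free = P_tot - PT`, a quadratic in `T_free`, using the
#' cancellation-safe root.
#'
#' @param T_tot Total drug concentration, uM (free + bound).
#' @param P_tot Total albumin concentration, uM.
#' @param K_A Association constant, 1/M. `K_A = 0` means no binding.
#' @return A species vector (competitor fields zero).
#' @examples
#' # 70 mg/L phenytoin against 650 uM albumin: ~13.6% free
#' s <- equilibrate_single(mgL_to_uM(70, 252.27), 650, 1.56e4)
#' s[["T"]] / (s[["T"]] + s[["PT"]])
#' @export
equilibrate_single <- function(T_tot, P_tot, K_A) {
  stopifnot(T_tot >= 0, P_tot >= 0, K_A >= 0)
  K <- K_A * 1e-6 # 1/uM
  if (K == 0 || T_tot == 0 || P_tot == 0) {
    return(species_vector(T_free = T_tot, P_free = P_tot))
  }
  b <- 1 + K * (P_tot - T_tot)
  disc <- b * b + 4 * K * T_tot
  if (disc < 0) stop("negative discriminant in binding quadratic (T_tot=",
                     T_tot, ", P_tot=", P_tot, ", K_A=", K_A, ")")
  T_free <- 2 * T_tot / (b + sqrt(disc))
  PT <- T_tot - T_free
  species_vector(T_free = T_free, P_free = P_tot - PT, PT = PT)
}

#' Competitive two-drug albumin binding equilibrium
#'
#' Solves the coupled equilibria `P + T <-> PT`, `P + D <-> PD` sharing one
#' albumin site. Conservation reduces the system to a scalar root problem in
#' free albumin: `f(P_free) = P_free * (1 + K_T*T_tot/(1 + K_T*P_free)
#' + K_D*D_tot/(1 + K_D*P_free)) - P_tot`, which is strictly increasing on
#' `[0, P_tot]`, so the physical root is unique. The bracketing solve is
#' polished by Newton steps to drive the conservation residuals below 1e-10
#' relative.
#'
#' @param T_tot,D_tot Total toxic and competitor drug, uM.
#' @param P_tot Total albumin, uM.
#' @param K_T,K_D Association constants, 1/M.
#' @return A species vector at equilibrium.
#' @export
equilibrate_competitive <- function(T_tot, D_tot, P_tot, K_T, K_D) {
  stopifnot(T_tot >= 0, D_tot >= 0, P_tot >= 0, K_T >= 0, K_D >= 0)
  if (D_tot == 0 || K_D == 0) {
    s <- equilibrate_single(T_tot, P_tot, K_T)
    s[["D"]] <- D_tot
    return(s)
  }
  if (T_tot == 0 || K_T == 0) {
    s <- equilibrate_single(D_tot, P_tot, K_D)
    return(species_vector(T_free = T_tot, D_free = s[["T"]],
                          P_free = s[["P"]], PD = s[["PT"]]))
  }
  kT <- K_T * 1e-6
  kD <- K_D * 1e-6
  if (P_tot == 0) return(species_vector(T_free = T_tot, D_free = D_tot))
  f <- function(P) {
    P * (1 + kT * T_tot / (1 + kT * P) + kD * D_tot / (1 + kD * P)) - P_tot
  }
  root <- tryCatch(
    stats::uniroot(f, c(0, P_tot), tol = 1e-14 * max(1, P_tot))$root,
    error = function(e) {
      stop("bracketing failure in competitive equilibrium (T_tot=", T_tot,
           ", D_tot=", D_tot, ", P_tot=", P_tot, ", K_T=", K_T,
           ", K_D=", K_D, "): ", conditionMessage(e))
    }
  )
  # Newton polish on the monotone objective
  for (i in 1:4) {
    gT <- kT * T_tot / (1 + kT * root)
    gD <- kD * D_tot / (1 + kD * root)
    fp <- 1 + gT / (1 + kT * root) + gD / (1 + kD * root)
    step <- f(root) / fp
    root <- min(max(root - step, 0), P_tot)
  }
  P_free <- root
  T_free <- T_tot / (1 + kT * P_free)
  D_free <- D_tot / (1 + kD * P_free)
  s <- species_vector(T_free = T_free, D_free = D_free, P_free = P_free,
                      PT = T_tot - T_free, PD = D_tot - D_free)
  res <- abs(s[["P"]] + s[["PT"]] + s[["PD"]] - P_tot) / max(P_tot, 1e-12)
  if (res > 1e-10) {
    stop("competitive equilibrium residual ", format(res), " exceeds 1e-10")
  }
  s
}

#' Association constant from a therapeutic bound fraction
#'
#' Inverts the single-drug equilibrium: given a total drug concentration and
#' the fraction bound at that concentration against a known total albumin
#' level, returns the association constant
#' `K_A = bound / (free * P_free)` with `P_free = P_tot - bound`.
#'
#' @param C_tot Total drug concentration, mg/L.
#' @param frac_bound Fraction of drug bound, in (0, 1).
#' @param P_tot Total albumin, uM.
#' @param mw Drug molecular weight, g/mol.
#' @return Association constant `K_A` in 1/M.
#' @examples
#' affinity_from_binding(20, 0.90, 650, 252.27) # phenytoin, ~1.56e4 1/M
#' affinity_from_binding(12, 0.75, 650, 236.27) # carbamazepine, ~4.9e3 1/M
#' @export
affinity_from_binding <- function(C_tot, frac_bound, P_tot, mw) {
  if (frac_bound <= 0 || frac_bound >= 1) {
    stop("`frac_bound` must be strictly between 0 and 1, got ", frac_bound)
  }
  stopifnot(C_tot > 0, P_tot > 0)
  tot_uM <- mgL_to_uM(C_tot, mw)
  bound <- frac_bound * tot_uM
  free <- tot_uM - bound
  if (bound >= P_tot) {
    stop("bound drug (", bound, " uM) cannot reach total albumin (",
         P_tot, " uM)")
  }
  P_free <- P_tot - bound
  1e6 * bound / (free * P_free)
}
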