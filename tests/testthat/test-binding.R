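test_that("affinity is recovered from therapeutic binding fractions", {
  # phenytoin: 20 mg/L, 90% bound, 650 uM albumin
  expect_equal(affinity_from_binding(20, 0.90, 650, 252.27), 1.56e4,
               tolerance = 0.005)
  # carbamazepine: 12 mg/L, 75% bound
  expect_equal(affinity_from_binding(12, 0.75, 650, 236.27), 4.9e3,
               tolerance = 0.005)
  # vanishing bound fraction -> vanishing affinity
  expect_lt(affinity_from_binding(20, 1e-9, 650, 252.27), 1e-2)
  # bound exceeding albumin is impossible
  expect_error(affinity_from_binding(400, 0.99, 100, 250), "albumin")
})

test_that("single-drug equilibrium solves the binding quadratic", {
  K <- affinity_from_binding(20, 0.90, 650, 252.27)
  s <- equilibrate_single(mgL_to_uM(20, 252.27), 650, K)
  # by construction the therapeutic point is reproduced
  expect_equal(s[["PT"]] / (s[["T"]] + s[["PT"]]), 0.90, tolerance = 1e-10)
  # zero affinity leaves everything free
  s0 <- equilibrate_single(50, 650, 0)
  expect_equal(s0[["T"]], 50)
  expect_equal(s0[["PT"]], 0)
  # conservation residuals
  s2 <- equilibrate_single(mgL_to_uM(70, 252.27), 650, K)
  expect_equal(s2[["T"]] + s2[["PT"]], mgL_to_uM(70, 252.27),
               tolerance = 1e-12)
  expect_equal(s2[["P"]] + s2[["PT"]], 650, tolerance = 1e-12)
})

test_that("competitive equilibrium agrees with the kinetic ODE oracle", {
  cases <- list(
    c(T_tot = 277.5, D_tot = 300, P_tot = 650, K_T = 1.56e4, K_D = 1.9e5),
    c(T_tot = 148.1, D_tot = 100, P_tot = 650, K_T = 4.9e3, K_D = 1.76e5),
    c(T_tot = 10, D_tot = 2000, P_tot = 650, K_T = 1.56e4, K_D = 1.9e5),
    c(T_tot = 500, D_tot = 500, P_tot = 325, K_T = 5e4, K_D = 5e4)
  )
  for (cs in cases) {
    s <- equilibrate_competitive(cs["T_tot"], cs["D_tot"], cs["P_tot"],
                                 cs["K_T"], cs["K_D"])
    o <- kinetic_equilibrium_oracle(cs["T_tot"], cs["D_tot"], cs["P_tot"],
                                    cs["K_T"], cs["K_D"])
    expect_equal(unname(s), unname(o), tolerance = 1e-6)
  }
})

test_that("competitive equilibrium reduces to the single-drug solution", {
  s1 <- equilibrate_competitive(100, 0, 650, 1.56e4, 1.9e5)
  s2 <- equilibrate_single(100, 650, 1.56e4)
  expect_equal(unname(s1), unname(s2), tolerance = 1e-12)
})

test_that("adding competitor strictly increases free toxic drug", {
  base <- equilibrate_competitive(277.5, 0, 650, 1.56e4, 1.9e5)[["T"]]
  prev <- base
  for (D in c(10, 100, 500, 2000)) {
    cur <- equilibrate_competitive(277.5, D, 650, 1.56e4, 1.9e5)[["T"]]
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("binding rates vanish at equilibrium and match the oracle", {
  tox <- drug_phenytoin()
  comp <- drug_aspirin()
  s_eq <- equilibrate_competitive(200, 300, 650, tox$K_A, comp$K_A)
  r <- binding_rates(s_eq, tox, comp)
  expect_true(all(abs(r) < 1e-8))
  # pure association from complexes-free state consumes free drug
  s0 <- species_vector(T_free = 50, D_free = 20, P_free = 400)
  r0 <- binding_rates(s0, tox, comp)
  expect_lt(r0[["T"]], 0)
  expect_lt(r0[["D"]], 0)
  expect_equal(r0[["PT"]], -r0[["T"]])
  # random states against the independently coded mass-action rates
  set.seed(42)
  for (i in 1:20) {
    s <- species_vector(T_free = runif(1, 0, 300), D_free = runif(1, 0, 300),
                        P_free = runif(1, 0, 650), PT = runif(1, 0, 300),
                        PD = runif(1, 0, 300))
    expect_equal(unname(binding_rates(s, tox, comp)),
                 unname(binding_rates_oracle(s, tox$k_on * 1e-6, tox$k_off,
                                             comp$k_on * 1e-6, comp$k_off)),
                 tolerance = 1e-12)
  }
})

test_that("kinetic integration conserves all three totals", {
  tox <- drug_phenytoin()
  comp <- drug_aspirin()
  rhs <- function(t, y, p) {
    list(unname(binding_rates(
      species_vector(y[1], y[2], y[3], y[4], y[5]), tox, comp)))
  }
  y0 <- c(200, 400, 650, 0, 0)
  out <- deSolve::lsoda(y0, seq(0, 10, length.out = 101), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  totT <- out[, 2] + out[, 5]
  totD <- out[, 3] + out[, 6]
  totP <- out[, 4] + out[, 5] + out[, 6]
  expect_lt(max(abs(totT - totT[1])) / totT[1], 1e-9)
  expect_lt(max(abs(totD - totD[1])) / totD[1], 1e-9)
  expect_lt(max(abs(totP - totP[1])) / totP[1], 1e-9)
})

test_that("detailed balance holds at equilibrium", {
  tox <- drug_carbamazepine()
  s <- equilibrate_single(148.1, 650, tox$K_A)
  kon <- tox$k_on * 1e-6
  expect_equal(kon * s[["P"]] * s[["T"]], tox$k_off * s[["PT"]],
               tolerance = 1e-8)
})

test_that("affinity estimation and equilibrium are mutual inverses", {
  for (f in c(0.25, 0.5, 0.75, 0.9, 0.98)) {
    K <- affinity_from_binding(15, f, 650, 236.27)
    s <- equilibrate_single(mgL_to_uM(15, 236.27), 650, K)
    expect_equal(s[["PT"]] / (s[["T"]] + s[["PT"]]), f, tolerance = 1e-8)
  }
})
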