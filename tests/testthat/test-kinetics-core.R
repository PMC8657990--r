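test_that("network derivatives reproduce the stated rate laws", {
  rc <- ref_rates()
  cond <- ref_conditions()

  # donor alone: all flux appears as HNO release at k_AS * [AS] = 0.016 uM/s
  st <- new_state(ref_conditions(FlBA0 = 0, O2 = 0))
  d <- rhs_full_model(st, rc, ref_conditions(FlBA0 = 0, O2 = 0))
  expect_equal(d[["AS"]], -1.6e-8)
  expect_equal(d[["HNO"]], 1.6e-8)
  expect_true(all(d[setdiff(names(d), c("AS", "HNO"))] == 0))

  # empty system is inert
  st0 <- st; st0[] <- 0
  expect_true(all(rhs_full_model(st0, rc, cond) == 0))

  # dimerization stoichiometry: 1 uM HNO alone, k_dim = 8e6
  st1 <- st0; st1[["HNO"]] <- 1e-6
  d1 <- rhs_full_model(st1, rc, ref_conditions(AS0 = 0, FlBA0 = 0, O2 = 0))
  expect_equal(d1[["HNO"]], -2 * 8e6 * (1e-6)^2)   # -1.6e-5 M/s
  expect_equal(d1[["N2O"]], 8e6 * (1e-6)^2)        # +8e-6 M/s

  # negative concentrations are rejected
  stn <- st; stn[["HNO"]] <- -1e-9
  expect_error(rhs_full_model(stn, rc, cond), "negative concentration")
})

test_that("full-model integration agrees with an independent RK4 oracle", {
  tr <- integrate_full_model(ref_rates(), ref_conditions(),
                             time_grid = seq(0, 600, 5))
  n <- nrow(tr)

  # frozen fixed-step RK4 value (dt = 5e-3, converged to 9 digits): the
  # fluorescein yield at 600 s reflects the 38% donor decay over the window
  expect_equal(tr$FlOH[n], 7.52748671e-06, tolerance = 1e-5)
  expect_equal(tr$HNO[n], 2.421878e-09, tolerance = 1e-4)

  # live short-horizon cross-check against the oracle in this suite
  y60 <- oracle_rk4(oracle_state0(), T = 60, dt = 0.02,
                    kAS = 8e-4, kO2 = 1.8e4, kFlBA = 1e6, kdim = 8e6, knuc = 0)
  i60 <- which(tr$time_s == 60)
  expect_equal(tr$FlOH[i60], y60[["FlOH"]], tolerance = 1e-6)
  expect_equal(tr$HNO[i60], y60[["HNO"]], tolerance = 1e-5)
  expect_equal(tr$ONOO[i60], y60[["ONOO"]], tolerance = 1e-5)

  # no source term: everything stays at its initial value
  tr0 <- integrate_full_model(ref_rates(k_AS = 0), ref_conditions(),
                              time_grid = seq(0, 600, 100))
  expect_true(all(abs(tr0$AS - 20e-6) < 1e-18))
  expect_true(all(tr0$FlOH == 0))

  # matched loss channels halve the fluorescein yield (within the small
  # dimerization correction)
  tri <- integrate_full_model(
    ref_rates(k_nucleophile = 1.8e4),
    ref_conditions(nucleophile0 = 225e-6),
    time_grid = seq(0, 600, 5))
  expect_equal(tri$FlOH[n] / tr$FlOH[n], 0.5, tolerance = 0.02)
})

test_that("trajectories conserve nitrogen and fluorophore bookkeeping", {
  cases <- list(c(k = 0, nuc = 0), c(k = 2.2e3, nuc = 1e-3),
                c(k = 1e5, nuc = 1e-2), c(k = 10, nuc = 5e-3))
  for (cs in cases) {
    tr <- integrate_full_model(ref_rates(k_nucleophile = cs[["k"]]),
                               ref_conditions(nucleophile0 = cs[["nuc"]]),
                               time_grid = seq(0, 600, 20))
    err <- conservation_errors(tr)
    expect_lt(err[["nitrogen"]], 1e-12)
    expect_lt(err[["fluorophore"]], 1e-12)
    expect_true(all(as.matrix(tr[-1]) >= 0))
  }
})

test_that("steady-state closed forms match their defining arithmetic", {
  # reference conditions, no scavenger: 1.6e-8 / (1.8e4 * 225e-6)
  expect_equal(hno_steady_state(ref_rates(), ref_conditions()),
               1.6e-8 / (1.8e4 * 225e-6))

  # no donor, no steady HNO
  expect_equal(hno_steady_state(ref_rates(), ref_conditions(AS0 = 0)), 0)

  # homogeneity: doubling every loss channel halves the pool
  h1 <- hno_steady_state(ref_rates(k_nucleophile = 2.2e3),
                         ref_conditions(nucleophile0 = 1e-3))
  h2 <- hno_steady_state(ref_rates(k_nucleophile = 4.4e3, k_O2 = 3.6e4),
                         ref_conditions(nucleophile0 = 1e-3))
  expect_equal(h2, h1 / 2)

  # no loss channel at all: no steady state
  expect_error(hno_steady_state(ref_rates(k_O2 = 0), ref_conditions(O2 = 0)),
               "loss channel")

  ss <- fluorescein_rates(ref_rates(), ref_conditions())
  expect_equal(ss$v0, 1.6e-8)          # k_AS * AS0, the 0.016 uM/s HNO flux
  expect_equal(ss$vi, ss$v0)           # no scavenger: vi = v0

  # matched channels partition the flux equally
  ss2 <- fluorescein_rates(ref_rates(k_nucleophile = 1.8e4),
                           ref_conditions(nucleophile0 = 225e-6))
  expect_equal(ss2$vi, ss2$v0 / 2)

  # overwhelming scavenger extinguishes the probe channel
  ss3 <- fluorescein_rates(ref_rates(k_nucleophile = 1e12),
                           ref_conditions(nucleophile0 = 1))
  expect_lt(ss3$vi / ss3$v0, 1e-10)

  # no probe: peroxynitrite pool undefined but rates remain
  expect_warning(ss4 <- fluorescein_rates(ref_rates(),
                                          ref_conditions(FlBA0 = 0)),
                 "undefined")
  expect_true(is.na(ss4$onoo_ss))
  expect_equal(ss4$v0, 1.6e-8)
})

test_that("the inhibition law is an identity with the steady-state rates", {
  # printed-constant case: k = 2.2e3, 1 mM scavenger, 225 uM O2
  expect_equal(inhibition_prediction(ref_rates(k_nucleophile = 2.2e3),
                                     1e-3, 225e-6),
               (2.2e3 / 1.8e4) * (1e-3 / 225e-6))
  expect_equal(inhibition_prediction(ref_rates(k_nucleophile = 1.8e4),
                                     225e-6, 225e-6), 1)
  expect_equal(inhibition_prediction(ref_rates(k_nucleophile = 5e3),
                                     0, 225e-6), 0)

  # v0/vi - 1 equals the prediction to machine precision across a box
  set.seed(17)
  for (i in 1:20) {
    k <- 10^stats::runif(1, 1, 5)
    nuc <- 10^stats::runif(1, -5, -2)
    rc <- ref_rates(k_nucleophile = k)
    cond <- ref_conditions(nucleophile0 = nuc)
    ss <- fluorescein_rates(rc, cond)
    pred <- inhibition_prediction(rc, nuc, cond$O2)
    expect_equal(ss$v0 / ss$vi - 1, pred, tolerance = 1e-13)
  }
})

test_that("vi and the HNO pool fall monotonically with each loss channel", {
  kx <- 10^seq(1, 5, length.out = 9)
  vi <- vapply(kx, function(k)
    fluorescein_rates(ref_rates(k_nucleophile = k),
                      ref_conditions(nucleophile0 = 1e-3))$vi, numeric(1))
  expect_true(all(diff(vi) < 0))

  hs <- vapply(kx, function(k)
    hno_steady_state(ref_rates(k_nucleophile = k),
                     ref_conditions(nucleophile0 = 1e-3)), numeric(1))
  expect_true(all(diff(hs) < 0))

  o2x <- seq(50e-6, 500e-6, length.out = 7)
  hs2 <- vapply(o2x, function(o2)
    hno_steady_state(ref_rates(), ref_conditions(O2 = o2)), numeric(1))
  expect_true(all(diff(hs2) < 0))
})

test_that("flux partition accounts exactly for every HNO equivalent", {
  # control run: O2 takes almost everything, dimerization is a ~1% channel
  tr <- integrate_full_model(ref_rates(), ref_conditions(),
                             time_grid = seq(0, 600, 5))
  fr <- flux_partition(tr)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_equal(fr[["nucleophile"]], 0)
  # frozen oracle value for the reference control window
  expect_equal(fr[["dimerization"]], 0.01231, tolerance = 1e-2)

  # no dimerization channel when k_dim = 0
  tr0 <- integrate_full_model(ref_rates(k_dim = 0), ref_conditions(),
                              time_grid = seq(0, 600, 20))
  expect_identical(flux_partition(tr0)[["dimerization"]], 0)

  # matched channels split the flux evenly
  tre <- integrate_full_model(ref_rates(k_nucleophile = 1.8e4),
                              ref_conditions(nucleophile0 = 225e-6),
                              time_grid = seq(0, 600, 5))
  fre <- flux_partition(tre)
  expect_lt(abs(fre[["O2"]] - fre[["nucleophile"]]), 0.01)
  # with a scavenger at work the dimerization channel drops below 1%
  expect_lt(fre[["dimerization"]], 0.01)

  # nothing consumed, nothing to partition
  trn <- integrate_full_model(ref_rates(k_AS = 0), ref_conditions(),
                              time_grid = c(0, 1, 2))
  expect_error(flux_partition(trn), "no HNO was consumed")
})

test_that("the steady-state rate law tracks the full model pointwise", {
  # instantaneous fluorescein production on the ODE trajectory versus the
  # closed form evaluated at the instantaneous donor and scavenger pools
  for (cs in list(c(k = 0, nuc = 0), c(k = 10, nuc = 1e-2),
                  c(k = 2.2e3, nuc = 1e-3), c(k = 1e5, nuc = 1e-4),
                  c(k = 1e5, nuc = 1e-2))) {
    rc <- ref_rates(k_nucleophile = cs[["k"]])
    cond <- ref_conditions(nucleophile0 = cs[["nuc"]])
    tr <- integrate_full_model(rc, cond, time_grid = seq(0, 600, 10))
    win <- tr$time_s >= 60
    rate_ode <- rc$k_FlBA * tr$FlBA[win] * tr$ONOO[win]
    rate_qssa <- rc$k_AS * tr$AS[win] * (rc$k_O2 * cond$O2) /
      (rc$k_nucleophile * tr$nucleophile[win] + rc$k_O2 * cond$O2)
    expect_lt(max(abs(rate_ode / rate_qssa - 1)), 0.05)
  }
})

test_that("dynamic-oxygen mode depletes the O2 pool as bookkept", {
  tr <- integrate_full_model(ref_rates(), ref_conditions(o2_clamped = FALSE),
                             time_grid = seq(0, 600, 20))
  n <- nrow(tr)
  consumed <- 225e-6 - tr$O2[n]
  expect_gt(consumed, 0)
  # every O2 consumed made one peroxynitrite
  expect_equal(consumed, tr$ONOO[n] + tr$NO2[n], tolerance = 1e-6)
  # bounded by total donor conversion (<= 9% of the pool)
  expect_lt(consumed, 0.09 * 225e-6)
})
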