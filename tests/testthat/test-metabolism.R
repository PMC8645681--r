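test_that("microsomal Vmax scales to the organ level by the unit-conversion chain", {
  p <- phys_mean; p$mppgl <- 40; p$liver_weight <- 1800
  # 39.1 pmol/min/mg x 40 mg/g x 1800 g x 60 min/h x 397.48e-12 g/pmol
  expect_equal(scale_vmax_to_organ(list(vmax = 39.1, km = 2.18), p, 397.48),
               67.14, tolerance = 1e-3)
  expect_equal(scale_vmax_to_organ(list(vmax = 39.1, km = 2.18), p, 397.48, 0), 0)
  # linear in MPPGL and liver weight
  p2 <- p; p2$mppgl <- 80
  expect_equal(scale_vmax_to_organ(list(vmax = 39.1, km = 2.18), p2, 397.48),
               2 * scale_vmax_to_organ(list(vmax = 39.1, km = 2.18), p, 397.48))
})

test_that("multi-enzyme saturable rate has the Michaelis-Menten limits", {
  vmax <- c(CYP3A4 = 60, CYP3A5 = 5, CYP2D6 = 15)
  km <- c(CYP3A4 = 2.0, CYP3A5 = 1.9, CYP2D6 = 1.4)
  # first-order limit: rate/Cu -> sum(Vmax/Km)
  cu <- 1e-6
  expect_equal(metabolic_rate(cu, vmax, km) / cu, sum(vmax / km),
               tolerance = 1e-5)
  # saturation: rate -> sum(Vmax)
  expect_equal(metabolic_rate(1e9, vmax, km), sum(vmax), tolerance = 1e-6)
  # competitive inhibition at Iu/Ki = 9 inflates Km tenfold; in the linear
  # range the rate drops tenfold
  iu <- c(CYP3A4 = 9, CYP3A5 = 9, CYP2D6 = 9)
  ki <- c(CYP3A4 = 1, CYP3A5 = 1, CYP2D6 = 1)
  expect_equal(metabolic_rate(cu, vmax, km, inhibitor_unbound = iu, ki = ki),
               metabolic_rate(cu, vmax, km) / 10, tolerance = 1e-4)
})

test_that("metabolic rate equals a brute-force per-enzyme sum on random inputs", {
  set.seed(31)
  for (r in 1:20) {
    ne <- sample(1:4, 1)
    vmax <- stats::setNames(runif(ne, 1, 100), paste0("E", seq_len(ne)))
    km <- stats::setNames(runif(ne, 0.5, 5), names(vmax))
    E <- stats::setNames(runif(ne, 0, 2), names(vmax))
    iu <- stats::setNames(runif(ne, 0, 5), names(vmax))
    ki <- stats::setNames(runif(ne, 0.1, 10), names(vmax))
    cu <- runif(1, 0, 10)
    brute <- 0
    for (e in names(vmax))
      brute <- brute + E[[e]] * vmax[[e]] * cu /
        (km[[e]] * (1 + iu[[e]] / ki[[e]]) + cu)
    expect_equal(metabolic_rate(cu, vmax, km, E, iu, ki), brute,
                 tolerance = 1e-10)
  }
})

test_that("enzyme turnover has the expected fixed points and closed-form steady states", {
  kdeg <- 0.0193
  # baseline fixed point at E = 1 without perpetrator
  expect_equal(enzyme_turnover_rhs(1, 0, kdeg), 0)
  expect_gt(enzyme_turnover_rhs(0.5, 0, kdeg), 0)   # recovery towards 1
  # pure induction at saturating exposure: steady state E = 1 + IndMax
  expect_equal(enzyme_turnover_rhs(1 + 8, 1e9, kdeg, ind_max = 8, ind_c50 = 0.3),
               0, tolerance = 1e-6)
  # pure inactivation at constant exposure: E_ss = kdeg/(kdeg + lambda),
  # cross-checked against numerical integration of the turnover equation
  iu <- 0.4; kinact <- 2; k_i <- 4
  lambda <- kinact * iu / (k_i + iu)
  ess <- kdeg / (kdeg + lambda)
  traj <- deSolve::lsoda(c(E = 1), seq(0, 600, 10), function(t, y, p)
    list(enzyme_turnover_rhs(y, iu, kdeg, kinact = kinact, k_i = k_i)), NULL)
  expect_equal(unname(traj[nrow(traj), "E"]), ess, tolerance = 1e-5)
})

test_that("renal clearance is glomerular filtration of unbound drug", {
  expect_equal(renal_clearance(0.076, 120), 0.5472, tolerance = 1e-12)
  expect_equal(renal_clearance(0.076, 0), 0)
  expect_equal(renal_clearance(2 * 0.076, 120), 2 * renal_clearance(0.076, 120))
  expect_equal(renal_clearance(0.076, 240), 2 * renal_clearance(0.076, 120))
})

test_that("perpetrator forcing follows one-compartment superposition", {
  p <- perpetrator_model("x", molecular_weight = 500, fu = 0.2, ka = 500,
                         v_f = 100, cl_f = 10, dose = 200, schedule = "qd",
                         days = 10, interactions = list(CYP3A4 = list(ki = 1)))
  expect_equal(perpetrator_concentration(p, 0), 0)
  # near the IV-bolus limit (huge ka): C(t) = D/V exp(-ke t)
  t1 <- 6
  expect_equal(perpetrator_concentration(p, t1, unbound = FALSE),
               200 / 100 * exp(-0.1 * t1), tolerance = 1e-3)
  # steady-state accumulation ratio at interval tau: 1/(1 - exp(-ke tau))
  tau <- 24; ke <- 10 / 100
  racc <- 1 / (1 - exp(-ke * tau))
  trough1 <- perpetrator_concentration(p, tau - 1e-9, unbound = FALSE)
  trough_ss <- perpetrator_concentration(p, 10 * tau - 1e-9, unbound = FALSE)
  expect_equal(trough_ss / trough1, racc, tolerance = 1e-3)
  # unbound output converts by fu and molecular weight
  expect_equal(perpetrator_concentration(p, t1),
               perpetrator_concentration(p, t1, unbound = FALSE) * 0.2 * 1000 / 500)
})

test_that("perpetrator constructor validates regimen and interaction terms", {
  expect_error(perpetrator_model("x", 500, 0.2, 1, 100, 10, 200, "qd", 5,
                                 interactions = list(CYP3A4 = list(foo = 1))),
               "mechanism")
  p <- load_perpetrator("erythromycin")
  expect_s3_class(p, "perpetrator")
  expect_equal(p$schedule, "qid")
  expect_length(p$dose_times, 4 * p$days)
  p2 <- load_perpetrator("erythromycin", days = 2)
  expect_length(p2$dose_times, 8)
})
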