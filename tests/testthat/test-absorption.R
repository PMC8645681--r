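test_that("dissolution rate vanishes without solid or at saturation and is linear in the driving force", {
  expect_equal(dissolution_rate(0, 0, 0.5, 1.2), 0)
  expect_equal(dissolution_rate(100, 0.5, 0.5, 1.2), 0)
  r0 <- dissolution_rate(100, 0, 0.5, 1.2)
  r_half <- dissolution_rate(100, 0.25, 0.5, 1.2)
  expect_equal(r0, 2 * r_half, tolerance = 1e-12)
  # supersaturated input is clamped, never negative
  expect_equal(dissolution_rate(100, 1.0, 0.5, 1.2), 0)
  expect_error(dissolution_rate(100, 0, -1, 1.2), ">= 0")
})

test_that("luminal solubility follows the ionization relation with a cap", {
  # far above pKa1 the solubility reduces to the intrinsic value
  expect_equal(segment_solubility(0.2, 12, apa), 0.2, tolerance = 1e-3)
  # at pH = pKa1 the amplification is 1/neutral_fraction (oracle value)
  expect_equal(segment_solubility(0.2, 6.6, apa), 0.2 / 0.487498,
               tolerance = 1e-4)
  expect_gt(segment_solubility(0.2, 5.0, apa), segment_solubility(0.2, 7.4, apa))
  # acidic pH hits the configured cap
  expect_equal(segment_solubility(0.2, 1.5, apa), apa$solubility_cap)
})

test_that("absorption rate constant is the permeability-radius relation", {
  # 2 x 0.80e-4 cm/s / 1 cm x 3600 s/h
  expect_equal(absorption_rate_constant(0.80, 1.0), 0.576, tolerance = 1e-12)
  expect_equal(absorption_rate_constant(1.60, 1.0),
               2 * absorption_rate_constant(0.80, 1.0))
  expect_equal(absorption_rate_constant(0.80, 2.0),
               absorption_rate_constant(0.80, 1.0) / 2)
})

test_that("gut derivatives conserve mass instantaneously", {
  g <- pbpkddi:::gut_parameters(apa, phys_mean)
  solid <- c(500, 40, 30, 20, 10, 5, 2, 1, 0.5)
  dis <- c(10, 2, 3, 2, 1, 0.5, 0.2, 0.1, 0.05)
  d <- gut_rhs(solid, dis, g)
  net <- sum(d$d_solid) + sum(d$d_dissolved) + d$absorption_flux + d$fecal_flux
  expect_equal(net, 0, tolerance = 1e-10)
})

test_that("impermeable gut sends the whole dose to feces", {
  cmp0 <- load_compound(peff_human = 1e-12, papp_caco2 = 1e-16)
  m <- pbpk_model(cmp0, phys_mean, composition = tissue_comp)
  s <- simulate(m, regimen = regimen(100), window = 400, dt_out = 1)
  expect_equal(unname(s$ledger[["fecal"]]), 100, tolerance = 5e-3)
  expect_lt(max(s$conc), 1e-6)
})

test_that("unlimited solubility and fast dissolution drive absorption towards its permeability cap", {
  fast <- linear_compound(kd = 1000)
  m <- pbpk_model(fast, phys_mean, composition = tissue_comp,
                  gut_first_pass = FALSE)
  s <- simulate(m, regimen = regimen(100), window = 200, dt_out = 0.5)
  fa_fast <- s$ledger[["absorbed"]] / 100
  expect_gt(fa_fast, 0.5)
  # packaged (solubility-limited) compound absorbs a far smaller fraction
  s_cal <- simulate(pbpk_model(apa, phys_mean, composition = tissue_comp),
                    regimen = regimen(100), window = 200, dt_out = 0.5)
  expect_lt(s_cal$ledger[["absorbed"]] / 100, fa_fast)
})

test_that("fraction absorbed is non-decreasing in permeability and solubility and sub-proportional in dose", {
  fa <- function(cmp, dose = 750) {
    s <- simulate(pbpk_model(cmp, phys_mean, composition = tissue_comp),
                  regimen = regimen(dose), window = 150, dt_out = 0.5)
    s$ledger[["absorbed"]] / dose
  }
  base <- fa(apa)
  expect_gt(fa(load_compound(peff_human = 1.6, papp_caco2 = apa$papp_caco2)), base)
  expect_gt(fa(load_compound(intrinsic_solubility = 0.36)), base)
  # the calibrated solubility-limited regime: dose-normalized absorption
  # falls from 250 to 750 mg
  expect_lt(base, fa(apa, dose = 250))
})

test_that("the dissolution coefficient is recovered from a tabulated profile", {
  kd_true <- 0.8; dose <- 250
  tt <- seq(0.25, 6, by = 0.25)
  f <- 1 - pmax(0, 1 - kd_true * tt / (3 * dose^(1 / 3)))^3
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_h = tt, fraction_dissolved = f), csv,
                   row.names = FALSE)
  prof <- load_dissolution_profile(csv)
  expect_equal(fit_dissolution_coefficient(prof, dose), kd_true,
               tolerance = 1e-4)
  bad <- data.frame(time_h = c(1, 2), fraction_dissolved = c(0.9, 0.4))
  csv2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, csv2, row.names = FALSE)
  expect_error(load_dissolution_profile(csv2), "non-decreasing")
})
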