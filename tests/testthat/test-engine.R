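test_that("total drug is conserved when every elimination pathway is silenced", {
  m <- pbpk_model(apa, no_elimination(), composition = tissue_comp,
                  gut_first_pass = FALSE)
  s <- simulate(m, regimen = regimen(50, route = "iv"), window = 120,
                dt_out = 1, keep_states = TRUE)
  totals <- rowSums(s$states[, 2:33])
  expect_lt(max(abs(totals[-1] - 50)) / 50, 1e-6)
  expect_lt(s$mass_balance_rel_error, 1e-6)
})

test_that("compiled and reference derivatives integrate to the same solution", {
  m <- pbpk_model(apa, phys_mean, composition = tissue_comp)
  sc <- simulate(m, regimen = regimen(250), dt_out = 0.5)
  sr <- simulate(m, regimen = regimen(250), dt_out = 0.5, engine = "r")
  expect_lt(max(abs(sc$conc - sr$conc)) / max(sr$conc), 1e-4)
  expect_equal(nca(sc)$auc, nca(sr)$auc, tolerance = 1e-5)
})

test_that("the forced-linear system matches an eigen-decomposition solution", {
  phys <- phys_mean
  m <- pbpk_model(apa, phys, composition = tissue_comp, force_linear = TRUE,
                  gut_first_pass = FALSE)
  p <- m$params
  # independent construction of the linear disposition matrix (amount basis)
  n <- 14
  M <- matrix(0, n, n)
  for (i in seq_len(12)) {
    if (i == 7 || i == 8) next
    M[i, 13] <- M[i, 13] + p$q[i] / p$v_art
    M[i, i] <- M[i, i] - p$q[i] * p$bp / p$kp[i] / p$v[i]
  }
  M[6, 13] <- M[6, 13] - p$clr / p$bp / p$v_art          # renal filtration
  M[7, 13] <- p$q[7] / p$v_art
  for (j in c(4, 11, 12))
    M[7, j] <- p$q[j] * p$bp / p$kp[j] / p$v[j]
  M[7, 7] <- -p$q_liver_out * p$bp / p$kp[7] / p$v[7] -
    sum(p$vmax_org / p$km) * p$fu / p$kp[7] * 1000 / p$mw / p$v[7]
  M[8, 14] <- p$co / p$v_ven
  M[8, 8] <- -p$co * p$bp / p$kp[8] / p$v[8]
  M[13, 8] <- p$co * p$bp / p$kp[8] / p$v[8]
  M[13, 13] <- -p$co / p$v_art
  for (i in c(1, 2, 3, 5, 6, 9, 10))
    M[14, i] <- p$q[i] * p$bp / p$kp[i] / p$v[i]
  M[14, 7] <- p$q_liver_out * p$bp / p$kp[7] / p$v[7]
  M[14, 14] <- -p$co / p$v_ven
  ev <- eigen(M)
  x0 <- numeric(n); x0[14] <- 50
  coef <- solve(ev$vectors, x0)
  conc_at <- function(t) {
    x <- Re(ev$vectors %*% (coef * exp(ev$values * t)))
    x[14] / p$v_ven / p$bp * 1000
  }
  s <- simulate(m, regimen = regimen(50, route = "iv"), dt_out = 0.1)
  for (t in c(1, 6, 24, 48)) {
    i <- which.min(abs(s$times - t))
    expect_equal(s$conc[i], conc_at(t), tolerance = 5e-3)
  }
})

test_that("a steady infusion settles at rate over clearance", {
  m <- pbpk_model(apa, phys_mean, composition = tissue_comp,
                  force_linear = TRUE)
  # dense early grid: the post-bolus distribution spike carries real exposure
  iv <- simulate(m, regimen = regimen(20, route = "iv"), window = 600,
                 dt_out = 0.02)
  cl <- 20 / (nca(iv)$auc / 1000)        # L/h from the IV exposure
  inf <- simulate(m, regimen = regimen(0), window = 600, dt_out = 1,
                  infusion = c(10, 0, 600))
  css <- inf$conc[length(inf$conc)]
  expect_equal(css, 10 / cl * 1000, tolerance = 0.02)
})

test_that("zero dose yields identically zero concentrations", {
  m <- pbpk_model(apa, phys_mean, composition = tissue_comp)
  s <- simulate(m, regimen = regimen(0), window = 24, dt_out = 1)
  expect_true(all(s$conc == 0))
})

test_that("halving the integrator tolerances moves the exposure by less than 0.1 percent", {
  m <- pbpk_model(apa, phys_mean, composition = tissue_comp)
  a1 <- nca(simulate(m, regimen = regimen(750), rtol = 1e-6, atol = 1e-9))$auc
  a2 <- nca(simulate(m, regimen = regimen(750), rtol = 5e-7, atol = 5e-10))$auc
  expect_lt(abs(a1 - a2) / a1, 1e-3)
})

test_that("the mean healthy subject peaks inside the expected window after 250 mg", {
  s <- mean_sim(250)
  n <- nca(s)
  expect_gte(n$tmax, 1); expect_lte(n$tmax, 4)
  expect_gt(n$cmax, 0)
})

test_that("superposition holds in the forced-linear configuration", {
  cmp <- linear_compound()
  m <- pbpk_model(cmp, phys_mean, composition = tissue_comp,
                  force_linear = TRUE)
  s1 <- simulate(m, regimen = regimen(100), window = 96, dt_out = 0.1)
  s2 <- simulate(m, regimen = regimen(100, at = c(0, 24)), window = 72,
                 dt_out = 0.1)
  shift <- stats::approx(s1$times, s1$conc, xout = s2$times - 24,
                         yleft = 0, rule = 2)$y
  base <- stats::approx(s1$times, s1$conc, xout = s2$times, rule = 2)$y
  err <- max(abs(s2$conc - (base + shift))) / max(s2$conc)
  expect_lt(err, 5e-3)
})

test_that("paired arms are identical when the perpetrator has no effective mechanism", {
  null_perp <- perpetrator_model("inert", 500, 0.1, 1, 100, 10, 100, "qd", 3,
                                 interactions = list(CYP3A4 = list(ki = Inf)))
  pop <- build_population(population_spec("healthy_chinese", seed = 3), 1, 2)
  tr <- run_trial(pop, apa, regimen(250, at = 48), null_perp,
                  composition = tissue_comp, dt_out = 0.5)
  r <- ddi_ratio(exposure_summary(tr$treatment), exposure_summary(tr$reference))
  expect_equal(r$auc_ratio, 1, tolerance = 1e-6)
  expect_equal(r$cmax_ratio, 1, tolerance = 1e-6)
})

test_that("trial runner pairs subjects across arms and preserves grouping", {
  pop <- build_population(population_spec("healthy_chinese", seed = 9), 2, 2)
  perp <- load_perpetrator("quinidine", days = 2)
  tr <- run_trial(pop, apa, regimen(250, at = 24), perp,
                  composition = tissue_comp, dt_out = 0.5, window = 48)
  expect_length(tr$reference, 4)
  expect_length(tr$treatment, 4)
  expect_equal(tr$trial, rep(1:2, each = 2))
  # permuting subjects leaves the population mean profile unchanged
  mean_ref <- rowMeans(vapply(tr$reference, `[[`, numeric(length(tr$reference[[1]]$conc)), "conc"))
  perm <- sample(4)
  mean_perm <- rowMeans(vapply(tr$reference[perm], `[[`,
                               numeric(length(tr$reference[[1]]$conc)), "conc"))
  expect_equal(mean_ref, mean_perm, tolerance = 1e-12)
})
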