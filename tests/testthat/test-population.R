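test_that("degenerate variability returns the mean physiology exactly", {
  spec <- population_spec("healthy_chinese", seed = 5,
                          mean_physiology = phys_mean,
                          variability_cv = list(volumes = 0, flows = 0,
                                                cardiac_output = 0, liver = 0,
                                                mppgl = 0, enzyme_abundance = 0,
                                                gfr = 0))
  ind <- sample_individual(spec, 3)
  expect_equal(ind$organ_volumes, phys_mean$organ_volumes)
  expect_equal(ind$cardiac_output, phys_mean$cardiac_output)
  expect_equal(ind$liver_weight, phys_mean$liver_weight)
  expect_equal(ind$gfr, phys_mean$gfr)
})

test_that("sampling is reproducible and seed-sensitive", {
  spec <- population_spec("healthy_chinese", seed = 11)
  a <- sample_individual(spec, 4)
  b <- sample_individual(spec, 4)
  expect_identical(a, b)
  c <- sample_individual(spec, 5)
  expect_false(identical(a$liver_weight, c$liver_weight))
  spec2 <- population_spec("healthy_chinese", seed = 12)
  d <- sample_individual(spec2, 4)
  expect_false(identical(a$liver_weight, d$liver_weight))
  # population-level contract
  p1 <- build_population(spec, 2, 3)
  p2 <- build_population(spec, 2, 3)
  expect_identical(unclass(p1), unclass(p2))
  expect_length(p1, 6)
  expect_equal(attr(p1, "trial"), rep(1:2, each = 3))
})

test_that("sampled liver weight reproduces the specified log-normal spread", {
  spec <- population_spec("healthy_chinese", seed = 42,
                          variability_cv = list(volumes = 0, flows = 0,
                                                cardiac_output = 0, liver = 0.25,
                                                mppgl = 0, enzyme_abundance = 0,
                                                gfr = 0))
  lw <- vapply(seq_len(10000) - 1L,
               function(i) sample_individual(spec, i)$liver_weight, numeric(1))
  cv <- stats::sd(lw) / mean(lw)
  expect_gt(cv, 0.24); expect_lt(cv, 0.26)
  expect_equal(mean(lw), phys_mean$liver_weight, tolerance = 0.01)
})

test_that("blood flows are conserved after sampling and impairment scaling", {
  spec <- population_spec("hi_cp_c", seed = 2)
  for (i in 0:4) {
    ind <- sample_individual(spec, i)
    expect_equal(sum(ind$organ_blood_flows), ind$cardiac_output,
                 tolerance = 1e-9)
  }
})

test_that("albumin reduction raises the unbound fraction per the binding relation", {
  fu <- 0.076
  expect_equal(fu_adjusted(fu, 1), fu, tolerance = 1e-12)
  expect_gt(fu_adjusted(fu, 0.6), fu)
  # closed form: fu' = 1 / (1 + a (1 - fu) / fu)
  expect_equal(fu_adjusted(fu, 0.5), 1 / (1 + 0.5 * (1 - fu) / fu),
               tolerance = 1e-12)
})

test_that("impairment stages apply monotone, stage-consistent multipliers", {
  imp <- load_impairment()
  s_a <- imp$hi_cp_a$enzyme$CYP3A4
  s_b <- imp$hi_cp_b$enzyme$CYP3A4
  s_c <- imp$hi_cp_c$enzyme$CYP3A4
  expect_true(s_c < s_b && s_b < s_a && s_a <= 1)
  pa <- apply_impairment(phys_mean, "hi_cp_b")
  # pure function: input untouched
  expect_equal(phys_mean$liver_weight, 1650)
  expect_lt(pa$liver_weight, phys_mean$liver_weight)
  expect_lt(pa$albumin_scalar, 1)
  # renal stages respect the GFR definition bands
  rm_ <- apply_impairment(phys_mean, "ri_moderate")
  rs <- apply_impairment(phys_mean, "ri_severe")
  expect_gte(rm_$gfr, 30); expect_lte(rm_$gfr, 60)
  expect_lt(rs$gfr, 30)
  expect_error(apply_impairment(phys_mean, "nonsense"), "unknown impairment")
  expect_error(population_spec("not_a_population"), "unknown population")
})
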