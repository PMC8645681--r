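# Shared fixtures, loaded once per test file.
apa <- load_compound()
phys_mean <- load_physiology()
tissue_comp <- load_tissue_composition()

# compound with linear, unlimited absorption and first-order metabolism for
# the forced-linear configuration checks
linear_compound <- function(kd = 1000) {
  load_compound(intrinsic_solubility = 1e6, solubility_cap = 1e6,
                dissolution_coefficient = kd)
}

# a physiology with all elimination pathways silenced
no_elimination <- function(p = phys_mean) {
  p$enzyme_abundance[] <- 1e-12
  p$gfr <- 0
  p$clint_gut_cyp3a4 <- 0
  p
}

mean_sim <- local({
  cache <- new.env()
  function(dose = 750, ...) {
    key <- paste(dose, ...)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate(pbpk_model(apa, phys_mean,
                                          composition = tissue_comp),
                               regimen = regimen(dose), ...)
    cache[[key]]
  }
})
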