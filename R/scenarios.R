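# Trial-design registry for the interaction scenarios: victim dose (mg),
# victim dosing day, and perpetrator dosing days (perpetrator always starts
# on day 1 at t = 0).
DDI_DESIGNS <- list(
  itraconazole  = list(dose = 250, victim_day = 4, days = 6),
  rifampin      = list(dose = 750, victim_day = 6, days = 10),
  fluvoxamine   = list(dose = 750, victim_day = 4, days = 6),
  quinidine     = list(dose = 750, victim_day = 4, days = 6),
  paroxetine    = list(dose = 750, victim_day = 4, days = 6),
  erythromycin  = list(dose = 750, victim_day = 4, days = 6),
  verapamil     = list(dose = 750, victim_day = 4, days = 6),
  carbamazepine = list(dose = 750, victim_day = 8, days = 10),
  efavirenz     = list(dose = 750, victim_day = 8, days = 10),
  phenytoin     = list(dose = 750, victim_day = 8, days = 10)
)

#' Interaction trial designs
#'
#' Victim dose, victim dosing day and perpetrator dosing duration for each
#' packaged perpetrator scenario.
#'
#' @return data.frame with one row per perpetrator.
#' @export
ddi_designs <- function() {
  data.frame(perpetrator = names(DDI_DESIGNS),
             victim_dose = vapply(DDI_DESIGNS, `[[`, numeric(1), "dose"),
             victim_day = vapply(DDI_DESIGNS, `[[`, numeric(1), "victim_day"),
             perpetrator_days = vapply(DDI_DESIGNS, `[[`, numeric(1), "days"),
             row.names = NULL)
}

#' Simulate one trial arm over a population
#'
#' @param population a `pbpk_population`.
#' @param compound victim `compound_params`.
#' @param regimen victim `dose_regimen`.
#' @param perpetrator optional `perpetrator`.
#' @param composition tissue-composition table.
#' @param ... further arguments to [simulate.pbpk_model()].
#' @return List of `pbpk_sim`, one per subject.
#' @export
run_arm <- function(population, compound, regimen, perpetrator = NULL,
                    composition = load_tissue_composition(), ...) {
  lapply(population, function(phys)
    simulate(pbpk_model(compound, phys, perpetrator, composition),
             regimen = regimen, ...))
}

#' Run one named scenario
#'
#' Executes a complete scenario — single-dose exposure in a named population,
#' or a paired two-arm interaction trial per the packaged trial designs — and
#' returns its summaries.
#'
#' @param name scenario id: `healthy_750`, `healthy_250`, one of the
#'   perpetrator names (see [ddi_designs()]), or an impairment stage
#'   (`hi_cp_a`, `hi_cp_b`, `hi_cp_c`, `ri_moderate`, `ri_severe`).
#' @param seed integer seed for the virtual population.
#' @param n_trials,n_subjects trial design.
#' @param compound victim compound (packaged apatinib file by default).
#' @param dt_out reporting grid, h.
#' @param baseline optional pre-computed reference arm (list of `pbpk_sim`
#'   from a healthy population built with the same seed/design) to avoid
#'   recomputation across scenarios.
#' @param ... further arguments to [simulate.pbpk_model()].
#' @return List with scenario `kind` (`exposure`/`ddi`/`ddzi`), per-arm
#'   `exposure_summary` objects, and for paired designs the [ddi_ratio()].
#' @export
run_scenario <- function(name, seed = 1L, n_trials = 10, n_subjects = 10,
                         compound = load_compound(), dt_out = 0.1,
                         baseline = NULL, ...) {
  comp <- load_tissue_composition()
  healthy <- function() build_population(
    population_spec("healthy_chinese", seed = seed), n_trials, n_subjects)
  if (name %in% c("healthy_750", "healthy_250")) {
    dose <- if (name == "healthy_750") 750 else 250
    sims <- run_arm(healthy(), compound, regimen(dose), NULL, comp,
                    dt_out = dt_out, ...)
    pop <- healthy()
    return(list(kind = "exposure", name = name,
                summary = exposure_summary(sims, attr(pop, "trial")),
                sims = sims))
  }
  if (name %in% names(DDI_DESIGNS)) {
    d <- DDI_DESIGNS[[name]]
    perp <- load_perpetrator(name, days = d$days)
    pop <- healthy()
    ref <- if (is.null(baseline))
      run_arm(pop, compound, regimen(d$dose), NULL, comp, dt_out = dt_out, ...)
    else baseline
    trt <- run_arm(pop, compound,
                   regimen(d$dose, at = (d$victim_day - 1) * 24), perp, comp,
                   dt_out = dt_out, ...)
    sr <- exposure_summary(ref, attr(pop, "trial"))
    st <- exposure_summary(trt, attr(pop, "trial"))
    return(list(kind = "ddi", name = name, reference = sr, treatment = st,
                ratio = ddi_ratio(st, sr)))
  }
  if (name %in% c("hi_cp_a", "hi_cp_b", "hi_cp_c", "ri_moderate", "ri_severe")) {
    pop <- build_population(population_spec(name, seed = seed),
                            n_trials, n_subjects)
    sims <- run_arm(pop, compound, regimen(750), NULL, comp,
                    dt_out = dt_out, ...)
    st <- exposure_summary(sims, attr(pop, "trial"))
    out <- list(kind = "ddzi", name = name, summary = st)
    if (!is.null(baseline)) {
      sh <- if (inherits(baseline, "exposure_summary")) baseline
            else exposure_summary(baseline)
      out$healthy <- sh
      out$ratio <- ddi_ratio(st, sh, paired = FALSE)
    }
    return(out)
  }
  stop("unknown scenario: ", name, call. = FALSE)
}

#' Reproduce the full result-table bundle
#'
#' Runs every packaged scenario — healthy-volunteer verification at 750 and
#' 250 mg, the itraconazole/rifampin interaction verification, the
#' eight-perpetrator interaction panel, and the five impairment populations —
#' and assembles the exposure, interaction and disease tables with fold
#' errors against the packaged observed values.
#'
#' @param seed integer seed.
#' @param n_trials,n_subjects trial design (the study design is 10 x 10).
#' @param outdir optional directory; when given, tables are written as
#'   `table3.csv` ... `table6.csv`.
#' @param perpetrators subset of perpetrator scenarios to run (all ten by
#'   default).
#' @param stages subset of impairment stages to run (all five by default).
#' @param dt_out reporting grid, h.
#' @param ... further arguments to [simulate.pbpk_model()].
#' @return Named list of data.frames `table3`, `table4`, `table5`, `table6`.
#' @export
reproduce_tables <- function(seed = 1L, n_trials = 10, n_subjects = 10,
                             outdir = NULL,
                             perpetrators = names(DDI_DESIGNS),
                             stages = c("hi_cp_a", "hi_cp_b", "hi_cp_c",
                                        "ri_moderate", "ri_severe"),
                             dt_out = 0.1, ...) {
  compound <- load_compound()
  comp <- load_tissue_composition()
  observed <- load_observed()
  pop <- build_population(population_spec("healthy_chinese", seed = seed),
                          n_trials, n_subjects)
  base750 <- run_arm(pop, compound, regimen(750), NULL, comp,
                     dt_out = dt_out, ...)
  base250 <- run_arm(pop, compound, regimen(250), NULL, comp,
                     dt_out = dt_out, ...)
  s750 <- exposure_summary(base750, attr(pop, "trial"))
  s250 <- exposure_summary(base250, attr(pop, "trial"))

  fe <- function(sim, obs) fold_error(sim, obs)
  obs_get <- function(sc, par)
    observed$observed[observed$scenario == sc & observed$parameter == par]
  mu7 <- attr(s750, "mean"); mu2 <- attr(s250, "mean")
  table3 <- data.frame(
    dose_level = c("750 mg", "250 mg"),
    tmax = c(mu7[["tmax"]], mu2[["tmax"]]),
    cmax = c(mu7[["cmax"]], mu2[["cmax"]]),
    auc = c(mu7[["auc"]], mu2[["auc"]]),
    tmax_observed = c(obs_get("healthy_750", "tmax"), obs_get("healthy_250", "tmax")),
    cmax_observed = c(obs_get("healthy_750", "cmax"), obs_get("healthy_250", "cmax")),
    auc_observed = c(obs_get("healthy_750", "auc"), obs_get("healthy_250", "auc")))
  table3$tmax_fold_error <- fe(table3$tmax, table3$tmax_observed)
  table3$cmax_fold_error <- fe(table3$cmax, table3$cmax_observed)
  table3$auc_fold_error <- fe(table3$auc, table3$auc_observed)

  ddi_rows <- lapply(perpetrators, function(nm) {
    d <- DDI_DESIGNS[[nm]]
    perp <- load_perpetrator(nm, days = d$days)
    ref <- if (d$dose == 750) s750 else s250
    trt <- exposure_summary(
      run_arm(pop, compound, regimen(d$dose, at = (d$victim_day - 1) * 24),
              perp, comp, dt_out = dt_out, ...), attr(pop, "trial"))
    r <- ddi_ratio(trt, ref)
    data.frame(perpetrator = nm, victim_dose = d$dose,
               cmax_ratio = r$cmax_ratio, auc_ratio = r$auc_ratio)
  })
  ddi <- do.call(rbind, ddi_rows)
  verification <- c("itraconazole", "rifampin")
  table4 <- ddi[ddi$perpetrator %in% verification, ]
  if (nrow(table4)) {
    table4$cmax_ratio_observed <- vapply(table4$perpetrator, obs_get,
                                         numeric(1), par = "cmax_ratio")
    table4$auc_ratio_observed <- vapply(table4$perpetrator, obs_get,
                                        numeric(1), par = "auc_ratio")
    table4$cmax_ratio_s_over_o <- table4$cmax_ratio / table4$cmax_ratio_observed
    table4$auc_ratio_s_over_o <- table4$auc_ratio / table4$auc_ratio_observed
  }
  table5 <- ddi[!ddi$perpetrator %in% verification, ]
  if (nrow(table5))
    table5$within_2fold_change <- table5$auc_ratio <= 2 & table5$auc_ratio >= 0.5

  ddzi_rows <- lapply(stages, function(st) {
    popd <- build_population(population_spec(st, seed = seed),
                             n_trials, n_subjects)
    sd <- exposure_summary(run_arm(popd, compound, regimen(750), NULL, comp,
                                   dt_out = dt_out, ...), attr(popd, "trial"))
    r <- ddi_ratio(sd, s750, paired = FALSE)
    data.frame(subjects = st, cmax = attr(sd, "mean")[["cmax"]],
               auc = attr(sd, "mean")[["auc"]],
               cmax_ratio = r$cmax_ratio, auc_ratio = r$auc_ratio)
  })
  table6 <- rbind(
    data.frame(subjects = "healthy", cmax = mu7[["cmax"]], auc = mu7[["auc"]],
               cmax_ratio = NA_real_, auc_ratio = NA_real_),
    do.call(rbind, ddzi_rows))

  out <- list(table3 = table3, table4 = table4, table5 = table5,
              table6 = table6)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(outdir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  out
}
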