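#' Virtual-subject physiology
#'
#' Organ volumes (L), arterial blood-flow fractions, cardiac output (L/h),
#' liver weight (g), microsomal protein per gram liver (MPPGL), enzyme
#' abundance scalars, hematocrit, serum-albumin scalar (1 = healthy mean;
#' rescales the fraction unbound), glomerular filtration rate (mL/min), gut
#' segment geometry/transit, and enterocyte CYP3A4 parameters for one virtual
#' subject. Blood-flow fractions are renormalized so organ flows sum exactly
#' to cardiac output.
#'
#' @param body_weight kg.
#' @param cardiac_output L/h.
#' @param organ_volumes named vector (L) over the 12 perfused tissues plus
#'   `arterial_blood` and `venous_blood`.
#' @param blood_flow_fractions named vector of arterial flow fractions over
#'   the 11 arterially supplied tissues (liver entry = hepatic artery).
#' @param liver_weight g.
#' @param mppgl mg microsomal protein per g liver.
#' @param enzyme_abundance named scalars (CYP3A4/CYP3A5/CYP2D6), 1 = healthy.
#' @param hematocrit fraction in (0.2, 0.6).
#' @param albumin_scalar dimensionless, > 0.
#' @param gfr mL/min, >= 0.
#' @param gut_segments data.frame with columns `names`, `volume_ml`, `ph`,
#'   `transit_h`, `radius_cm`, `peff_scalar` (9 rows, stomach first).
#' @param enterocyte_cyp3a4_scalar dimensionless.
#' @param clint_gut_cyp3a4 L/h unbound intrinsic gut-wall clearance.
#' @param q_villi L/h mucosal blood flow.
#' @param kdeg named enzyme degradation constants (1/h):
#'   `liver_CYP3A4`, `liver_CYP3A5`, `liver_CYP2D6`, `gut_CYP3A4`.
#' @return An object of class `physiology`.
#' @export
physiology <- function(body_weight, cardiac_output, organ_volumes,
                       blood_flow_fractions, liver_weight, mppgl,
                       enzyme_abundance, hematocrit, albumin_scalar = 1,
                       gfr, gut_segments, enterocyte_cyp3a4_scalar = 1,
                       clint_gut_cyp3a4 = 0, q_villi = 18, kdeg) {
  tissues <- c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
               "lung", "muscle", "skin", "spleen", "pancreas")
  stopifnot(all(c(tissues, "arterial_blood", "venous_blood") %in%
                  names(organ_volumes)),
            all(organ_volumes > 0), cardiac_output > 0,
            all(blood_flow_fractions > 0), liver_weight > 0, mppgl > 0,
            hematocrit > 0.2, hematocrit < 0.6, gfr >= 0,
            albumin_scalar > 0, all(gut_segments$transit_h > 0))
  arterial <- setdiff(tissues, "lung")
  stopifnot(all(arterial %in% names(blood_flow_fractions)))
  fr <- blood_flow_fractions[arterial]
  flows <- fr / sum(fr) * cardiac_output      # renormalize: sum == CO exactly
  structure(list(
    body_weight = body_weight, cardiac_output = cardiac_output,
    organ_volumes = organ_volumes[c(tissues, "arterial_blood", "venous_blood")],
    organ_blood_flows = flows, liver_weight = liver_weight, mppgl = mppgl,
    enzyme_abundance = enzyme_abundance, hematocrit = hematocrit,
    albumin_scalar = albumin_scalar, gfr = gfr, gut_segments = gut_segments,
    enterocyte_cyp3a4_scalar = enterocyte_cyp3a4_scalar,
    clint_gut_cyp3a4 = clint_gut_cyp3a4, q_villi = q_villi, kdeg = kdeg
  ), class = "physiology")
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("Virtual subject: BW %.1f kg, CO %.0f L/h, liver %.0f g, GFR %.0f mL/min\n",
              x$body_weight, x$cardiac_output, x$liver_weight, x$gfr))
  cat(sprintf("  hematocrit %.2f | albumin scalar %.2f | MPPGL %.0f\n",
              x$hematocrit, x$albumin_scalar, x$mppgl))
  cat("  enzyme abundance:",
      paste(sprintf("%s %.2f", names(x$enzyme_abundance), x$enzyme_abundance),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fraction unbound under a reduced-albumin state
#'
#' fu' = 1 / (1 + albumin_scalar x (1 - fu) / fu); equals fu at scalar 1 and
#' rises as albumin falls.
#'
#' @param fu healthy fraction unbound in (0, 1].
#' @param albumin_scalar albumin level relative to healthy, > 0.
#' @return Adjusted fraction unbound.
#' @export
fu_adjusted <- function(fu, albumin_scalar) {
  1 / (1 + albumin_scalar * (1 - fu) / fu)
}

#' Population specification
#'
#' Binds a mean physiology to a named population, between-subject coefficients
#' of variation, a disease stage, and a seed. Sampling is log-normal on
#' positive parameters with the stated CVs; disease multipliers are applied
#' after sampling.
#'
#' @param name one of `healthy_chinese`, `hi_cp_a`, `hi_cp_b`, `hi_cp_c`,
#'   `ri_moderate`, `ri_severe`.
#' @param seed integer seed governing all between-subject sampling.
#' @param mean_physiology healthy mean `physiology` (the packaged fixture by
#'   default).
#' @param variability_cv named list of coefficients of variation:
#'   `volumes`, `flows`, `cardiac_output`, `liver`, `mppgl`,
#'   `enzyme_abundance`, `gfr`.
#' @param impairment disease multiplier table from [load_impairment()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name = "healthy_chinese", seed = 1L,
                            mean_physiology = load_physiology(),
                            variability_cv = list(
                              volumes = 0.20, flows = 0.20,
                              cardiac_output = 0.15, liver = 0.20,
                              mppgl = 0.30, enzyme_abundance = 0.30,
                              gfr = 0.20),
                            impairment = load_impairment()) {
  known <- c("healthy_chinese", "hi_cp_a", "hi_cp_b", "hi_cp_c",
             "ri_moderate", "ri_severe")
  if (!name %in% known)
    stop("unknown population name: ", name, call. = FALSE)
  stopifnot(all(unlist(variability_cv) >= 0))
  structure(list(name = name, seed = as.integer(seed),
                 mean_physiology = mean_physiology,
                 variability_cv = variability_cv,
                 impairment = impairment),
            class = "population_spec")
}

# log-normal draw with arithmetic mean `m` and coefficient of variation `cv`
rlnorm_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  m * exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Sample one virtual subject
#'
#' Deterministic in (spec seed, subject index): organ volumes, blood flows,
#' cardiac output, liver weight (with volume), MPPGL, enzyme abundances and
#' GFR receive independent log-normal perturbations at the specified CVs;
#' flows are then renormalized to cardiac output; body weight is rescaled with
#' total sampled volume; finally the stage-specific disease multipliers are
#' applied.
#'
#' @param spec a `population_spec`.
#' @param subject_index integer >= 0.
#' @return A `physiology` object.
#' @export
sample_individual <- function(spec, subject_index = 0L) {
  stopifnot(inherits(spec, "population_spec"), subject_index >= 0)
  m <- spec$mean_physiology
  cv <- spec$variability_cv
  sub_seed <- (abs(spec$seed) * 1009L + as.integer(subject_index) * 7919L + 1L) %%
    2147483562L
  phys <- with_seed(sub_seed, {
    vols <- m$organ_volumes
    liver_f <- rlnorm_cv(1, 1, cv$liver)
    for (t in names(vols)) {
      f <- if (t == "liver") liver_f else rlnorm_cv(1, 1, cv$volumes)
      vols[t] <- vols[t] * f
    }
    co <- rlnorm_cv(1, m$cardiac_output, cv$cardiac_output)
    fr <- m$organ_blood_flows * vapply(m$organ_blood_flows,
                                       function(.) rlnorm_cv(1, 1, cv$flows),
                                       numeric(1))
    enz <- vapply(m$enzyme_abundance,
                  function(e) rlnorm_cv(1, e, cv$enzyme_abundance), numeric(1))
    physiology(
      body_weight = m$body_weight * sum(vols) / sum(m$organ_volumes),
      cardiac_output = co, organ_volumes = vols,
      blood_flow_fractions = fr,
      liver_weight = m$liver_weight * liver_f,
      mppgl = rlnorm_cv(1, m$mppgl, cv$mppgl),
      enzyme_abundance = enz, hematocrit = m$hematocrit,
      albumin_scalar = m$albumin_scalar,
      gfr = rlnorm_cv(1, m$gfr, cv$gfr),
      gut_segments = m$gut_segments,
      enterocyte_cyp3a4_scalar = m$enterocyte_cyp3a4_scalar,
      clint_gut_cyp3a4 = m$clint_gut_cyp3a4, q_villi = m$q_villi,
      kdeg = m$kdeg)
  })
  if (spec$name != "healthy_chinese")
    phys <- apply_impairment(phys, spec$name, spec$impairment)
  phys
}

#' Apply a hepatic- or renal-impairment stage to a physiology
#'
#' Pure function: returns a modified copy with the packaged stage multipliers
#' applied to liver size (weight and volume), hepatic enzyme abundances,
#' enterocyte CYP3A4, serum albumin (raising the unbound fraction), hematocrit,
#' GFR and hepatic blood flows (hepatic artery plus portal organs, with
#' cardiac output reduced by the removed flow so conservation holds).
#'
#' @param mean_healthy a `physiology` object (healthy, mean or sampled).
#' @param stage one of `hi_cp_a`, `hi_cp_b`, `hi_cp_c`, `ri_moderate`,
#'   `ri_severe`.
#' @param impairment multiplier table from [load_impairment()].
#' @return A `physiology` object.
#' @export
apply_impairment <- function(mean_healthy, stage,
                             impairment = load_impairment()) {
  if (!stage %in% names(impairment))
    stop("unknown impairment stage: ", stage, call. = FALSE)
  s <- impairment[[stage]]
  p <- mean_healthy
  p$liver_weight <- p$liver_weight * s$liver_size
  p$organ_volumes[["liver"]] <- p$organ_volumes[["liver"]] * s$liver_size
  for (e in names(s$enzyme))
    p$enzyme_abundance[[e]] <- p$enzyme_abundance[[e]] * s$enzyme[[e]]
  p$enterocyte_cyp3a4_scalar <- p$enterocyte_cyp3a4_scalar * s$enterocyte_cyp3a4
  p$albumin_scalar <- p$albumin_scalar * s$albumin
  p$hematocrit <- max(0.201, p$hematocrit * s$hematocrit)
  p$gfr <- p$gfr * s$gfr
  hep <- c("liver", "gut", "spleen", "pancreas")
  flows <- p$organ_blood_flows
  removed <- sum(flows[hep]) * (1 - s$hepatic_flow)
  flows[hep] <- flows[hep] * s$hepatic_flow
  p$organ_blood_flows <- flows
  p$cardiac_output <- p$cardiac_output - removed
  p
}

#' Build a virtual population grouped in trials
#'
#' @param spec a `population_spec`.
#' @param n_trials,n_subjects trial design (>= 1 each); subjects are indexed
#'   globally so trial t, subject j is reproducible in isolation.
#' @return List of `physiology` objects with attributes `trial` (integer
#'   vector) and class `pbpk_population`.
#' @export
build_population <- function(spec, n_trials = 10, n_subjects = 10) {
  stopifnot(n_trials >= 1, n_subjects >= 1)
  n <- n_trials * n_subjects
  pop <- lapply(seq_len(n) - 1L, function(i) sample_individual(spec, i))
  structure(pop, trial = rep(seq_len(n_trials), each = n_subjects),
            population = spec$name, seed = spec$seed,
            class = "pbpk_population")
}

#' @export
print.pbpk_population <- function(x, ...) {
  cat(sprintf("Virtual population '%s': %d subjects in %d trials (seed %d)\n",
              attr(x, "population"), length(x),
              length(unique(attr(x, "trial"))), attr(x, "seed")))
  invisible(x)
}
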