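#' Victim-drug parameter set
#'
#' Container for the physicochemical, permeability, partitioning,
#' biopharmaceutic and enzyme-kinetic inputs of the simulated (victim) drug.
#' Quantities follow the conventional PBPK input set: molecular weight (g/mol),
#' octanol-water log P, ionization class and pKa values, fraction unbound in
#' plasma (fu), blood-to-plasma ratio (B/P), Caco-2 apparent permeability
#' (cm/s), human jejunal effective permeability (1e-4 cm/s), a uniform
#' empirical scalar on predicted tissue partition coefficients, intrinsic
#' (un-ionized) solubility (mg/mL) with a cap on the pH-amplified luminal
#' solubility, a Noyes-Whitney dissolution coefficient, and per-enzyme
#' Michaelis-Menten constants (Vmax in pmol/min/mg microsomal protein,
#' Km in uM).
#'
#' @param name compound label.
#' @param molecular_weight g/mol, > 0.
#' @param log_p octanol-water log partition coefficient.
#' @param compound_class one of `"diprotic_base"`, `"monoprotic_base"`,
#'   `"acid"`, `"neutral"`.
#' @param pka1,pka2 dissociation constants; for a diprotic base `pka1 >= pka2`.
#' @param fu_plasma fraction unbound in plasma, in (0, 1].
#' @param blood_to_plasma blood-to-plasma concentration ratio, > 0.
#' @param papp_caco2 Caco-2 apparent permeability, cm/s.
#' @param peff_calibration_factor linear anchor mapping Papp to Peff.
#' @param peff_human effective jejunal permeability, 1e-4 cm/s units; if `NULL`
#'   it is computed from `papp_caco2` via [peff_from_papp()].
#' @param kp_scalar uniform multiplier on predicted Kp values, in (0, 1].
#' @param vss_predicted reference steady-state volume of distribution, L/kg.
#' @param intrinsic_solubility solubility of the un-ionized species, mg/mL.
#' @param solubility_cap ceiling on luminal solubility, mg/mL.
#' @param dissolution_coefficient Noyes-Whitney rate coefficient, 1/h on a
#'   mg^(1/3) basis.
#' @param salt_factor labelled-dose to free-base mass conversion factor.
#' @param fu_microsomes fraction unbound in the microsomal incubation; the
#'   apparent in vitro Km is multiplied by this value to give the unbound Km
#'   used in vivo (standard nonspecific-binding correction; 1 = no binding).
#' @param enzymes named list of `list(vmax=, km=)` per enzyme
#'   (CYP3A4/CYP3A5/CYP2D6).
#' @return An object of class `compound_params`.
#' @export
compound_parameters <- function(name = "compound",
                                molecular_weight, log_p,
                                compound_class = c("diprotic_base", "monoprotic_base",
                                                   "acid", "neutral"),
                                pka1 = NA_real_, pka2 = NA_real_,
                                fu_plasma, blood_to_plasma,
                                papp_caco2 = NA_real_,
                                peff_calibration_factor = NA_real_,
                                peff_human = NULL,
                                kp_scalar = 1,
                                vss_predicted = NA_real_,
                                intrinsic_solubility = Inf,
                                solubility_cap = Inf,
                                dissolution_coefficient = Inf,
                                salt_factor = 1,
                                fu_microsomes = 1,
                                enzymes = list(), ...) {
  compound_class <- match.arg(compound_class)
  stopifnot(molecular_weight > 0, fu_plasma > 0, fu_plasma <= 1,
            blood_to_plasma > 0, kp_scalar > 0, kp_scalar <= 1,
            salt_factor > 0, intrinsic_solubility > 0,
            fu_microsomes > 0, fu_microsomes <= 1)
  if (compound_class == "diprotic_base" && !is.na(pka1) && !is.na(pka2) &&
      pka1 < pka2)
    stop("for a diprotic base pka1 must be >= pka2", call. = FALSE)
  if (is.null(peff_human)) {
    peff_human <- peff_from_papp(papp_caco2, peff_calibration_factor)
  }
  for (e in enzymes) stopifnot(e$vmax > 0, e$km > 0)
  structure(list(
    name = name, molecular_weight = molecular_weight, log_p = log_p,
    compound_class = compound_class, pka1 = pka1, pka2 = pka2,
    fu_plasma = fu_plasma, blood_to_plasma = blood_to_plasma,
    papp_caco2 = papp_caco2,
    peff_calibration_factor = peff_calibration_factor,
    peff_human = peff_human, kp_scalar = kp_scalar,
    vss_predicted = vss_predicted,
    intrinsic_solubility = intrinsic_solubility,
    solubility_cap = solubility_cap,
    dissolution_coefficient = dissolution_coefficient,
    salt_factor = salt_factor, fu_microsomes = fu_microsomes,
    enzymes = enzymes
  ), class = "compound_params")
}

#' @export
print.compound_params <- function(x, ...) {
  cat("Compound parameter set:", x$name, "\n")
  cat(sprintf("  MW %.2f g/mol | log P %.2f | %s (pKa %.2f / %.2f)\n",
              x$molecular_weight, x$log_p, x$compound_class, x$pka1, x$pka2))
  cat(sprintf("  fu %.3f | B/P %.3f | Peff %.2f x1e-4 cm/s | Kp scalar %.2f\n",
              x$fu_plasma, x$blood_to_plasma, x$peff_human, x$kp_scalar))
  if (length(x$enzymes)) {
    cat("  Enzyme kinetics (Vmax pmol/min/mg, Km uM):\n")
    for (e in names(x$enzymes))
      cat(sprintf("    %s: Vmax %.2f, Km %.2f\n", e,
                  x$enzymes[[e]]$vmax, x$enzymes[[e]]$km))
  }
  invisible(x)
}

#' Apparent permeability from a transport experiment
#'
#' Computes Papp = dQ / (dT x A x C0) from the cumulative amount transported
#' across a cell monolayer.
#'
#' @param cumulative_amount_transported nmol transported, >= 0.
#' @param elapsed_time s, > 0.
#' @param membrane_area cm^2, > 0.
#' @param initial_donor_concentration nmol/cm^3, > 0.
#' @return Apparent permeability in cm/s.
#' @export
calc_papp <- function(cumulative_amount_transported, elapsed_time,
                      membrane_area, initial_donor_concentration) {
  if (any(cumulative_amount_transported < 0))
    stop("cumulative amount transported must be >= 0", call. = FALSE)
  if (any(elapsed_time <= 0) || any(membrane_area <= 0) ||
      any(initial_donor_concentration <= 0))
    stop("time, area and donor concentration must be > 0", call. = FALSE)
  cumulative_amount_transported /
    (elapsed_time * membrane_area * initial_donor_concentration)
}

#' Effective human jejunal permeability from Caco-2 permeability
#'
#' Linear single-point calibration: Peff (1e-4 cm/s) =
#' `calibration_factor * papp` with `papp` in cm/s, expressed in 1e-4 cm/s
#' units. The packaged anchor maps the fixture pair (6.81e-6 cm/s -> 0.80)
#' exactly.
#'
#' @param papp apparent permeability, cm/s, > 0.
#' @param calibration_factor dimensionless, > 0.
#' @return Peff in 1e-4 cm/s units.
#' @export
peff_from_papp <- function(papp, calibration_factor) {
  if (any(papp <= 0) || any(calibration_factor <= 0))
    stop("papp and calibration factor must be > 0", call. = FALSE)
  calibration_factor * papp / 1e-4
}

#' Un-ionized fraction of a compound at a given pH
#'
#' Henderson-Hasselbalch speciation. For a diprotic base the neutral fraction
#' is 1 / (1 + 10^(pka1 - pH) + 10^(pka1 + pka2 - 2 pH)); it is strictly
#' increasing in pH.
#'
#' @param ph pH in (0, 14).
#' @param pka1 higher pKa (first protonation of the base).
#' @param pka2 lower pKa; `NA` for a monoprotic species.
#' @param compound_class ionization class (see [compound_parameters()]).
#' @return Fraction of the un-ionized species, in (0, 1].
#' @export
neutral_fraction <- function(ph, pka1 = NA_real_, pka2 = NA_real_,
                             compound_class = "diprotic_base") {
  if (any(ph <= 0) || any(ph >= 14)) stop("ph must be in (0, 14)", call. = FALSE)
  switch(compound_class,
    diprotic_base = 1 / (1 + 10^(pka1 - ph) + 10^(pka1 + pka2 - 2 * ph)),
    monoprotic_base = 1 / (1 + 10^(pka1 - ph)),
    acid = 1 / (1 + 10^(ph - pka1)),
    neutral = rep(1, length(ph)),
    stop("unknown compound class: ", compound_class, call. = FALSE)
  )
}
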