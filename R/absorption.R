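#' Noyes-Whitney dissolution rate
#'
#' rate = kd x M_solid^(2/3) x (1 - C/S), floored at zero: the surface term
#' shrinks with the remaining solid (sphere-area law) and the driving force
#' vanishes at saturation. Dissolution never pushes the dissolved
#' concentration above solubility (no precipitation is modelled: an
#' already-supersaturated segment simply stops dissolving).
#'
#' @param solid_amount mg of undissolved drug, >= 0.
#' @param dissolved_concentration mg/mL in the segment fluid, >= 0.
#' @param solubility_at_ph mg/mL, > 0 (may be `Inf`).
#' @param dissolution_coefficient kd, 1/h on a mg^(1/3) basis.
#' @return Dissolution rate, mg/h.
#' @export
dissolution_rate <- function(solid_amount, dissolved_concentration,
                             solubility_at_ph, dissolution_coefficient) {
  if (any(solubility_at_ph < 0))
    stop("solubility must be >= 0", call. = FALSE)
  stopifnot(all(solid_amount >= 0), all(dissolved_concentration >= 0),
            dissolution_coefficient >= 0)
  drive <- 1 - dissolved_concentration / solubility_at_ph
  drive[!is.finite(solubility_at_ph)] <- 1
  drive[drive < 0] <- 0
  dissolution_coefficient * solid_amount^(2 / 3) * drive
}

#' pH-dependent luminal solubility of an ionizable compound
#'
#' S(pH) = S0 / neutral_fraction(pH), capped by the compound's configurable
#' maximum: for a base, solubility is amplified at acidic pH where the
#' ionized species dominates.
#'
#' @param intrinsic_solubility S0 of the un-ionized species, mg/mL, > 0.
#' @param ph segment pH.
#' @param compound a `compound_params` object (supplies pKa values, class and
#'   the solubility cap).
#' @return Solubility in mg/mL.
#' @export
segment_solubility <- function(intrinsic_solubility, ph, compound) {
  stopifnot(all(intrinsic_solubility > 0))
  fn <- neutral_fraction(ph, compound$pka1, compound$pka2,
                         compound$compound_class)
  pmin(intrinsic_solubility / fn, compound$solubility_cap)
}

#' Absorption rate constant from effective permeability
#'
#' ka = 2 Peff / R converted to 1/h (cylindrical-lumen transit-model
#' relation).
#'
#' @param peff effective permeability in 1e-4 cm/s units, > 0.
#' @param segment_radius cm, > 0.
#' @return First-order absorption rate constant, 1/h.
#' @export
absorption_rate_constant <- function(peff, segment_radius) {
  stopifnot(all(peff > 0), all(segment_radius > 0))
  2 * (peff * 1e-4) / segment_radius * 3600
}

# Precompute the per-segment constants used by the gut subsystem.
gut_parameters <- function(compound, physiology) {
  seg <- physiology$gut_segments
  s_sat <- segment_solubility(compound$intrinsic_solubility, seg$ph, compound)
  ka <- numeric(nrow(seg))
  pos <- seg$peff_scalar > 0
  ka[pos] <- absorption_rate_constant(compound$peff_human * seg$peff_scalar[pos],
                                      seg$radius_cm[pos])
  list(n = nrow(seg), names = seg$names, v_ml = seg$volume_ml,
       kt = 1 / seg$transit_h, ka = ka, s_sat = s_sat,
       kd = compound$dissolution_coefficient)
}

#' Gastrointestinal transit, dissolution and uptake derivatives
#'
#' One evaluation of the nine-segment gut subsystem: solid and dissolved drug
#' move by first-order transit (stomach, duodenum, two jejunal, three ileal
#' segments, caecum, colon; the last segment empties to feces), dissolution
#' couples the two states per [dissolution_rate()], and dissolved drug leaves
#' each segment into the portal circulation at the permeability-derived rate
#' constant.
#'
#' @param solid,dissolved per-segment amounts, mg (length 9, stomach first).
#' @param gut precomputed parameter list from the model (segment volumes,
#'   transit and absorption rate constants, saturation solubilities, kd).
#' @return List with `d_solid`, `d_dissolved` (mg/h), `absorption_flux`
#'   (mg/h leaving the lumen towards the portal blood, gross of gut-wall
#'   extraction) and `fecal_flux` (mg/h exiting the final segment).
#' @export
gut_rhs <- function(solid, dissolved, gut) {
  sol <- pmax(solid, 0)
  dis <- pmax(dissolved, 0)
  n <- gut$n
  diss <- gut$kd * sol^(2 / 3) *
    pmax(0, 1 - (dis / gut$v_ml) / gut$s_sat)
  out_s <- gut$kt * sol
  out_d <- gut$kt * dis
  abs_seg <- gut$ka * dis
  d_sol <- c(0, out_s[-n]) - out_s - diss
  d_dis <- c(0, out_d[-n]) - out_d + diss - abs_seg
  list(d_solid = d_sol, d_dissolved = d_dis,
       absorption_flux = sum(abs_seg),
       fecal_flux = out_s[n] + out_d[n])
}

#' Load a tabulated in vitro dissolution profile
#'
#' CSV with columns `time_h` and `fraction_dissolved` (non-decreasing, in
#' \[0, 1\]), as produced by a compendial dissolution test.
#'
#' @param file path to the CSV.
#' @return data.frame with the validated profile.
#' @export
load_dissolution_profile <- function(file) {
  prof <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("time_h", "fraction_dissolved") %in% names(prof)))
  if (is.unsorted(prof$time_h, strictly = TRUE))
    stop("profile times must be strictly increasing", call. = FALSE)
  f <- prof$fraction_dissolved
  if (any(f < 0 | f > 1) || is.unsorted(f))
    stop("dissolved fractions must be non-decreasing within [0, 1]",
         call. = FALSE)
  prof
}

#' Calibrate the dissolution coefficient to a measured profile
#'
#' Under sink conditions the surface-law model dM/dt = -kd M^(2/3) has the
#' closed form f(t) = 1 - (1 - kd t / (3 D^(1/3)))^3 for the dissolved
#' fraction of a dose D. The coefficient is fitted by least squares, letting
#' users drive the mechanistic gut model from their own tablet dissolution
#' data.
#'
#' @param profile data.frame from [load_dissolution_profile()].
#' @param dose mg of drug in the tested dosage form.
#' @return Fitted dissolution coefficient (1/h on a mg^(1/3) basis).
#' @export
fit_dissolution_coefficient <- function(profile, dose) {
  stopifnot(dose > 0, nrow(profile) >= 2)
  pred <- function(kd, t) {
    core <- pmax(0, 1 - kd * t / (3 * dose^(1 / 3)))
    1 - core^3
  }
  sse <- function(lkd)
    sum((pred(exp(lkd), profile$time_h) - profile$fraction_dissolved)^2)
  opt <- stats::optimize(sse, lower = log(1e-4), upper = log(1e4))
  exp(opt$minimum)
}
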