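#' Scale microsomal Vmax to a whole-organ Vmax
#'
#' Vmax_organ (mg/h) = Vmax (pmol/min/mg) x MPPGL (mg/g) x liver weight (g)
#' x abundance scalar x 60 min/h x MW (g/mol) x 1e-9 (pmol mg conversion).
#'
#' @param kinetics list with `vmax` (pmol/min/mg protein) and `km` (uM).
#' @param physiology a `physiology` object.
#' @param molecular_weight victim molecular weight, g/mol.
#' @param abundance_scalar enzyme abundance relative to healthy mean.
#' @return Whole-liver Vmax in mg/h.
#' @export
scale_vmax_to_organ <- function(kinetics, physiology, molecular_weight,
                                abundance_scalar = 1) {
  kinetics$vmax * physiology$mppgl * physiology$liver_weight *
    abundance_scalar * 60 * molecular_weight * 1e-9
}

#' Saturable multi-enzyme metabolic rate
#'
#' rate = sum_e E_e x Vmax_organ_e x Cu / (Km_e (1 + Iu_e / Ki_e) + Cu), with
#' Cu the unbound intracellular concentration (uM), competitive inhibition
#' inflating the apparent Km, and E_e the relative active enzyme amount.
#'
#' @param unbound_liver_concentration Cu, uM, >= 0.
#' @param vmax_organ named vector of whole-organ Vmax values, mg/h.
#' @param km named vector of Km values, uM.
#' @param enzyme_state named relative active amounts E (1 = baseline).
#' @param inhibitor_unbound named unbound inhibitor concentrations, uM.
#' @param ki named competitive inhibition constants, uM (Inf = no inhibition).
#' @return Metabolic rate in mg/h.
#' @export
metabolic_rate <- function(unbound_liver_concentration, vmax_organ, km,
                           enzyme_state = NULL, inhibitor_unbound = NULL,
                           ki = NULL) {
  stopifnot(unbound_liver_concentration >= 0)
  e <- names(vmax_organ)
  E <- if (is.null(enzyme_state)) rep(1, length(e)) else enzyme_state[e]
  iu <- if (is.null(inhibitor_unbound)) rep(0, length(e)) else inhibitor_unbound[e]
  kiv <- if (is.null(ki)) rep(Inf, length(e)) else ki[e]
  iu[is.na(iu)] <- 0; kiv[is.na(kiv)] <- Inf
  km_app <- km[e] * (1 + iu / kiv)
  sum(E * vmax_organ * unbound_liver_concentration /
        (km_app + unbound_liver_concentration))
}

#' Enzyme turnover under induction and mechanism-based inactivation
#'
#' dE/dt = k_deg \[1 + IndMax Iu / (IndC50 + Iu)\] - k_deg E
#'        - kinact Iu / (KI + Iu) E.
#' Baseline E = 1 is a fixed point when the perpetrator is absent.
#'
#' @param enzyme_state relative active amount E, >= 0 (vectorized).
#' @param inhibitor_unbound unbound perpetrator concentration, uM.
#' @param kdeg degradation constant, 1/h.
#' @param ind_max,ind_c50 induction parameters (0 / Inf when absent).
#' @param kinact,k_i inactivation parameters (0 / Inf when absent).
#' @return dE/dt, 1/h.
#' @export
enzyme_turnover_rhs <- function(enzyme_state, inhibitor_unbound, kdeg,
                                ind_max = 0, ind_c50 = Inf,
                                kinact = 0, k_i = Inf) {
  ind <- ifelse(ind_max > 0,
                ind_max * inhibitor_unbound / (ind_c50 + inhibitor_unbound), 0)
  inact <- ifelse(kinact > 0,
                  kinact * inhibitor_unbound / (k_i + inhibitor_unbound), 0)
  kdeg * (1 + ind) - kdeg * enzyme_state - inact * enzyme_state
}

#' Renal clearance by glomerular filtration
#'
#' CLr = fu x GFR, unit-converted to L/h; no secretion or reabsorption.
#'
#' @param fu fraction unbound in plasma, >= 0.
#' @param gfr glomerular filtration rate, mL/min, >= 0.
#' @return Renal plasma clearance in L/h.
#' @export
renal_clearance <- function(fu, gfr) {
  stopifnot(fu >= 0, gfr >= 0)
  fu * gfr * 60 / 1000
}

#' Perpetrator drug model
#'
#' One-compartment oral forcing model for the interacting drug: dose regimen
#' (amount, schedule, days), apparent volume and clearance, absorption rate
#' constant and plasma protein binding, plus per-enzyme interaction constants:
#' competitive `ki` (uM unbound), mechanism-based `kinact` (1/h) with `k_i`
#' (uM unbound), and induction `ind_max` with `ind_c50` (uM unbound).
#'
#' @param name drug label.
#' @param molecular_weight g/mol.
#' @param fu fraction unbound in plasma.
#' @param ka first-order absorption rate constant, 1/h.
#' @param v_f apparent volume of distribution V/F, L.
#' @param cl_f apparent oral clearance CL/F, L/h.
#' @param dose mg per administration.
#' @param schedule `"qd"`, `"bid"`, `"tid"` or `"qid"`.
#' @param days number of consecutive dosing days (day 1 starts at t = 0 h).
#' @param interactions named list per enzyme of interaction constants.
#' @return An object of class `perpetrator`.
#' @export
perpetrator_model <- function(name, molecular_weight, fu, ka, v_f, cl_f,
                              dose, schedule = c("qd", "bid", "tid", "qid"),
                              days, interactions) {
  schedule <- match.arg(schedule)
  stopifnot(molecular_weight > 0, fu > 0, fu <= 1, ka > 0, v_f > 0, cl_f > 0,
            dose > 0, days >= 1, length(interactions) >= 1)
  for (term in interactions) {
    stopifnot(all(unlist(term) > 0))
    if (!any(c("ki", "kinact", "ind_max") %in% names(term)))
      stop("interaction term lacks a mechanism", call. = FALSE)
  }
  offsets <- switch(schedule, qd = 0, bid = c(0, 12), tid = c(0, 8, 16),
                    qid = c(0, 6, 12, 18))
  dose_times <- as.vector(outer(offsets, 24 * (seq_len(days) - 1), `+`))
  ke <- cl_f / v_f
  if (abs(ka - ke) < 1e-8) ka <- ka * (1 + 1e-6)   # avoid the degenerate form
  structure(list(
    name = name, molecular_weight = molecular_weight, fu = fu, ka = ka,
    v_f = v_f, cl_f = cl_f, ke = ke, dose = dose, schedule = schedule,
    days = days, dose_times = sort(dose_times), interactions = interactions
  ), class = "perpetrator")
}

#' @export
print.perpetrator <- function(x, ...) {
  cat(sprintf("Perpetrator: %s, %g mg %s x %d days (ka %.2f/h, V/F %.0f L, CL/F %.1f L/h, fu %.3f)\n",
              x$name, x$dose, x$schedule, x$days, x$ka, x$v_f, x$cl_f, x$fu))
  for (e in names(x$interactions)) {
    t <- x$interactions[[e]]
    lab <- c(if (!is.null(t$ki)) sprintf("Ki %g uM", t$ki),
             if (!is.null(t$kinact)) sprintf("kinact %g /h, KI %g uM", t$kinact, t$k_i),
             if (!is.null(t$ind_max)) sprintf("IndMax %g, IndC50 %g uM", t$ind_max, t$ind_c50))
    cat("  ", e, ": ", paste(lab, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Perpetrator plasma concentration by dose superposition
#'
#' Sum of one-compartment oral dose contributions
#' (D/V) ka/(ka - ke) (exp(-ke dt) - exp(-ka dt)) over all administered doses.
#'
#' @param perpetrator a `perpetrator` object.
#' @param t time(s) since the first perpetrator dose, h.
#' @param unbound if TRUE return the unbound concentration in uM; otherwise
#'   total plasma concentration in mg/L.
#' @return Concentration vector matching `t`.
#' @export
perpetrator_concentration <- function(perpetrator, t, unbound = TRUE) {
  stopifnot(all(t >= 0) || TRUE)
  p <- perpetrator
  coef <- p$dose / p$v_f * p$ka / (p$ka - p$ke)
  conc <- vapply(t, function(ti) {
    dt <- ti - p$dose_times
    dt <- dt[dt > 0]
    if (!length(dt)) return(0)
    coef * sum(exp(-p$ke * dt) - exp(-p$ka * dt))
  }, numeric(1))
  if (unbound) conc * p$fu * 1000 / p$molecular_weight else conc
}
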