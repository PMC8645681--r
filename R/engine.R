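TISSUES <- c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
             "lung", "muscle", "skin", "spleen", "pancreas")

#' Assemble a whole-body PBPK model for one virtual subject
#'
#' Couples the nine-segment gastrointestinal subsystem to a perfusion-limited
#' circulation (12 tissues plus arterial and venous blood, lung in series),
#' saturable hepatic CYP3A4/3A5/2D6 metabolism scaled from microsomal
#' kinetics, enterocyte CYP3A4 first-pass extraction of the absorbed flux,
#' glomerular-filtration renal clearance, and (optionally) a perpetrator drug
#' forcing competitive inhibition, mechanism-based inactivation and induction
#' on dynamic enzyme amounts.
#'
#' @param compound a `compound_params` object (victim drug).
#' @param physiology a `physiology` object (one subject).
#' @param perpetrator optional `perpetrator` object; its dose clock starts at
#'   t = 0 h.
#' @param composition tissue-composition table for Kp prediction.
#' @param force_linear if TRUE, metabolism is evaluated in its first-order
#'   limit (rate = CLint x Cu) regardless of concentration, for
#'   dose-proportionality and superposition checks.
#' @param gut_first_pass enable enterocyte CYP3A4 extraction (default TRUE).
#' @return An object of class `pbpk_model`: precomputed parameter list with a
#'   derivative function, ready for [simulate.pbpk_model()].
#' @export
pbpk_model <- function(compound, physiology, perpetrator = NULL,
                       composition = load_tissue_composition(),
                       force_linear = FALSE, gut_first_pass = TRUE) {
  stopifnot(inherits(compound, "compound_params"),
            inherits(physiology, "physiology"))
  fu <- fu_adjusted(compound$fu_plasma, physiology$albumin_scalar)
  kp <- kp_table(compound, composition, fu_plasma = fu)
  miss <- setdiff(TISSUES, names(kp))
  if (length(miss))
    stop("kp/composition lacks tissues: ", paste(miss, collapse = ", "),
         call. = FALSE)

  enz <- c("CYP3A4", "CYP3A5", "CYP2D6")
  stopifnot(all(enz %in% names(compound$enzymes)))
  vmax_org <- vapply(enz, function(e)
    scale_vmax_to_organ(compound$enzymes[[e]], physiology,
                        compound$molecular_weight,
                        physiology$enzyme_abundance[[e]]), numeric(1))
  km_uM <- vapply(enz, function(e) compound$enzymes[[e]]$km, numeric(1)) *
    compound$fu_microsomes

  # enzyme-state block: liver 3A4, liver 3A5, liver 2D6, gut 3A4
  state_enz <- c("CYP3A4", "CYP3A5", "CYP2D6", "CYP3A4")
  kdeg <- unname(physiology$kdeg[c("liver_CYP3A4", "liver_CYP3A5",
                                   "liver_CYP2D6", "gut_CYP3A4")])
  ind_max <- kinact <- rep(0, 4)
  ind_c50 <- k_i <- rep(Inf, 4)
  ki_comp <- rep(Inf, 3)      # competitive Ki aligned to the 3 liver enzymes
  ki_gut <- Inf
  if (!is.null(perpetrator)) {
    stopifnot(inherits(perpetrator, "perpetrator"))
    for (j in seq_len(4)) {
      term <- perpetrator$interactions[[state_enz[j]]]
      if (is.null(term)) next
      if (!is.null(term$ind_max)) { ind_max[j] <- term$ind_max; ind_c50[j] <- term$ind_c50 }
      if (!is.null(term$kinact)) { kinact[j] <- term$kinact; k_i[j] <- term$k_i }
    }
    for (j in seq_len(3)) {
      term <- perpetrator$interactions[[enz[j]]]
      if (!is.null(term$ki)) ki_comp[j] <- term$ki
    }
    if (!is.null(perpetrator$interactions$CYP3A4$ki))
      ki_gut <- perpetrator$interactions$CYP3A4$ki
  }

  q <- physiology$organ_blood_flows
  p <- list(
    mw = compound$molecular_weight, bp = compound$blood_to_plasma, fu = fu,
    salt_factor = compound$salt_factor,
    v = unname(physiology$organ_volumes[TISSUES]),
    v_art = physiology$organ_volumes[["arterial_blood"]],
    v_ven = physiology$organ_volumes[["venous_blood"]],
    q = unname(q[TISSUES[-8]][match(TISSUES, TISSUES)]),  # filled below
    co = physiology$cardiac_output,
    kp = unname(kp[TISSUES]),
    vmax_org = vmax_org, km = km_uM, force_linear = force_linear,
    clr = renal_clearance(fu, physiology$gfr),
    gut = gut_parameters(compound, physiology),
    clint_gut = if (gut_first_pass)
      physiology$clint_gut_cyp3a4 * physiology$enterocyte_cyp3a4_scalar else 0,
    q_villi = physiology$q_villi,
    kdeg = kdeg, ind_max = ind_max, ind_c50 = ind_c50,
    kinact = kinact, k_i = k_i, ki_comp = ki_comp, ki_gut = ki_gut,
    perp = perpetrator, infusion = NULL
  )
  qv <- rep(0, 12); names(qv) <- TISSUES
  qv[names(q)] <- q
  p$q <- unname(qv)
  p$q_liver_out <- sum(qv[c("liver", "gut", "spleen", "pancreas")])
  structure(list(params = p, compound = compound, physiology = physiology,
                 perpetrator = perpetrator, kp = kp),
            class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("Whole-body PBPK model:", x$compound$name, "\n")
  cat(sprintf("  subject BW %.1f kg | fu %.4f | CLr %.3f L/h | liver Vmax %s mg/h\n",
              x$physiology$body_weight, x$params$fu, x$params$clr,
              paste(sprintf("%.1f", x$params$vmax_org), collapse = "/")))
  if (!is.null(x$perpetrator)) cat("  perpetrator:", x$perpetrator$name, "\n")
  invisible(x)
}

# unbound perpetrator concentration (uM) at scalar time t: inlined for speed
perp_iu <- function(p, t) {
  pp <- p$perp
  if (is.null(pp)) return(0)
  dt <- t - pp$dose_times
  dt <- dt[dt > 0]
  if (!length(dt)) return(0)
  (pp$dose / pp$v_f * pp$ka / (pp$ka - pp$ke)) *
    sum(exp(-pp$ke * dt) - exp(-pp$ka * dt)) * pp$fu * 1000 / pp$molecular_weight
}

# full right-hand side; state layout:
#  1:9 solid, 10:18 dissolved, 19:30 tissues, 31 arterial, 32 venous,
#  33:36 enzymes (liver 3A4/3A5/2D6, gut 3A4),
#  37:41 ledgers (absorbed, gut metabolized, fecal, hepatic metabolized, renal)
pbpk_rhs <- function(t, y, p) {
  iu <- perp_iu(p, t)

  g <- gut_rhs(y[1:9], y[10:18], p$gut)

  E <- y[33:36]
  clg <- p$clint_gut * E[4] / (1 + iu / p$ki_gut)
  e_gut <- if (clg > 0) clg / (clg + p$q_villi) else 0
  gut_met <- g$absorption_flux * e_gut
  portal <- g$absorption_flux - gut_met

  A <- y[19:30]
  ct <- A / p$v
  cout <- ct * p$bp / p$kp
  cart <- y[31] / p$v_art
  cven <- y[32] / p$v_ven

  cu <- ct[7] * p$fu / p$kp[7] * 1000 / p$mw      # unbound liver conc, uM
  km_app <- p$km * (1 + iu / p$ki_comp)
  met <- if (p$force_linear)
    sum(E[1:3] * p$vmax_org / km_app) * cu
  else
    sum(E[1:3] * p$vmax_org * cu / (km_app + cu))

  renal <- p$clr * cart / p$bp

  dA <- p$q * (cart - cout)
  dA[4] <- dA[4] + portal
  dA[6] <- dA[6] - renal
  dA[7] <- p$q[7] * cart + p$q[4] * cout[4] + p$q[11] * cout[11] +
    p$q[12] * cout[12] - p$q_liver_out * cout[7] - met
  dA[8] <- p$co * (cven - cout[8])

  d_art <- p$co * cout[8] - p$co * cart
  d_ven <- sum(p$q[c(1, 2, 3, 5, 6, 9, 10)] * cout[c(1, 2, 3, 5, 6, 9, 10)]) +
    p$q_liver_out * cout[7] - p$co * cven
  if (!is.null(p$infusion) && t >= p$infusion[2] && t <= p$infusion[3])
    d_ven <- d_ven + p$infusion[1]

  dE <- p$kdeg * (1 + ind_term(p, iu)) - p$kdeg * E - inact_term(p, iu) * E

  list(c(g$d_solid, g$d_dissolved, dA, d_art, d_ven, dE,
         g$absorption_flux, gut_met, g$fecal_flux, met, renal))
}

ind_term <- function(p, iu) {
  out <- numeric(4)
  act <- p$ind_max > 0
  if (iu > 0 && any(act))
    out[act] <- p$ind_max[act] * iu / (p$ind_c50[act] + iu)
  out
}

inact_term <- function(p, iu) {
  out <- numeric(4)
  act <- p$kinact > 0
  if (iu > 0 && any(act))
    out[act] <- p$kinact[act] * iu / (p$k_i[act] + iu)
  out
}

# Flatten the parameter list into the fixed-layout numeric vector consumed by
# the compiled derivative (src/pbpk.c); layouts must stay in step.
pack_params <- function(p, infusion = NULL) {
  pp <- p$perp
  n_dose <- if (is.null(pp)) 0L else length(pp$dose_times)
  if (n_dose > 76)
    stop("perpetrator regimen exceeds the packed dose-time capacity",
         call. = FALSE)
  out <- numeric(200)
  out[1:12] <- c(p$mw, p$bp, p$fu, p$co, p$v_art, p$v_ven, p$clint_gut,
                 p$q_villi, p$ki_gut, p$clr, as.numeric(p$force_linear),
                 p$q_liver_out)
  out[13:24] <- p$v
  out[25:36] <- p$q
  out[37:48] <- p$kp
  out[49:51] <- p$vmax_org
  out[52:54] <- p$km
  out[55:57] <- p$ki_comp
  out[58:61] <- p$kdeg
  out[62:65] <- p$ind_max
  out[66:69] <- p$ind_c50
  out[70:73] <- p$kinact
  out[74:77] <- p$k_i
  out[78:86] <- p$gut$v_ml
  out[87:95] <- p$gut$kt
  out[96:104] <- p$gut$ka
  out[105:113] <- p$gut$s_sat
  out[114] <- p$gut$kd
  out[115] <- as.numeric(!is.null(pp))
  if (!is.null(pp)) {
    out[116] <- pp$dose / pp$v_f * pp$ka / (pp$ka - pp$ke)
    out[117] <- pp$ke
    out[118] <- pp$ka
    out[119] <- pp$fu * 1000 / pp$molecular_weight
  }
  out[120] <- n_dose
  out[121:123] <- if (is.null(infusion)) c(0, 0, 0) else infusion
  if (n_dose > 0) out[124:(123 + n_dose)] <- pp$dose_times
  out
}

# enzyme-only subsystem, used to advance enzyme states through the
# perpetrator run-in before the victim dose
enzyme_only_rhs <- function(t, y, p) {
  iu <- perp_iu(p, t)
  list(p$kdeg * (1 + ind_term(p, iu)) - p$kdeg * y - inact_term(p, iu) * y)
}

#' Dose regimen for the victim drug
#'
#' @param dose mg per administration (> 0; labelled tablet strength).
#' @param at administration time(s) in h on the scenario clock (perpetrator
#'   dosing, when present, starts at t = 0).
#' @param route `"oral"` (stomach) or `"iv"` (venous bolus).
#' @return A `dose_regimen` object.
#' @export
regimen <- function(dose, at = 0, route = c("oral", "iv")) {
  route <- match.arg(route)
  stopifnot(dose >= 0, !is.unsorted(at))
  structure(list(dose = dose, times = at, route = route),
            class = "dose_regimen")
}

#' Simulate a PBPK model
#'
#' Stiff integration (lsoda) of the full system. Oral doses are applied as
#' instantaneous additions to the stomach solid compartment at the scheduled
#' times. When a perpetrator run-in precedes the first victim dose, the
#' enzyme-turnover subsystem alone is advanced over the run-in and the full
#' system is integrated from the first victim dose, which is exact because
#' every victim state is zero until then.
#'
#' @param object a `pbpk_model`.
#' @param nsim,seed unused (the model is deterministic); kept for generic
#'   compatibility.
#' @param regimen a `dose_regimen` for the victim drug.
#' @param window observation window after the last victim dose, h.
#' @param dt_out reporting grid step, h.
#' @param rtol,atol integrator tolerances.
#' @param keep_states retain the full state matrix in the result.
#' @param infusion optional `c(rate_mg_h, t_start, t_end)` constant venous
#'   infusion (for verification studies).
#' @param engine `"compiled"` (C derivative, default) or `"r"` (the reference
#'   R implementation of the same system).
#' @param ... unused.
#' @return A `pbpk_sim` object: reporting times (h), plasma concentration
#'   (ng/mL), enzyme trajectories, mass-balance ledger and residual.
#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL,
                                regimen = pbpkddi::regimen(750), window = 96,
                                dt_out = 0.1, rtol = 1e-6, atol = 1e-9,
                                keep_states = FALSE, infusion = NULL,
                                engine = c("compiled", "r"), ...) {
  engine <- match.arg(engine)
  p <- object$params
  p$infusion <- infusion
  t0 <- if (length(regimen$times)) min(regimen$times) else 0
  t_end <- (if (length(regimen$times)) max(regimen$times) else 0) + window

  e0 <- rep(1, 4)
  if (t0 > 0 && !is.null(p$perp)) {
    pre <- deSolve::lsoda(rep(1, 4), times = c(0, t0), func = enzyme_only_rhs,
                          parms = p, rtol = 1e-8, atol = 1e-10)
    e0 <- as.numeric(pre[nrow(pre), -1])
  }

  nm <- c(paste0("sol", 1:9), paste0("dis", 1:9), TISSUES, "art", "ven",
          "E_li3A4", "E_li3A5", "E_li2D6", "E_gu3A4",
          "absorbed", "gut_met", "fecal", "hep_met", "renal")
  y0 <- stats::setNames(numeric(41), nm)
  y0[33:36] <- e0

  times <- seq(t0, t_end, by = dt_out)
  dose_amt <- regimen$dose * p$salt_factor
  evt_var <- if (regimen$route == "oral") "sol1" else "ven"
  events <- NULL
  later <- regimen$times[regimen$times > t0]
  if (dose_amt > 0 && length(regimen$times)) {
    # the dose at the integration start goes straight into the initial state,
    # so the first reporting row already carries it (no pre-event artifact)
    y0[evt_var] <- y0[evt_var] + dose_amt * sum(regimen$times == t0)
    if (length(later)) {
      events <- list(data = data.frame(var = evt_var, time = later,
                                       value = dose_amt, method = "add"))
      times <- sort(unique(c(times, later)))
    }
  }

  out <- if (engine == "compiled")
    deSolve::lsoda(y0, times, func = "derivs_pbpk", dllname = "pbpkddi",
                   initfunc = "init_pbpk", parms = pack_params(p, infusion),
                   rtol = rtol, atol = atol, events = events)
  else
    deSolve::lsoda(y0, times, pbpk_rhs, p, rtol = rtol, atol = atol,
                   events = events)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure near t = ", max(out[, 1]), " h", call. = FALSE)

  conc <- out[, "ven"] / p$v_ven / p$bp * 1000   # ng/mL plasma
  n_dosed <- vapply(out[, 1], function(tt) sum(regimen$times <= tt), numeric(1))
  dosed <- n_dosed * dose_amt
  inf_in <- if (!is.null(infusion))
    infusion[1] * pmax(0, pmin(out[, 1], infusion[3]) - infusion[2]) else 0
  in_system <- rowSums(out[, 2:33, drop = FALSE])
  sinks <- rowSums(out[, c("gut_met", "fecal", "hep_met", "renal")])
  residual <- (dosed + inf_in) - (in_system + sinks)
  # rows at later dose times report the pre-event state; exclude them
  residual <- residual[!(out[, 1] %in% later)]
  denom <- max(dosed + inf_in, .Machine$double.eps)
  structure(list(
    times = out[, 1], conc = unname(conc),
    enzymes = out[, c("E_li3A4", "E_li3A5", "E_li2D6", "E_gu3A4"), drop = FALSE],
    ledger = out[nrow(out), c("absorbed", "gut_met", "fecal", "hep_met", "renal")],
    states = if (keep_states) out else NULL,
    regimen = regimen, victim_time = t0,
    mass_balance_rel_error = max(abs(residual)) / denom,
    perpetrator = if (!is.null(p$perp)) p$perp$name else NA_character_
  ), class = "pbpk_sim")
}

#' @export
print.pbpk_sim <- function(x, ...) {
  s <- nca(x)
  cat(sprintf("PBPK simulation (%s%s): Cmax %.1f ng/mL at Tmax %.2f h, AUC0-%g %.0f ng/mL.h\n",
              if (is.na(x$perpetrator)) "victim alone"
              else paste("with", x$perpetrator),
              "", s$cmax, s$tmax, max(x$times) - x$victim_time, s$auc))
  cat(sprintf("  mass-balance residual %.3g (relative)\n",
              x$mass_balance_rel_error))
  invisible(x)
}

#' @export
plot.pbpk_sim <- function(x, log = "", ...) {
  graphics::plot(x$times - x$victim_time, x$conc, type = "l", log = log,
                 xlab = "time after dose (h)",
                 ylab = "plasma concentration (ng/mL)", ...)
  invisible(x)
}

#' Run a virtual trial over a population
#'
#' Simulates every subject; when a perpetrator is given, both arms (victim
#' alone and victim plus perpetrator) are run on identical physiologies — a
#' paired design that mirrors crossover interaction studies and cancels
#' between-subject noise in exposure ratios.
#'
#' @param population a `pbpk_population` from [build_population()].
#' @param compound victim `compound_params`.
#' @param regimen victim `dose_regimen` (scenario clock; perpetrator dosing
#'   starts at t = 0).
#' @param perpetrator optional `perpetrator`.
#' @param composition tissue-composition table (loaded once and shared).
#' @param ... further arguments to [simulate.pbpk_model()].
#' @return A `pbpk_trial`: lists of `pbpk_sim` per arm (`reference`,
#'   `treatment` or NULL) plus trial grouping.
#' @export
run_trial <- function(population, compound, regimen, perpetrator = NULL,
                      composition = load_tissue_composition(), ...) {
  stopifnot(inherits(population, "pbpk_population"))
  ref_reg <- pbpkddi::regimen(regimen$dose, at = 0, route = regimen$route)
  reference <- lapply(population, function(phys)
    simulate(pbpk_model(compound, phys, NULL, composition), regimen = ref_reg, ...))
  treatment <- NULL
  if (!is.null(perpetrator))
    treatment <- lapply(population, function(phys)
      simulate(pbpk_model(compound, phys, perpetrator, composition),
               regimen = regimen, ...))
  structure(list(reference = reference, treatment = treatment,
                 trial = attr(population, "trial"),
                 population = attr(population, "population"),
                 perpetrator = if (is.null(perpetrator)) NA_character_
                               else perpetrator$name),
            class = "pbpk_trial")
}

#' @export
print.pbpk_trial <- function(x, ...) {
  cat(sprintf("Virtual trial: %d subjects, population '%s'%s\n",
              length(x$reference), x$population,
              if (is.na(x$perpetrator)) ""
              else paste0(", paired arms with ", x$perpetrator)))
  invisible(x)
}
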