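#' Noncompartmental exposure metrics
#'
#' Cmax is the maximum observed concentration, Tmax the earliest time
#' attaining it (relative to the victim dose), and AUC the linear-trapezoid
#' area over the reporting grid.
#'
#' @param x a `pbpk_sim`, or a numeric time vector (h).
#' @param ... passed to methods.
#' @return List with `cmax` (ng/mL), `tmax` (h) and `auc` (ng/mL.h).
#' @export
nca <- function(x, ...) UseMethod("nca")

#' @rdname nca
#' @param conc concentration vector matching the time vector.
#' @export
nca.default <- function(x, conc, ...) {
  times <- x
  if (length(times) < 2) stop("need at least two time points", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  stopifnot(length(conc) == length(times))
  i <- which.max(conc)
  auc <- sum(diff(times) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
  list(cmax = conc[i], tmax = times[i] - times[1], auc = auc)
}

#' @rdname nca
#' @export
nca.pbpk_sim <- function(x, ...) {
  keep <- x$times >= x$victim_time
  nca.default(x$times[keep], x$conc[keep])
}

#' Per-subject exposure summary for a trial arm
#'
#' @param sims list of `pbpk_sim` (one arm of a [run_trial()] result).
#' @param trial optional integer trial grouping.
#' @return data.frame of class `exposure_summary` with per-subject `cmax`,
#'   `tmax`, `auc` plus `subject` and `trial` columns; arithmetic and
#'   geometric means are attached as attributes.
#' @export
exposure_summary <- function(sims, trial = NULL) {
  m <- t(vapply(sims, function(s) unlist(nca(s)), numeric(3)))
  out <- data.frame(subject = seq_along(sims),
                    trial = if (is.null(trial)) 1L else trial,
                    cmax = m[, "cmax"], tmax = m[, "tmax"], auc = m[, "auc"])
  attr(out, "mean") <- colMeans(m)
  attr(out, "geomean") <- exp(colMeans(log(pmax(m, .Machine$double.xmin))))
  class(out) <- c("exposure_summary", "data.frame")
  out
}

#' Fold error of a simulated against an observed value
#'
#' fold error = simulated / observed; a prediction is conventionally accepted
#' when the fold error lies within \[0.5, 2.0\].
#'
#' @param simulated,observed numeric values; `observed` must be non-zero.
#' @return The fold error (dimensionless).
#' @export
fold_error <- function(simulated, observed) {
  if (any(observed == 0)) stop("observed value must be non-zero", call. = FALSE)
  simulated / observed
}

#' Is a fold error inside the acceptance band?
#'
#' @param fe fold error value(s).
#' @param lower,upper band limits (default 0.5-2.0).
#' @return Logical vector.
#' @export
fold_error_ok <- function(fe, lower = 0.5, upper = 2.0) {
  fe >= lower & fe <= upper
}

#' Exposure ratios between paired trial arms
#'
#' Ratio of arithmetic-mean AUC and Cmax in the presence versus the absence
#' of the perpetrator (or versus a healthy reference arm). Per-subject ratios
#' are returned for dispersion when the arms are paired.
#'
#' @param with_perpetrator,without `exposure_summary` objects (or lists of
#'   `pbpk_sim` which are summarized first).
#' @param paired require matching subject sets and return per-subject ratios.
#' @return List with `cmax_ratio`, `auc_ratio` (ratios of means), and when
#'   paired, `auc_ratio_subject` / `cmax_ratio_subject` vectors.
#' @export
ddi_ratio <- function(with_perpetrator, without, paired = TRUE) {
  if (!inherits(with_perpetrator, "exposure_summary"))
    with_perpetrator <- exposure_summary(with_perpetrator)
  if (!inherits(without, "exposure_summary"))
    without <- exposure_summary(without)
  if (paired && nrow(with_perpetrator) != nrow(without))
    stop("paired arms must contain the same subjects", call. = FALSE)
  out <- list(
    cmax_ratio = mean(with_perpetrator$cmax) / mean(without$cmax),
    auc_ratio = mean(with_perpetrator$auc) / mean(without$auc))
  if (paired) {
    out$cmax_ratio_subject <- with_perpetrator$cmax / without$cmax
    out$auc_ratio_subject <- with_perpetrator$auc / without$auc
  }
  out
}

#' Tabular report across simulated scenarios
#'
#' Builds the machine-readable result tables: single-dose exposure metrics
#' with fold errors against observed values, interaction AUC/Cmax ratios, and
#' disease-population exposure changes relative to the healthy arm.
#'
#' @param scenarios named list; each element is a list with elements
#'   `kind` (`"exposure"`, `"ddi"` or `"ddzi"`), plus for `exposure` an
#'   `exposure_summary` and optional observed values; for `ddi` a
#'   [ddi_ratio()] result; for `ddzi` a disease and healthy
#'   `exposure_summary` pair.
#' @param observed observed-value table from [load_observed()].
#' @return Named list of data.frames (`exposure`, `ddi`, `ddzi` as present).
#' @export
build_report <- function(scenarios, observed = load_observed()) {
  rows_exp <- list(); rows_ddi <- list(); rows_ddzi <- list()
  healthy_ref <- NULL
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    if (sc$kind == "exposure") {
      mu <- attr(sc$summary, "mean")
      obs <- observed[observed$scenario == nm, ]
      get_obs <- function(par) {
        v <- obs$observed[obs$parameter == par]
        if (length(v)) v else NA_real_
      }
      rows_exp[[nm]] <- data.frame(
        scenario = nm, cmax = mu["cmax"], tmax = mu["tmax"], auc = mu["auc"],
        cmax_observed = get_obs("cmax"), auc_observed = get_obs("auc"),
        cmax_fold_error = if (!is.na(get_obs("cmax")))
          fold_error(mu[["cmax"]], get_obs("cmax")) else NA_real_,
        auc_fold_error = if (!is.na(get_obs("auc")))
          fold_error(mu[["auc"]], get_obs("auc")) else NA_real_,
        row.names = NULL)
      if (isTRUE(sc$healthy_reference)) healthy_ref <- sc$summary
    } else if (sc$kind == "ddi") {
      obs <- observed[observed$scenario == nm, ]
      oa <- obs$observed[obs$parameter == "auc_ratio"]
      rows_ddi[[nm]] <- data.frame(
        scenario = nm, cmax_ratio = sc$ratio$cmax_ratio,
        auc_ratio = sc$ratio$auc_ratio,
        auc_ratio_observed = if (length(oa)) oa else NA_real_,
        auc_ratio_vs_observed = if (length(oa))
          fold_error(sc$ratio$auc_ratio, oa) else NA_real_,
        within_band = NA,
        row.names = NULL)
    } else if (sc$kind == "ddzi") {
      r <- ddi_ratio(sc$summary, sc$healthy, paired = FALSE)
      rows_ddzi[[nm]] <- data.frame(
        scenario = nm, cmax = attr(sc$summary, "mean")[["cmax"]],
        auc = attr(sc$summary, "mean")[["auc"]],
        cmax_ratio = r$cmax_ratio, auc_ratio = r$auc_ratio, row.names = NULL)
    }
  }
  out <- list()
  if (length(rows_exp)) out$exposure <- do.call(rbind, rows_exp)
  if (length(rows_ddi)) {
    ddi <- do.call(rbind, rows_ddi)
    ddi$within_band <- is.na(ddi$auc_ratio_vs_observed) |
      fold_error_ok(ddi$auc_ratio_vs_observed)
    out$ddi <- ddi
  }
  if (length(rows_ddzi)) out$ddzi <- do.call(rbind, rows_ddzi)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
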