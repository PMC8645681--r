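#' Path to a packaged fixture file
#'
#' Resolves a file shipped under `inst/extdata`.
#'
#' @param ... path components below `extdata`.
#' @return Absolute path to the file.
#' @export
pbpk_file <- function(...) {
  p <- system.file("extdata", ..., package = "pbpkddi", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture file not found: ", file.path(...), call. = FALSE)
  p
}

#' Load victim-drug parameters
#'
#' Reads a structured compound parameter file (YAML) and validates it via
#' [compound_parameters()]. The packaged default is `apatinib.yaml`.
#'
#' @param file path to a compound YAML file, or a bare compound name resolved
#'   against the packaged fixtures.
#' @param ... named overrides of individual fields (e.g.
#'   `intrinsic_solubility = Inf` for a solubility-unlimited sensitivity run).
#' @return A `compound_params` object.
#' @export
load_compound <- function(file = "apatinib", ...) {
  if (!file.exists(file)) file <- pbpk_file(paste0(file, ".yaml"))
  x <- yaml::read_yaml(file)
  dots <- list(...)
  x[names(dots)] <- dots
  do.call(compound_parameters, x)
}

#' Load a mean physiology fixture
#'
#' @param file path to a physiology YAML file or a bare population file name.
#' @return A `physiology` object.
#' @export
load_physiology <- function(file = "physiology_healthy_chinese") {
  if (!file.exists(file)) file <- pbpk_file(paste0(file, ".yaml"))
  x <- yaml::read_yaml(file)
  physiology(
    body_weight = x$body_weight,
    cardiac_output = x$cardiac_output,
    organ_volumes = unlist(x$organ_volumes),
    blood_flow_fractions = unlist(x$blood_flow_fractions),
    liver_weight = x$liver_weight,
    mppgl = x$mppgl,
    enzyme_abundance = unlist(x$enzyme_abundance),
    hematocrit = x$hematocrit,
    albumin_scalar = x$albumin_scalar,
    gfr = x$gfr,
    gut_segments = as.data.frame(x$gut_segments, stringsAsFactors = FALSE),
    enterocyte_cyp3a4_scalar = x$enterocyte_cyp3a4_scalar,
    clint_gut_cyp3a4 = x$clint_gut_cyp3a4,
    q_villi = x$q_villi,
    kdeg = unlist(x$kdeg)
  )
}

#' Load the disease-stage multiplier table
#'
#' @param file path to an impairment YAML file.
#' @return Named list of per-stage multiplier sets.
#' @export
load_impairment <- function(file = pbpk_file("impairment.yaml")) {
  yaml::read_yaml(file)
}

#' Load the tissue-composition table
#'
#' Fractional water, neutral-lipid and phospholipid content per tissue plus a
#' `plasma` row, used by the Poulin-Theil partitioning method.
#'
#' @param file path to the composition CSV.
#' @return data.frame with columns `tissue`, `f_water`, `f_neutral_lipid`,
#'   `f_phospholipid`.
#' @export
load_tissue_composition <- function(file = pbpk_file("tissue_composition.csv")) {
  comp <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("tissue", "f_water", "f_neutral_lipid", "f_phospholipid") %in% names(comp)))
  bad <- with(comp, f_water < 0 | f_neutral_lipid < 0 | f_phospholipid < 0 |
                f_water + f_neutral_lipid + f_phospholipid > 1)
  if (any(bad)) stop("invalid tissue composition rows: ",
                     paste(comp$tissue[bad], collapse = ", "), call. = FALSE)
  comp
}

#' Load a perpetrator drug model
#'
#' @param file path to a perpetrator YAML file or a bare drug name resolved
#'   against the packaged fixtures (e.g. `"itraconazole"`).
#' @param days override of the number of dosing days.
#' @return A `perpetrator` object.
#' @export
load_perpetrator <- function(file, days = NULL) {
  if (!file.exists(file)) file <- pbpk_file("perpetrators", paste0(file, ".yaml"))
  x <- yaml::read_yaml(file)
  if (!is.null(days)) x$dosing$days <- days
  perpetrator_model(
    name = x$name, molecular_weight = x$molecular_weight, fu = x$fu,
    ka = x$pk$ka, v_f = x$pk$v_f, cl_f = x$pk$cl_f,
    dose = x$dosing$dose_mg, schedule = x$dosing$schedule, days = x$dosing$days,
    interactions = x$interactions
  )
}

#' Observed clinical reference values
#'
#' Exposure values and ratios from the published single-dose and interaction
#' studies, used only for fold-error reporting.
#'
#' @param file path to the observed-data CSV.
#' @return data.frame keyed by scenario and parameter.
#' @export
load_observed <- function(file = pbpk_file("observed_pk.csv")) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
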