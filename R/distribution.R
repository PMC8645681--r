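#' Tissue-to-plasma partition coefficient by the tissue-composition method
#'
#' Poulin-Theil partitioning: the drug distributes between neutral lipid,
#' phospholipid and water in tissue and plasma according to its lipophilicity,
#' with a residual plasma-protein binding correction.
#'
#' Kp = scalar x
#'   \[P (fNL_t + 0.3 fPL_t) + (fW_t + 0.7 fPL_t)\] /
#'   \[P (fNL_p + 0.3 fPL_p) + (fW_p + 0.7 fPL_p)\] x fu_p / fu_t
#'
#' For non-adipose tissues P = 10^logP and fu_t follows the method's dilution
#' relation fu_t = 1 / (1 + 0.5 (1 - fu_p) / fu_p). For adipose the
#' vegetable-oil surrogate is used, log Pvo:w = 1.115 logP - 1.35, corrected by
#' the un-ionized fraction at pH 7.4, and macromolecular binding in the tissue
#' is neglected (fu_t = 1).
#'
#' @param compound a `compound_params` object.
#' @param tissue one row of the tissue-composition table (list or data.frame
#'   row with `f_water`, `f_neutral_lipid`, `f_phospholipid`, and optionally
#'   `tissue`).
#' @param plasma the plasma composition row.
#' @param adipose logical; treat this tissue with the adipose variant.
#'   Defaults to `TRUE` when `tissue$tissue == "adipose"`.
#' @param fu_plasma optional override of the compound's fraction unbound
#'   (used when disease states rescale binding).
#' @return Partition coefficient Kp (dimensionless, > 0).
#' @export
kp_poulin_theil <- function(compound, tissue, plasma, adipose = NULL,
                            fu_plasma = NULL) {
  fu <- if (is.null(fu_plasma)) compound$fu_plasma else fu_plasma
  stopifnot(fu > 0, fu <= 1)
  if (is.null(adipose))
    adipose <- !is.null(tissue$tissue) && identical(tissue$tissue, "adipose")
  if (adipose) {
    fn74 <- neutral_fraction(7.4, compound$pka1, compound$pka2,
                             compound$compound_class)
    p <- 10^(1.115 * compound$log_p - 1.35) * fn74
    fu_t <- 1
  } else {
    p <- 10^compound$log_p
    fu_t <- 1 / (1 + 0.5 * (1 - fu) / fu)
  }
  lip <- function(f) p * (f$f_neutral_lipid + 0.3 * f$f_phospholipid) +
    (f$f_water + 0.7 * f$f_phospholipid)
  den <- lip(plasma)
  if (den <= 0) stop("degenerate plasma composition", call. = FALSE)
  kp <- compound$kp_scalar * lip(tissue) / den * fu / fu_t
  unname(kp)
}

#' Partition coefficients for all tissues
#'
#' Evaluates [kp_poulin_theil()] against every tissue row of a composition
#' table.
#'
#' @param compound a `compound_params` object.
#' @param composition tissue-composition table from
#'   [load_tissue_composition()]; must contain a `plasma` row.
#' @param fu_plasma optional fraction-unbound override.
#' @return Named numeric vector of Kp values, one per tissue.
#' @export
kp_table <- function(compound, composition = load_tissue_composition(),
                     fu_plasma = NULL) {
  ip <- match("plasma", composition$tissue)
  if (is.na(ip)) stop("composition table lacks a plasma row", call. = FALSE)
  plasma <- composition[ip, ]
  tis <- composition[-ip, ]
  kp <- vapply(seq_len(nrow(tis)), function(i)
    kp_poulin_theil(compound, tis[i, ], plasma, fu_plasma = fu_plasma),
    numeric(1))
  names(kp) <- tis$tissue
  kp
}

#' Steady-state volume of distribution from tissue partitioning
#'
#' Vss = (V_plasma + sum_t Kp_t V_t + V_rbc x E:P) / body weight, where the
#' erythrocyte-to-plasma ratio E:P is derived from the blood-to-plasma ratio
#' and hematocrit: E:P = (B/P - (1 - Hct)) / Hct (floored at zero).
#'
#' @param kp_map named Kp vector covering every perfused tissue of the
#'   physiology (see [kp_table()]).
#' @param physiology a `physiology` object.
#' @param compound a `compound_params` object.
#' @param erythrocyte include the red-cell partitioning term (default TRUE).
#' @return Vss in L/kg.
#' @export
vss_from_kp <- function(kp_map, physiology, compound, erythrocyte = TRUE) {
  tissues <- setdiff(names(physiology$organ_volumes),
                     c("arterial_blood", "venous_blood"))
  missing <- setdiff(tissues, names(kp_map))
  if (length(missing))
    stop("kp_map lacks tissues: ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- physiology$organ_volumes
  v_blood <- v[["arterial_blood"]] + v[["venous_blood"]]
  hct <- physiology$hematocrit
  v_plasma <- (1 - hct) * v_blood
  tissue_term <- sum(kp_map[tissues] * v[tissues])
  rbc_term <- 0
  if (erythrocyte) {
    ep <- max(0, (compound$blood_to_plasma - (1 - hct)) / hct)
    rbc_term <- hct * v_blood * ep
  }
  (v_plasma + tissue_term + rbc_term) / physiology$body_weight
}
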