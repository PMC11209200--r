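#' Seth estimate of the organic carbon/water partition coefficient
#'
#' Koc = 0.35 * Kow, the Seth one-parameter regression linking sorption to
#' soil organic carbon with hydrophobicity. This is the relation used to
#' fill the Koc column of the packaged property table for most compounds;
#' a few rows there (oxamyl, metam sodium, fluazaindolizine, fluensulfone)
#' carry database-reported Koc values that do not follow it.
#'
#' @param log_kow base-10 log of the octanol/water partition coefficient.
#' @return Koc (dimensionless), full precision. Use [signif3()] for the
#'   3-significant-figure presentation used in published tables.
#' @examples
#' estimate_koc_seth(5.13)          # 47213.7
#' signif3(estimate_koc_seth(5.13)) # 47200
#' @export
estimate_koc_seth <- function(log_kow) {
  stopifnot(is.numeric(log_kow), all(is.finite(log_kow)))
  0.35 * 10^log_kow
}

#' Round to three significant figures
#'
#' Presentation helper matching how partition coefficients are printed in
#' property tables.
#'
#' @param x numeric vector.
#' @export
signif3 <- function(x) signif(x, 3)

#' Henry's law constant from vapour pressure, molar mass and solubility
#'
#' H = P * M / S, with the vapour pressure P in Pa, molar mass M in g/mol
#' and aqueous solubility S in mg/L (numerically g/m^3), giving H in
#' Pa m^3 / mol. Valid at dilute equilibrium.
#'
#' @param vapour_pressure Pa.
#' @param molar_mass g/mol.
#' @param solubility mg/L.
#' @return H in Pa m^3 / mol.
#' @examples
#' derive_henry(1.2e-6, 396.76, 16) # 2.98e-5 at 3 s.f.
#' @export
derive_henry <- function(vapour_pressure, molar_mass, solubility) {
  if (any(!is.na(solubility) & solubility <= 0)) {
    stop("solubility must be > 0", call. = FALSE)
  }
  vapour_pressure * molar_mass / solubility
}

#' Fugacity ratio of a solid
#'
#' Converts a solid's vapour pressure to its hypothetical subcooled-liquid
#' value for aerosol partitioning: F = exp(6.79 * (1 - Tm/T)) when the
#' melting point Tm exceeds the system temperature T (both in kelvin), and
#' F = 1 for liquids (Tm <= T). The constant 6.79 is the conventional
#' default entropy-of-fusion term (dS_fus/R); no compound-specific entropy
#' is supported.
#'
#' @param melting_point_c melting point in degrees Celsius.
#' @param temperature_k system temperature in kelvin (default 298.15).
#' @return F in (0, 1].
#' @export
fugacity_ratio <- function(melting_point_c, temperature_k = 298.15) {
  stopifnot(all(temperature_k > 0))
  tm_k <- melting_point_c + 273.15
  ifelse(is.na(tm_k) | tm_k <= temperature_k, 1,
         exp(6.79 * (1 - tm_k / temperature_k)))
}

#' Reconcile printed and derived Henry's law constants
#'
#' Published property tables sometimes print an H that is mutually
#' inconsistent with the printed vapour pressure, molar mass and solubility
#' of the same row (unit slips of ~100-fold are typical). This routine
#' derives H = P*M/S where possible, compares it with any printed value,
#' and chooses one according to a policy.
#'
#' @param compounds a `compound_tbl` (or compatible data frame).
#' @param tolerance_fold flag a row as discrepant when
#'   `max(printed/derived, derived/printed)` exceeds this (default 3).
#' @param policy `"printed_first"` (default; use the printed H when
#'   present) or `"derived_first"`.
#' @return a data frame with one row per compound: `cas`, `name`,
#'   `henry_printed`, `henry_derived`, `discrepancy_ratio`,
#'   `henry_consistency` (`consistent` / `discrepant` / `printed_missing`),
#'   and `henry_chosen`. Errors if a row has neither a printed nor a
#'   derivable H.
#' @examples
#' d <- bundled_dataset()
#' rec <- reconcile_henry(d$compounds)
#' rec[rec$henry_consistency == "discrepant", ]
#' @export
reconcile_henry <- function(compounds, tolerance_fold = 3,
                            policy = c("printed_first", "derived_first")) {
  policy <- match.arg(policy)
  printed <- compounds$henry_pa_m3_mol
  derivable <- !is.na(compounds$vapour_pressure_pa) &
    !is.na(compounds$molar_mass_g_mol) &
    !is.na(compounds$solubility_mg_l) & compounds$solubility_mg_l > 0
  derived <- rep(NA_real_, nrow(compounds))
  derived[derivable] <- derive_henry(compounds$vapour_pressure_pa[derivable],
                                     compounds$molar_mass_g_mol[derivable],
                                     compounds$solubility_mg_l[derivable])
  if (any(is.na(printed) & !derivable)) {
    bad <- which(is.na(printed) & !derivable)[1]
    stop(sprintf("row %d (%s): Henry's law constant neither printed nor derivable",
                 bad, compounds$name[bad]), call. = FALSE)
  }
  ratio <- ifelse(!is.na(printed) & !is.na(derived) & derived > 0 & printed > 0,
                  pmax(printed / derived, derived / printed), NA_real_)
  consistency <- ifelse(is.na(printed), "printed_missing",
                        ifelse(!is.na(ratio) & ratio > tolerance_fold,
                               "discrepant", "consistent"))
  chosen <- if (policy == "printed_first") {
    ifelse(is.na(printed), derived, printed)
  } else {
    ifelse(is.na(derived), printed, derived)
  }
  data.frame(cas = compounds$cas, name = compounds$name,
             henry_printed = printed, henry_derived = derived,
             discrepancy_ratio = ratio, henry_consistency = consistency,
             henry_chosen = chosen, stringsAsFactors = FALSE)
}

#' Derived partition parameters for the fugacity model
#'
#' Assembles, per compound, every quantity the Level I engine needs that is
#' not read directly from the property table: the Seth Koc (used when the
#' printed Koc is absent), the derived Henry's law constant with its
#' consistency status, the solid-phase fugacity ratio F, and the
#' subcooled-liquid vapour pressure P_L = VP / F used for aerosol
#' association. Doubles as the estimation audit log; serialise with
#' [jsonlite::write_json()] for a structured record of source decisions.
#'
#' @inheritParams reconcile_henry
#' @param temperature_k system temperature (K).
#' @return data frame: `cas`, `name`, `koc_printed`, `koc_seth`,
#'   `koc_chosen`, `koc_source`, Henry reconciliation columns as in
#'   [reconcile_henry()] plus `henry_source`, `fugacity_ratio_f`,
#'   `subcooled_vp_pl`.
#' @export
derive_properties <- function(compounds, tolerance_fold = 3,
                              policy = c("printed_first", "derived_first"),
                              temperature_k = 298.15) {
  policy <- match.arg(policy)
  rec <- reconcile_henry(compounds, tolerance_fold, policy)
  koc_seth <- ifelse(is.na(compounds$log_kow), NA_real_,
                     estimate_koc_seth(compounds$log_kow))
  koc_printed <- compounds$koc
  koc_chosen <- ifelse(is.na(koc_printed), koc_seth, koc_printed)
  f <- fugacity_ratio(compounds$melting_point_c, temperature_k)
  pl <- ifelse(is.na(compounds$vapour_pressure_pa), NA_real_,
               compounds$vapour_pressure_pa / f)
  cbind(rec[c("cas", "name")],
        data.frame(koc_printed = koc_printed, koc_seth = koc_seth,
                   koc_chosen = koc_chosen,
                   koc_source = ifelse(is.na(koc_printed), "estimated_seth",
                                       "printed"),
                   stringsAsFactors = FALSE),
        rec[setdiff(names(rec), c("cas", "name"))],
        data.frame(henry_source = ifelse(rec$henry_consistency ==
                                           "printed_missing", "derived",
                                         policy),
                   fugacity_ratio_f = f, subcooled_vp_pl = pl,
                   stringsAsFactors = FALSE))
}
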