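COMPARTMENTS <- c("aerosols", "air", "biota", "sediment", "soil",
                  "suspended_particles", "water")

#' The standard Level I evaluative environment
#'
#' A closed, hypothetical unit world at equilibrium: seven compartments
#' (air, water, soil, sediment, suspended particles, biota, aerosols) with
#' fixed volumes, solids densities, organic-carbon fractions and a biota
#' lipid fraction, at 25 degrees C, receiving a fixed emission of
#' 100,000 kg. These are the conventional Level I defaults; with the
#' printed-first Henry policy they reproduce the published distribution
#' table to the printed decimal for its internally consistent rows.
#'
#' Override any constant by passing a modified copy to the engine, or load
#' overrides from a JSON file with [read_environment()].
#'
#' @return an object of class `level1_env`: a list with `temperature_k`,
#'   `gas_constant_r` (Pa m^3 / (mol K)), `emission_kg`, and named vectors
#'   `volumes_m3`, `solids_density_kg_m3`, `organic_carbon_fraction`,
#'   `lipid_fraction`, plus a `version` stamp.
#' @examples
#' env <- default_environment()
#' env$volumes_m3[["air"]]
#' @export
default_environment <- function() {
  structure(list(
    temperature_k = 298.15,
    gas_constant_r = 8.314,
    emission_kg = 1e5,
    volumes_m3 = c(air = 1e14, water = 2e11, soil = 9e9, sediment = 1e8,
                   suspended_particles = 1e6, biota = 2e5, aerosols = 2e3),
    solids_density_kg_m3 = c(soil = 2400, sediment = 2400,
                             suspended_particles = 1500, biota = 1000,
                             aerosols = 2000),
    organic_carbon_fraction = c(soil = 0.02, sediment = 0.04,
                                suspended_particles = 0.2),
    lipid_fraction = c(biota = 0.05),
    version = "level1-default-1"
  ), class = "level1_env")
}

#' Read an evaluative-environment configuration
#'
#' Loads a JSON file whose entries override fields of the default world.
#' Unknown top-level names are rejected; partial overrides of the named
#' vectors are merged element-wise.
#'
#' @param path JSON file.
#' @return a `level1_env`.
#' @export
read_environment <- function(path) {
  env <- default_environment()
  over <- jsonlite::fromJSON(path)
  known <- setdiff(names(unclass(env)), "version")
  bad <- setdiff(names(over), known)
  if (length(bad)) {
    stop("unknown environment field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(over)) {
    if (is.list(over[[nm]]) || length(over[[nm]]) > 1 ||
        !is.null(names(over[[nm]]))) {
      v <- unlist(over[[nm]])
      env[[nm]][names(v)] <- v
    } else {
      env[[nm]] <- over[[nm]]
    }
  }
  validate_environment(env)
  env
}

validate_environment <- function(env) {
  stopifnot(env$temperature_k > 0, env$gas_constant_r > 0,
            env$emission_kg > 0,
            all(env$volumes_m3 >= 0), any(env$volumes_m3 > 0),
            all(env$solids_density_kg_m3 > 0),
            all(env$organic_carbon_fraction >= 0),
            all(env$organic_carbon_fraction <= 1),
            all(env$lipid_fraction >= 0), all(env$lipid_fraction <= 1))
  invisible(env)
}

# Resolve the H / Koc / Kow / P_L inputs for one compound row, applying the
# reconcile policy. `derived` is the matching row of derive_properties().
resolve_basis <- function(compound, derived) {
  h <- derived$henry_chosen
  koc <- derived$koc_chosen
  kow <- 10^compound$log_kow
  pl <- derived$subcooled_vp_pl
  if (is.na(h) || h <= 0) {
    stop(sprintf("%s: Henry's law constant must be > 0 (got %s)",
                 compound$name, format(h)), call. = FALSE)
  }
  if (is.na(koc) || koc < 0) {
    stop(sprintf("%s: Koc must be >= 0", compound$name), call. = FALSE)
  }
  list(henry = h, koc = koc, kow = kow, subcooled_vp = pl)
}

#' Fugacity capacities (Z-values) for one compound
#'
#' Z expresses how much chemical a compartment holds per unit volume and
#' unit fugacity (mol / (m^3 Pa)):
#' \itemize{
#'   \item air: 1 / (R T)
#'   \item water: 1 / H
#'   \item soil, sediment, suspended particles: Z_water * (rho/1000) * foc * Koc
#'   \item biota: Z_water * (rho/1000) * L * Kow
#'   \item aerosols: Z_air * 6e6 / P_L, with P_L the subcooled-liquid
#'     vapour pressure (VP / F); zero when no vapour pressure is available
#'     or VP = 0.
#' }
#'
#' @param compound one-row `compound_tbl` slice.
#' @param env a `level1_env`.
#' @param derived optional matching row of [derive_properties()]; computed
#'   on the fly when omitted.
#' @inheritParams reconcile_henry
#' @return list with `z` (named vector over the seven compartments) and
#'   `basis` (the H, Koc, Kow and P_L actually used).
#' @export
compute_z_values <- function(compound, env = default_environment(),
                             derived = NULL,
                             policy = c("printed_first", "derived_first")) {
  policy <- match.arg(policy)
  validate_environment(env)
  if (is.null(derived)) {
    derived <- derive_properties(compound, policy = policy,
                                 temperature_k = env$temperature_k)
  }
  basis <- resolve_basis(compound, derived)
  z_air <- 1 / (env$gas_constant_r * env$temperature_k)
  z_water <- 1 / basis$henry
  solid <- function(comp) {
    z_water * (env$solids_density_kg_m3[[comp]] / 1000) *
      env$organic_carbon_fraction[[comp]] * basis$koc
  }
  z_biota <- z_water * (env$solids_density_kg_m3[["biota"]] / 1000) *
    env$lipid_fraction[["biota"]] * basis$kow
  z_aero <- if (is.na(basis$subcooled_vp) || basis$subcooled_vp <= 0) {
    0
  } else {
    z_air * 6e6 / basis$subcooled_vp
  }
  z <- c(aerosols = z_aero, air = z_air, biota = z_biota,
         sediment = solid("sediment"), soil = solid("soil"),
         suspended_particles = solid("suspended_particles"),
         water = z_water)
  list(z = z, basis = basis)
}

#' Level I equilibrium distribution of one compound
#'
#' Distributes a fixed emission E over the compartments of a closed
#' evaluative environment at a single equilibrium fugacity:
#' total moles n = 1000 E / M, fugacity f = n / sum(Z_c V_c), and the mass
#' fraction in compartment c is 100 * Z_c V_c / sum(Z_j V_j). Fractions are
#' kept at full precision; round half-up to one decimal with
#' [round_percent()] for display.
#'
#' @inheritParams compute_z_values
#' @return object of class `ped_result`: list with `cas`, `name`,
#'   `fugacity_pa`, `total_mol`, `percent` (named vector summing to 100),
#'   `z` and `basis`.
#' @examples
#' d <- bundled_dataset()
#' distribute(d$compounds[d$compounds$name == "Fluopyram", ])
#' @export
distribute <- function(compound, env = default_environment(), derived = NULL,
                       policy = c("printed_first", "derived_first")) {
  policy <- match.arg(policy)
  zs <- compute_z_values(compound, env, derived, policy)
  zv <- zs$z * env$volumes_m3[names(zs$z)]
  total_zv <- sum(zv)
  if (!is.finite(total_zv) || total_zv <= 0) {
    stop(compound$name, ": no compartment has positive capacity",
         call. = FALSE)
  }
  n <- env$emission_kg * 1000 / compound$molar_mass_g_mol
  structure(list(
    cas = compound$cas, name = compound$name,
    fugacity_pa = n / total_zv, total_mol = n,
    percent = 100 * zv / total_zv,
    z = zs$z, basis = zs$basis
  ), class = "ped_result")
}

#' @export
print.ped_result <- function(x, ...) {
  cat(sprintf("Level I distribution: %s (%s)\n", x$name, x$cas))
  cat(sprintf("  fugacity %.4g Pa over %.4g mol\n", x$fugacity_pa,
              x$total_mol))
  pct <- round_percent(x$percent)
  for (c in names(pct)) cat(sprintf("  %-20s %6.1f %%\n", c, pct[[c]]))
  invisible(x)
}

#' Round percentages half-up to one decimal
#'
#' Presentation rounding used for distribution tables (base R `round()`
#' rounds half to even, which published tables do not).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @export
round_percent <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Batch Level I distribution over a compound table
#'
#' Runs [distribute()] on every row, preserving input order. Per-row
#' failures are collected into the `flags` column (`error:<message>`) rather
#' than aborting the batch. Henry-reconciliation status other than
#' `consistent` is carried into `flags`. When a reference distribution
#' table is supplied, rows whose computed distribution cannot reproduce the
#' reference under either Henry policy (within `tol_pp` percentage points on
#' every compartment) are flagged `non_reconstructable`.
#'
#' @inheritParams distribute
#' @param compounds a `compound_tbl`.
#' @param reference optional data frame with `cas` plus the seven
#'   compartment columns holding reference percentages.
#' @param tol_pp tolerance (percentage points) for the reference comparison.
#' @return data frame of class `ped_tbl`: `cas`, `name`, one column per
#'   compartment (full-precision percentages, alphabetical compartment
#'   order), `fugacity_pa`, `flags`.
#' @export
batch_distribute <- function(compounds, env = default_environment(),
                             policy = c("printed_first", "derived_first"),
                             reference = NULL, tol_pp = 0.5) {
  policy <- match.arg(policy)
  n <- nrow(compounds)
  out <- data.frame(cas = compounds$cas, name = compounds$name,
                    stringsAsFactors = FALSE)
  for (c in COMPARTMENTS) out[[c]] <- rep(NA_real_, n)
  out$fugacity_pa <- rep(NA_real_, n)
  out$flags <- rep("", n)
  if (n == 0) {
    class(out) <- c("ped_tbl", "data.frame")
    return(out)
  }
  for (i in seq_len(n)) {
    flags <- character()
    res <- tryCatch({
      derived_i <- derive_properties(compounds[i, , drop = FALSE],
                                     policy = policy,
                                     temperature_k = env$temperature_k)
      if (derived_i$henry_consistency != "consistent") {
        flags <- c(flags, paste0("henry_", derived_i$henry_consistency))
      }
      distribute(compounds[i, , drop = FALSE], env, derived_i, policy)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      flags <- c(flags, paste0("error:", conditionMessage(res)))
    } else {
      out[i, COMPARTMENTS] <- as.list(res$percent[COMPARTMENTS])
      out$fugacity_pa[i] <- res$fugacity_pa
    }
    out$flags[i] <- paste(flags, collapse = ";")
  }
  if (!is.null(reference)) {
    out <- flag_non_reconstructable(out, compounds, env, reference, tol_pp,
                                    policy)
  }
  class(out) <- c("ped_tbl", "data.frame")
  out
}

# A row is flagged non_reconstructable when the distribution just computed
# (under the selected policy) does not reproduce the reference within
# tol_pp on every compartment. If the alternative Henry policy does
# reproduce it, a supplementary flag records that the row is recoverable
# by switching policy.
flag_non_reconstructable <- function(ped, compounds, env, reference, tol_pp,
                                     policy = "printed_first") {
  alt_policy <- setdiff(c("printed_first", "derived_first"), policy)
  alt <- batch_distribute(compounds, env, alt_policy)
  for (i in seq_len(nrow(ped))) {
    j <- match(ped$cas[i], reference$cas)
    if (is.na(j)) next
    ref <- as.numeric(reference[j, COMPARTMENTS])
    ok_main <- !anyNA(as.numeric(ped[i, COMPARTMENTS])) &&
      all(abs(as.numeric(ped[i, COMPARTMENTS]) - ref) <= tol_pp)
    ok_alt <- !anyNA(as.numeric(alt[i, COMPARTMENTS])) &&
      all(abs(as.numeric(alt[i, COMPARTMENTS]) - ref) <= tol_pp)
    if (!ok_main) {
      extra <- c("non_reconstructable",
                 if (ok_alt) paste0(sub("_first", "", alt_policy),
                                    "_h_reproduces_reference"))
      ped$flags[i] <- paste(c(Filter(nzchar, ped$flags[i]), extra),
                            collapse = ";")
    }
  }
  ped
}

#' Write a distribution table to CSV
#'
#' Columns `cas,name,aerosols,air,biota,sediment,soil,suspended_particles,`
#' `water,flags`, percentages rounded half-up to one decimal.
#'
#' @param ped a `ped_tbl` from [batch_distribute()].
#' @param path output CSV path.
#' @export
write_ped_table <- function(ped, path) {
  out <- ped[c("cas", "name", COMPARTMENTS, "flags")]
  for (c in COMPARTMENTS) out[[c]] <- round_percent(out[[c]])
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
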