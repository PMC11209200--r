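# Build a one-row compound table without going through the loader, so tests
# can construct degenerate inputs (zero Koc, absent H, ...).
make_compound <- function(name = "testol", cas = "50-00-0",
                          class_group = "terpene", molar_mass = 150,
                          melting_point = -10, vapour_pressure = 1,
                          solubility = 1000, henry = NA_real_,
                          log_kow = 2, koc = NA_real_) {
  df <- data.frame(
    name = name, cas = cas, class_group = class_group,
    molar_mass_g_mol = molar_mass, melting_point_c = melting_point,
    vapour_pressure_pa = vapour_pressure, solubility_mg_l = solubility,
    henry_pa_m3_mol = henry, log_kow = log_kow, koc = koc,
    provenance = "", stringsAsFactors = FALSE
  )
  class(df) <- c("compound_tbl", "data.frame")
  df
}

# Independent brute-force oracle for the Level I distribution: a literal
# transcription of the Z-value and mass-balance formulas, kept free of any
# package internals. Takes resolved inputs (no policy logic).
oracle_ped <- function(h, koc, kow, vp, melting_c, env) {
  t_k <- env$temperature_k
  z_air <- 1 / (env$gas_constant_r * t_k)
  z_water <- 1 / h
  tm_k <- melting_c + 273.15
  f <- if (tm_k > t_k) exp(6.79 * (1 - tm_k / t_k)) else 1
  pl <- vp / f
  z <- c(
    aerosols = if (vp > 0) z_air * 6e6 / pl else 0,
    air = z_air,
    biota = z_water * (env$solids_density_kg_m3[["biota"]] / 1000) *
      env$lipid_fraction[["biota"]] * kow,
    sediment = z_water * (env$solids_density_kg_m3[["sediment"]] / 1000) *
      env$organic_carbon_fraction[["sediment"]] * koc,
    soil = z_water * (env$solids_density_kg_m3[["soil"]] / 1000) *
      env$organic_carbon_fraction[["soil"]] * koc,
    suspended_particles =
      z_water * (env$solids_density_kg_m3[["suspended_particles"]] / 1000) *
      env$organic_carbon_fraction[["suspended_particles"]] * koc,
    water = z_water
  )
  zv <- z * env$volumes_m3[names(z)]
  100 * zv / sum(zv)
}

extract_flags <- function(ped, cas) {
  strsplit(ped$flags[match(cas, ped$cas)], ";")[[1]]
}
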