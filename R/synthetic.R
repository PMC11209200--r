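#' Synthetic compound profiles
#'
#' Mechanism-targeted property envelopes for generating test compounds.
#' Partition-relevant properties are sampled log-uniformly (they span many
#' orders of magnitude in real property tables), and each profile's bounds
#' are chosen so that, under the default evaluative environment, the
#' expected dominant compartment holds by construction:
#' \describe{
#'   \item{air_seeking}{high Henry's law constant (1e2-1e4 Pa m^3/mol), low
#'     Koc (1-1e2): effectively all mass ends in air.}
#'   \item{water_seeking}{very low H (1e-8-1e-4), Koc below 1.}
#'   \item{soil_seeking}{high Koc (1e4-1e6) with moderate H (1e-2-1).}
#'   \item{mixed}{wide bounds spanning all three regimes; no expected
#'     label.}
#' }
#'
#' @param name one of `"air_seeking"`, `"water_seeking"`, `"soil_seeking"`,
#'   `"mixed"`.
#' @return a `synthetic_profile`: list of (low, high) bounds plus the
#'   expected dominant compartment label (`NA` for mixed).
#' @export
synthetic_profile <- function(name = c("air_seeking", "water_seeking",
                                       "soil_seeking", "mixed")) {
  name <- match.arg(name)
  p <- switch(name,
    air_seeking = list(henry = c(1e2, 1e4), koc = c(1, 1e2),
                       solubility = c(1, 1e3), melting_point = c(-80, 20),
                       expected = "air"),
    water_seeking = list(henry = c(1e-8, 1e-4), koc = c(1e-3, 1),
                         solubility = c(1e3, 1e6),
                         melting_point = c(-50, 150), expected = "water"),
    soil_seeking = list(henry = c(1e-2, 1), koc = c(1e4, 1e6),
                        solubility = c(10, 1e4),
                        melting_point = c(-50, 100), expected = "soil"),
    mixed = list(henry = c(1e-6, 1e4), koc = c(1e-2, 1e6),
                 solubility = c(1, 1e5), melting_point = c(-80, 150),
                 expected = NA_character_)
  )
  for (f in c("henry", "koc", "solubility", "melting_point")) {
    stopifnot(p[[f]][1] < p[[f]][2])
  }
  structure(c(list(name = name), p), class = "synthetic_profile")
}

runif_log <- function(n, bounds) 10^runif(n, log10(bounds[1]), log10(bounds[2]))

#' Generate a synthetic compound set
#'
#' Draws `n` internally consistent compound records from a
#' [synthetic_profile()]. The Henry's law constant is sampled directly (it
#' is what the profile controls) and the vapour pressure is back-solved as
#' VP = H S / M, so derived and stored H always agree -- unlike some rows
#' of real property tables. Koc is sampled log-uniformly within the profile
#' bounds and logKow set Seth-consistently (`log10(Koc / 0.35)`). Molar
#' mass is uniform on [100, 500] g/mol. CAS numbers are synthetic but
#' carry valid check digits. One record in five omits the stored H
#' (derivable-but-missing, exercising the reconciliation path); with
#' `n >= 1` at least one such record is guaranteed.
#'
#' @param n number of records (>= 0).
#' @param seed integer seed; identical inputs give identical sets.
#' @param profile a `synthetic_profile`.
#' @return a `compound_tbl` with an extra `expected_dominant` column.
#' @export
generate_compound_set <- function(n, seed,
                                  profile = synthetic_profile("mixed")) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  stopifnot(inherits(profile, "synthetic_profile"))
  empty <- new_compound_tbl(data.frame(
    name = character(), cas = character(), class_group = character(),
    molar_mass_g_mol = numeric(), melting_point_c = numeric(),
    vapour_pressure_pa = numeric(), solubility_mg_l = numeric(),
    henry_pa_m3_mol = numeric(), log_kow = numeric(), koc = numeric(),
    provenance = character(), expected_dominant = character(),
    stringsAsFactors = FALSE))
  if (n == 0) return(empty)
  set.seed(seed)
  h <- runif_log(n, profile$henry)
  koc <- runif_log(n, profile$koc)
  s <- runif_log(n, profile$solubility)
  tm <- runif(n, profile$melting_point[1], profile$melting_point[2])
  m <- runif(n, 100, 500)
  vp <- h * s / m
  hide_h <- seq_len(n) %% 5 == 1  # every fifth record: H must be derived
  df <- data.frame(
    name = sprintf("syn-%s-%03d", profile$name, seq_len(n)),
    cas = vapply(seq_len(n), function(i) {
      cas_complete(sprintf("%d-%02d", 10000 + i, i %% 100))
    }, character(1)),
    class_group = rep_len(CLASS_GROUPS, n),
    molar_mass_g_mol = m, melting_point_c = tm, vapour_pressure_pa = vp,
    solubility_mg_l = s,
    henry_pa_m3_mol = ifelse(hide_h, NA_real_, h),
    log_kow = log10(koc / 0.35), koc = koc,
    provenance = "synthetic",
    expected_dominant = profile$expected,
    stringsAsFactors = FALSE
  )
  check_compound_rows(df)
  new_compound_tbl(df)
}

#' Generate synthetic toxicity endpoint tables
#'
#' Draws aquatic (fish/algae/invertebrate, mg/L) and mammalian (oral and
#' dermal LD50, mg/kg) endpoints log-normally around per-class medians:
#' `exp(rnorm(meanlog = log(median), sdlog = dispersion))`. This emulates
#' the class structure of real screening tables, where synthetic
#' pesticides sit orders of magnitude below phytochemicals on invertebrate
#' EC50. A configurable fraction of entries receives a `">"` qualifier;
#' with at least one row generated, at least one qualifier is guaranteed
#' per batch so downstream qualifier paths are always exercised.
#'
#' @param compounds a `compound_tbl` (class groups drive the medians).
#' @param seed integer seed.
#' @param class_medians named list, one entry per class group present, each
#'   a vector `c(aquatic = <mg/L>, oral = <mg/kg>)`; all > 0.
#' @param dispersion log-scale (natural log) standard deviation, >= 0.
#'   Zero gives every endpoint exactly its class median.
#' @param gt_fraction fraction of entries qualified `">"` (default 0.05).
#' @return list with `ecotox` and `mamm_tox` data frames in the packaged
#'   schema.
#' @export
generate_endpoint_tables <- function(compounds, seed, class_medians,
                                     dispersion = 0.2, gt_fraction = 0.05) {
  stopifnot(dispersion >= 0, gt_fraction >= 0, gt_fraction <= 1)
  med <- function(cls, what) {
    m <- class_medians[[cls]][[what]]
    if (is.null(m) || is.na(m) || m <= 0) {
      stop("class_medians must provide a positive '", what, "' median for ",
           cls, call. = FALSE)
    }
    m
  }
  n <- nrow(compounds)
  set.seed(seed)
  aq_med <- vapply(compounds$class_group, med, numeric(1), what = "aquatic")
  or_med <- vapply(compounds$class_group, med, numeric(1), what = "oral")
  draw <- function(m) exp(rnorm(n, log(m), dispersion))
  quals <- function() {
    q <- ifelse(runif(n) < gt_fraction, "gt", "eq")
    q
  }
  ecotox <- data.frame(
    name = compounds$name, cas = compounds$cas,
    fish_lc50 = draw(aq_med), fish_lc50_qual = quals(),
    fish_lc50_model = "synthetic fish", fish_lc50_predicted = FALSE,
    algae_ec50 = draw(aq_med), algae_ec50_qual = quals(),
    algae_ec50_model = "synthetic algae", algae_ec50_predicted = FALSE,
    invertebrate_ec50 = draw(aq_med), invertebrate_ec50_qual = quals(),
    invertebrate_ec50_model = "synthetic invertebrate",
    invertebrate_ec50_predicted = FALSE,
    stringsAsFactors = FALSE
  )
  mamm <- data.frame(
    name = compounds$name, cas = compounds$cas,
    oral_ld50 = draw(or_med), oral_ld50_qual = quals(),
    oral_ld50_model = "synthetic rat", oral_ld50_predicted = FALSE,
    dermal_ld50 = draw(or_med), dermal_ld50_qual = quals(),
    dermal_ld50_model = "synthetic rabbit", dermal_ld50_predicted = FALSE,
    stringsAsFactors = FALSE
  )
  if (n >= 1 && !any(c(ecotox$fish_lc50_qual, ecotox$algae_ec50_qual,
                       ecotox$invertebrate_ec50_qual) == "gt")) {
    ecotox$invertebrate_ec50_qual[1] <- "gt"
  }
  list(ecotox = ecotox, mamm_tox = mamm)
}

#' @importFrom stats rnorm
NULL
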