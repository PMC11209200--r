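#' @importFrom utils read.csv write.csv
#' @importFrom stats median setNames runif
NULL

CLASS_GROUPS <- c("pesticide", "terpene", "phenylpropanoid", "organosulfur",
                  "beta_keto_fatty_acid")

COMPOUND_COLS <- c("name", "cas", "class_group", "molar_mass_g_mol",
                   "melting_point_c", "vapour_pressure_pa", "solubility_mg_l",
                   "henry_pa_m3_mol", "log_kow", "koc")

COMPOUND_NUMERIC <- c("molar_mass_g_mol", "melting_point_c",
                      "vapour_pressure_pa", "solubility_mg_l",
                      "henry_pa_m3_mol", "log_kow", "koc")

# Strip thousands separators and normalise unicode minus signs, then convert.
# Unparseable non-empty strings raise rather than silently becoming NA.
parse_numeric <- function(x, column, allow_empty = TRUE) {
  x <- gsub(",", "", trimws(as.character(x)))
  x <- gsub("−|–", "-", x)
  out <- rep(NA_real_, length(x))
  present <- !is.na(x) & nzchar(x)
  vals <- suppressWarnings(as.numeric(x[present]))
  if (anyNA(vals)) {
    bad <- which(present)[is.na(vals)]
    stop(sprintf("column '%s': unparseable numeric value '%s' (row %d)",
                 column, x[bad[1]], bad[1]), call. = FALSE)
  }
  if (!allow_empty && any(!present)) {
    stop(sprintf("column '%s': missing value in row %d", column,
                 which(!present)[1]), call. = FALSE)
  }
  out[present] <- vals
  out
}

# Split optional ">" prefixes off a threshold column into value + qualifier.
parse_qualified <- function(x, column) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  qual <- ifelse(grepl("^>", x), "gt", "eq")
  val <- parse_numeric(sub("^>", "", x), column)
  qual[is.na(val)] <- NA_character_
  list(value = val, qualifier = qual)
}

new_compound_tbl <- function(df) {
  class(df) <- c("compound_tbl", "data.frame")
  df
}

check_compound_rows <- function(df) {
  bad_cas <- which(!cas_is_valid(df$cas))
  if (length(bad_cas)) {
    stop(sprintf("invalid CAS number '%s' (checksum or format) in row %d",
                 df$cas[bad_cas[1]], bad_cas[1]), call. = FALSE)
  }
  checks <- list(
    c("molar_mass_g_mol", "molar_mass must be > 0"),
    c("solubility_mg_l", "water solubility must be > 0")
  )
  for (ch in checks) {
    v <- df[[ch[1]]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop(sprintf("row %d (%s): %s", bad[1], df$name[bad[1]], ch[2]),
           call. = FALSE)
    }
  }
  bad <- which(!is.na(df$vapour_pressure_pa) & df$vapour_pressure_pa < 0)
  if (length(bad)) {
    stop(sprintf("row %d (%s): vapour pressure must be >= 0",
                 bad[1], df$name[bad[1]]), call. = FALSE)
  }
  for (col in c("henry_pa_m3_mol", "koc")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("row %d (%s): %s must be > 0 when present",
                   bad[1], df$name[bad[1]], col), call. = FALSE)
    }
  }
  bad <- which(!df$class_group %in% CLASS_GROUPS)
  if (length(bad)) {
    stop(sprintf("row %d: unknown class_group '%s'", bad[1],
                 df$class_group[bad[1]]), call. = FALSE)
  }
  invisible(df)
}

#' Read a compound property table
#'
#' Reads a table of per-compound physicochemical properties and partition
#' coefficients from CSV or JSON. The documented schema is
#' `name,cas,class_group,molar_mass_g_mol,melting_point_c,vapour_pressure_pa,`
#' `solubility_mg_l,henry_pa_m3_mol,log_kow,koc` with an optional
#' `provenance` column of semicolon-separated `field:source` tags. Empty
#' strings mark absent optional values (Henry's law constant and Koc);
#' thousands separators and unicode minus signs are normalised on ingest.
#' Every row is validated: the CAS number must pass its check-digit test,
#' molar mass and solubility must be positive, vapour pressure non-negative.
#'
#' @param path path to the file.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @return a `compound_tbl` data frame, one validated row per compound.
#' @seealso [write_compound_table()], [bundled_dataset()]
#' @export
read_compound_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (format == "csv") {
    read.csv(path, colClasses = "character", check.names = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(COMPOUND_COLS, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- raw[COMPOUND_COLS]
  for (col in COMPOUND_NUMERIC) df[[col]] <- parse_numeric(df[[col]], col)
  df$provenance <- if ("provenance" %in% names(raw)) {
    as.character(raw$provenance)
  } else {
    ""
  }
  df$provenance[is.na(df$provenance)] <- ""
  check_compound_rows(df)
  new_compound_tbl(df)
}

#' Write a compound property table
#'
#' Inverse of [read_compound_table()]; round-tripping is lossless.
#'
#' @param x a `compound_tbl`.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_compound_table <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  df <- as.data.frame(x)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

read_qualified_table <- function(path, value_cols) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  df <- data.frame(name = raw$name, cas = raw$cas, stringsAsFactors = FALSE)
  for (col in names(value_cols)) {
    colspec <- value_cols[[col]]
    q <- parse_qualified(raw[[colspec["src"]]], colspec["src"])
    df[[col]] <- q$value
    df[[paste0(col, "_qual")]] <- q$qualifier
    if (!is.na(colspec["model"])) {
      mdl <- as.character(raw[[colspec["model"]]])
      mdl[is.na(mdl)] <- ""
      df[[paste0(col, "_model")]] <- mdl
    }
    if (!is.na(colspec["pred"])) {
      df[[paste0(col, "_predicted")]] <-
        toupper(trimws(raw[[colspec["pred"]]])) == "TRUE"
    }
  }
  df
}

#' Packaged screening dataset: 20 plant volatiles and 5 synthetic nematicides
#'
#' Returns the packaged dataset underlying the comparative screen: five
#' compounds from each of four phytochemical classes (terpenes,
#' phenylpropanoids, organosulfur compounds, beta-keto acid/fatty acid
#' derivatives) and five synthetic nematicides, with their published
#' physicochemical properties, acute aquatic ecotoxicity thresholds
#' (fish LC50, algae EC50, *Daphnia magna* EC50, mg/L), mammalian acute oral
#' and dermal LD50 values (mg/kg), nematicidal EC50 records (mg/mL), and the
#' published predicted-environmental-distribution table used as the
#' reconstruction reference. All values were compiled from public databases
#' (PubChem, PPDB, ECHA) or QSAR predictions and are stored verbatim,
#' including `>` qualifiers and predicted-value flags; they are never
#' recomputed. Known quirks of the source tables are preserved as printed
#' (for instance the unusually low carvone water solubility of 27 mg/L,
#' well below common literature values).
#'
#' @return a list with elements `compounds` (a `compound_tbl`), `ecotox`,
#'   `mamm_tox`, `activity`, and `ped_reference` (data frames).
#' @examples
#' d <- bundled_dataset()
#' subset(d$compounds, cas == "23135-22-0")
#' @export
bundled_dataset <- function() {
  ext <- function(f) system.file("extdata", f, package = "fugascreen",
                                 mustWork = TRUE)
  compounds <- read_compound_table(ext("compound_properties.csv"))
  ecotox <- read_qualified_table(ext("aquatic_toxicity.csv"), list(
    fish_lc50 = c(src = "fish_lc50_mg_l", model = "fish_species",
                  pred = "fish_predicted"),
    algae_ec50 = c(src = "algae_ec50_mg_l", model = "algae_species",
                   pred = "algae_predicted"),
    invertebrate_ec50 = c(src = "invertebrate_ec50_mg_l",
                          model = "invertebrate_species",
                          pred = "invertebrate_predicted")
  ))
  mamm <- read_qualified_table(ext("mammalian_toxicity.csv"), list(
    oral_ld50 = c(src = "oral_ld50_mg_kg", model = "oral_model",
                  pred = "oral_predicted"),
    dermal_ld50 = c(src = "dermal_ld50_mg_kg", model = "dermal_model",
                    pred = "dermal_predicted")
  ))
  act_raw <- read.csv(ext("nematicidal_activity.csv"),
                      colClasses = "character")
  activity <- data.frame(
    name = act_raw$name, cas = act_raw$cas,
    target_species = act_raw$target_species,
    ec50_low = parse_numeric(act_raw$ec50_low_mg_ml, "ec50_low_mg_ml"),
    ec50_high = parse_numeric(act_raw$ec50_high_mg_ml, "ec50_high_mg_ml"),
    qualifier = act_raw$qualifier,
    note = act_raw$note,
    stringsAsFactors = FALSE
  )
  ped_ref <- read.csv(ext("ped_reference.csv"), stringsAsFactors = FALSE)
  stopifnot(all(ecotox$cas %in% compounds$cas),
            all(mamm$cas %in% compounds$cas),
            all(activity$cas %in% compounds$cas))
  list(compounds = compounds, ecotox = ecotox, mamm_tox = mamm,
       activity = activity, ped_reference = ped_ref)
}

#' Validate a single compound record
#'
#' Checks one compound record against the registry invariants and reports
#' whether it is ready for the Level I fugacity model. Violations are
#' returned as data, not raised: the loader enforces hard constraints, this
#' helper supports interactive triage and the estimation audit trail.
#'
#' Completeness status:
#' \describe{
#'   \item{`model-ready`}{Henry's law constant and Koc both present.}
#'   \item{`needs-estimation`}{one or both absent but derivable (H from
#'     vapour pressure, molar mass and solubility; Koc from logKow via the
#'     Seth relation).}
#'   \item{`insufficient`}{a required quantity is neither present nor
#'     derivable, or a validity constraint is violated.}
#' }
#'
#' @param record a one-row `compound_tbl` slice, or a named list with the
#'   same fields.
#' @return a list with `violations` (character vector, possibly empty) and
#'   `status` (one of the three labels above).
#' @export
validate_record <- function(record) {
  r <- as.list(record)
  num <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)
  violations <- character()
  add <- function(v, msg) if (v) c(violations, msg) else violations

  m <- num(r$molar_mass_g_mol); s <- num(r$solubility_mg_l)
  vp <- num(r$vapour_pressure_pa); h <- num(r$henry_pa_m3_mol)
  lk <- num(r$log_kow); koc <- num(r$koc)

  violations <- add(is.na(m) || m <= 0, "molar_mass_g_mol must be > 0")
  violations <- add(is.na(s) || s <= 0,
                    "solubility_mg_l must be > 0 (division by zero downstream)")
  violations <- add(!is.na(vp) && vp < 0, "vapour_pressure_pa must be >= 0")
  violations <- add(!is.na(h) && h <= 0, "henry_pa_m3_mol must be > 0")
  violations <- add(!is.na(koc) && koc <= 0, "koc must be > 0")
  violations <- add(!is.null(r$cas) && !cas_is_valid(r$cas),
                    "cas fails format or checksum")
  violations <- add(!is.null(r$class_group) &&
                      !r$class_group %in% CLASS_GROUPS,
                    "class_group not one of the five recognised groups")

  h_ok <- !is.na(h) || (!is.na(vp) && !is.na(m) && !is.na(s) && s > 0 && m > 0)
  koc_ok <- !is.na(koc) || !is.na(lk)
  status <- if (length(violations)) {
    "insufficient"
  } else if (!is.na(h) && !is.na(koc)) {
    "model-ready"
  } else if (h_ok && koc_ok) {
    "needs-estimation"
  } else {
    "insufficient"
  }
  list(violations = violations, status = status)
}
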