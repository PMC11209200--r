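#' Fold difference between two toxicity thresholds
#'
#' How many fold lower `value_a` is than `value_b`: `ratio = value_b /
#' value_a`. When the numerator (`value_b`) carries a `">"` qualifier the
#' true ratio is at least as large, so the result is qualified `"ge"`; a
#' `">"` on the denominator caps the ratio, giving `"le"`; both give the
#' unqualified point estimate with qualifier `"uncertain"`.
#'
#' @param value_a,value_b positive thresholds (same units).
#' @param qual_a,qual_b `"eq"` or `"gt"`.
#' @return list with `ratio` and `qualifier` (`"eq"`, `"ge"`, `"le"` or
#'   `"uncertain"`).
#' @examples
#' fold_difference(0.3, 120, qual_b = "gt") # at least 400-fold
#' @export
fold_difference <- function(value_a, value_b, qual_a = "eq", qual_b = "eq") {
  if (any(c(value_a, value_b) <= 0) || anyNA(c(value_a, value_b))) {
    stop("both values must be > 0", call. = FALSE)
  }
  qualifier <- ifelse(qual_a == "gt" & qual_b == "gt", "uncertain",
                      ifelse(qual_b == "gt", "ge",
                             ifelse(qual_a == "gt", "le", "eq")))
  list(ratio = value_b / value_a, qualifier = qualifier)
}

# "ca. N-fold" display convention: ratios rounded to the nearest 10.
round_fold <- function(ratio) round_percent(ratio / 10, 0) * 10

#' Default screening thresholds
#'
#' The exposure-by-hazard crossing is rule-transparent: a compartment
#' affinity flag fires when that compartment holds at least
#' `affinity_percent` of the emitted mass; `aquatic_concern` when the
#' compound is water-affine and its minimum aquatic threshold is below
#' `aquatic_mg_l`; `mammalian_concern` when the GHS oral category is at or
#' below `ghs_oral_max`. All values are echoed into the report.
#'
#' @return named list of thresholds.
#' @export
default_screen_config <- function() {
  list(affinity_percent = 50, aquatic_mg_l = 10, ghs_oral_max = 2)
}

#' Integrated exposure-by-hazard screening
#'
#' Joins the Level I distribution table with the aquatic and mammalian
#' hazard summaries per compound and applies the configured flag rules.
#' Missing endpoints never silently pass: compounds without aquatic data
#' or without an oral LD50 are marked `insufficient_data:<which>` instead
#' of receiving the corresponding concern flag. `non_reconstructable`
#' distribution flags are carried through from the input table.
#'
#' @param ped a `ped_tbl` from [batch_distribute()].
#' @param ecotox aquatic endpoint table (as `bundled_dataset()$ecotox`);
#'   rows may be missing for some compounds.
#' @param hazard classification table from [classify_hazard_table()].
#' @param compounds the compound table (for class groups).
#' @param config list from [default_screen_config()] (any element may be
#'   overridden).
#' @param comparisons optional data frame of fold-difference requests with
#'   columns `endpoint` (`fish_lc50`, `algae_ec50` or `invertebrate_ec50`),
#'   `compound_a`, `compound_b` (CAS).
#' @return object of class `screening_report`: list with `rows` (one row
#'   per compound: distribution, dominant compartment, aquatic minimum,
#'   GHS categories, semicolon-joined `flags`), `comparisons`, and
#'   `config_echo`.
#' @export
screen_compounds <- function(ped, ecotox, hazard, compounds,
                             config = default_screen_config(),
                             comparisons = NULL) {
  cfg <- utils::modifyList(default_screen_config(), config)
  aq <- aquatic_minimum(ecotox)
  rows <- data.frame(cas = ped$cas, name = ped$name, stringsAsFactors = FALSE)
  rows$class_group <- compounds$class_group[match(rows$cas, compounds$cas)]
  for (c in COMPARTMENTS) rows[[c]] <- ped[[c]]
  # dominant compartment: arg-max, ties broken in the documented
  # alphabetical compartment order (aerosols, air, biota, sediment, soil,
  # suspended_particles, water)
  pct <- as.matrix(ped[COMPARTMENTS])
  rows$dominant_compartment <- apply(pct, 1, function(p) {
    if (anyNA(p)) NA_character_ else COMPARTMENTS[which.max(p)]
  })
  j_aq <- match(rows$cas, aq$cas)
  rows$min_aquatic_mg_l <- aq$min_threshold[j_aq]
  rows$limiting_trophic_group <- aq$limiting_trophic_group[j_aq]
  rows$aquatic_qualifier <- aq$qualifier[j_aq]
  j_hz <- match(rows$cas, hazard$cas)
  rows$ghs_oral <- hazard$ghs_oral[j_hz]
  rows$ghs_dermal <- hazard$ghs_dermal[j_hz]
  rows$toxicity_band <- hazard$toxicity_band[j_hz]

  flags <- lapply(seq_len(nrow(rows)), function(i) {
    f <- character()
    p <- pct[i, ]
    if (!anyNA(p)) {
      if (p[["water"]] >= cfg$affinity_percent) f <- c(f, "water_affine")
      if (p[["air"]] >= cfg$affinity_percent) f <- c(f, "air_disperser")
      if (p[["soil"]] >= cfg$affinity_percent) f <- c(f, "soil_affine")
    }
    if (is.na(rows$min_aquatic_mg_l[i])) {
      f <- c(f, "insufficient_data:aquatic")
    } else if ("water_affine" %in% f &&
               rows$min_aquatic_mg_l[i] < cfg$aquatic_mg_l) {
      f <- c(f, "aquatic_concern")
    }
    if (is.na(rows$ghs_oral[i])) {
      f <- c(f, "insufficient_data:oral")
    } else if (rows$ghs_oral[i] <= cfg$ghs_oral_max) {
      f <- c(f, "mammalian_concern")
    }
    if (nzchar(ped$flags[i]) && grepl("non_reconstructable", ped$flags[i])) {
      f <- c(f, "non_reconstructable_ped")
    }
    f
  })
  rows$flags <- vapply(flags, paste, character(1), collapse = ";")

  comp_out <- NULL
  if (!is.null(comparisons)) {
    comp_out <- comparisons
    comp_out$ratio <- NA_real_
    comp_out$ratio_rounded <- NA_real_
    comp_out$qualifier <- NA_character_
    for (k in seq_len(nrow(comparisons))) {
      col <- comparisons$endpoint[k]
      ia <- match(comparisons$compound_a[k], ecotox$cas)
      ib <- match(comparisons$compound_b[k], ecotox$cas)
      fd <- fold_difference(ecotox[[col]][ia], ecotox[[col]][ib],
                            ecotox[[paste0(col, "_qual")]][ia],
                            ecotox[[paste0(col, "_qual")]][ib])
      comp_out$ratio[k] <- fd$ratio
      comp_out$ratio_rounded[k] <- round_fold(fd$ratio)
      comp_out$qualifier[k] <- fd$qualifier
    }
  }
  structure(list(rows = rows, comparisons = comp_out, config_echo = cfg),
            class = "screening_report")
}

#' Per-class aggregate of a screening report
#'
#' Medians of the full-precision distribution percentages and counts of
#' each flag, by compound class. Empty classes are omitted; a class of one
#' reports that compound's own values.
#'
#' @param report a `screening_report`.
#' @return data frame, one row per class group present.
#' @export
class_summary <- function(report) {
  rows <- report$rows
  stopifnot(nrow(rows) > 0)
  flag_names <- c("water_affine", "air_disperser", "soil_affine",
                  "aquatic_concern", "mammalian_concern",
                  "non_reconstructable_ped")
  out <- lapply(split(rows, rows$class_group), function(g) {
    med <- vapply(COMPARTMENTS, function(c) median(g[[c]], na.rm = TRUE),
                  numeric(1))
    cnt <- vapply(flag_names, function(f) {
      sum(vapply(strsplit(g$flags, ";"), function(x) f %in% x, logical(1)))
    }, numeric(1))
    c(list(class_group = g$class_group[1], n = nrow(g)),
      setNames(as.list(med), paste0("median_", COMPARTMENTS)),
      setNames(as.list(cnt), paste0("n_", flag_names)))
  })
  out <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$class_group), ]
}

#' Write a screening report
#'
#' Serialises a report to CSV (rows + comparisons as separate files),
#' JSON (one document), or markdown (joined tables plus a comparisons
#' section). Output is bit-stable for fixed input and configuration: no
#' timestamps enter the payload.
#'
#' @param report a `screening_report`.
#' @param path output file (for `csv`, the comparisons table lands next to
#'   it as `<path stem>_comparisons.csv`).
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return the main output path, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  rows <- report$rows
  if (format == "csv") {
    write.csv(rows, path, row.names = FALSE, na = "")
    if (!is.null(report$comparisons)) {
      cpath <- paste0(tools::file_path_sans_ext(path), "_comparisons.csv")
      write.csv(report$comparisons, cpath, row.names = FALSE, na = "")
    }
  } else if (format == "json") {
    jsonlite::write_json(
      list(rows = rows, comparisons = report$comparisons,
           config = report$config_echo),
      path, dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  } else {
    md <- c("# Screening report", "", md_table(rows), "", "## Comparisons",
            "")
    if (!is.null(report$comparisons)) {
      md <- c(md, md_table(report$comparisons))
    } else {
      md <- c(md, "(none requested)")
    }
    md <- c(md, "", "## Configuration", "",
            sprintf("- %s: %s", names(report$config_echo),
                    unlist(report$config_echo)))
    writeLines(md, path)
  }
  invisible(path)
}

md_table <- function(df) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) {
      ifelse(is.na(col), "", format(round(col, 3), trim = TRUE,
                                    drop0trailing = TRUE))
    } else {
      ifelse(is.na(col), "", as.character(col))
    }
  }, character(nrow(df)))
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                           " |"))
  c(header, sep, body)
}

#' Read a screening report back from JSON
#'
#' Round-trip counterpart of `write_report(..., format = "json")`.
#'
#' @param path JSON file written by [write_report()].
#' @return a `screening_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(rows = as.data.frame(x$rows),
                 comparisons = if (is.null(x$comparisons)) NULL else
                   as.data.frame(x$comparisons),
                 config_echo = x$config),
            class = "screening_report")
}
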