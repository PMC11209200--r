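GHS_ORAL_CUTOFFS <- c(5, 50, 300, 2000, 5000)
GHS_DERMAL_CUTOFFS <- c(50, 200, 1000, 2000)

# Interval convention: left-open, right-closed everywhere, i.e. a cutpoint
# value belongs to the more severe class ((0,5] -> 1, (5,50] -> 2, ...).
# A ">" qualifier classifies the value immediately above the bound.
classify_on_cutoffs <- function(ld50, qualifier, cutoffs) {
  if (any(is.na(ld50)) || any(ld50 <= 0)) {
    stop("LD50 values must be > 0", call. = FALSE)
  }
  qualifier <- rep_len(ifelse(is.na(qualifier), "eq", qualifier),
                       length(ld50))
  eff <- ifelse(qualifier == "gt", ld50 * (1 + 1e-12), ld50)
  # findInterval with left.open gives the count of cutoffs < eff under
  # right-closed intervals
  findInterval(eff, cutoffs, left.open = TRUE) + 1L
}

#' GHS acute oral toxicity category
#'
#' Assigns categories 1 (most severe) to 5 from a rat oral LD50 (mg/kg)
#' using the harmonised cut-offs 5, 50, 300, 2000 and 5000 mg/kg, with
#' left-open, right-closed intervals: (0,5] is category 1, (5,50] category
#' 2, and so on. Values above 5000 mg/kg fall outside the five GHS
#' categories; by default they are reported as category 5 (the least
#' severe class also used for "effectively non-toxic" screening summaries),
#' or as `NA` when `above_5000 = "unclassified"`.
#'
#' A `">"` qualifier means the true LD50 exceeds the stated bound, so the
#' value is classified as if infinitesimally above it: `>2000` gives
#' category 5, `>50` category 3.
#'
#' @param ld50 numeric vector of oral LD50 values, mg/kg; must be > 0.
#' @param qualifier `"eq"` (default) or `"gt"`, recycled.
#' @param above_5000 `"category5"` (default) or `"unclassified"`.
#' @return integer vector of categories (1-5, or `NA` if unclassified).
#' @examples
#' classify_ghs_oral(c(3, 5, 671, 7936))
#' classify_ghs_oral(2000, qualifier = "gt")
#' @export
classify_ghs_oral <- function(ld50, qualifier = "eq",
                              above_5000 = c("category5", "unclassified")) {
  above_5000 <- match.arg(above_5000)
  cat <- classify_on_cutoffs(ld50, qualifier, GHS_ORAL_CUTOFFS)
  if (above_5000 == "category5") {
    pmin(cat, 5L)
  } else {
    ifelse(cat > 5L, NA_integer_, cat)
  }
}

#' GHS acute dermal toxicity category
#'
#' Cut-offs 50, 200, 1000 and 2000 mg/kg with the same left-open,
#' right-closed convention as [classify_ghs_oral()]; everything above
#' 2000 mg/kg is category 5 (the dermal scheme's top band is unbounded).
#' `">2000"` therefore classifies as category 5, while an unqualified 2000
#' classifies as category 4 -- a deliberate divergence from summaries that
#' treat printed 2000s as "above 2000".
#'
#' @inheritParams classify_ghs_oral
#' @param ld50 dermal LD50 values, mg/kg.
#' @return integer vector of categories 1-5.
#' @export
classify_ghs_dermal <- function(ld50, qualifier = "eq") {
  pmin(classify_on_cutoffs(ld50, qualifier, GHS_DERMAL_CUTOFFS), 5L)
}

#' Six-band GHS toxicity class from an oral LD50
#'
#' The six-band scheme used by computational toxicology tools: bands 1-5
#' coincide with the GHS oral categories ((0,5], (5,50], (50,300],
#' (300,2000], (2000,5000] mg/kg) and band 6 collects everything above
#' 5000 mg/kg ("non-toxic").
#'
#' @inheritParams classify_ghs_oral
#' @return integer vector of bands 1-6.
#' @examples
#' classify_toxicity_band(c(3, 5000, 5001, 7936))
#' @export
classify_toxicity_band <- function(ld50, qualifier = "eq") {
  classify_on_cutoffs(ld50, qualifier, GHS_ORAL_CUTOFFS)
}

#' Classify a mammalian toxicity table
#'
#' Applies [classify_ghs_oral()], [classify_ghs_dermal()] and
#' [classify_toxicity_band()] across a mammalian endpoint table (as in
#' `bundled_dataset()$mamm_tox`), carrying qualifiers and annotating rows
#' whose input carried a `">"` bound.
#'
#' @param mamm_tox data frame with `cas`, `name`, `oral_ld50`,
#'   `oral_ld50_qual`, and optionally `dermal_ld50`, `dermal_ld50_qual`.
#' @inheritParams classify_ghs_oral
#' @return data frame `cas, name, oral_ld50, ghs_oral, dermal_ld50,
#'   ghs_dermal, toxicity_band, boundary_rule, notes`.
#' @export
classify_hazard_table <- function(mamm_tox,
                                  above_5000 = c("category5",
                                                 "unclassified")) {
  above_5000 <- match.arg(above_5000)
  oral_ok <- !is.na(mamm_tox$oral_ld50)
  dermal_ok <- !is.na(mamm_tox$dermal_ld50)
  ghs_oral <- rep(NA_integer_, nrow(mamm_tox))
  band <- rep(NA_integer_, nrow(mamm_tox))
  ghs_dermal <- rep(NA_integer_, nrow(mamm_tox))
  if (any(oral_ok)) {
    ghs_oral[oral_ok] <- classify_ghs_oral(mamm_tox$oral_ld50[oral_ok],
                                           mamm_tox$oral_ld50_qual[oral_ok],
                                           above_5000)
    band[oral_ok] <- classify_toxicity_band(mamm_tox$oral_ld50[oral_ok],
                                            mamm_tox$oral_ld50_qual[oral_ok])
  }
  if (any(dermal_ok)) {
    ghs_dermal[dermal_ok] <-
      classify_ghs_dermal(mamm_tox$dermal_ld50[dermal_ok],
                          mamm_tox$dermal_ld50_qual[dermal_ok])
  }
  notes <- ifelse(oral_ok & mamm_tox$oral_ld50_qual == "gt",
                  "oral LD50 is a lower bound", "")
  notes2 <- ifelse(dermal_ok & mamm_tox$dermal_ld50_qual == "gt",
                   "dermal LD50 is a lower bound", "")
  notes <- trimws(paste(notes, notes2, sep = "; "))
  notes <- gsub("^; |; $", "", notes)
  data.frame(cas = mamm_tox$cas, name = mamm_tox$name,
             oral_ld50 = mamm_tox$oral_ld50, ghs_oral = ghs_oral,
             dermal_ld50 = mamm_tox$dermal_ld50, ghs_dermal = ghs_dermal,
             toxicity_band = band,
             boundary_rule = "left-open right-closed; '>' promotes above bound",
             notes = notes, stringsAsFactors = FALSE)
}

#' Minimum acute aquatic threshold across trophic groups
#'
#' For each compound, the smallest present endpoint among fish LC50, algae
#' EC50 and invertebrate EC50 (mg/L), with the limiting trophic group and
#' the qualifier of that endpoint. `">"`-qualified values compare by their
#' stated bound. Ties resolve in the order fish, algae, invertebrates.
#'
#' @param ecotox data frame as `bundled_dataset()$ecotox`.
#' @return data frame `cas, name, min_threshold, limiting_trophic_group,
#'   qualifier`. Errors if a row has no endpoint at all.
#' @examples
#' aquatic_minimum(bundled_dataset()$ecotox)
#' @export
aquatic_minimum <- function(ecotox) {
  groups <- c(fish = "fish_lc50", algae = "algae_ec50",
              invertebrates = "invertebrate_ec50")
  vals <- sapply(groups, function(col) ecotox[[col]])
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, names(groups)))
  no_data <- apply(vals, 1, function(r) all(is.na(r)))
  if (any(no_data)) {
    stop(sprintf("row %d (%s): no aquatic endpoint present",
                 which(no_data)[1], ecotox$name[which(no_data)[1]]),
         call. = FALSE)
  }
  idx <- apply(vals, 1, which.min)
  qual_cols <- paste0(groups, "_qual")
  data.frame(
    cas = ecotox$cas, name = ecotox$name,
    min_threshold = vals[cbind(seq_len(nrow(vals)), idx)],
    limiting_trophic_group = names(groups)[idx],
    qualifier = vapply(seq_along(idx), function(i) {
      q <- ecotox[[qual_cols[idx[i]]]][i]
      if (is.na(q)) "eq" else q
    }, character(1)),
    stringsAsFactors = FALSE
  )
}
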