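test_that("fold differences reproduce the published daphnia comparisons", {
  d <- bundled_dataset()$ecotox
  v <- function(nm) d$invertebrate_ec50[d$name == nm]
  q <- function(nm) d$invertebrate_ec50_qual[d$name == nm]
  flz <- "Fluazaindolizine"
  fd_oxa <- fold_difference(v("Oxamyl"), v(flz), q("Oxamyl"), q(flz))
  expect_equal(fd_oxa$ratio, 400)
  expect_equal(fd_oxa$qualifier, "ge")  # >120 numerator: at least 400-fold
  fd_met <- fold_difference(v("Metam sodium"), v(flz), "eq", q(flz))
  expect_equal(fd_met$ratio, 120)
  fd_flu <- fold_difference(v("Fluensulfone"), v(flz), "eq", q(flz))
  expect_equal(fd_flu$ratio, 150)
  expect_equal(fold_difference(5, 5)$ratio, 1)
  expect_error(fold_difference(0, 5), "must be > 0")
})

test_that("fold_difference(a,b) * fold_difference(b,a) = 1 for unqualified pairs", {
  set.seed(11)
  a <- 10^runif(20, -3, 3); b <- 10^runif(20, -3, 3)
  for (i in seq_along(a)) {
    expect_equal(fold_difference(a[i], b[i])$ratio *
                   fold_difference(b[i], a[i])$ratio, 1)
  }
})

full_screen <- function() {
  d <- bundled_dataset()
  ped <- batch_distribute(d$compounds, reference = d$ped_reference)
  hz <- classify_hazard_table(d$mamm_tox)
  screen_compounds(ped, d$ecotox, hz, d$compounds,
                   comparisons = data.frame(
                     endpoint = "invertebrate_ec50",
                     compound_a = c("23135-22-0", "137-42-8", "318290-98-1"),
                     compound_b = "1254304-22-7"))
}

test_that("screening flags follow the documented rules on the packaged data", {
  rep <- full_screen()
  rows <- rep$rows
  fl <- function(nm) strsplit(rows$flags[rows$name == nm], ";")[[1]]
  expect_setequal(fl("Oxamyl"),
                  c("water_affine", "aquatic_concern", "mammalian_concern"))
  # carvone: air-dominant and mild thresholds -> no concern flags
  expect_false(any(c("aquatic_concern", "mammalian_concern") %in%
                     fl("Carvone")))
  expect_equal(rows$dominant_compartment[rows$name == "Fluopyram"], "soil")
  expect_equal(rows$dominant_compartment[rows$name == "Oxamyl"], "water")
  # comparisons round to the published "ca." values
  expect_equal(rep$comparisons$ratio_rounded, c(400, 120, 150))
  # config echo allows exact re-derivation
  expect_equal(rep$config_echo$affinity_percent, 50)
})

test_that("missing endpoints yield insufficient-data markers, not silent passes", {
  d <- bundled_dataset()
  ped <- batch_distribute(d$compounds[1:2, ])
  hz <- classify_hazard_table(d$mamm_tox[1:2, ])
  eco <- d$ecotox[1:2, ]
  # drop compound 2 from the aquatic table entirely
  rep <- screen_compounds(ped, eco[1, , drop = FALSE], hz,
                          d$compounds[1:2, ])
  fl2 <- strsplit(rep$rows$flags[2], ";")[[1]]
  expect_true("insufficient_data:aquatic" %in% fl2)
  expect_false("aquatic_concern" %in% fl2)
})

test_that("screening is a pure function of its echoed config", {
  rep <- full_screen()
  d <- bundled_dataset()
  ped <- batch_distribute(d$compounds, reference = d$ped_reference)
  hz <- classify_hazard_table(d$mamm_tox)
  rep2 <- screen_compounds(ped, d$ecotox, hz, d$compounds,
                           config = rep$config_echo,
                           comparisons = rep$comparisons[
                             c("endpoint", "compound_a", "compound_b")])
  expect_equal(rep2$rows, rep$rows)
  expect_equal(rep2$comparisons, rep$comparisons)
})

test_that("class summary aggregates medians and flag counts per class", {
  rep <- full_screen()
  cs <- class_summary(rep)
  expect_equal(sort(cs$class_group), sort(unique(rep$rows$class_group)))
  # four of the five synthetic pesticides are water-affine, fluopyram not
  expect_equal(cs$n_water_affine[cs$class_group == "pesticide"], 4)
  expect_equal(cs$n[cs$class_group == "pesticide"], 5)
  # single-compound class reports its own values
  one <- rep; one$rows <- rep$rows[rep$rows$name == "Oxamyl", ]
  cs1 <- class_summary(one)
  expect_equal(cs1$median_water, rep$rows$water[rep$rows$name == "Oxamyl"])
})

test_that("reports serialise bit-stably and round-trip through JSON", {
  rep <- full_screen()
  dir <- tempfile(); dir.create(dir)
  csv <- file.path(dir, "report.csv")
  write_report(rep, csv, "csv")
  expect_true(file.exists(csv))
  expect_true(file.exists(file.path(dir, "report_comparisons.csv")))
  expect_equal(nrow(read.csv(csv)), 25)
  # bit-stable: same input, same bytes
  csv2 <- file.path(dir, "report2.csv")
  write_report(rep, csv2, "csv")
  expect_identical(readLines(csv), readLines(csv2))
  js <- file.path(dir, "report.json")
  write_report(rep, js, "json")
  back <- read_report(js)
  expect_equal(back$rows$flags, rep$rows$flags)
  md <- file.path(dir, "report.md")
  write_report(rep, md, "markdown")
  lines <- readLines(md)
  expect_equal(sum(lines == "## Comparisons"), 1)
  unlink(dir, recursive = TRUE)
})
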