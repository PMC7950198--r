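# The 63 pilot-study derived-trait labels (printed association table order
# within each site: branching, fucosylation, then descending sialylation
# ratio); the temporal-stability study lacks three of them.
TRAITS_63 <- c(
  paste("I_1", c("BiAnt", "TriAnt", "TetraAnt", "F", "S1/1", "S3/4", "S2/3", "S1/2", "S1/3")),
  paste("I_12", c("BiAnt", "TriAnt", "TetraAnt", "F", "S1/1", "S3/4", "S2/3", "S1/2", "S1/3")),
  paste("II_12", c("BiAnt", "TriAnt", "TetraAnt", "F", "S1/1", "S3/4", "S2/3", "S1/2", "S1/3")),
  paste("III_12", c("BiAnt", "TriAnt", "TetraAnt", "F", "S1/1", "S3/4", "S2/3", "S1/2", "S1/3", "S1/4")),
  paste("IV_1", c("BiAnt", "TriAnt", "TetraAnt", "F", "S1/1", "S3/4", "S2/3", "S1/2", "S1/3", "S1/4")),
  paste("V_1", c("TriAnt", "TetraAnt", "F", "S1/1", "S3/4", "S2/3", "S1/2")),
  paste("V_2", c("BiAnt", "TriAnt", "TetraAnt", "F", "S1/1", "S3/4", "S2/3", "S1/2", "S1/3"))
)
STABILITY_ABSENT <- c("I_1 TetraAnt", "I_1 S3/4", "III_12 S1/4")

test_that("branching classification follows the capped-HexNAc rule", {
  expect_equal(antennarity("N4H5S2")$class, "BiAnt")
  expect_equal(antennarity("N5H6S3")$class, "TriAnt")
  a <- antennarity("N7H8S4")
  expect_equal(a$class, "TetraAnt")
  expect_equal(a$antennae, 4)
  expect_equal(a$lacnac_repeats, 1)
  expect_error(antennarity("N3H4S1"), "fewer than 4")
})

test_that("sialylation class is the reduced sialic-per-galactose ratio", {
  expect_equal(sialylation_class("N5H6S3")$label, "S1/1")
  expect_equal(sialylation_class("N6H7S3")$label, "S3/4")
  expect_equal(sialylation_class("N6H7S1")$label, "S1/4")
  expect_equal(sialylation_class("N4H5S1")$label, "S1/2")
  expect_equal(sialylation_class("N7H8S4")$label, "S1/1") # capped denominator
  expect_equal(sialylation_class("N4H5S0")$label, "S0")
  expect_error(sialylation_class("N4H5S3"), "oversialylated")
})

test_that("the bundled library enumerates exactly the 63 pilot-study traits", {
  defs <- enumerate_traits(AGP_LIB)
  expect_identical(defs$trait, TRAITS_63)
  # the stability study's 60 traits are these minus three
  expect_equal(setdiff(TRAITS_63, STABILITY_ABSENT), TRAITS_63[!TRAITS_63 %in% STABILITY_ABSENT])
  expect_length(setdiff(TRAITS_63, STABILITY_ABSENT), 60)
  # every member belongs to its site's composition set
  for (i in seq_len(nrow(defs))) {
    site_comps <- AGP_LIB$composition[AGP_LIB$site_group == defs$site_group[i]]
    expect_true(all(defs$members[[i]] %in% site_comps))
    expect_gt(length(defs$members[[i]]), 0)
  }
})

test_that("single-composition sites produce only the applicable traits", {
  lib1 <- AGP_LIB[AGP_LIB$site_group == "II_12" & AGP_LIB$composition == "N4H5S2", ]
  class(lib1) <- class(AGP_LIB)
  defs <- enumerate_traits(lib1)
  expect_setequal(defs$trait, c("II_12 BiAnt", "II_12 S1/1")) # no F trait
})

test_that("trait values are member-fraction sums with missing propagation", {
  ab <- data.frame(
    sample = "s1", site_group = "II_12",
    composition = c("N4H5S2", "N5H6S3", "N5H6S3F1"),
    fraction = c(0.2, 0.5, 0.3), stringsAsFactors = FALSE
  )
  lib <- AGP_LIB[AGP_LIB$site_group == "II_12" &
                   AGP_LIB$composition %in% ab$composition, ]
  class(lib) <- class(AGP_LIB)
  tt <- compute_traits(ab, enumerate_traits(lib))
  expect_equal(tt[["II_12 BiAnt"]], 0.2)
  expect_equal(tt[["II_12 TriAnt"]], 0.8)
  expect_equal(tt[["II_12 F"]], 0.3)
  expect_equal(tt[["II_12 S1/1"]], 1.0)

  # all mass on one composition
  ab2 <- ab; ab2$fraction <- c(1, 0, 0)
  tt2 <- compute_traits(ab2, enumerate_traits(lib))
  expect_equal(tt2[["II_12 BiAnt"]], 1)
  expect_equal(tt2[["II_12 TriAnt"]], 0)

  # NA member fraction propagates to the trait
  ab3 <- ab; ab3$fraction[2] <- NA
  tt3 <- compute_traits(ab3, enumerate_traits(lib))
  expect_true(is.na(tt3[["II_12 TriAnt"]]))
  expect_equal(tt3[["II_12 BiAnt"]], 0.2)

  # unknown composition in a definition is an error
  defs <- enumerate_traits(lib)
  defs$members[[1]] <- c(defs$members[[1]], "N9H9S1")
  expect_error(compute_traits(ab, defs), "absent")
})

test_that("branching and sialylation traits partition each site", {
  set.seed(33)
  # random fractions over the full library, two samples
  ab <- do.call(rbind, lapply(c("s1", "s2"), function(s) {
    do.call(rbind, lapply(unique(AGP_LIB$site_group), function(sg) {
      comps <- AGP_LIB$composition[AGP_LIB$site_group == sg]
      fr <- runif(length(comps)); fr <- fr / sum(fr)
      data.frame(sample = s, site_group = sg, composition = comps,
                 fraction = fr, stringsAsFactors = FALSE)
    }))
  }))
  defs <- enumerate_traits(AGP_LIB)
  tt <- compute_traits(ab, defs)
  expect_true(all(tt[, -1] >= 0 & tt[, -1] <= 1 + 1e-12))
  for (sg in unique(defs$site_group)) {
    br <- defs$trait[defs$site_group == sg & defs$kind == "branching"]
    si <- defs$trait[defs$site_group == sg & defs$kind == "sialylation"]
    expect_equal(unname(rowSums(tt[, br, drop = FALSE])), c(1, 1), tolerance = 1e-9)
    expect_equal(unname(rowSums(tt[, si, drop = FALSE])), c(1, 1), tolerance = 1e-9)
  }
})
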