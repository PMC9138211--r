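test_that("component category maps reproduce the published point values", {
  expect_identical(score_age(c(10, 38, 39)), c(15L, 6L, 3L))
  expect_identical(score_clinical("rhinitis"), 9L)
  expect_identical(score_clinical(c("rhinitis", "asthma")), 6L)
  expect_identical(score_clinical(c("rhinitis", "asthma", "other_allergies")), 3L)
  expect_error(score_clinical("asthma"), "rhinitis")
  expect_identical(score_onset(c(2, 10, 11)), c(9L, 6L, 3L))
  expect_identical(score_sensitizations(c(1, 3, 6)), c(16L, 12L, 4L))
  expect_error(score_sensitizations(0), "ineligible")
  expect_identical(score_exposure(c(1, 3, 7)), c(12L, 6L, 3L))
  expect_identical(score_ratio(c(20, 10, 4), 100), c(12L, 8L, 4L))
  expect_error(score_ratio(5, 0), "total_ige")
  expect_identical(score_crd(c("high_positive", "positive", "negative")),
                   c(12L, 6L, 0L))
  expect_identical(score_dominance(c(1, 3, 4)), c(15L, 5L, 0L))
})

test_that("best-, worst- and mid-case patients sum to 100, 20 and 71", {
  best <- make_record(age = 10, diseases = "rhinitis", onset = 2, exposure = 1,
                      wheal = c(grass = 9), specific = c(grass = 25),
                      component = c("Phl p1" = 5), total_ige = 100)
  expect_identical(compute_pris(best)$total, 100L)

  # six equal sensitizations (all co-dominant, > 3 dominant), s/t = 0.01,
  # no CRD component assayed
  srcs <- c("grass", "mite", "pellitory", "cat", "dog", "olive")
  worst <- make_record(age = 40,
                       diseases = c("rhinitis", "asthma", "other_allergies"),
                       act = 22, onset = 15, exposure = 5,
                       wheal = setNames(rep(6, 6), srcs),
                       specific = setNames(rep(1, 6), srcs),
                       total_ige = 100)
  b <- compute_pris(worst)
  expect_identical(b$total, 20L)
  expect_identical(b$crd_score, 0L)
  expect_identical(b$dominance_score, 0L)

  mid <- make_record(age = 25, diseases = c("rhinitis", "asthma"), act = 21,
                     onset = 5, exposure = 2,
                     wheal = c(grass = 9, mite = 3),
                     specific = c(grass = 10, mite = 1),
                     component = c("Phl p1" = 1.2), total_ige = 100)
  b <- compute_pris(mid)
  expect_identical(b$total, 71L)
  expect_identical(unlist(b[c("age_score", "clinical_score", "onset_score",
                              "sensitization_score", "exposure_score",
                              "ratio_score", "crd_score", "dominance_score")],
                          use.names = FALSE),
                   c(9L, 6L, 6L, 12L, 9L, 8L, 6L, 15L))
})

test_that("rhinitis plus other allergies without asthma takes the one-comorbidity tier and is flagged", {
  rec <- make_record(diseases = c("rhinitis", "other_allergies"))
  b <- compute_pris(rec)
  expect_identical(b$clinical_score, 6L)
  expect_true(b$extrapolated_clinical)
  expect_false(compute_pris(make_record())$extrapolated_clinical)
})

test_that("the CRD input is the best category among dominant-source components", {
  # dominant allergen grass; component of a non-dominant source ignored
  rec <- make_record(wheal = c(grass = 9, mite = 3),
                     specific = c(grass = 10, mite = 1),
                     component = c("Der p1" = 9.9), total_ige = 100)
  expect_identical(compute_pris(rec)$crd_score, 0L)
  rec$ige$component <- c("Der p1" = 9.9, "Phl p1" = 0.9, "Phl p5" = 4.2)
  expect_identical(compute_pris(rec)$crd_score, 12L)
})

test_that("exhaustive category enumeration respects the 20-100 bounds", {
  g <- pris_score_grid()
  expect_identical(nrow(g), 25920L)
  expect_identical(min(g$total), 20L)
  expect_identical(max(g$total), 100L)
})

test_that("raising any single parameter never lowers the total", {
  g <- pris_score_grid()
  for (comp in setdiff(names(g), "total")) {
    others <- setdiff(names(g), c(comp, "total"))
    key <- do.call(paste, g[others])
    ord <- order(key, g[[comp]])
    gg <- g[ord, ]
    same <- key[ord][-1] == key[ord][-nrow(gg)]
    expect_true(all(diff(gg$total)[same] >= 0), label = comp)
  }
})

test_that("the quartile map partitions [20, 100] with inclusive lower edges", {
  totals <- 20:100
  bands <- pris_quartile(totals)
  expect_false(anyNA(bands))
  # ascending totals 39, 41, 59, 60, 79, 80
  expect_identical(as.character(bands[totals %in% c(39, 41, 59, 60, 79, 80)]),
                   c("Q4", "Q3", "Q3", "Q2", "Q2", "Q1"))
  expect_error(pris_quartile(19), "\\[20, 100\\]")
  expect_error(pris_quartile(101), "\\[20, 100\\]")
})
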