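test_that("a clearly separated allergen is the single dominant one", {
  rec <- make_record(wheal = c(grass = 9, mite = 3),
                     specific = c(grass = 10, mite = 1))
  d <- identify_dominant_allergens(rec)
  expect_identical(d$dominant, "grass")
  expect_identical(d$n_dominant, 1L)
  expect_equal(d$separation_wheal_mm, 6)
  expect_equal(d$separation_log10_ige, 1)
})

test_that("both margins are required to separate", {
  # wheal margin met, IgE margin not
  rec <- make_record(wheal = c(grass = 9, mite = 3),
                     specific = c(grass = 10, mite = 5))
  expect_identical(identify_dominant_allergens(rec)$n_dominant, 2L)
  # IgE margin met, wheal margin not
  rec <- make_record(wheal = c(grass = 9, mite = 6),
                     specific = c(grass = 10, mite = 1))
  expect_identical(identify_dominant_allergens(rec)$n_dominant, 2L)
})

test_that("ties and single sensitizations behave as expected", {
  rec <- make_record(wheal = c(grass = 6, mite = 6),
                     specific = c(grass = 5, mite = 5))
  d <- identify_dominant_allergens(rec)
  expect_identical(sort(d$dominant), c("grass", "mite"))
  expect_identical(d$separation_wheal_mm, 0)

  solo <- make_record(wheal = c(cat = 7), specific = c(cat = 3))
  d <- identify_dominant_allergens(solo)
  expect_identical(d$dominant, "cat")
  expect_identical(d$n_dominant, 1L)

  negative <- make_record(wheal = c(cat = 1), specific = c(cat = 0.1))
  expect_error(identify_dominant_allergens(negative), "no positive")
})

test_that("dominance is invariant to input order and to IgE rescaling", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    srcs <- sample(allergen_sources(), k)
    wheal <- setNames(sample(c(3, 4, 6, 9, 12), k, replace = TRUE), srcs)
    sige <- setNames(10^runif(k, -0.3, 1.7), srcs)
    rec <- make_record(wheal = wheal, specific = sige)
    d0 <- identify_dominant_allergens(rec)

    perm <- sample(k)
    rec_p <- make_record(wheal = wheal[perm], specific = sige[perm])
    d_p <- identify_dominant_allergens(rec_p)
    expect_identical(sort(d_p$dominant), sort(d0$dominant))

    fac <- sample(c(0.5, 2, 10), 1)
    rec_s <- make_record(wheal = wheal, specific = sige * fac)
    d_s <- identify_dominant_allergens(rec_s)
    expect_identical(sort(d_s$dominant), sort(d0$dominant))
  }
})

test_that("prefix identification matches the brute-force subset oracle", {
  set.seed(7)
  wheal_grid <- c(3, 4, 6, 8, 9, 14)
  sige_grid <- c(0.4, 1.2, 4, 13, 40)
  for (i in 1:300) {
    k <- sample(1:5, 1)
    srcs <- sample(allergen_sources(), k)
    wheal <- setNames(sample(wheal_grid, k, replace = TRUE), srcs)
    sige <- setNames(sample(sige_grid, k, replace = TRUE), srcs)
    rec <- make_record(wheal = wheal, specific = sige)
    d <- identify_dominant_allergens(rec)
    expect_identical(sort(d$dominant), oracle_dominance(wheal, sige),
                     label = paste(srcs, wheal, sige, collapse = "|"))
    if (d$n_dominant == 1L && k > 1L) {
      others <- setdiff(srcs, d$dominant)
      expect_true(all(wheal[d$dominant] - wheal[others] >= 5))
      expect_true(all(log10(sige[d$dominant]) - log10(sige[others]) >= 0.5))
    }
  }
})

test_that("dominance margins are configurable", {
  rec <- make_record(wheal = c(grass = 9, mite = 5),
                     specific = c(grass = 10, mite = 1))
  expect_identical(identify_dominant_allergens(rec)$n_dominant, 2L)
  expect_identical(
    identify_dominant_allergens(rec, wheal_margin_mm = 4)$n_dominant, 1L)
})
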