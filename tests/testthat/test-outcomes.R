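test_that("MSS is the unweighted item mean, bounded by the item extremes", {
  expect_equal(mss(rep(80, 5)), 80)
  expect_equal(mss(rep(0, 3)), 0)
  expect_equal(mss(c(60, 70, 80, 90)), 75)
  expect_error(mss(numeric(0)), "empty item set")
  expect_error(mss(c(50, 101)), "\\[0, 100\\]")

  set.seed(3)
  for (i in 1:20) {
    items <- runif(sample(1:14, 1), 0, 100)
    m <- mss(items)
    expect_true(m >= min(items) && m <= max(items))
  }
})

test_that("the efficacy index is the percentage drop from baseline", {
  expect_equal(delta_mss(80, 20), 75)
  expect_equal(delta_mss(55, 55), 0)
  expect_equal(delta_mss(100, 25), 75)
  expect_equal(delta_mss(40, 50), -25)
  expect_error(delta_mss(0, 10), "undefined-baseline")
  # scale invariance
  expect_equal(delta_mss(80, 20), delta_mss(8, 2))
})

test_that("response bands use inclusive lower edges and map worsening to low", {
  expect_identical(as.character(response_quartile(c(75, 74.9, 50, 49.9,
                                                    25, 24.9, -10))),
                   c("very_high", "high", "high", "mild",
                     "mild", "low", "low"))
})

test_that("outcome table computes per-patient indices and leaves dropouts NA", {
  co <- make_tiny_cohort()
  ot <- outcome_table(co)
  expect_equal(ot$mss0[ot$id == "A"], 75)
  expect_equal(ot$mss12[ot$id == "A"], 30)
  expect_equal(ot$delta12_pct[ot$id == "A"], 60)
  expect_equal(ot$delta24_pct[ot$id == "A"], 70)
  expect_identical(as.character(ot$response24[ot$id == "A"]), "high")
  expect_true(is.na(ot$mss12[ot$id == "C"]))
  expect_true(is.na(ot$response24[ot$id == "C"]))
})

test_that("group summaries degenerate sensibly and conserve band counts", {
  co <- make_tiny_cohort()
  co$patients$dropped_out <- c(FALSE, TRUE, TRUE)
  one <- summarize_cohort(slit_cohort(co$patients, co$spt, co$ige, co$vas),
                          "overall")
  expect_identical(one$n, 1L)
  expect_equal(one$mss0_sd, 0)
  expect_equal(one$mss0_mean, 75)

  co98 <- generate_cohort(cohort_config(n_patients = 98, seed = 21))
  s <- summarize_cohort(co98, "overall")
  n_comp <- sum(!co98$patients$dropped_out)
  expect_identical(s$n, n_comp)
  bands <- c("very_high", "high", "mild", "low")
  expect_identical(sum(unlist(s[paste0("n_", bands, "_24")])), n_comp)
  expect_identical(sum(unlist(s[paste0("n_", bands, "_12")])), n_comp)
  expect_equal(sum(unlist(s[paste0("pct_", bands, "_24")])), 100)

  for (g in c("slit_type", "disease_group", "pris_band")) {
    sg <- summarize_cohort(co98, g)
    expect_identical(sum(sg$n), n_comp, label = g)
  }
})

test_that("empty groups are reported with n = 0 and NA statistics", {
  co <- make_tiny_cohort()  # nobody in Q4 here
  s <- summarize_cohort(co, "pris_band")
  expect_true(any(s$n == 0L))
  expect_true(all(is.na(s$mss0_mean[s$n == 0L])))
})

test_that("the PRIS-by-response cross-tab conserves the completer total", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 13))
  xt <- cross_tab(co)
  ot <- outcome_table(co)
  expect_identical(sum(xt),
                   as.integer(sum(!ot$dropped_out & !is.na(ot$delta24_pct))))
  expect_identical(dim(xt), c(4L, 4L))
})

test_that("printed-style percentages recompute from counts", {
  expect_equal(pct(12, 110, 1), 10.9)
  expect_equal(pct(41, 98), 41.84)
  expect_equal(pct(39, 98), 39.8)
})
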