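test_that("the generator is deterministic given the config", {
  cfg <- cohort_config(n_patients = 40, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (tab in c("patients", "spt", "ige", "vas")) {
    expect_identical(a[[tab]], b[[tab]], label = tab)
  }
  expect_identical(attr(a, "truth"), attr(b, "truth"))

  c2 <- generate_cohort(cohort_config(n_patients = 40, seed = 124))
  expect_false(identical(a$patients, c2$patients))
})

test_that("a noiseless positive link gives a perfect PRIS-response correlation", {
  cfg <- cohort_config(n_patients = 60, seed = 31,
                       response_link = list(a = 20, b = 0.5, sigma = 0),
                       dropout_prob = 0)
  co <- generate_cohort(cfg)
  pt <- pris_table(co)
  ot <- outcome_table(co)
  d24 <- ot$delta24_pct[match(pt$id, ot$id)]
  expect_equal(cor(pt$total, d24), 1, tolerance = 1e-10)
})

test_that("defaults reproduce the target age and baseline-MSS means at scale", {
  co <- generate_cohort(cohort_config(n_patients = 5000, seed = 41))
  tr <- attr(co, "truth")
  expect_lt(abs(mean(co$patients$age_years) - 24.87), 0.5)
  expect_lt(abs(mean(tr$mss0) - 80.97), 0.5)
  expect_true(all(co$patients$age_years >= 6 & co$patients$age_years <= 63))
  expect_lt(abs(mean(co$patients$dropped_out) - 0.109), 0.02)
  expect_lt(abs(mean(co$patients$sex == "male") - 0.618), 0.025)
})

test_that("generated raw data reproduce the sampled PRIS for every patient", {
  for (s in c(51, 52)) {
    co <- generate_cohort(cohort_config(n_patients = 110, seed = s))
    tr <- attr(co, "truth")
    pt <- pris_table(co)
    expect_identical(pt$total[match(tr$id, pt$id)], as.integer(tr$pris_total))
    dt <- dominance_table(co)
    expect_identical(dt$n_dominant[match(tr$id, dt$id)],
                     as.integer(tr$n_dominant))
  }
})

test_that("generated records survive a write/read round trip and screening", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_patients = 30, seed = 61))
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_true(all(screen_cohort(co2)$eligible))
})

test_that("dropouts carry only the baseline assessment", {
  co <- generate_cohort(cohort_config(n_patients = 200, seed = 71))
  dropped <- co$patients$id[co$patients$dropped_out]
  expect_gt(length(dropped), 0)
  v <- co$vas[co$vas$id %in% dropped, ]
  expect_true(all(v$timepoint == "T0"))
  ot <- outcome_table(co)
  expect_true(all(is.na(ot$delta24_pct[ot$id %in% dropped])))
})

test_that("link calibration hits degenerate targets exactly and errors on bad input", {
  cfg <- cohort_config(n_patients = 10, seed = 1)
  expect_identical(calibrate_link(0, 10, cfg)$b, 0)
  zl <- calibrate_link(0.5, 0, cfg)
  expect_gt(zl$b, 0)
  expect_error(calibrate_link(1.2, 10, cfg), "target_r")
  expect_error(calibrate_link(0.5, -1, cfg), "sigma")
  expect_error(cohort_config(n_patients = 10, sigma = -2), "sigma")
  expect_error(cohort_config(n_patients = 10, dropout_prob = 1.4), "dropout_prob")
})

test_that("the calibrated link recovers the target correlation empirically", {
  cfg <- cohort_config(n_patients = 2000, seed = 81)
  rs <- vapply(1:5, function(s) {
    cfg$seed <- 81 + s
    co <- generate_cohort(cfg)
    tr <- attr(co, "truth")
    cor(tr$pris_total, tr$delta24)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.62), 0.04)
})

test_that("calibration leaves the caller's random stream untouched", {
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(calibrate_link(0.5, 10, cohort_config(n_patients = 5)))
  after <- rnorm(3)
  expect_identical(before, after)
})
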