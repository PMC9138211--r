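test_that("Fisher-z sample size reproduces the design calculation and is monotone", {
  expect_identical(sample_size_pearson(0.3, 0.05, 0.80), 85L)
  expect_true(sample_size_pearson(0.2) > sample_size_pearson(0.3))
  expect_true(sample_size_pearson(0.3) > sample_size_pearson(0.5))
  expect_error(sample_size_pearson(0), "no finite sample size")
  expect_error(sample_size_pearson(1), "strictly in")
})

test_that("analytic power behaves at the design point, under the null and asymptotically", {
  expect_equal(power_pearson(85, 0.3, 0.05), 0.80, tolerance = 0.01)
  expect_equal(power_pearson(50, 0, 0.05), 0.05, tolerance = 1e-10)
  expect_true(power_pearson(5000, 0.3, 0.05) > 0.9999)
  expect_error(power_pearson(3, 0.3), "at least 4")
})

test_that("sample size and power are mutually consistent across specs", {
  for (r in c(0.2, 0.3, 0.5)) {
    for (pw in c(0.80, 0.90)) {
      n <- sample_size_pearson(r, 0.05, pw)
      expect_gte(power_pearson(n, r, 0.05), pw)
      expect_lt(power_pearson(n - 1, r, 0.05), pw)
    }
  }
})

test_that("Monte-Carlo power agrees with the analytic approximation within 3 SE", {
  set.seed(101)
  for (case in list(c(30, 0), c(30, 0.5), c(85, 0.3), c(200, 0.3))) {
    n <- case[1]; r <- case[2]
    mc <- power_pearson_mc(n, r, alpha = 0.05, n_rep = 4000)
    expect_lt(abs(mc$power - power_pearson(n, r, 0.05)),
              3 * max(mc$se, 1e-3),
              label = sprintf("n=%d r=%.1f", n, r))
  }
})

test_that("simple regression matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5); y <- c(1, 3, 2, 5, 4)
  fit <- simple_regression(x, y)
  expect_equal(fit$slope, 0.8)
  expect_equal(fit$intercept, 0.6)
  expect_equal(fit$r, 0.8)
  expect_equal(fit$f_stat, 0.64 / 0.36 * 3)
  expect_identical(fit$df, c(1L, 3L))

  perfect <- suppressWarnings(simple_regression(x, 2 * x))
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p_value, 1e-10)

  expect_error(simple_regression(rep(2, 5), y), "degenerate-design")
})

test_that("F = R^2/(1-R^2) (n-2) holds exactly on random inputs", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    fit <- simple_regression(x, y)
    expect_equal(fit$f_stat, fit$r^2 / (1 - fit$r^2) * (n - 2))
  }
})

test_that("repeated-measures ANOVA matches the aov() error-stratum oracle", {
  set.seed(8)
  m <- matrix(rnorm(12 * 3, mean = rep(c(80, 35, 30), each = 12), sd = 10),
              ncol = 3)
  fit <- rm_anova(m)
  oracle <- oracle_rm_anova(m)
  expect_equal(fit$f_stat, oracle$f)
  expect_equal(fit$p_value, oracle$p)
  expect_equal(fit$df, c(2, 22))

  toy <- matrix(c(10, 12, 14, 7, 9, 12, 5, 8, 10), nrow = 3, byrow = TRUE)
  expect_equal(rm_anova(toy)$f_stat, oracle_rm_anova(toy)$f)

  flat <- matrix(rep(rnorm(6), 3), ncol = 3)
  expect_equal(rm_anova(flat)$f_stat, 0)

  m_na <- m; m_na[1, 2] <- NA
  expect_error(rm_anova(m_na), "completers")
})

test_that("Greenhouse-Geisser correction shrinks df and epsilon is in (1/(t-1), 1]", {
  set.seed(9)
  m <- matrix(rnorm(30), ncol = 3) %*% matrix(c(1, .8, .1, 0, 1, .5, 0, 0, 1), 3)
  fit <- rm_anova(m, gg = TRUE)
  expect_lte(fit$epsilon, 1)
  expect_gte(fit$epsilon, 0.5)
  expect_equal(fit$df[1], 2 * fit$epsilon)
})

test_that("one-way ANOVA matches the hand SS oracle and the t^2 identity", {
  set.seed(10)
  y <- rnorm(60, mean = rep(c(50, 60, 70), each = 20), sd = 12)
  g <- rep(c("Q3", "Q2", "Q1"), each = 20)
  fit <- oneway_anova_posthoc(y, g)
  expect_equal(fit$f_stat, oracle_oneway_f(y, g))
  expect_equal(fit$df, c(2, 57))
  expect_identical(nrow(fit$pairwise), 3L)

  y2 <- y[1:40]; g2 <- rep(c("A", "B"), each = 20)
  fit2 <- oneway_anova_posthoc(y2, g2)
  tt <- t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(fit2$f_stat, unname(tt$statistic)^2)
  expect_null(fit2$pairwise)

  expect_error(oneway_anova_posthoc(y, rep("A", 60)), "at least 2")
})

test_that("Tukey and Bonferroni post-hoc variants both order the strata", {
  set.seed(11)
  y <- rnorm(90, mean = rep(c(79, 66, 54), each = 30), sd = 12)
  g <- factor(rep(c("Q1", "Q2", "Q3"), each = 30), levels = c("Q1", "Q2", "Q3"))
  for (m in c("tukey", "bonferroni")) {
    fit <- oneway_anova_posthoc(y, g, posthoc = m)
    expect_lt(fit$p_value, 0.001)
    expect_true(all(fit$pairwise$p < 0.05))
  }
})

test_that("component regression uses the lowest category as reference and finds built-in effects", {
  co <- generate_cohort(cohort_config(n_patients = 300, seed = 17))
  pt <- pris_table(co)
  ot <- outcome_table(co)
  res <- component_regression(pt, ot)
  expect_true(length(res) >= 6)
  for (cr in res) {
    expect_true(is.na(cr$betas$beta[1]))  # reference row
    expect_true(all(diff(cr$betas$score) > 0))
    expect_true(cr$p_value >= 0 && cr$p_value <= 1)
  }
  # the response link is built on the total, so every component's top
  # category should sit above its reference on average
  age <- res$age_score
  expect_gt(age$betas$beta[nrow(age$betas)], 0)
})

test_that("two categories with equal means give a beta near zero with CI covering zero", {
  set.seed(12)
  pt <- data.frame(id = as.character(1:200),
                   age_score = rep(c(3L, 15L), 100))
  for (comp in c("clinical_score", "onset_score", "sensitization_score",
                 "exposure_score", "ratio_score", "crd_score",
                 "dominance_score")) {
    pt[[comp]] <- 6L
  }
  ot <- data.frame(id = pt$id, delta24_pct = rnorm(200, 60, 10))
  w <- capture_warnings(res <- component_regression(pt, ot))
  expect_length(w, 7)  # the seven constant parameters are skipped
  expect_true(all(grepl("single category", w)))
  beta <- res$age_score$betas
  expect_lt(abs(beta$beta[2]), 0.05)
  expect_true(beta$ci_lo[2] < 0 && beta$ci_hi[2] > 0)
})
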