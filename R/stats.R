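#' Power and sample size for a Pearson correlation test
#'
#' Analytic power of the two-tailed test of zero Pearson correlation via
#' the Fisher z approximation: `atanh(r) * sqrt(n - 3)` is approximately
#' standard normal with the stated mean, so
#' `power = Phi(atanh(r) sqrt(n-3) - z_{1-a/2}) + Phi(-atanh(r) sqrt(n-3) - z_{1-a/2})`
#' (both rejection tails; the far tail is negligible for r away from 0 and
#' makes the size exactly `alpha` at r = 0). The minimal sample size
#' inverts the one-tail expression:
#' `n = ceiling(((z_{1-a/2} + z_{power}) / atanh(r))^2 + 3)`.
#'
#' @param r Target population correlation (effect size), 0 < r < 1.
#' @param alpha Two-tailed significance level.
#' @param power Target power in (0, 1).
#' @param n Sample size (at least 4).
#' @return `sample_size_pearson()`: the smallest integer sample size
#'   achieving the target power. `power_pearson()`: the analytic power.
#' @examples
#' sample_size_pearson(r = 0.3, alpha = 0.05, power = 0.80) # 85
#' power_pearson(n = 85, r = 0.3)
#' @export
sample_size_pearson <- function(r, alpha = 0.05, power = 0.80) {
  if (!is.finite(r) || r <= 0 || r >= 1) {
    stop("validation error: effect size r must lie strictly in (0, 1); at r = 0 no finite sample size attains the target power",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("validation error: alpha and power must lie in (0, 1)", call. = FALSE)
  }
  z_a <- qnorm(1 - alpha / 2)
  z_b <- qnorm(power)
  as.integer(ceiling(((z_a + z_b) / atanh(r))^2 + 3))
}

#' @rdname sample_size_pearson
#' @export
power_pearson <- function(n, r, alpha = 0.05) {
  if (any(n < 4)) stop("validation error: n must be at least 4", call. = FALSE)
  if (any(abs(r) >= 1)) {
    stop("validation error: |r| must be below 1", call. = FALSE)
  }
  z_a <- qnorm(1 - alpha / 2)
  m <- atanh(r) * sqrt(n - 3)
  pnorm(m - z_a) + pnorm(-m - z_a)
}

#' Monte-Carlo power of the Pearson correlation test
#'
#' Simulates bivariate-normal cohorts with the given population
#' correlation, applies the exact t test of zero correlation two-tailed
#' at level `alpha` to each, and returns the rejection fraction. The
#' caller controls the random stream via `set.seed()`.
#'
#' @param n Per-cohort sample size.
#' @param r Population correlation.
#' @param alpha Two-tailed level.
#' @param n_rep Number of simulated cohorts.
#' @return A list: `power` (rejection fraction), `se` (binomial standard
#'   error), `n_rep`.
#' @examples
#' set.seed(1)
#' power_pearson_mc(30, 0.5, n_rep = 2000)$power
#' @export
power_pearson_mc <- function(n, r, alpha = 0.05, n_rep = 20000) {
  stopifnot(n >= 4, abs(r) < 1, n_rep >= 1)
  r_crit <- cor_critical(n, alpha)
  rej <- 0L
  block <- max(1L, min(n_rep, floor(5e6 / n)))
  done <- 0L
  while (done < n_rep) {
    b <- min(block, n_rep - done)
    z1 <- matrix(rnorm(n * b), nrow = n)
    z2 <- matrix(rnorm(n * b), nrow = n)
    x <- z1
    y <- r * z1 + sqrt(1 - r^2) * z2
    x <- sweep(x, 2L, colMeans(x))
    y <- sweep(y, 2L, colMeans(y))
    rhat <- colSums(x * y) / sqrt(colSums(x^2) * colSums(y^2))
    rej <- rej + sum(abs(rhat) >= r_crit)
    done <- done + b
  }
  p <- rej / n_rep
  list(power = p, se = sqrt(p * (1 - p) / n_rep), n_rep = n_rep)
}

# critical |r| of the exact t test of zero correlation
cor_critical <- function(n, alpha) {
  tc <- qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Simple linear regression of response on PRIS
#'
#' Ordinary least squares of the SLIT efficacy index on the predictor
#' (typically ΔMSS-24(%) on PRIS total), reporting the correlation
#' magnitude R, the F statistic with (1, n - 2) degrees of freedom, and
#' its two-sided p-value. The identity `F = R^2 / (1 - R^2) * (n - 2)`
#' holds exactly.
#'
#' @param x Predictor (e.g. PRIS totals); must not be constant.
#' @param y Response (e.g. ΔMSS-24 percentages).
#' @return List of class `pris_regression`: `slope`, `intercept`, `r`
#'   (correlation magnitude), `f_stat`, `df` (numerator, denominator),
#'   `p_value`, `n`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 2 * x + rnorm(50)
#' simple_regression(x, y)$r
#' @export
simple_regression <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("validation error: need at least 3 complete observations",
                   call. = FALSE)
  if (var(x) == 0) {
    stop("degenerate-design error: predictor is constant", call. = FALSE)
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  f <- r2 / (1 - r2) * (n - 2)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r = abs(cor(x, y)),
    f_stat = f,
    df = c(1L, n - 2L),
    p_value = pf(f, 1, n - 2, lower.tail = FALSE),
    n = n
  ), class = "pris_regression")
}

#' @export
print.pris_regression <- function(x, ...) {
  cat(sprintf("R = %.3f; F(%d,%d) = %.3f; p = %.3g; slope = %.4f\n",
              x$r, x$df[1], x$df[2], x$f_stat, x$p_value, x$slope))
  invisible(x)
}

#' Per-parameter regression of response on PRIS component categories
#'
#' For each of the eight PRIS parameters, regresses the 24-month response
#' expressed as a proportion (ΔMSS-24(%) / 100) on the parameter's
#' category indicators, with the lowest-scoring observed category as the
#' reference level. Reports each non-reference category's coefficient
#' (beta) with a 95 percent confidence interval and the parameter's
#' overall F-test p-value. Parameters observed in a single category are
#' skipped with a warning.
#'
#' @param pris A data frame from [pris_table()] (or any frame with the
#'   eight component-score columns and `id`).
#' @param outcomes A data frame from [outcome_table()] with `id` and
#'   `delta24_pct` (dropouts/missing excluded automatically).
#' @return Named list (one element per parameter) of lists with
#'   `parameter`, `p_value`, and `betas` (data frame: `score`, `n`,
#'   `beta`, `ci_lo`, `ci_hi`; the reference row has `NA` beta/CI).
#' @export
component_regression <- function(pris, outcomes) {
  d24 <- outcomes$delta24_pct[match(pris$id, outcomes$id)] / 100
  keep <- !is.na(d24)
  res <- list()
  for (comp in component_score_names()) {
    sc <- pris[[comp]][keep]
    y <- d24[keep]
    levs <- sort(unique(sc))  # ascending score: lowest category = reference
    if (length(levs) < 2L) {
      warning(sprintf("parameter %s observed in a single category; skipped",
                      comp), call. = FALSE)
      next
    }
    f <- factor(sc, levels = levs)
    fit <- lm(y ~ f)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    ci <- confint(fit, level = 0.95)
    betas <- data.frame(
      score = levs,
      n = as.integer(table(f)),
      beta = c(NA, unname(coef(fit)[-1])),
      ci_lo = c(NA, ci[-1, 1]),
      ci_hi = c(NA, ci[-1, 2])
    )
    res[[comp]] <- list(
      parameter = comp,
      p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
      betas = betas
    )
  }
  res
}

#' Repeated-measures one-way ANOVA on MSS over time
#'
#' Within-subject one-way ANOVA with timepoint (T0, T12, T24) as the
#' within factor, computed by the standard two-way (subject x time)
#' sum-of-squares decomposition: `F = MS_time / MS_(subject x time)` with
#' degrees of freedom `(t - 1, (n - 1)(t - 1))`. An optional
#' Greenhouse-Geisser correction multiplies both df by the epsilon
#' estimated from the sample covariance of the columns. Pairwise
#' timepoint contrasts are paired t tests with the configured p-value
#' adjustment.
#'
#' @param mss_matrix Numeric matrix, one row per completer, one column
#'   per timepoint (no missing cells; filter to completers first).
#' @param gg Apply the Greenhouse-Geisser sphericity correction.
#' @param adjust P-value adjustment for the pairwise contrasts
#'   (`"bonferroni"`, `"holm"` or `"none"`).
#' @return List of class `pris_anova`: `f_stat`, `df`, `p_value`,
#'   `epsilon` (GG epsilon, reported even when uncorrected), and
#'   `pairwise` (data frame: `contrast`, `mean_diff`, `p`).
#' @export
rm_anova <- function(mss_matrix, gg = FALSE,
                     adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  m <- as.matrix(mss_matrix)
  if (anyNA(m)) {
    stop("validation error: missing cells; repeated-measures ANOVA needs completers only (filter dropouts first)",
         call. = FALSE)
  }
  n <- nrow(m); t <- ncol(m)
  if (n < 2L || t < 2L) {
    stop("validation error: need at least 2 subjects and 2 timepoints",
         call. = FALSE)
  }
  grand <- mean(m)
  ss_time <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- t * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- max(ss_tot - ss_time - ss_subj, 0)
  df1 <- t - 1
  df2 <- (n - 1) * (t - 1)
  f <- if (ss_time <= 1e-12 * max(ss_tot, 1)) {
    0  # no timepoint effect at all (flat columns)
  } else if (ss_err <= 1e-12 * max(ss_tot, 1)) {
    Inf
  } else {
    (ss_time / df1) / (ss_err / df2)
  }

  # Greenhouse-Geisser epsilon from the sample covariance matrix
  S <- stats::cov(m)
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (t * (dbar - sbar))^2
  den <- (t - 1) * (sum(S^2) - 2 * t * sum(rowMeans(S)^2) + t^2 * sbar^2)
  eps <- if (den > 0) min(1, num / den) else 1

  if (gg) { df1 <- df1 * eps; df2 <- df2 * eps }
  p <- pf(f, df1, df2, lower.tail = FALSE)

  cn <- colnames(m) %||% paste0("T", seq_len(t))
  pairs <- utils::combn(t, 2)
  pw <- apply(pairs, 2L, function(ix) {
    d <- m[, ix[1]] - m[, ix[2]]
    tt <- t.test(d)
    c(mean_diff = mean(d), p = tt$p.value)
  })
  pairwise <- data.frame(
    contrast = apply(pairs, 2L, function(ix) paste(cn[ix], collapse = " vs ")),
    mean_diff = pw["mean_diff", ],
    p = p.adjust(pw["p", ], method = if (adjust == "none") "none" else adjust)
  )
  structure(list(f_stat = f, df = c(df1, df2), p_value = p,
                 epsilon = eps, pairwise = pairwise, n = n),
            class = "pris_anova")
}

#' One-way ANOVA of ΔMSS-24 across PRIS bands, with post hoc comparisons
#'
#' Between-group one-way ANOVA of the 24-month response across the PRIS
#' quartile strata, with all pairwise post-hoc comparisons (Tukey HSD by
#' default, Bonferroni-adjusted pairwise t tests as an alternative).
#' Empty bands are dropped.
#'
#' @param delta24 Numeric vector of ΔMSS-24(%) values.
#' @param band Grouping factor (e.g. PRIS quartile bands).
#' @param posthoc `"tukey"` or `"bonferroni"`.
#' @return List of class `pris_anova`: `f_stat`, `df` (k - 1, n - k),
#'   `p_value`, `group_means` (data frame: `group`, `n`, `mean`, `sd`),
#'   and `pairwise` (data frame: `contrast`, `diff`, `p`; present when 3
#'   or more groups).
#' @export
oneway_anova_posthoc <- function(delta24, band,
                                 posthoc = c("tukey", "bonferroni")) {
  posthoc <- match.arg(posthoc)
  keep <- !is.na(delta24) & !is.na(band)
  y <- delta24[keep]
  g <- droplevels(factor(band[keep]))
  k <- nlevels(g)
  if (k < 2L) {
    stop("validation error: need at least 2 non-empty strata", call. = FALSE)
  }
  fit <- aov(y ~ g)
  sm <- summary(fit)[[1]]
  f <- sm$`F value`[1]
  df <- c(sm$Df[1], sm$Df[2])
  p <- sm$`Pr(>F)`[1]
  gm <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(y, g, mean)),
    sd = as.numeric(tapply(y, g, sd))
  )
  pairwise <- NULL
  if (k >= 3L) {
    if (posthoc == "tukey") {
      tk <- TukeyHSD(fit)$g
      pairwise <- data.frame(contrast = rownames(tk),
                             diff = tk[, "diff"], p = tk[, "p adj"],
                             row.names = NULL)
    } else {
      pairs <- utils::combn(levels(g), 2)
      pw <- apply(pairs, 2L, function(gg2) {
        a <- y[g == gg2[1]]; b <- y[g == gg2[2]]
        tt <- t.test(a, b, var.equal = TRUE)
        c(diff = mean(b) - mean(a), p = tt$p.value)
      })
      pairwise <- data.frame(
        contrast = apply(pairs, 2L, paste, collapse = "-"),
        diff = pw["diff", ],
        p = p.adjust(pw["p", ], method = "bonferroni")
      )
    }
  }
  structure(list(f_stat = f, df = df, p_value = p,
                 group_means = gm, pairwise = pairwise, n = length(y)),
            class = "pris_anova")
}

#' @export
print.pris_anova <- function(x, ...) {
  cat(sprintf("F(%s,%s) = %.3f; p = %.3g\n",
              format(x$df[1]), format(x$df[2]), x$f_stat, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
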