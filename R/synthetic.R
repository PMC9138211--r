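#' Configuration for the synthetic SLIT cohort generator
#'
#' Bundles every distributional knob of [generate_cohort()]. Defaults
#' emulate the package's reference cohort conditions:
#' 110 enrolled patients, age 24.87 +/- 10.80 years truncated to 6-63,
#' 61.8 percent male, half with concomitant asthma, 10.9 percent dropout,
#' baseline mean symptom score 80.97 +/- 8.24, an allergen mix dominated
#' by pellitory, grass and house dust mite, and a linear PRIS-response
#' link calibrated so that the population correlation between PRIS and
#' ΔMSS-24(%) is 0.62 with mean response 67.71 percent.
#'
#' @param n_patients Number of enrolled patients.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#' @param age_mean,age_sd,age_range Age distribution (years); sampling is
#'   truncated normal on `age_range` with the location shifted so the
#'   realized mean of whole-year ages matches `age_mean`.
#' @param male_fraction Probability of male sex (recorded but unused by
#'   any analysis).
#' @param asthma_fraction Probability of concomitant asthma.
#' @param other_allergy_given_asthma Probability of additional allergic
#'   comorbidity among asthmatics (the third clinical tier).
#' @param dropout_prob Probability a patient drops before T12 (dropouts
#'   keep only the baseline VAS).
#' @param mss0_mean,mss0_sd Baseline MSS distribution.
#' @param response_link `NULL` (calibrate with `target_r`, `sigma`,
#'   `mean_delta`) or a list `a`, `b`, `sigma` for
#'   `ΔMSS-24(%) = a + b * PRIS + e`, `e ~ N(0, sigma)`.
#' @param target_r,mean_delta Calibration targets used when
#'   `response_link` is `NULL`.
#' @param sigma Residual SD of the response link (percentage points).
#' @param gap_mean,gap_sd `ΔMSS-12 = ΔMSS-24 - gap`, `gap ~ N(mean, sd)`:
#'   the additional improvement accrued between months 12 and 24.
#' @param delta_range Responses are clipped to this interval so MSS
#'   values stay on the VAS scale.
#' @param allergen_mix Named probability vector over
#'   [allergen_sources()] used to draw each patient's sensitizations.
#' @param onset_probs,sens_probs,exposure_probs,ratio_probs,crd_probs,dominance_probs
#'   Category probabilities for the corresponding PRIS parameters
#'   (ordered from the highest-scoring to the lowest-scoring category).
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()], [calibrate_link()]
#' @export
cohort_config <- function(n_patients = 110,
                          seed = 1,
                          age_mean = 24.87, age_sd = 10.80,
                          age_range = c(6, 63),
                          male_fraction = 0.618,
                          asthma_fraction = 0.5,
                          other_allergy_given_asthma = 0.2,
                          dropout_prob = 0.109,
                          mss0_mean = 80.97, mss0_sd = 8.24,
                          response_link = NULL,
                          target_r = 0.62,
                          sigma = 13,
                          mean_delta = 67.71,
                          gap_mean = 6.36, gap_sd = 12.5,
                          delta_range = c(-25, 100),
                          allergen_mix = default_allergen_mix(),
                          onset_probs = c(le3 = 0.35, mid = 0.40, gt10 = 0.25),
                          sens_probs = c(n1 = 0.30, n2_3 = 0.40,
                                         n4_5 = 0.20, gt5 = 0.10),
                          exposure_probs = c(n1 = 0.40, n2 = 0.30,
                                             n3 = 0.20, ge4 = 0.10),
                          ratio_probs = c(high = 0.35, mid = 0.40, low = 0.25),
                          crd_probs = c(high = 0.35, pos = 0.40, neg = 0.25),
                          dominance_probs = c(d1 = 0.65, d2 = 0.30,
                                              d3 = 0.04, d4 = 0.01)) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    male_fraction = male_fraction,
    asthma_fraction = asthma_fraction,
    other_allergy_given_asthma = other_allergy_given_asthma,
    dropout_prob = dropout_prob,
    mss0_mean = mss0_mean, mss0_sd = mss0_sd,
    response_link = response_link,
    gap_mean = gap_mean, gap_sd = gap_sd,
    delta_range = delta_range,
    allergen_mix = allergen_mix,
    onset_probs = onset_probs, sens_probs = sens_probs,
    exposure_probs = exposure_probs, ratio_probs = ratio_probs,
    crd_probs = crd_probs, dominance_probs = dominance_probs
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  if (is.null(cfg$response_link)) {
    cfg$response_link <- calibrate_link(target_r, sigma, cfg,
                                        mean_delta = mean_delta)
  } else {
    rl <- cfg$response_link
    if (!is.list(rl) || !all(c("a", "b", "sigma") %in% names(rl))) {
      stop("validation error: response_link must be a list with a, b, sigma",
           call. = FALSE)
    }
    if (!is.finite(rl$sigma) || rl$sigma < 0) {
      stop("validation error: response noise sigma must be >= 0",
           call. = FALSE)
    }
  }
  cfg
}

default_allergen_mix <- function() {
  # SLIT prescription counts in the reference cohort: pellitory 67,
  # grass 48, mite 19, mugwort 4, olive 4, molds 1; one pseudo-count for
  # each source never prescribed, then normalized.
  counts <- c(grass = 48, ambrosia = 1, mugwort = 4, pellitory = 67,
              olive = 4, cypress = 1, birch = 1, cat = 1, dog = 1,
              mite = 19, molds = 1)
  counts[allergen_sources()] / sum(counts)
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1)
  probs <- list(allergen_mix = cfg$allergen_mix, onset = cfg$onset_probs,
                sens = cfg$sens_probs, exposure = cfg$exposure_probs,
                ratio = cfg$ratio_probs, crd = cfg$crd_probs,
                dominance = cfg$dominance_probs)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("validation error: %s probabilities must be non-negative and sum to 1",
                   nm), call. = FALSE)
    }
  }
  for (nm in c("male_fraction", "asthma_fraction",
               "other_allergy_given_asthma", "dropout_prob")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(sprintf("validation error: %s must lie in [0, 1]", nm),
           call. = FALSE)
    }
  }
  if (cfg$age_sd <= 0 || cfg$mss0_sd < 0 || cfg$gap_sd < 0) {
    stop("validation error: scale parameters must be positive", call. = FALSE)
  }
  if (cfg$age_range[1] < 6) {
    stop("validation error: generated patients must be at least 6 years old (enrolment criterion)",
         call. = FALSE)
  }
  invisible(cfg)
}

# mean of a normal truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# location shift so that E[floor(truncated normal)] matches the target
age_location <- function(cfg) {
  target <- cfg$age_mean + 0.5  # floor() loses about half a year on average
  f <- function(mu) truncnorm_mean(mu, cfg$age_sd,
                                   cfg$age_range[1], cfg$age_range[2]) - target
  stats::uniroot(f, interval = c(cfg$age_mean - 3 * cfg$age_sd,
                                 cfg$age_mean + 3 * cfg$age_sd))$root
}

rtruncnorm <- function(n, mu, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mu, sd), pnorm(hi, mu, sd))
  qnorm(u, mu, sd)
}

sample_int_range <- function(lo, hi) {
  if (hi <= lo) return(as.integer(lo))
  as.integer(lo + floor(runif(1) * (hi - lo + 1)))
}

# Draw the per-patient covariates and PRIS categories (no response, no
# panel realization). One row per patient; category draws are already
# reconciled (onset feasible for the age, exposure and dominance clamped
# to the sensitization count), so the recorded category IS the realized
# one.
sample_covariates <- function(cfg, n) {
  age_mu <- age_location(cfg)
  age <- floor(rtruncnorm(n, age_mu, cfg$age_sd,
                          cfg$age_range[1], cfg$age_range[2]))
  male <- runif(n) < cfg$male_fraction
  asthma <- runif(n) < cfg$asthma_fraction
  other <- asthma & (runif(n) < cfg$other_allergy_given_asthma)
  act <- ifelse(asthma, 20L + floor(runif(n) * 6), NA_integer_)

  onset_band <- sample.int(3L, n, replace = TRUE, prob = cfg$onset_probs)
  onset <- integer(n)
  for (i in seq_len(n)) {
    b <- onset_band[i]
    if (b == 3L && age[i] < 11L) b <- 2L  # onset cannot exceed age
    onset_band[i] <- b
    onset[i] <- switch(b,
                       sample_int_range(0L, 3L),
                       sample_int_range(4L, min(10L, age[i])),
                       sample_int_range(11L, min(20L, age[i])))
  }

  sens_band <- sample.int(4L, n, replace = TRUE, prob = cfg$sens_probs)
  n_sens <- vapply(sens_band, function(b) {
    switch(b, 1L, sample_int_range(2L, 3L), sample_int_range(4L, 5L),
           sample_int_range(6L, 8L))
  }, integer(1))

  expo_band <- sample.int(4L, n, replace = TRUE, prob = cfg$exposure_probs)
  exposure <- vapply(expo_band, function(b) {
    switch(b, 1L, 2L, 3L, sample_int_range(4L, 5L))
  }, integer(1))
  exposure <- pmin(exposure, n_sens)

  dom_band <- sample.int(4L, n, replace = TRUE, prob = cfg$dominance_probs)
  n_dom <- pmin(dom_band, n_sens)

  ratio_band <- sample.int(3L, n, replace = TRUE, prob = cfg$ratio_probs)
  ratio <- vapply(ratio_band, function(b) {
    switch(b, runif(1, 0.20, 0.45), runif(1, 0.055, 0.195),
           runif(1, 0.005, 0.045))
  }, numeric(1))

  crd_band <- sample.int(3L, n, replace = TRUE, prob = cfg$crd_probs)
  crd_value <- vapply(crd_band, function(b) {
    switch(b, runif(1, 3.6, 30), runif(1, 0.36, 3.4), runif(1, 0.01, 0.30))
  }, numeric(1))
  crd_cat <- c("high_positive", "positive", "negative")[crd_band]

  diseases <- ifelse(other, "rhinitis;asthma;other_allergies",
                     ifelse(asthma, "rhinitis;asthma", "rhinitis"))
  clin_score <- ifelse(other, 3L, ifelse(asthma, 6L, 9L))

  total <- score_age(age) + clin_score + score_onset(onset) +
    score_sensitizations(n_sens) + score_exposure(exposure) +
    score_ratio(ratio, 1) + score_crd(crd_cat) + score_dominance(n_dom)

  data.frame(
    age = age, male = male, asthma = asthma, other = other, act = act,
    diseases = diseases, onset = onset, n_sens = n_sens,
    exposure = exposure, n_dom = n_dom, ratio = ratio,
    crd_value = crd_value, crd_cat = crd_cat, pris_total = total
  )
}

#' Calibrate the PRIS-to-response link
#'
#' Chooses slope and intercept of the linear response link
#' `ΔMSS-24(%) = a + b * PRIS + e` so that the population correlation
#' between PRIS and the response equals `target_r` given noise SD
#' `sigma`, and the mean response equals `mean_delta`. The PRIS standard
#' deviation implied by the configured category distributions is
#' estimated by simulating `n_sim` covariate draws (deterministically,
#' from a seed derived from the config seed; the caller's random stream
#' is left untouched), giving
#' `b = target_r / sqrt(1 - target_r^2) * sigma / sd(PRIS)`.
#' With `sigma = 0` any positive slope yields a perfect correlation and
#' `b = 1` is returned; with `target_r = 0`, `b = 0`.
#'
#' @param target_r Desired population correlation in \[0, 1).
#' @param sigma Residual SD (percentage points), non-negative.
#' @param config A [cohort_config()] (its category distributions define
#'   the PRIS variance). A config whose `response_link` is still `NULL`
#'   is acceptable.
#' @param mean_delta Desired mean ΔMSS-24(%).
#' @param n_sim Covariate draws used to estimate the PRIS SD.
#' @return List `a`, `b`, `sigma` (plus `pris_mean`, `pris_sd` used for
#'   the calibration).
#' @export
calibrate_link <- function(target_r, sigma, config, mean_delta = 67.71,
                           n_sim = 20000) {
  if (!is.finite(target_r) || target_r < 0 || target_r >= 1) {
    stop("validation error: target_r must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma < 0) {
    stop("validation error: sigma must be >= 0", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed((config$seed %% 1000003L) + 524287L)
  cov <- sample_covariates(config, n_sim)
  mu_p <- mean(cov$pris_total)
  sd_p <- sd(cov$pris_total)

  b <- if (sigma == 0) {
    if (target_r == 0) 0 else 1
  } else {
    target_r / sqrt(1 - target_r^2) * sigma / sd_p
  }
  a <- mean_delta - b * mu_p
  sd_total <- sqrt((b * sd_p)^2 + sigma^2)
  lo <- config$delta_range %||% c(-25, 100)
  if (mean_delta < lo[1] || mean_delta > lo[2] || sd_total > diff(lo) / 3) {
    stop("validation error: target correlation/noise not reachable within the bounded response support",
         call. = FALSE)
  }
  list(a = a, b = b, sigma = sigma, pris_mean = mu_p, pris_sd = sd_p)
}

#' Generate a synthetic SLIT cohort
#'
#' Draws a complete, internally consistent cohort: demographics and PRIS
#' parameter categories first, then raw measurements realized so that
#' re-deriving every score from the raw data reproduces the sampled
#' category — the SPT/IgE panel is constructed so
#' [identify_dominant_allergens()] returns exactly the sampled dominance
#' count (dominant extracts share a high wheal and specific IgE; the
#' remaining sensitizations sit 6 mm and 0.7 log10 units below), the s/t
#' ratio is realized through the total IgE, and the CRD category through
#' a molecular component of the top dominant extract (never Bet v2, which
#' would exclude the patient). VAS items at each timepoint are set
#' uniformly to the latent MSS value, so [mss()] and [delta_mss()]
#' reproduce the latent response draw exactly (up to clipping of MSS to
#' \[0, 100\]). Every generated patient passes [screen_eligibility()].
#' Dropouts (no T12/T24 assessments) are sampled independently of PRIS
#' and response.
#'
#' @param config A [cohort_config()].
#' @return A [slit_cohort()] with attributes `truth` (data frame of
#'   latent per-patient quantities: realized PRIS total, latent
#'   ΔMSS-12/24 before clipping, baseline MSS, dominance count),
#'   `link` (the response-link parameters used) and `n_clipped` (number
#'   of clipped MSS/response values).
#' @examples
#' co <- generate_cohort(cohort_config(n_patients = 20, seed = 7))
#' co
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  cov <- sample_covariates(config, n)

  spt_rows <- vector("list", n)
  ige_rows <- vector("list", n)
  comp_map <- allergen_components()
  for (i in seq_len(n)) {
    k <- cov$n_sens[i]; d <- cov$n_dom[i]
    sources <- sample(allergen_sources(), k, prob = config$allergen_mix)
    dom <- sources[seq_len(d)]
    s_top <- 10^runif(1, log10(2), log10(30))
    sige <- c(rep(s_top, d),
              rep(s_top * 10^-0.7, k - d))
    wheal <- c(rep(9, d), rep(3, k - d))
    spt_rows[[i]] <- data.frame(
      id = ids[i], allergen = sources, wheal_mm = wheal,
      histamine_mm = 5, saline_mm = 0
    )
    total_ige <- s_top / cov$ratio[i]
    comp_candidates <- names(comp_map)[comp_map == dom[1]]
    comp_candidates <- setdiff(comp_candidates, "Bet v2")
    comp_label <- comp_candidates[1]
    ige_rows[[i]] <- data.frame(
      id = ids[i], total_ige = total_ige,
      allergen_or_component = c(sources, comp_label),
      value = c(sige, cov$crd_value[i])
    )
  }

  link <- config$response_link
  eps <- rnorm(n, 0, link$sigma)
  delta24 <- link$a + link$b * cov$pris_total + eps
  gap <- rnorm(n, config$gap_mean, config$gap_sd)
  lo <- config$delta_range[1]; hi <- config$delta_range[2]
  n_clip <- sum(delta24 < lo | delta24 > hi)
  delta24 <- pmin(pmax(delta24, lo), hi)
  delta12 <- delta24 - gap
  n_clip <- n_clip + sum(delta12 < lo | delta12 > hi)
  delta12 <- pmin(pmax(delta12, lo), hi)

  mss0 <- pmin(pmax(rnorm(n, config$mss0_mean, config$mss0_sd), 1), 100)
  mss12 <- mss0 * (1 - delta12 / 100)
  mss24 <- mss0 * (1 - delta24 / 100)
  n_clip <- n_clip + sum(mss12 > 100 | mss12 < 0) + sum(mss24 > 100 | mss24 < 0)
  mss12 <- pmin(pmax(mss12, 0), 100)
  mss24 <- pmin(pmax(mss24, 0), 100)

  dropped <- runif(n) < config$dropout_prob

  vas_rows <- vector("list", n)
  for (i in seq_len(n)) {
    items <- c(vas_items_rhinitis(), vas_items_general())
    if (cov$asthma[i]) {
      items <- c(items, vas_items_asthma(), vas_items_asthma_extra())
    }
    tps <- if (dropped[i]) "T0" else timepoint_levels()
    vals <- c(T0 = mss0[i], T12 = mss12[i], T24 = mss24[i])
    vas_rows[[i]] <- do.call(rbind, lapply(tps, function(tp) {
      data.frame(id = ids[i], timepoint = tp, item = items,
                 score = vals[[tp]])
    }))
  }

  patients <- data.frame(
    id = ids,
    age_years = cov$age,
    diseases = cov$diseases,
    onset_years = cov$onset,
    n_symptom_triggering_allergens = cov$exposure,
    act_score = cov$act,
    nasal_polyposis = FALSE,
    dropped_out = dropped,
    sex = ifelse(cov$male, "male", "female")
  )

  cohort <- slit_cohort(
    patients,
    do.call(rbind, spt_rows),
    do.call(rbind, ige_rows),
    do.call(rbind, vas_rows)
  )
  attr(cohort, "truth") <- data.frame(
    id = ids, pris_total = cov$pris_total, n_dominant = cov$n_dom,
    delta12 = delta12, delta24 = delta24,
    mss0 = mss0, dropped_out = dropped
  )
  attr(cohort, "link") <- link
  attr(cohort, "n_clipped") <- n_clip
  cohort
}
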