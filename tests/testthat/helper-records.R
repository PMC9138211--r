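# Builders for hand-crafted patient records and tiny cohorts, plus the
# independent oracles used against the package implementations.

make_record <- function(id = "X1",
                        age = 30,
                        diseases = "rhinitis",
                        onset = 2,
                        exposure = 1,
                        act = NA_integer_,
                        polyposis = FALSE,
                        wheal = c(grass = 9),
                        specific = c(grass = 10),
                        component = numeric(0),
                        total_ige = 100,
                        vas = list()) {
  spt <- if (length(wheal) > 0) {
    data.frame(id = id, allergen = names(wheal), wheal_mm = unname(wheal),
               histamine_mm = 5, saline_mm = 0)
  } else {
    data.frame(id = character(), allergen = character(),
               wheal_mm = numeric(), histamine_mm = numeric(),
               saline_mm = numeric())
  }
  list(
    id = id,
    profile = list(
      age_years = age,
      diseases = diseases,
      onset_years = onset,
      n_symptom_triggering_allergens = exposure,
      act_score = act,
      nasal_polyposis = polyposis,
      dropped_out = FALSE
    ),
    spt = spt,
    ige = list(total = total_ige, specific = specific, component = component),
    vas = vas
  )
}

make_tiny_cohort <- function() {
  patients <- data.frame(
    id = c("A", "B", "C"),
    age_years = c(10L, 25L, 45L),
    diseases = c("rhinitis", "rhinitis;asthma", "rhinitis"),
    onset_years = c(2, 5, 12),
    n_symptom_triggering_allergens = c(1L, 2L, 1L),
    act_score = c(NA_integer_, 22L, NA_integer_),
    nasal_polyposis = FALSE,
    dropped_out = c(FALSE, FALSE, TRUE)
  )
  spt <- data.frame(
    id = c("A", "B", "B", "C"),
    allergen = c("grass", "grass", "mite", "pellitory"),
    wheal_mm = c(9, 8, 3, 6),
    histamine_mm = 5, saline_mm = 0
  )
  ige <- data.frame(
    id = c("A", "B", "B", "C"),
    total_ige = c(100, 200, 200, 150),
    allergen_or_component = c("grass", "grass", "mite", "pellitory"),
    value = c(25, 12, 0.9, 10)
  )
  vas <- do.call(rbind, lapply(c("T0", "T12", "T24"), function(tp) {
    data.frame(id = rep(c("A", "B"), each = 2), timepoint = tp,
               item = rep(c("sneezing", "rhinorrhea"), 2),
               score = c(80, 70, 85, 75) *
                 c(T0 = 1, T12 = 0.4, T24 = 0.3)[[tp]])
  }))
  vas_c <- data.frame(id = "C", timepoint = "T0",
                      item = c("sneezing", "rhinorrhea"), score = c(60, 70))
  slit_cohort(patients, spt, ige, rbind(vas, vas_c))
}

# Brute-force dominance oracle: enumerate every non-empty subset of the
# positive set and keep those whose members all exceed all non-members by
# both margins; the minimal valid subset (unique when it exists) is the
# dominant set, otherwise everything is co-dominant.
oracle_dominance <- function(wheal, sige, wheal_margin = 5,
                             log_margin = 0.5, floor_kua = 0.01) {
  labs <- names(wheal)
  lsige <- log10(pmax(sige, floor_kua))
  n <- length(labs)
  best <- NULL
  for (size in seq_len(n - 1)) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      inside <- idx; outside <- setdiff(seq_len(n), idx)
      ok <- all(outer(wheal[inside], wheal[outside], "-") >= wheal_margin) &&
        all(outer(lsige[inside], lsige[outside], "-") >= log_margin)
      if (ok) { best <- labs[idx]; break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) best <- labs
  sort(best)
}

# Independent repeated-measures oracle via aov() with an Error stratum.
oracle_rm_anova <- function(m) {
  d <- data.frame(
    y = as.vector(m),
    time = factor(rep(seq_len(ncol(m)), each = nrow(m))),
    subj = factor(rep(seq_len(nrow(m)), times = ncol(m)))
  )
  fit <- stats::aov(y ~ time + Error(subj / time), data = d)
  sm <- summary(fit)[["Error: subj:time"]][[1]]
  list(f = sm$`F value`[1], p = sm$`Pr(>F)`[1], df = sm$Df)
}

# Hand sum-of-squares decomposition for a between-groups one-way ANOVA.
oracle_oneway_f <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ss_b <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_w <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  k <- nlevels(g); n <- length(y)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}
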