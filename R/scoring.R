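#' PRIS component scores
#'
#' The Predictive Response to Immunotherapy Score (PRIS) combines eight
#' clinical and laboratory parameters, each mapped to a point value by a
#' fixed category table; the total is the plain sum and ranges from 20 to
#' 100. These functions implement the eight category maps verbatim. All
#' printed category endpoints are inclusive; fractional ages and onsets
#' are floored to whole years before lookup.
#'
#' \itemize{
#'   \item age (years): 0-12 -> 15, 13-18 -> 12, 19-28 -> 9, 29-38 -> 6,
#'     over 38 -> 3
#'   \item clinical features: rhinitis only -> 9, rhinitis + asthma -> 6,
#'     rhinitis + asthma + other allergies -> 3
#'   \item disease onset (years since first symptoms): up to 3 -> 9,
#'     4-10 -> 6, over 10 -> 3
#'   \item number of allergen sensitizations: 1 -> 16, 2-3 -> 12,
#'     4-5 -> 8, over 5 -> 4
#'   \item symptoms following exposure to n sensitized allergens:
#'     1 -> 12, 2 -> 9, 3 -> 6, 4 or more -> 3
#'   \item specific/total IgE (s/t) ratio: >= 0.2 -> 12,
#'     0.05 <= s/t < 0.2 -> 8, < 0.05 -> 4
#'   \item CRD for major allergens: high positive (>= 3.50 kUA/L) -> 12,
#'     positive (0.35-3.50) -> 6, negative -> 0
#'   \item allergen dominance: 1 dominant -> 15, 2 -> 10, 3 -> 5,
#'     more than 3 -> 0
#' }
#'
#' @param age_years,onset_years Non-negative years.
#' @param diseases Character vector; must contain `"rhinitis"`.
#' @param n,n_dominant Positive integer counts.
#' @param specific_ige,total_ige Concentrations (kUA/L, kU/L);
#'   `total_ige` must be strictly positive.
#' @param category CRD category from [crd_category()].
#' @param thresholds See [pris_thresholds()].
#' @return Integer component score.
#' @name pris_components
NULL

#' @rdname pris_components
#' @export
score_age <- function(age_years) {
  if (any(!is.finite(age_years) | age_years < 0)) {
    stop("validation error: age_years must be non-negative", call. = FALSE)
  }
  a <- floor(age_years)
  unname(ifelse(a <= 12, 15L,
         ifelse(a <= 18, 12L,
         ifelse(a <= 28, 9L,
         ifelse(a <= 38, 6L, 3L)))))
}

#' @rdname pris_components
#' @export
score_clinical <- function(diseases) {
  if (!"rhinitis" %in% diseases) {
    stop("validation error: every enrolled patient has rhinitis", call. = FALSE)
  }
  if (any(!diseases %in% disease_levels())) {
    stop("validation error: unknown disease label", call. = FALSE)
  }
  has_asthma <- "asthma" %in% diseases
  has_other <- "other_allergies" %in% diseases
  if (has_asthma && has_other) return(3L)
  if (has_asthma || has_other) return(6L)  # one comorbidity tier
  9L
}

#' @rdname pris_components
#' @export
score_onset <- function(onset_years) {
  if (any(!is.finite(onset_years) | onset_years < 0)) {
    stop("validation error: onset_years must be non-negative", call. = FALSE)
  }
  o <- floor(onset_years)
  unname(ifelse(o <= 3, 9L, ifelse(o <= 10, 6L, 3L)))
}

#' @rdname pris_components
#' @export
score_sensitizations <- function(n) {
  if (any(!is.finite(n) | n < 1)) {
    stop("validation error: sensitization count must be >= 1 (patients without any positive sensitization are ineligible)",
         call. = FALSE)
  }
  unname(ifelse(n == 1, 16L, ifelse(n <= 3, 12L, ifelse(n <= 5, 8L, 4L))))
}

#' @rdname pris_components
#' @export
score_exposure <- function(n) {
  if (any(!is.finite(n) | n < 1)) {
    stop("validation error: symptom-triggering allergen count must be >= 1",
         call. = FALSE)
  }
  unname(ifelse(n == 1, 12L, ifelse(n == 2, 9L, ifelse(n == 3, 6L, 3L))))
}

#' @rdname pris_components
#' @export
score_ratio <- function(specific_ige, total_ige,
                        thresholds = pris_thresholds()) {
  if (any(!is.finite(total_ige) | total_ige <= 0)) {
    stop("validation error: total_ige must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(specific_ige) | specific_ige < 0)) {
    stop("validation error: specific_ige must be non-negative", call. = FALSE)
  }
  st <- specific_ige / total_ige
  unname(ifelse(st >= thresholds$ratio_high, 12L,
         ifelse(st >= thresholds$ratio_mid, 8L, 4L)))
}

#' @rdname pris_components
#' @export
score_crd <- function(category) {
  ok <- category %in% c("negative", "positive", "high_positive")
  if (any(!ok)) {
    stop("validation error: CRD category must be negative/positive/high_positive",
         call. = FALSE)
  }
  unname(ifelse(category == "high_positive", 12L,
         ifelse(category == "positive", 6L, 0L)))
}

#' @rdname pris_components
#' @export
score_dominance <- function(n_dominant) {
  if (any(!is.finite(n_dominant) | n_dominant < 1)) {
    stop("validation error: number of dominant allergens must be >= 1",
         call. = FALSE)
  }
  unname(ifelse(n_dominant == 1, 15L,
         ifelse(n_dominant == 2, 10L,
         ifelse(n_dominant == 3, 5L, 0L))))
}

#' Compute a patient's PRIS breakdown and total
#'
#' Resolves the eight component inputs from a patient record and a
#' dominance result and sums them. Two inputs need a resolution rule for
#' polysensitized patients:
#' \itemize{
#'   \item the s/t ratio uses the extract-level specific IgE of the
#'     highest-IgE dominant allergen (the allergen driving the SLIT
#'     prescription);
#'   \item the CRD category is the maximum category over the molecular
#'     components of all dominant allergen source(s); when no component
#'     of a dominant source was assayed the category is `negative`
#'     (score 0).
#' }
#'
#' @param record A patient record from [patient_record()].
#' @param dominance Result of [identify_dominant_allergens()]; computed
#'   on the fly when `NULL`.
#' @param thresholds See [pris_thresholds()].
#' @return A list of class `pris_breakdown`: the eight component scores
#'   (`age_score`, `clinical_score`, `onset_score`, `sensitization_score`,
#'   `exposure_score`, `ratio_score`, `crd_score`, `dominance_score`),
#'   `total`, and `extrapolated_clinical` flagging the category
#'   (rhinitis + other allergies without asthma) that the score table does
#'   not print and which is scored at the one-comorbidity tier (6).
#' @examples
#' co <- generate_cohort(cohort_config(n_patients = 2, seed = 4))
#' rec <- patient_record(co, co$patients$id[1])
#' compute_pris(rec)$total
#' @export
compute_pris <- function(record, dominance = NULL,
                         thresholds = pris_thresholds()) {
  if (is.null(dominance)) {
    dominance <- identify_dominant_allergens(record, thresholds = thresholds)
  }
  prof <- record$profile
  n_sens <- count_sensitizations(record, thresholds)

  # s/t ratio: specific IgE of the highest-IgE dominant allergen
  dom_sige <- record$ige$specific[dominance$dominant]
  dom_sige <- dom_sige[!is.na(dom_sige)]
  top_sige <- if (length(dom_sige) > 0L) max(dom_sige) else thresholds$ige_floor_kua_l
  if (is.na(record$ige$total)) {
    stop(sprintf("validation error: patient %s has no total IgE", record$id),
         call. = FALSE)
  }

  # CRD: best category among assayed components of the dominant source(s)
  comp_map <- allergen_components()
  dom_comps <- names(comp_map)[comp_map %in% dominance$dominant]
  vals <- record$ige$component[intersect(dom_comps, names(record$ige$component))]
  crd_cat <- "negative"
  if (length(vals) > 0L) {
    cats <- crd_category(unname(vals), thresholds)
    lev <- c("negative", "positive", "high_positive")
    crd_cat <- lev[max(match(cats, lev))]
  }

  b <- list(
    age_score = score_age(prof$age_years),
    clinical_score = score_clinical(prof$diseases),
    onset_score = score_onset(prof$onset_years),
    sensitization_score = score_sensitizations(n_sens),
    exposure_score = score_exposure(prof$n_symptom_triggering_allergens),
    ratio_score = score_ratio(top_sige, record$ige$total, thresholds),
    crd_score = score_crd(crd_cat),
    dominance_score = score_dominance(dominance$n_dominant)
  )
  b$total <- sum(unlist(b))
  b$extrapolated_clinical <- setequal(intersect(prof$diseases, disease_levels()),
                                      c("rhinitis", "other_allergies"))
  class(b) <- "pris_breakdown"
  b
}

#' @export
print.pris_breakdown <- function(x, ...) {
  comp <- unlist(x[component_score_names()])
  cat("<pris_breakdown>\n")
  for (nm in names(comp)) cat(sprintf("  %-20s %3d\n", nm, comp[[nm]]))
  cat(sprintf("  %-20s %3d\n", "total", x$total))
  if (isTRUE(x$extrapolated_clinical)) {
    cat("  note: clinical category (rhinitis + other allergies) extrapolated\n")
  }
  invisible(x)
}

component_score_names <- function() {
  c("age_score", "clinical_score", "onset_score", "sensitization_score",
    "exposure_score", "ratio_score", "crd_score", "dominance_score")
}

#' PRIS quartile band
#'
#' The score is stratified into fixed bands: Q1 (PRIS >= 80),
#' Q2 (60 <= PRIS < 80), Q3 (40 <= PRIS < 60), Q4 (PRIS < 40). Boundaries
#' are inclusive on the lower edge of each band.
#'
#' @param total PRIS total(s), in \[20, 100\].
#' @return Factor with levels `Q1`, `Q2`, `Q3`, `Q4`.
#' @examples
#' pris_quartile(c(93, 80, 79, 41))
#' @export
pris_quartile <- function(total) {
  if (any(!is.finite(total) | total < 20 | total > 100)) {
    stop("validation error: PRIS total must lie in [20, 100]", call. = FALSE)
  }
  band <- ifelse(total >= 80, "Q1",
          ifelse(total >= 60, "Q2",
          ifelse(total >= 40, "Q3", "Q4")))
  factor(band, levels = c("Q1", "Q2", "Q3", "Q4"))
}

#' Per-patient PRIS table for a cohort
#'
#' @param cohort A [slit_cohort()].
#' @param thresholds See [pris_thresholds()].
#' @return Data frame: `id`, the eight component scores, `total`,
#'   `quartile`.
#' @export
pris_table <- function(cohort, thresholds = pris_thresholds()) {
  rows <- lapply(cohort$patients$id, function(i) {
    rec <- patient_record(cohort, i)
    b <- compute_pris(rec, thresholds = thresholds)
    cbind(data.frame(id = i),
          as.data.frame(b[component_score_names()]),
          data.frame(total = b$total))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$quartile <- pris_quartile(out$total)
  out
}

#' Enumerate all PRIS category combinations
#'
#' Expands the full cartesian product of the eight parameters' category
#' scores (5 x 3 x 3 x 4 x 4 x 3 x 3 x 4 = 25920 combinations) with the
#' total of each. Useful for exhaustive bound and monotonicity checks.
#'
#' @return Data frame with one column per component score and `total`.
#' @examples
#' g <- pris_score_grid()
#' range(g$total)
#' @export
pris_score_grid <- function() {
  g <- expand.grid(
    age_score = c(15L, 12L, 9L, 6L, 3L),
    clinical_score = c(9L, 6L, 3L),
    onset_score = c(9L, 6L, 3L),
    sensitization_score = c(16L, 12L, 8L, 4L),
    exposure_score = c(12L, 9L, 6L, 3L),
    ratio_score = c(12L, 8L, 4L),
    crd_score = c(12L, 6L, 0L),
    dominance_score = c(15L, 10L, 5L, 0L),
    KEEP.OUT.ATTRS = FALSE
  )
  g$total <- as.integer(rowSums(g))
  g
}
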