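#' Positivity rules for skin prick tests and specific IgE
#'
#' An SPT is positive at a wheal diameter of at least 3 mm; a specific-IgE
#' (or component-IgE) assay is positive at 0.35 kUA/L or above. Component
#' IgE is further graded for component-resolved diagnosis (CRD): values at
#' or above 3.50 kUA/L are "high_positive", values in \[0.35, 3.50) are
#' "positive", below 0.35 "negative".
#'
#' @param wheal_mm Wheal diameter(s) in millimetres, non-negative.
#' @param value_kua_l IgE concentration(s) in kUA/L, non-negative.
#' @param thresholds Threshold registry, see [pris_thresholds()].
#' @return Logical vector for `spt_positive()`/`ige_positive()`; for
#'   `crd_category()` a character vector with values
#'   `"negative"`, `"positive"`, `"high_positive"`.
#' @examples
#' spt_positive(c(0, 2.9, 3))
#' ige_positive(c(0.34, 0.35))
#' crd_category(c(0.1, 0.35, 3.5))
#' @export
spt_positive <- function(wheal_mm, thresholds = pris_thresholds()) {
  if (any(!is.finite(wheal_mm) | wheal_mm < 0)) {
    stop("validation error: wheal_mm must be non-negative", call. = FALSE)
  }
  wheal_mm >= thresholds$spt_positive_mm
}

#' @rdname spt_positive
#' @export
ige_positive <- function(value_kua_l, thresholds = pris_thresholds()) {
  if (any(!is.finite(value_kua_l) | value_kua_l < 0)) {
    stop("validation error: IgE value must be non-negative", call. = FALSE)
  }
  value_kua_l >= thresholds$ige_positive_kua_l
}

#' @rdname spt_positive
#' @export
crd_category <- function(value_kua_l, thresholds = pris_thresholds()) {
  if (any(!is.finite(value_kua_l) | value_kua_l < 0)) {
    stop("validation error: IgE value must be non-negative", call. = FALSE)
  }
  ifelse(value_kua_l >= thresholds$crd_high_kua_l, "high_positive",
         ifelse(value_kua_l >= thresholds$ige_positive_kua_l,
                "positive", "negative"))
}

# Allergen sources positive by SPT or by extract-level specific IgE (union).
positive_sources <- function(record, thresholds = pris_thresholds()) {
  spt_pos <- character(0)
  if (nrow(record$spt) > 0L) {
    spt_pos <- record$spt$allergen[spt_positive(record$spt$wheal_mm, thresholds)]
  }
  ige_pos <- character(0)
  if (length(record$ige$specific) > 0L) {
    ige_pos <- names(record$ige$specific)[
      ige_positive(record$ige$specific, thresholds)]
  }
  unique(c(spt_pos, ige_pos))
}

#' Count allergen sensitizations
#'
#' Number of distinct allergen sources to which a patient is sensitized,
#' assessed by skin prick test and/or extract-level specific IgE: a source
#' counts once if it is positive by either assay (union semantics).
#'
#' @param record A patient record from [patient_record()].
#' @param thresholds See [pris_thresholds()].
#' @return Integer count (0 when no assay is positive).
#' @export
count_sensitizations <- function(record, thresholds = pris_thresholds()) {
  length(positive_sources(record, thresholds))
}

#' Screen a patient against the enrolment criteria
#'
#' Exclusion rules: age under six years; concomitant asthma not adequately
#' controlled (Asthma Control Test score below the controlled threshold,
#' default 20); nasal polyposis; profilin allergy (positive component IgE
#' to Bet v2); and absence of any positive skin prick test or any positive
#' specific IgE (the diagnosis of IgE-mediated allergy must be supported
#' by both assays being available with at least one positive each).
#'
#' @param record A patient record from [patient_record()].
#' @param act_controlled ACT score at or above which asthma counts as
#'   controlled.
#' @param thresholds See [pris_thresholds()].
#' @return A list with `eligible` (flag) and `reasons` (character vector
#'   of exclusion codes among `age_under_6`, `uncontrolled_asthma`,
#'   `nasal_polyposis`, `profilin_betv2`, `no_positive_spt`,
#'   `no_positive_sige`); `eligible` is `TRUE` iff `reasons` is empty.
#' @export
screen_eligibility <- function(record,
                               act_controlled = pris_thresholds()$act_controlled,
                               thresholds = pris_thresholds()) {
  reasons <- character(0)
  prof <- record$profile
  if (prof$age_years < 6) reasons <- c(reasons, "age_under_6")
  if ("asthma" %in% prof$diseases) {
    if (is.na(prof$act_score)) {
      stop(sprintf(
        "validation error: patient %s has asthma but no ACT score; asthma control cannot be assessed",
        record$id), call. = FALSE)
    }
    if (prof$act_score < act_controlled) {
      reasons <- c(reasons, "uncontrolled_asthma")
    }
  }
  if (isTRUE(prof$nasal_polyposis)) reasons <- c(reasons, "nasal_polyposis")
  betv2 <- record$ige$component["Bet v2"]
  if (!is.na(betv2) && ige_positive(unname(betv2), thresholds)) {
    reasons <- c(reasons, "profilin_betv2")
  }
  any_spt <- nrow(record$spt) > 0L &&
    any(spt_positive(record$spt$wheal_mm, thresholds))
  if (!any_spt) reasons <- c(reasons, "no_positive_spt")
  any_sige <- length(record$ige$specific) > 0L &&
    any(ige_positive(record$ige$specific, thresholds))
  if (!any_sige) reasons <- c(reasons, "no_positive_sige")
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Identify a patient's dominant allergen(s)
#'
#' The dominant allergens are the ones driving symptoms and are the
#' allergens prescribed for SLIT. Operationally: take all positive
#' sensitizations, sort them by extract-level specific IgE (descending;
#' ties broken by wheal diameter descending, then by label), and find the
#' shortest non-empty prefix whose every member exceeds every non-member
#' by BOTH margins — a wheal-diameter difference of at least 5 mm and a
#' specific-IgE difference of at least half a log10 unit. If no proper
#' prefix separates, all positive allergens are co-dominant.
#'
#' Specific IgE is floored at `ige_floor_kua_l` (0.01 kUA/L, below assay
#' range) before logs so margins stay finite; a source positive only by
#' SPT and lacking an IgE row takes the floor value, a source positive
#' only by IgE and lacking an SPT row takes wheal 0.
#'
#' @param record A patient record from [patient_record()].
#' @param wheal_margin_mm,log10_margin Separation margins (defaults 5 mm
#'   and 0.5 log10 units).
#' @param thresholds See [pris_thresholds()].
#' @return A list with `dominant` (character vector, ordered as in the
#'   sort), `n_dominant`, and the achieved minimum separations across the
#'   dominant / non-dominant boundary: `separation_wheal_mm` and
#'   `separation_log10_ige` (both 0 when everything is co-dominant).
#' @export
identify_dominant_allergens <- function(record,
                                        wheal_margin_mm = pris_thresholds()$dominance_wheal_mm,
                                        log10_margin = pris_thresholds()$dominance_log10_ige,
                                        thresholds = pris_thresholds()) {
  pos <- positive_sources(record, thresholds)
  if (length(pos) == 0L) {
    stop(sprintf("validation error: patient %s has no positive sensitization",
                 record$id), call. = FALSE)
  }
  wheal <- vapply(pos, function(a) {
    w <- record$spt$wheal_mm[record$spt$allergen == a]
    if (length(w) > 0L) max(w) else 0
  }, numeric(1))
  sige <- vapply(pos, function(a) {
    v <- record$ige$specific[a]
    if (is.na(v)) thresholds$ige_floor_kua_l else unname(v)
  }, numeric(1))
  lsige <- log10(pmax(sige, thresholds$ige_floor_kua_l))

  ord <- order(-lsige, -wheal, pos)
  pos <- pos[ord]; wheal <- wheal[ord]; lsige <- lsige[ord]
  n <- length(pos)

  sep_w <- 0
  sep_l <- 0
  k_dom <- n
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      dw <- min(wheal[seq_len(k)]) - max(wheal[(k + 1L):n])
      dl <- min(lsige[seq_len(k)]) - max(lsige[(k + 1L):n])
      if (dw >= wheal_margin_mm && dl >= log10_margin) {
        k_dom <- k
        sep_w <- dw
        sep_l <- dl
        break
      }
    }
  }
  list(
    dominant = pos[seq_len(k_dom)],
    n_dominant = k_dom,
    separation_wheal_mm = sep_w,
    separation_log10_ige = sep_l
  )
}

#' Cohort-level screening and dominance tables
#'
#' Vectorized wrappers applying [screen_eligibility()] and
#' [identify_dominant_allergens()] to every patient of a cohort.
#'
#' @param cohort A [slit_cohort()].
#' @param ... Passed on to the per-patient function.
#' @return `screen_cohort()`: data frame `id`, `eligible`, `reasons`
#'   (semicolon-joined). `dominance_table()`: data frame `id`, `dominant`
#'   (semicolon-joined), `n_dominant`, `separation_wheal_mm`,
#'   `separation_log10_ige`.
#' @export
screen_cohort <- function(cohort, ...) {
  ids <- cohort$patients$id
  rows <- lapply(ids, function(i) {
    r <- screen_eligibility(patient_record(cohort, i), ...)
    data.frame(id = i, eligible = r$eligible,
               reasons = paste(r$reasons, collapse = ";"))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @rdname screen_cohort
#' @export
dominance_table <- function(cohort, ...) {
  ids <- cohort$patients$id
  rows <- lapply(ids, function(i) {
    d <- identify_dominant_allergens(patient_record(cohort, i), ...)
    data.frame(id = i, dominant = paste(d$dominant, collapse = ";"),
               n_dominant = d$n_dominant,
               separation_wheal_mm = d$separation_wheal_mm,
               separation_log10_ige = d$separation_log10_ige)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
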