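#' Mean symptom score and SLIT efficacy index
#'
#' `mss()` is the unweighted arithmetic mean of all VAS items recorded at
#' one timepoint (symptom severity items plus the frequency, exacerbation
#' and on-demand medication items — a combined symptom and medication
#' score on \[0, 100\]). `delta_mss()` is the percentage improvement from
#' baseline, `(MSS-0 - MSS-t) / MSS-0 * 100`; negative values mean the
#' symptoms worsened.
#'
#' @param items Named numeric vector of VAS item scores on \[0, 100\].
#' @param mss0,mss_t Mean symptom scores at baseline and follow-up;
#'   `mss0` must be positive.
#' @return A single number.
#' @examples
#' mss(c(sneezing = 60, rhinorrhea = 70, frequency = 80, medication = 90))
#' delta_mss(80, 20)
#' @export
mss <- function(items) {
  if (length(items) == 0L) {
    stop("validation error: cannot compute MSS from an empty item set",
         call. = FALSE)
  }
  if (any(!is.finite(items) | items < 0 | items > 100)) {
    stop("validation error: VAS item scores must lie in [0, 100]",
         call. = FALSE)
  }
  mean(items)
}

#' @rdname mss
#' @export
delta_mss <- function(mss0, mss_t) {
  if (any(!is.finite(mss0) | mss0 <= 0)) {
    stop("undefined-baseline error: MSS-0 must be positive to express a percentage change",
         call. = FALSE)
  }
  (mss0 - mss_t) / mss0 * 100
}

#' Response quartile band from a percentage improvement
#'
#' Symptom-improvement bands: `very_high` (delta >= 75 percent), `high`
#' (50-75), `mild` (25-50), `low` (below 25, including worsening).
#'
#' @param delta_pct Numeric vector of percentage improvements.
#' @return Factor with levels `very_high`, `high`, `mild`, `low`.
#' @examples
#' response_quartile(c(75, 74.9, -10))
#' @export
response_quartile <- function(delta_pct) {
  if (any(!is.finite(delta_pct))) {
    stop("validation error: delta must be finite", call. = FALSE)
  }
  band <- ifelse(delta_pct >= 75, "very_high",
          ifelse(delta_pct >= 50, "high",
          ifelse(delta_pct >= 25, "mild", "low")))
  factor(band, levels = c("very_high", "high", "mild", "low"))
}

#' Per-patient outcome table
#'
#' Computes MSS at every recorded timepoint, the efficacy indices
#' ΔMSS-12(%) and ΔMSS-24(%), and the response bands, for each patient of
#' a cohort. Timepoints without a VAS assessment (dropouts) yield `NA`.
#'
#' @param cohort A [slit_cohort()].
#' @return Data frame: `id`, `dropped_out`, `mss0`, `mss12`, `mss24`,
#'   `delta12_pct`, `delta24_pct`, `response12`, `response24`.
#' @export
outcome_table <- function(cohort) {
  rows <- lapply(cohort$patients$id, function(i) {
    rec <- patient_record(cohort, i)
    m <- vapply(timepoint_levels(), function(tp) {
      v <- rec$vas[[tp]]
      if (is.null(v)) NA_real_ else mss(v)
    }, numeric(1))
    d12 <- if (is.na(m["T12"])) NA_real_ else delta_mss(m["T0"], m["T12"])
    d24 <- if (is.na(m["T24"])) NA_real_ else delta_mss(m["T0"], m["T24"])
    data.frame(id = i, dropped_out = rec$profile$dropped_out,
               mss0 = unname(m["T0"]), mss12 = unname(m["T12"]),
               mss24 = unname(m["T24"]),
               delta12_pct = unname(d12), delta24_pct = unname(d24))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$response12 <- factor(NA, levels = levels(response_quartile(0)))
  out$response24 <- out$response12
  ok12 <- !is.na(out$delta12_pct)
  ok24 <- !is.na(out$delta24_pct)
  out$response12[ok12] <- response_quartile(out$delta12_pct[ok12])
  out$response24[ok24] <- response_quartile(out$delta24_pct[ok24])
  out
}

group_stat <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0)
}

#' Group-level outcome summary
#'
#' Summarizes completer outcomes (mean and SD of MSS-0/12/24 and
#' ΔMSS-12/24, plus response-band counts and percentages) for one of the
#' groupings used in the validation analyses:
#' \describe{
#'   \item{overall}{the whole completer cohort;}
#'   \item{slit_type}{single-allergen (mono) vs multi-allergen (mix) SLIT,
#'     from the number of dominant allergens;}
#'   \item{disease_group}{rhinitis only vs rhinitis + asthma;}
#'   \item{pris_band}{PRIS quartile bands.}
#' }
#' Dropouts are excluded (no imputation). Empty groups are reported with
#' `n = 0` and `NA` statistics.
#'
#' @param cohort A [slit_cohort()].
#' @param grouping One of `"overall"`, `"slit_type"`, `"disease_group"`,
#'   `"pris_band"`.
#' @return Data frame with one row per group: `group`, `n`, `mss0_mean`,
#'   `mss0_sd`, ..., `delta24_mean`, `delta24_sd`, and per-band counts
#'   `n_very_high_24` ... `pct_low_24` for ΔMSS-24 (and the T12
#'   analogues).
#' @export
summarize_cohort <- function(cohort,
                             grouping = c("overall", "slit_type",
                                          "disease_group", "pris_band")) {
  grouping <- match.arg(grouping)
  out <- outcome_table(cohort)
  comp <- out[!out$dropped_out, , drop = FALSE]

  grp <- switch(grouping,
    overall = rep("all", nrow(comp)),
    slit_type = {
      dom <- dominance_table(cohort)
      nd <- dom$n_dominant[match(comp$id, dom$id)]
      ifelse(nd == 1L, "mono_slit", "mix_slit")
    },
    disease_group = {
      p <- cohort$patients
      dis <- p$diseases[match(comp$id, p$id)]
      ifelse(grepl("asthma", dis), "rhinitis_asthma", "rhinitis_only")
    },
    pris_band = {
      pt <- pris_table(cohort)
      as.character(pt$quartile[match(comp$id, pt$id)])
    })
  levels_grp <- switch(grouping,
    overall = "all",
    slit_type = c("mono_slit", "mix_slit"),
    disease_group = c("rhinitis_only", "rhinitis_asthma"),
    pris_band = c("Q1", "Q2", "Q3", "Q4"))
  grp <- factor(grp, levels = levels_grp)

  rows <- lapply(levels_grp, function(g) {
    d <- comp[!is.na(grp) & grp == g, , drop = FALSE]
    st <- c(group_stat(d$mss0), group_stat(d$mss12), group_stat(d$mss24),
            group_stat(d$delta12_pct), group_stat(d$delta24_pct))
    names(st) <- paste0(rep(c("mss0", "mss12", "mss24", "delta12", "delta24"),
                            each = 2), "_", c("mean", "sd"))
    bands <- levels(response_quartile(0))
    cnt24 <- table(factor(d$response24, levels = bands))
    cnt12 <- table(factor(d$response12, levels = bands))
    n <- nrow(d)
    band_cols <- c(
      as.list(setNames(as.integer(cnt12), paste0("n_", bands, "_12"))),
      as.list(setNames(if (n > 0) 100 * as.integer(cnt12) / n
                       else rep(NA_real_, 4),
                       paste0("pct_", bands, "_12"))),
      as.list(setNames(as.integer(cnt24), paste0("n_", bands, "_24"))),
      as.list(setNames(if (n > 0) 100 * as.integer(cnt24) / n
                       else rep(NA_real_, 4),
                       paste0("pct_", bands, "_24")))
    )
    cbind(data.frame(group = g, n = n), as.data.frame(t(st)),
          as.data.frame(band_cols))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' PRIS-band by response-band cross-tabulation
#'
#' Counts completers in each combination of PRIS quartile band and
#' ΔMSS-24(%) response band — the matrix behind the stacked-bar
#' stratification display. Row/column sums equal the stratum sizes and
#' the grand total equals the completer count.
#'
#' @param cohort A [slit_cohort()].
#' @return Integer matrix, rows = PRIS bands Q1..Q4, columns = response
#'   bands very_high..low.
#' @export
cross_tab <- function(cohort) {
  out <- outcome_table(cohort)
  comp <- out[!out$dropped_out & !is.na(out$delta24_pct), , drop = FALSE]
  pt <- pris_table(cohort)
  pband <- pt$quartile[match(comp$id, pt$id)]
  table(pris = pband, response = comp$response24)
}

#' Percentage of a count, as printed in cohort tables
#'
#' @param n Numerator count(s).
#' @param total Denominator count.
#' @param digits Decimal places to round to (cohort tables print 1 or 2).
#' @return Numeric percentage(s).
#' @examples
#' pct(12, 110, 1) # 10.9
#' pct(66, 98)     # 67.35 by strict rounding of 67.3469...
#' @export
pct <- function(n, total, digits = 2) {
  round(100 * n / total, digits)
}
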