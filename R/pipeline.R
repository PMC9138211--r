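#' Run the full validation pipeline on a cohort
#'
#' Executes the whole workflow in the order used for score validation:
#' eligibility screening, dominant-allergen identification, PRIS scoring,
#' outcome computation, group summaries, cross-tabulation, and the
#' statistical battery (repeated-measures ANOVA on MSS, simple regression
#' of ΔMSS-24(%) on PRIS, per-parameter regressions, one-way ANOVA with
#' post-hoc tests across PRIS strata, and the Pearson power analysis that
#' sized the design). Writes every table as CSV, all statistics as one
#' JSON metrics file, and the four standard figures as PDFs.
#'
#' @param cohort A [slit_cohort()]; alternatively `input` may name a
#'   directory of cohort CSVs.
#' @param output_dir Directory for the report bundle (created if needed);
#'   `NULL` to skip writing and just return the bundle.
#' @param input Optional path to a cohort directory (ignored when
#'   `cohort` is given).
#' @param act_controlled,posthoc,wheal_margin_mm,log10_margin
#'   Threshold overrides, see [screen_eligibility()],
#'   [oneway_anova_posthoc()], [identify_dominant_allergens()].
#' @param figures Write the PDF figures (the underlying data tables are
#'   always included).
#' @return Invisibly, a list with all tables and fitted results
#'   (`screening`, `dominance`, `pris`, `outcomes`, `summary_*`,
#'   `cross_tab`, `rm_anova`, `regression`, `component_regression`,
#'   `strata_anova`, `power`).
#' @export
run_pipeline <- function(cohort = NULL, output_dir = NULL, input = NULL,
                         act_controlled = pris_thresholds()$act_controlled,
                         posthoc = c("tukey", "bonferroni"),
                         wheal_margin_mm = pris_thresholds()$dominance_wheal_mm,
                         log10_margin = pris_thresholds()$dominance_log10_ige,
                         figures = TRUE) {
  posthoc <- match.arg(posthoc)
  if (is.null(cohort)) {
    if (is.null(input)) stop("either a cohort or an input directory is required",
                             call. = FALSE)
    cohort <- read_cohort(input)
  }
  if (nrow(cohort$patients) == 0L) {
    stop("pipeline error at stage 'screen': empty cohort", call. = FALSE)
  }

  screening <- screen_cohort(cohort, act_controlled = act_controlled)
  dominance <- dominance_table(cohort, wheal_margin_mm = wheal_margin_mm,
                               log10_margin = log10_margin)
  pris <- pris_table(cohort)
  outcomes <- outcome_table(cohort)
  comp <- outcomes[!outcomes$dropped_out & !is.na(outcomes$mss24), ,
                   drop = FALSE]
  if (nrow(comp) < 3L) {
    stop("pipeline error at stage 'outcomes': fewer than 3 completers",
         call. = FALSE)
  }

  summaries <- lapply(
    c(overall = "overall", slit_type = "slit_type",
      disease_group = "disease_group", pris_band = "pris_band"),
    function(g) summarize_cohort(cohort, g)
  )
  xt <- cross_tab(cohort)

  mss_mat <- as.matrix(comp[, c("mss0", "mss12", "mss24")])
  colnames(mss_mat) <- timepoint_levels()
  rma <- rm_anova(mss_mat)

  p24 <- pris$total[match(comp$id, pris$id)]
  reg <- simple_regression(p24, comp$delta24_pct)
  creg <- component_regression(pris, outcomes)
  strata <- oneway_anova_posthoc(comp$delta24_pct,
                                 pris_quartile(p24), posthoc = posthoc)
  pow <- list(n_required = sample_size_pearson(0.3, 0.05, 0.80),
              analytic_power_at_n = power_pearson(nrow(comp), 0.3, 0.05))

  bundle <- list(screening = screening, dominance = dominance, pris = pris,
                 outcomes = outcomes,
                 summary_overall = summaries$overall,
                 summary_slit_type = summaries$slit_type,
                 summary_disease_group = summaries$disease_group,
                 summary_pris_band = summaries$pris_band,
                 cross_tab = xt, rm_anova = rma, regression = reg,
                 component_regression = creg, strata_anova = strata,
                 power = pow)

  if (!is.null(output_dir)) {
    write_report_bundle(bundle, output_dir, figures = figures)
  }
  invisible(bundle)
}

report_metrics <- function(bundle) {
  reg <- bundle$regression
  rma <- bundle$rm_anova
  st <- bundle$strata_anova
  list(
    n_patients = nrow(bundle$screening),
    n_completers = sum(!bundle$outcomes$dropped_out),
    power = bundle$power,
    rm_anova = list(f = rma$f_stat, df = rma$df, p = rma$p_value,
                    pairwise = rma$pairwise),
    regression = list(r = reg$r, f = reg$f_stat, df = reg$df,
                      p = reg$p_value, slope = reg$slope,
                      intercept = reg$intercept),
    component_regression = lapply(bundle$component_regression, function(cr) {
      list(p = cr$p_value, betas = cr$betas)
    }),
    strata_anova = list(f = st$f_stat, df = st$df, p = st$p_value,
                        group_means = st$group_means,
                        pairwise = st$pairwise),
    cross_tab = as.data.frame.matrix(bundle$cross_tab)
  )
}

write_report_bundle <- function(bundle, output_dir, figures = TRUE) {
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  tabs <- c("screening", "dominance", "pris", "outcomes",
            "summary_overall", "summary_slit_type", "summary_disease_group",
            "summary_pris_band")
  for (tb in tabs) {
    write.csv(bundle[[tb]], file.path(output_dir, paste0(tb, ".csv")),
              row.names = FALSE)
  }
  write.csv(as.data.frame.matrix(bundle$cross_tab),
            file.path(output_dir, "cross_tab.csv"))
  jsonlite::write_json(report_metrics(bundle),
                       file.path(output_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  if (figures) {
    save_fig <- function(p, name, w = 6, h = 4.5) {
      ggplot2::ggsave(file.path(output_dir, name), p, width = w, height = h)
    }
    save_fig(plot_mss_summary(bundle$summary_overall), "fig_mss.pdf")
    comp <- bundle$outcomes[!bundle$outcomes$dropped_out, , drop = FALSE]
    p24 <- bundle$pris$total[match(comp$id, bundle$pris$id)]
    save_fig(plot_pris_regression(p24, comp$delta24_pct), "fig_regression.pdf")
    save_fig(plot_strata_means(bundle$strata_anova), "fig_strata.pdf")
    save_fig(plot_cross_tab(bundle$cross_tab), "fig_cross_tab.pdf")
  }
  invisible(output_dir)
}

#' Standard figures of the validation workflow
#'
#' `plot_mss_summary()`: mean MSS with SD bars per timepoint.
#' `plot_pris_regression()`: ΔMSS-24(%) against PRIS with the fitted
#' line. `plot_strata_means()`: mean response per PRIS band with SD
#' bars. `plot_cross_tab()`: stacked response-band composition per PRIS
#' band.
#'
#' @param summary_overall Output of `summarize_cohort(cohort, "overall")`.
#' @param pris_total,delta24 Per-completer PRIS totals and ΔMSS-24(%).
#' @param strata Output of [oneway_anova_posthoc()].
#' @param xt Output of [cross_tab()].
#' @return A ggplot object.
#' @name pris_figures
#' @export
plot_mss_summary <- function(summary_overall) {
  s <- summary_overall[1, ]
  d <- data.frame(
    timepoint = factor(timepoint_levels(), timepoint_levels()),
    mean = c(s$mss0_mean, s$mss12_mean, s$mss24_mean),
    sd = c(s$mss0_sd, s$mss12_sd, s$mss24_sd)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "Mean symptom score (MSS)") +
    ggplot2::theme_minimal()
}

#' @rdname pris_figures
#' @export
plot_pris_regression <- function(pris_total, delta24) {
  d <- data.frame(pris = pris_total, delta24 = delta24)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pris, y = .data$delta24)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "steelblue") +
    ggplot2::labs(x = "PRIS", y = "Delta-MSS-24 (%)") +
    ggplot2::theme_minimal()
}

#' @rdname pris_figures
#' @export
plot_strata_means <- function(strata) {
  d <- strata$group_means
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = "PRIS band", y = "Delta-MSS-24 (%), mean +/- SD") +
    ggplot2::theme_minimal()
}

#' @rdname pris_figures
#' @export
plot_cross_tab <- function(xt) {
  d <- as.data.frame(xt)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pris, y = .data$Freq,
                                  fill = .data$response)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = "PRIS band", y = "Patients",
                  fill = "Delta-MSS-24 band") +
    ggplot2::theme_minimal()
}

utils::globalVariables(".data")
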