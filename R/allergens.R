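#' Inhalant allergen panel
#'
#' The extract-level allergen sources used for skin prick testing (SPT) and
#' specific-IgE assays, and the molecular components measured by
#' component-resolved diagnosis (CRD). Every component maps to exactly one
#' extract source; `Bet v2` (profilin, a cross-reactive panallergen) is on
#' the panel only so that positivity can trigger exclusion.
#'
#' @return `allergen_sources()` returns a character vector of the eleven
#'   extract labels; `allergen_components()` returns a named character
#'   vector mapping each molecular component to its source extract.
#' @examples
#' allergen_sources()
#' allergen_components()[["Der p1"]]
#' @export
allergen_sources <- function() {
  c("grass", "ambrosia", "mugwort", "pellitory", "olive", "cypress",
    "birch", "cat", "dog", "mite", "molds")
}

#' @rdname allergen_sources
#' @export
allergen_components <- function() {
  c("Phl p1" = "grass", "Phl p5" = "grass",
    "Bet v1" = "birch", "Bet v2" = "birch",
    "Amb a1" = "ambrosia", "Art v1" = "mugwort",
    "Par j2" = "pellitory", "Ole e1" = "olive",
    "Cup a1" = "cypress", "Fel d1" = "cat", "Can f1" = "dog",
    "Der p1" = "mite", "Der p2" = "mite",
    "Alt a1" = "molds")
}

#' Clinical and laboratory thresholds
#'
#' Central registry of every cutoff the scoring and screening rules use.
#' All values are overridable where a function takes the corresponding
#' argument, but these are the defaults applied throughout the package.
#'
#' \describe{
#'   \item{spt_positive_mm}{wheal diameter (mm) at or above which an SPT is
#'     positive (3 mm).}
#'   \item{ige_positive_kua_l}{specific-IgE positivity cutoff, 0.35 kUA/L.}
#'   \item{crd_high_kua_l}{component IgE at or above which CRD is
#'     "high positive", 3.50 kUA/L.}
#'   \item{ratio_high, ratio_mid}{specific/total IgE (s/t) ratio cutpoints
#'     0.2 and 0.05.}
#'   \item{dominance_wheal_mm}{wheal-diameter margin (5 mm) separating a
#'     dominant allergen from the rest.}
#'   \item{dominance_log10_ige}{specific-IgE margin on the log10 scale
#'     (0.5, i.e. half a logarithm).}
#'   \item{ige_floor_kua_l}{floor applied to specific IgE before taking
#'     log10 (0.01 kUA/L, below assay range) so margins stay finite.}
#'   \item{act_controlled}{Asthma Control Test score at or above which
#'     asthma counts as adequately controlled (20).}
#' }
#'
#' @return Named list of numeric thresholds.
#' @examples
#' pris_thresholds()$spt_positive_mm
#' @export
pris_thresholds <- function() {
  list(
    spt_positive_mm = 3,
    ige_positive_kua_l = 0.35,
    crd_high_kua_l = 3.50,
    ratio_high = 0.2,
    ratio_mid = 0.05,
    dominance_wheal_mm = 5,
    dominance_log10_ige = 0.5,
    ige_floor_kua_l = 0.01,
    act_controlled = 20
  )
}

timepoint_levels <- function() c("T0", "T12", "T24")

disease_levels <- function() c("rhinitis", "asthma", "other_allergies")

# VAS item vocabulary: rhinitis severity, asthma severity, plus the
# frequency / exacerbation / on-demand medication items.
vas_items_rhinitis <- function() {
  c("sneezing", "nasal_congestion", "rhinorrhea", "nasal_itching",
    "throat_itching", "eye_itching", "ear_itching")
}

vas_items_asthma <- function() {
  c("chest_tightness", "breathlessness", "wheezing", "coughing")
}

vas_items_general <- function() {
  c("frequency", "medication")
}

vas_items_asthma_extra <- function() {
  c("exacerbation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
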