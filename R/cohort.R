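#' SLIT cohort container
#'
#' A `slit_cohort` bundles the four tables that describe an allergen
#' immunotherapy cohort, cross-linked by patient `id`:
#'
#' \describe{
#'   \item{patients}{one row per subject: `id`, `age_years`, `diseases`
#'     (semicolon-joined subset of rhinitis/asthma/other_allergies),
#'     `onset_years`, `n_symptom_triggering_allergens`, `act_score`
#'     (NA when no asthma), `nasal_polyposis`, `dropped_out`.}
#'   \item{spt}{skin prick test battery: `id`, `allergen` (extract label),
#'     `wheal_mm`, `histamine_mm`, `saline_mm`.}
#'   \item{ige}{`id`, `total_ige` (kU/L), `allergen_or_component` (extract
#'     or molecular component label), `value` (kUA/L).}
#'   \item{vas}{`id`, `timepoint` (T0/T12/T24), `item`, `score` on
#'     \[0, 100\] (VAS marks already normalized from the 10 cm line).}
#' }
#'
#' The constructor validates every invariant (known allergen labels,
#' non-negative wheals and concentrations, VAS scores in range, rhinitis
#' present in every enrolled patient, at most one assessment per item and
#' timepoint) and fails with a message naming the offending column or
#' patient; nothing is silently coerced.
#'
#' @param patients,spt,ige,vas Data frames as described above. `spt`,
#'   `ige` and `vas` may be empty (zero rows) but must carry the schema
#'   columns.
#' @return An object of class `slit_cohort` (a named list of the four
#'   validated data frames).
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
slit_cohort <- function(patients,
                        spt = empty_spt(),
                        ige = empty_ige(),
                        vas = empty_vas()) {
  x <- structure(
    list(patients = coerce_types(as.data.frame(patients), "patients"),
         spt = coerce_types(as.data.frame(spt), "spt"),
         ige = coerce_types(as.data.frame(ige), "ige"),
         vas = coerce_types(as.data.frame(vas), "vas")),
    class = "slit_cohort"
  )
  validate_cohort(x)
  x
}

# canonical column types, applied on construction and after CSV reads so
# that write/read round-trips are bit-exact
cohort_types <- function() {
  list(
    patients = c(id = "character", age_years = "integer",
                 diseases = "character", onset_years = "double",
                 n_symptom_triggering_allergens = "integer",
                 act_score = "integer", nasal_polyposis = "logical",
                 dropped_out = "logical"),
    spt = c(id = "character", allergen = "character", wheal_mm = "double",
            histamine_mm = "double", saline_mm = "double"),
    ige = c(id = "character", total_ige = "double",
            allergen_or_component = "character", value = "double"),
    vas = c(id = "character", timepoint = "character", item = "character",
            score = "double")
  )
}

coerce_types <- function(df, table) {
  types <- cohort_types()[[table]]
  for (col in intersect(names(types), names(df))) {
    df[[col]] <- switch(types[[col]],
                        character = as.character(df[[col]]),
                        integer = as.integer(df[[col]]),
                        double = as.double(df[[col]]),
                        logical = as.logical(df[[col]]))
  }
  df
}

empty_spt <- function() {
  data.frame(id = character(), allergen = character(),
             wheal_mm = numeric(), histamine_mm = numeric(),
             saline_mm = numeric())
}

empty_ige <- function() {
  data.frame(id = character(), total_ige = numeric(),
             allergen_or_component = character(), value = numeric())
}

empty_vas <- function() {
  data.frame(id = character(), timepoint = character(),
             item = character(), score = numeric())
}

cohort_schema <- function() {
  list(
    patients = c("id", "age_years", "diseases", "onset_years",
                 "n_symptom_triggering_allergens", "act_score",
                 "nasal_polyposis", "dropped_out"),
    spt = c("id", "allergen", "wheal_mm", "histamine_mm", "saline_mm"),
    ige = c("id", "total_ige", "allergen_or_component", "value"),
    vas = c("id", "timepoint", "item", "score")
  )
}

check_columns <- function(df, table, required) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("schema error in '%s' table: missing column(s) %s",
                 table, paste(sQuote(missing), collapse = ", ")),
         call. = FALSE)
  }
}

#' @export
print.slit_cohort <- function(x, ...) {
  n <- nrow(x$patients)
  n_comp <- sum(!x$patients$dropped_out)
  cat(sprintf("<slit_cohort> %d patients (%d completers)\n", n, n_comp))
  cat(sprintf("  spt: %d rows | ige: %d rows | vas: %d rows\n",
              nrow(x$spt), nrow(x$ige), nrow(x$vas)))
  invisible(x)
}

validate_cohort <- function(x) {
  sch <- cohort_schema()
  for (tab in names(sch)) check_columns(x[[tab]], tab, sch[[tab]])

  p <- x$patients
  if (anyDuplicated(p$id)) {
    stop("validation error: duplicated patient id(s) in patients table",
         call. = FALSE)
  }
  if (nrow(p) > 0L) {
    if (any(!is.finite(p$age_years) | p$age_years < 0)) {
      stop("validation error: age_years must be a non-negative number",
           call. = FALSE)
    }
    if (any(!is.finite(p$onset_years) | p$onset_years < 0)) {
      stop("validation error: onset_years must be a non-negative number",
           call. = FALSE)
    }
    dis <- strsplit(as.character(p$diseases), ";", fixed = TRUE)
    bad <- vapply(dis, function(d) any(!d %in% disease_levels()), logical(1))
    if (any(bad)) {
      stop(sprintf("validation error: unknown disease label for patient %s",
                   p$id[which(bad)[1]]), call. = FALSE)
    }
    no_rhin <- !vapply(dis, function(d) "rhinitis" %in% d, logical(1))
    if (any(no_rhin)) {
      stop(sprintf(
        "validation error: patient %s lacks rhinitis (all enrolled patients have allergic rhinitis)",
        p$id[which(no_rhin)[1]]), call. = FALSE)
    }
    act <- p$act_score
    bad_act <- !is.na(act) & (act < 5 | act > 25)
    if (any(bad_act)) {
      stop(sprintf("validation error: act_score outside 5-25 for patient %s",
                   p$id[which(bad_act)[1]]), call. = FALSE)
    }
  }

  s <- x$spt
  if (nrow(s) > 0L) {
    if (any(!s$allergen %in% allergen_sources())) {
      bad <- setdiff(unique(s$allergen), allergen_sources())
      stop(sprintf("validation error: unknown allergen label(s) in spt table: %s",
                   paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    }
    if (any(!is.finite(s$wheal_mm) | s$wheal_mm < 0)) {
      bad_id <- s$id[which(!is.finite(s$wheal_mm) | s$wheal_mm < 0)[1]]
      stop(sprintf("validation error: negative or missing wheal_mm for patient %s",
                   bad_id), call. = FALSE)
    }
    orphan <- setdiff(unique(s$id), p$id)
    if (length(orphan) > 0L) {
      stop(sprintf("validation error: spt rows for unknown patient id %s",
                   sQuote(orphan[1])), call. = FALSE)
    }
  }

  g <- x$ige
  if (nrow(g) > 0L) {
    known <- c(allergen_sources(), names(allergen_components()))
    if (any(!g$allergen_or_component %in% known)) {
      bad <- setdiff(unique(g$allergen_or_component), known)
      stop(sprintf("validation error: unknown allergen label(s) in ige table: %s",
                   paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    }
    if (any(!is.finite(g$value) | g$value < 0)) {
      bad_id <- g$id[which(!is.finite(g$value) | g$value < 0)[1]]
      stop(sprintf("validation error: negative or missing IgE value for patient %s",
                   bad_id), call. = FALSE)
    }
    if (any(!is.finite(g$total_ige) | g$total_ige <= 0)) {
      bad_id <- g$id[which(!is.finite(g$total_ige) | g$total_ige <= 0)[1]]
      stop(sprintf("validation error: total_ige must be > 0 for patient %s",
                   bad_id), call. = FALSE)
    }
    tot_per_id <- tapply(g$total_ige, g$id, function(v) length(unique(v)))
    if (any(tot_per_id > 1L)) {
      stop(sprintf("validation error: inconsistent total_ige for patient %s",
                   names(tot_per_id)[which(tot_per_id > 1L)[1]]), call. = FALSE)
    }
    orphan <- setdiff(unique(g$id), p$id)
    if (length(orphan) > 0L) {
      stop(sprintf("validation error: ige rows for unknown patient id %s",
                   sQuote(orphan[1])), call. = FALSE)
    }
  }

  v <- x$vas
  if (nrow(v) > 0L) {
    if (any(!v$timepoint %in% timepoint_levels())) {
      stop("validation error: vas timepoint must be one of T0/T12/T24",
           call. = FALSE)
    }
    bad <- !is.finite(v$score) | v$score < 0 | v$score > 100
    if (any(bad)) {
      stop(sprintf("validation error: VAS score outside [0,100] for patient %s",
                   v$id[which(bad)[1]]), call. = FALSE)
    }
    key <- paste(v$id, v$timepoint, v$item)
    if (anyDuplicated(key)) {
      dup <- v$id[which(duplicated(key))[1]]
      stop(sprintf("validation error: duplicated VAS item at a timepoint for patient %s",
                   dup), call. = FALSE)
    }
    orphan <- setdiff(unique(v$id), p$id)
    if (length(orphan) > 0L) {
      stop(sprintf("validation error: vas rows for unknown patient id %s",
                   sQuote(orphan[1])), call. = FALSE)
    }
  }
  invisible(x)
}

#' Read and write SLIT cohorts as CSV tables
#'
#' A cohort lives in a directory of four CSV files (`patients.csv`,
#' `spt.csv`, `ige.csv`, `vas.csv`), comma-separated, UTF-8, header row
#' mandatory, decimal point. Numeric fields are serialized at full double
#' precision so `read_cohort(write_cohort(x))` reproduces `x` bit-exactly.
#' Any schema or invariant violation aborts the read with an informative
#' error; nothing is silently coerced.
#'
#' @param path Directory containing (or to receive) the four CSV files.
#' @param cohort A [slit_cohort()].
#' @return `read_cohort()` returns a validated `slit_cohort`;
#'   `write_cohort()` invisibly returns `path`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' co <- generate_cohort(cohort_config(n_patients = 3, seed = 1))
#' write_cohort(co, dir)
#' co2 <- read_cohort(dir)
#' identical(co$patients$id, co2$patients$id)
#' @export
read_cohort <- function(path) {
  files <- file.path(path, paste0(names(cohort_schema()), ".csv"))
  names(files) <- names(cohort_schema())
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    stop(sprintf("cannot read cohort: missing file(s) %s",
                 paste(sQuote(basename(missing)), collapse = ", ")),
         call. = FALSE)
  }
  tabs <- lapply(files, function(f) {
    read.csv(f, stringsAsFactors = FALSE, colClasses = NA)
  })
  # enforce declared types column-by-column before validation
  for (tab in names(tabs)) {
    tabs[[tab]]$id <- as.character(tabs[[tab]]$id)
  }
  slit_cohort(tabs$patients, tabs$spt, tabs$ige, tabs$vas)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "slit_cohort"))
  validate_cohort(cohort)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory %s", sQuote(path)),
                  call. = FALSE)
  }
  for (tab in names(cohort_schema())) {
    df <- cohort[[tab]]
    out <- df
    for (col in names(out)) {
      if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
        # %.17g round-trips doubles exactly through decimal text
        out[[col]] <- ifelse(is.na(df[[col]]), NA,
                             sprintf("%.17g", df[[col]]))
      }
    }
    write.csv(out, file.path(path, paste0(tab, ".csv")),
              row.names = FALSE, quote = TRUE, na = "NA")
  }
  invisible(path)
}

#' Extract one patient's cross-linked record
#'
#' Pulls a single subject out of a cohort as a self-contained list used by
#' the per-patient operations ([screen_eligibility()],
#' [identify_dominant_allergens()], [compute_pris()]).
#'
#' @param cohort A [slit_cohort()].
#' @param id Patient identifier.
#' @return A list with elements `id`, `profile` (age, diseases vector,
#'   onset, exposure count, ACT, polyposis, dropout), `spt` (data frame),
#'   `ige` (list: `total`, named `specific` vector over sources, named
#'   `component` vector), and `vas` (list of named item-score vectors,
#'   one per timepoint present).
#' @export
patient_record <- function(cohort, id) {
  stopifnot(inherits(cohort, "slit_cohort"))
  p <- cohort$patients[cohort$patients$id == id, , drop = FALSE]
  if (nrow(p) != 1L) {
    stop(sprintf("unknown patient id %s", sQuote(id)), call. = FALSE)
  }
  g <- cohort$ige[cohort$ige$id == id, , drop = FALSE]
  src <- g$allergen_or_component %in% allergen_sources()
  specific <- setNames(g$value[src], g$allergen_or_component[src])
  component <- setNames(g$value[!src], g$allergen_or_component[!src])
  vrows <- cohort$vas[cohort$vas$id == id, , drop = FALSE]
  vas <- lapply(split(vrows, factor(vrows$timepoint, timepoint_levels())),
                function(d) setNames(d$score, d$item))
  vas <- Filter(function(v) length(v) > 0L, vas)
  list(
    id = id,
    profile = list(
      age_years = p$age_years,
      diseases = strsplit(as.character(p$diseases), ";", fixed = TRUE)[[1]],
      onset_years = p$onset_years,
      n_symptom_triggering_allergens = p$n_symptom_triggering_allergens,
      act_score = p$act_score,
      nasal_polyposis = isTRUE(as.logical(p$nasal_polyposis)),
      dropped_out = isTRUE(as.logical(p$dropped_out))
    ),
    spt = cohort$spt[cohort$spt$id == id, , drop = FALSE],
    ige = list(
      total = if (nrow(g) > 0L) g$total_ige[1] else NA_real_,
      specific = specific,
      component = component
    ),
    vas = vas
  )
}
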