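#' Default taxonomy-to-specialty mapping
#'
#' A compact stand-in for the full NUCC provider-taxonomy code set, mapping
#' roughly twenty taxonomy codes to the four analytic specialty groups:
#' `pcp` (internal medicine, family/general practice, nurse practitioners),
#' `psychiatrist` (MD mental-health specialties), `psychologist` (PhD-level),
#' and `bh_specialist` (masters-level counselors, social workers, therapists).
#' Users with access to the full taxonomy can supply their own two-column
#' table.
#'
#' @param path optional path to a replacement CSV with columns
#'   `taxonomy_code`, `specialty_group`.
#' @return a tibble with columns `taxonomy_code`, `specialty_group`.
#' @export
default_taxonomy_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "taxonomy_groups.csv",
                                package = "psnet", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Default behavioral-health diagnosis hierarchy
#'
#' Six mutually exclusive diagnosis categories assigned hierarchically:
#' schizophrenia/other psychotic disorders, bipolar disorders,
#' depression/other mood disorders, anxiety/stress-related disorders, other
#' mental disorders, and substance use disorders. A patient is placed in the
#' highest-ranked category matched by any of their diagnosis codes. The
#' shipped mapping keys on ICD-10 three-character prefixes (a compact stand-in
#' for the full CCSR crosswalk) and is user-replaceable.
#'
#' @param path optional path to a replacement CSV with columns
#'   `category_rank`, `category_name`, `icd10_prefix` (prefix or range such
#'   as `"F20-F29"`).
#' @return an object of class `diagnosis_hierarchy`: a tibble with one row
#'   per expanded prefix, ordered by rank, with an `exclusions` attribute
#'   (prefixes never counted as qualifying behavioral-health diagnoses:
#'   nicotine dependence F17, neonatal abstinence P96.1, fetal alcohol Q86.0).
#' @export
default_diagnosis_hierarchy <- function(path = NULL) {
  path <- path %||% system.file("extdata", "diagnosis_hierarchy.csv",
                                package = "psnet", mustWork = TRUE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    category_rank = "i", category_name = "c", icd10_prefix = "c"
  ), progress = FALSE)
  hier <- raw |>
    dplyr::rowwise() |>
    dplyr::reframe(
      category_rank = .data$category_rank,
      category_name = .data$category_name,
      icd10_prefix = expand_icd_prefixes(.data$icd10_prefix)
    ) |>
    dplyr::arrange(.data$category_rank, .data$icd10_prefix)
  # hierarchical assignment: a prefix claimed by a higher rank never recurs
  hier <- hier |> dplyr::distinct(.data$icd10_prefix, .keep_all = TRUE)
  attr(hier, "exclusions") <- c("F17", "P96.1", "Q86.0")
  class(hier) <- c("diagnosis_hierarchy", class(hier))
  hier
}

#' Cohort configuration
#'
#' Bundles the cohort, visit and study-window rules: adults at least
#' `min_age` at the start of a year and under `max_age_exclusive` at its end,
#' qualifying behavioral-health diagnosis codes, eligible provider specialty
#' groups, and the outpatient procedure-code value set (Evaluation and
#' Management range 99201-99499 by default).
#'
#' @param study_years calendar years covered by the claims window.
#' @param min_age minimum age (years) at the start of a qualifying year.
#' @param max_age_exclusive exclusive maximum age at the end of a qualifying
#'   year.
#' @param eligible_specialties specialty groups whose claims qualify a
#'   patient for the cohort and whose providers enter the network.
#' @param outpatient_code_set character vector of procedure codes and/or
#'   numeric ranges defining an outpatient visit.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(study_years = c(2016L, 2017L),
                          min_age = 18L,
                          max_age_exclusive = 65L,
                          eligible_specialties = c("pcp", "psychiatrist",
                                                   "psychologist",
                                                   "bh_specialist"),
                          outpatient_code_set = "99201-99499") {
  stopifnot(min_age < max_age_exclusive, length(outpatient_code_set) > 0)
  structure(
    list(study_years = sort(as.integer(study_years)),
         min_age = as.integer(min_age),
         max_age_exclusive = as.integer(max_age_exclusive),
         eligible_specialties = eligible_specialties,
         outpatient_code_set = outpatient_code_set),
    class = "cohort_config"
  )
}

#' Classify providers into specialty groups
#'
#' Maps provider taxonomy codes to the four analytic specialty groups; codes
#' absent from the mapping (including empty strings) fall into `"other"` and
#' are excluded from the analytic network downstream.
#'
#' @param taxonomy_code character vector of taxonomy codes.
#' @param mapping a mapping table as returned by [default_taxonomy_map()].
#' @return character vector of specialty groups, same length as input.
#' @export
#' @examples
#' classify_provider(c("2084P0800X", "207R00000X", ""))
classify_provider <- function(taxonomy_code, mapping = default_taxonomy_map()) {
  idx <- match(taxonomy_code, mapping$taxonomy_code)
  out <- mapping$specialty_group[idx]
  out[is.na(out)] <- "other"
  out
}

# Long diagnosis table from wide dx columns: one row per (claim row, code).
claims_diagnoses <- function(claims) {
  dx_cols <- grep("^dx[0-9]+$", names(claims), value = TRUE)
  if (length(dx_cols) == 0) {
    return(tibble::tibble(.claim = integer(), patient_id = character(),
                          year = integer(), code = character()))
  }
  claims |>
    dplyr::mutate(.claim = dplyr::row_number(),
                  year = as.integer(format(.data$service_date, "%Y"))) |>
    dplyr::select(".claim", "patient_id", "year",
                  dplyr::all_of(dx_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(dx_cols), names_to = NULL,
                        values_to = "code") |>
    dplyr::filter(!is.na(.data$code), nzchar(.data$code))
}

# Rank of the hierarchy category matched by each code; NA when no match,
# excluded codes never match. Malformed codes are dropped with one warning.
match_hierarchy_rank <- function(codes, hierarchy) {
  codes <- toupper(codes)
  ok <- grepl("^[A-Z][0-9]{2}", codes)
  if (any(!ok)) {
    warning(sum(!ok), " malformed ICD-10 code(s) skipped",
            call. = FALSE)
  }
  rank <- rep(NA_integer_, length(codes))
  excl <- attr(hierarchy, "exclusions", exact = TRUE) %||% character()
  excluded <- rep(FALSE, length(codes))
  for (e in excl) excluded <- excluded | startsWith(codes, e)
  use <- ok & !excluded
  pref <- substr(codes, 1, 3)
  idx <- match(pref, hierarchy$icd10_prefix)
  rank[use] <- hierarchy$category_rank[idx[use]]
  rank
}

#' Classify one patient-year of claims into a diagnosis category
#'
#' All diagnosis positions (principal and secondary) on all claim types are
#' considered; the patient is placed in the highest-ranked (lowest rank
#' number) category matched by any code. Codes in the exclusion set (nicotine
#' dependence, neonatal abstinence, fetal alcohol) never qualify.
#'
#' @param claims claims tibble for a single patient-year (columns
#'   `service_date` and `dx1`, `dx2`, ...).
#' @param hierarchy a [default_diagnosis_hierarchy()] table.
#' @return the matched `category_name`, or `NA_character_` when no qualifying
#'   behavioral-health code is present.
#' @export
classify_patient_diagnosis <- function(claims,
                                       hierarchy = default_diagnosis_hierarchy()) {
  long <- claims_diagnoses(claims)
  if (nrow(long) == 0) return(NA_character_)
  rank <- match_hierarchy_rank(long$code, hierarchy)
  if (all(is.na(rank))) return(NA_character_)
  best <- min(rank, na.rm = TRUE)
  hierarchy$category_name[match(best, hierarchy$category_rank)]
}

#' Classify diagnosis category for every patient-year
#'
#' Vectorized form of [classify_patient_diagnosis()] over a full claims
#' table.
#'
#' @inheritParams classify_patient_diagnosis
#' @return tibble with columns `patient_id`, `year`, `category` (NA rows are
#'   omitted: only qualifying patient-years are returned).
#' @export
classify_diagnoses <- function(claims,
                               hierarchy = default_diagnosis_hierarchy()) {
  long <- claims_diagnoses(claims)
  if (nrow(long) == 0) {
    return(tibble::tibble(patient_id = character(), year = integer(),
                          category = character()))
  }
  long$rank <- match_hierarchy_rank(long$code, hierarchy)
  long |>
    dplyr::filter(!is.na(.data$rank)) |>
    dplyr::group_by(.data$patient_id, .data$year) |>
    dplyr::summarise(rank = min(.data$rank), .groups = "drop") |>
    dplyr::mutate(category = hierarchy$category_name[
      match(.data$rank, hierarchy$category_rank)]) |>
    dplyr::select("patient_id", "year", "category")
}

#' Derive the insurance-coverage category over the study window
#'
#' Categorizes each patient from the set of payers observed on all of their
#' claims over the full window: `dual` when both medicaid and medicare
#' appear, `commercial_plus_public` when commercial appears together with any
#' public payer, otherwise the single observed class (covering both
#' simultaneous and sequential coverage).
#'
#' @param claims claims tibble with columns `patient_id`, `payer`.
#' @return tibble `patient_id`, `insurance_category`.
#' @export
derive_insurance_category <- function(claims) {
  claims |>
    dplyr::distinct(.data$patient_id, .data$payer) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      has_mcd = any(.data$payer == "medicaid"),
      has_mcr = any(.data$payer == "medicare"),
      has_com = any(.data$payer == "commercial"),
      .groups = "drop"
    ) |>
    dplyr::mutate(insurance_category = dplyr::case_when(
      .data$has_com & (.data$has_mcd | .data$has_mcr) ~ "commercial_plus_public",
      .data$has_mcd & .data$has_mcr ~ "dual",
      .data$has_mcd ~ "medicaid_only",
      .data$has_mcr ~ "medicare_only",
      .data$has_com ~ "commercial_only",
      TRUE ~ NA_character_
    )) |>
    dplyr::select("patient_id", "insurance_category")
}

#' Apply the cohort inclusion filters
#'
#' Retains patients who, in at least one study year, simultaneously (i) meet
#' the age bounds, (ii) carry at least one qualifying behavioral-health
#' diagnosis, and (iii) have at least one claim with an individual provider
#' of an eligible specialty group. Ages are computed from birth year:
#' `year - birth_year >= min_age` at the start of the year and
#' `year - birth_year < max_age_exclusive` at its end. Patients with missing
#' birth year are excluded and counted separately.
#'
#' @param claims claims tibble.
#' @param patients patients tibble (`patient_id`, `birth_year`, ...).
#' @param providers providers tibble (`provider_id`, `specialty_group`).
#' @param config a [cohort_config()].
#' @param hierarchy diagnosis hierarchy used for criterion (ii).
#' @return list with elements `claims` (all claims of retained patients),
#'   `patients` (retained patient rows, with `diagnosis_category` from the
#'   highest qualifying year assignment), and `audit` (a tibble of per-filter
#'   counts).
#' @export
apply_cohort_filters <- function(claims, patients, providers,
                                 config = cohort_config(),
                                 hierarchy = default_diagnosis_hierarchy()) {
  years <- config$study_years

  missing_by <- patients$patient_id[is.na(patients$birth_year)]

  # criterion grid: one row per patient x study year
  grid <- tidyr::expand_grid(
    patient_id = setdiff(patients$patient_id, missing_by),
    year = years
  ) |>
    dplyr::left_join(
      dplyr::select(patients, "patient_id", "birth_year"),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      age = .data$year - .data$birth_year,
      age_ok = .data$age >= config$min_age &
        .data$age < config$max_age_exclusive
    )

  dx <- classify_diagnoses(claims, hierarchy) |>
    dplyr::mutate(dx_ok = TRUE)

  eligible_providers <- providers$provider_id[
    providers$specialty_group %in% config$eligible_specialties]
  prov_years <- claims |>
    dplyr::filter(nzchar(.data$provider_id),
                  .data$provider_id %in% eligible_providers) |>
    dplyr::mutate(year = as.integer(format(.data$service_date, "%Y"))) |>
    dplyr::distinct(.data$patient_id, .data$year) |>
    dplyr::mutate(prov_ok = TRUE)

  grid <- grid |>
    dplyr::left_join(dx, by = c("patient_id", "year")) |>
    dplyr::left_join(prov_years, by = c("patient_id", "year")) |>
    dplyr::mutate(dx_ok = !is.na(.data$dx_ok),
                  prov_ok = !is.na(.data$prov_ok),
                  all_ok = .data$age_ok & .data$dx_ok & .data$prov_ok)

  per_patient <- grid |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      any_age = any(.data$age_ok),
      any_dx = any(.data$dx_ok),
      any_prov = any(.data$prov_ok),
      keep = any(.data$all_ok),
      .groups = "drop"
    )

  kept_ids <- per_patient$patient_id[per_patient$keep]

  # diagnosis category reported from qualifying years (earliest qualifying
  # year's hierarchical assignment; re-resolved hierarchically across years)
  kept_dx <- dx |>
    dplyr::semi_join(
      dplyr::filter(grid, .data$all_ok),
      by = c("patient_id", "year")
    ) |>
    dplyr::mutate(rank = match(
      .data$category,
      hierarchy$category_name[!duplicated(hierarchy$category_name)])) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", diagnosis_category = "category")

  out_patients <- patients |>
    dplyr::filter(.data$patient_id %in% kept_ids) |>
    dplyr::left_join(kept_dx, by = "patient_id")

  audit <- tibble::tibble(
    criterion = c("input_patients", "missing_birth_year",
                  "fails_age_all_years", "fails_diagnosis_all_years",
                  "fails_provider_type_all_years", "retained"),
    n = c(nrow(patients), length(missing_by),
          sum(!per_patient$any_age), sum(!per_patient$any_dx),
          sum(!per_patient$any_prov), length(kept_ids))
  )

  list(
    claims = dplyr::filter(claims, .data$patient_id %in% kept_ids),
    patients = out_patients,
    audit = audit
  )
}

#' Identify deduplicated outpatient visits
#'
#' An outpatient visit is a claim of outpatient type whose procedure code
#' falls in the configured outpatient value set and that names an individual
#' provider. At most one visit per day is counted for each patient-provider
#' combination.
#'
#' @param claims claims tibble.
#' @param config a [cohort_config()] supplying `outpatient_code_set`.
#' @return tibble of visit records: `patient_id`, `provider_id`,
#'   `service_date`, `year`.
#' @export
identify_outpatient_visits <- function(claims, config = cohort_config()) {
  matcher <- procedure_code_matcher(config$outpatient_code_set)
  claims |>
    dplyr::filter(.data$claim_type == "outpatient",
                  nzchar(.data$provider_id),
                  matcher(.data$procedure_code)) |>
    dplyr::distinct(.data$patient_id, .data$provider_id, .data$service_date) |>
    dplyr::mutate(year = as.integer(format(.data$service_date, "%Y"))) |>
    dplyr::arrange(.data$patient_id, .data$provider_id, .data$service_date)
}
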