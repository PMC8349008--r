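#' Read a claims CSV
#'
#' Expects header columns `patient_id`, `provider_id`, `service_date`
#' (ISO-8601), `claim_type`, `procedure_code`, `payer` and any number of
#' diagnosis columns `dx1`, `dx2`, ... Gzip files are read transparently.
#' Missing provider ids and codes are normalized to empty strings.
#'
#' @param path file path (plain or `.gz`).
#' @return claims tibble.
#' @export
read_claims <- function(path) {
  claims <- readr::read_csv(
    path,
    col_types = readr::cols(service_date = readr::col_date(),
                            .default = readr::col_character()),
    progress = FALSE, na = character()
  )
  required <- c("patient_id", "provider_id", "service_date", "claim_type",
                "procedure_code", "payer")
  missing <- setdiff(required, names(claims))
  if (length(missing) > 0) {
    stop("claims file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(claims$patient_id))) {
    stop("claims file has empty patient_id values", call. = FALSE)
  }
  claims
}

#' Read a patients CSV
#'
#' Columns `patient_id`, `birth_year`, plus any extras (sex, insurance).
#'
#' @param path file path.
#' @return patients tibble.
#' @export
read_patients <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(birth_year = readr::col_integer(),
                            .default = readr::col_character()),
    progress = FALSE
  )
}

#' Read a providers CSV
#'
#' Columns `provider_id`, `taxonomy_code`; `specialty_group` is derived via
#' [classify_provider()] when absent.
#'
#' @param path file path.
#' @param taxonomy_map mapping passed to [classify_provider()].
#' @return providers tibble with `specialty_group`.
#' @export
read_providers <- function(path, taxonomy_map = default_taxonomy_map()) {
  prov <- readr::read_csv(path,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!"specialty_group" %in% names(prov)) {
    prov$specialty_group <- classify_provider(prov$taxonomy_code,
                                              taxonomy_map)
  }
  prov
}
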