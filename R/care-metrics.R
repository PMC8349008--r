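#' Bice-Boxerman continuity of care per patient-year
#'
#' For each patient-year with at least `min_visits` deduplicated outpatient
#' visits, computes
#' \deqn{CoC = (\sum_i n_i^2 - n) / (n (n - 1))}
#' where \eqn{n} is the total visit count, and \eqn{n_i} the number of visits
#' with provider \eqn{i}. CoC is 1 when all visits are with a single provider
#' and 0 when every visit is with a different provider. Patient-years below
#' the visit minimum are returned with `eligible = FALSE` and `coc = NA`
#' (high CoC variability among low utilizers is the standard rationale for
#' the four-visit floor).
#'
#' @param visits visit records from [identify_outpatient_visits()] (already
#'   deduplicated to one visit per patient-provider-day).
#' @param min_visits minimum yearly visits for eligibility (default 4).
#' @return tibble with one row per patient-year: `patient_id`, `year`,
#'   `p` (distinct providers), `n` (total visits), `coc`, `eligible`.
#' @export
patient_coc <- function(visits, min_visits = 4L) {
  visits |>
    dplyr::count(.data$patient_id, .data$year, .data$provider_id,
                 name = "n_i") |>
    dplyr::group_by(.data$patient_id, .data$year) |>
    dplyr::summarise(
      p = dplyr::n(),
      n = sum(.data$n_i),
      coc = if (sum(.data$n_i) >= 2) {
        (sum(.data$n_i^2) - sum(.data$n_i)) /
          (sum(.data$n_i) * (sum(.data$n_i) - 1))
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(eligible = .data$n >= min_visits,
                  coc = ifelse(.data$eligible, .data$coc, NA_real_))
}

#' Provider-level mean continuity of care
#'
#' Averages the CoC of the eligible patient-years in which a provider
#' appears (at least one visit with the patient that year); each patient-year
#' contributes once, unweighted, pooled across study years. Providers seen
#' only by ineligible (< 4-visit) patient-years get `NA`.
#'
#' @param visits visit records.
#' @param coc_records output of [patient_coc()].
#' @return tibble `provider_id`, `mean_coc`, `n_patient_years`.
#' @export
provider_mean_coc <- function(visits, coc_records) {
  eligible <- dplyr::filter(coc_records, .data$eligible)
  visits |>
    dplyr::distinct(.data$patient_id, .data$year, .data$provider_id) |>
    dplyr::inner_join(eligible, by = c("patient_id", "year")) |>
    dplyr::group_by(.data$provider_id) |>
    dplyr::summarise(mean_coc = mean(.data$coc),
                     n_patient_years = dplyr::n(), .groups = "drop")
}

#' Alter mean continuity of care
#'
#' For each provider, the unweighted mean of the provider-level `mean_coc`
#' of their direct network neighbors ("alters"), skipping neighbors with
#' missing values; `NA` when no usable neighbor exists (including isolated
#' vertices).
#'
#' @param graph provider graph.
#' @param profiles tibble with `provider_id` and `mean_coc`.
#' @return tibble `provider_id`, `alter_mean_coc`.
#' @export
alter_mean_coc <- function(graph, profiles) {
  vn <- igraph::V(graph)$name
  mc <- profiles$mean_coc[match(vn, profiles$provider_id)]
  adj <- igraph::as_adj_list(graph, mode = "all")
  alter <- vapply(seq_along(vn), function(i) {
    vals <- mc[as.integer(adj[[i]])]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))
  tibble::tibble(provider_id = vn, alter_mean_coc = alter)
}

#' Local transitivity (clustering coefficient) per provider
#'
#' The fraction of a provider's neighbor pairs that are themselves
#' connected: edges among neighbors divided by \eqn{k(k-1)/2} for degree
#' \eqn{k \ge 2}; undefined (`NA`) below degree 2.
#'
#' @param graph provider graph.
#' @return tibble `provider_id`, `degree`, `transitivity`.
#' @export
local_transitivity <- function(graph) {
  vn <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  tr <- unname(suppressWarnings(
    igraph::transitivity(graph, type = "local", isolates = "NaN")))
  tr[deg < 2] <- NA_real_
  tr[is.nan(tr)] <- NA_real_
  tibble::tibble(provider_id = vn, degree = as.integer(deg),
                 transitivity = tr)
}

#' Assemble per-provider structural profiles
#'
#' One row per provider in the analytic network carrying all quantities used
#' by the summary tables and the mixed model: degree, degree to PCPs, degree
#' to PCPs in the same community and sub-community, local transitivity,
#' distinct patient counts (total, with any PCP claim, with a PCP claim in
#' the provider's own community), provider mean CoC and alter mean CoC, and
#' the hierarchical community labels.
#'
#' @param graph provider graph (largest component).
#' @param assignments hierarchical labels from [nested_subcommunities()]
#'   (`provider_id`, `community`, `subcommunity`).
#' @param claims cohort claims (for patient attribution; all claim types
#'   naming an individual provider, mirroring network construction).
#' @param visits visit records (for CoC).
#' @param coc_records output of [patient_coc()].
#' @return tibble of class rows described above, one per vertex of `graph`.
#' @export
structural_profile <- function(graph, assignments, claims, visits,
                               coc_records) {
  nodes <- graph_tables(graph)$nodes |>
    dplyr::left_join(assignments, by = "provider_id")

  deg_tr <- local_transitivity(graph)

  # neighbor tables for specialty- and community-specific degree
  el <- igraph::as_data_frame(graph, what = "edges")
  nbr <- dplyr::bind_rows(
    tibble::tibble(provider_id = el$from, neighbor = el$to),
    tibble::tibble(provider_id = el$to, neighbor = el$from)
  ) |>
    dplyr::left_join(
      dplyr::select(nodes, neighbor = "provider_id",
                    neighbor_specialty = "specialty_group",
                    neighbor_community = "community",
                    neighbor_subcommunity = "subcommunity"),
      by = "neighbor"
    ) |>
    dplyr::left_join(
      dplyr::select(nodes, "provider_id", "community", "subcommunity"),
      by = "provider_id"
    )

  deg_pcp <- nbr |>
    dplyr::group_by(.data$provider_id) |>
    dplyr::summarise(
      degree_to_pcp = sum(.data$neighbor_specialty == "pcp"),
      degree_to_pcp_same_community = sum(
        .data$neighbor_specialty == "pcp" &
          !is.na(.data$community) &
          .data$neighbor_community == .data$community),
      degree_to_pcp_same_subcommunity = sum(
        .data$neighbor_specialty == "pcp" &
          !is.na(.data$subcommunity) &
          !is.na(.data$neighbor_subcommunity) &
          .data$neighbor_subcommunity == .data$subcommunity),
      .groups = "drop"
    )

  # patient attribution from all claims naming an individual provider
  pp <- claims |>
    dplyr::filter(nzchar(.data$provider_id),
                  .data$provider_id %in% nodes$provider_id) |>
    dplyr::distinct(.data$patient_id, .data$provider_id)

  pcp_ids <- nodes$provider_id[nodes$specialty_group == "pcp"]
  pcp_patients <- pp |>
    dplyr::filter(.data$provider_id %in% pcp_ids) |>
    dplyr::left_join(dplyr::select(nodes, "provider_id",
                                   pcp_community = "community"),
                     by = "provider_id") |>
    dplyr::distinct(.data$patient_id, .data$pcp_community)

  n_pat <- pp |>
    dplyr::group_by(.data$provider_id) |>
    dplyr::summarise(n_patients = dplyr::n_distinct(.data$patient_id),
                     .groups = "drop")

  with_pcp <- pp |>
    dplyr::semi_join(dplyr::distinct(pcp_patients, .data$patient_id),
                     by = "patient_id") |>
    dplyr::count(.data$provider_id, name = "n_patients_with_pcp")

  with_pcp_same <- pp |>
    dplyr::left_join(dplyr::select(nodes, "provider_id", "community"),
                     by = "provider_id") |>
    dplyr::inner_join(pcp_patients,
                      by = "patient_id", relationship = "many-to-many") |>
    dplyr::filter(!is.na(.data$community),
                  .data$pcp_community == .data$community) |>
    dplyr::distinct(.data$provider_id, .data$patient_id) |>
    dplyr::count(.data$provider_id,
                 name = "n_patients_with_pcp_same_community")

  mean_coc <- provider_mean_coc(visits, coc_records)

  profiles <- nodes |>
    dplyr::left_join(deg_tr, by = "provider_id") |>
    dplyr::left_join(deg_pcp, by = "provider_id") |>
    dplyr::left_join(n_pat, by = "provider_id") |>
    dplyr::left_join(with_pcp, by = "provider_id") |>
    dplyr::left_join(with_pcp_same, by = "provider_id") |>
    dplyr::left_join(mean_coc, by = "provider_id") |>
    dplyr::mutate(dplyr::across(
      c("degree_to_pcp", "degree_to_pcp_same_community",
        "degree_to_pcp_same_subcommunity", "n_patients",
        "n_patients_with_pcp", "n_patients_with_pcp_same_community"),
      ~ tidyr::replace_na(.x, 0L)))

  profiles |>
    dplyr::left_join(alter_mean_coc(graph, profiles), by = "provider_id") |>
    dplyr::arrange(.data$provider_id)
}

#' Network-level five-number summaries of provider characteristics
#'
#' Minimum, median, mean and maximum over providers for each structural
#' metric (degree, transitivity, PCP degree, patient counts, CoC).
#'
#' @param profiles output of [structural_profile()].
#' @return tibble `variable`, `minimum`, `median`, `mean`, `maximum`, `n`.
#' @export
network_summary <- function(profiles) {
  vars <- c(degree = "degree",
            transitivity = "transitivity",
            degree_to_pcp = "degree_to_pcp",
            degree_to_pcp_same_community = "degree_to_pcp_same_community",
            n_patients = "n_patients",
            n_patients_with_pcp = "n_patients_with_pcp",
            n_patients_with_pcp_same_community =
              "n_patients_with_pcp_same_community",
            mean_coc = "mean_coc")
  purrr::map_dfr(vars, function(v) {
    x <- profiles[[v]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble::tibble(minimum = NA_real_, median = NA_real_,
                            mean = NA_real_, maximum = NA_real_, n = 0L))
    }
    tibble::tibble(minimum = min(x), median = median(x),
                   mean = mean(x), maximum = max(x),
                   n = length(x))
  }, .id = "variable")
}

#' Summarize retained sub-communities
#'
#' One row per retained sub-community: size, mean degree, mean PCP degree,
#' the mean per-provider proportion of PCP connections that stay inside the
#' provider's own sub-community (providers with no PCP connections
#' contribute nothing), mean local transitivity, mean provider CoC, and the
#' specialty composition proportions.
#'
#' @param profiles output of [structural_profile()].
#' @return tibble with one row per sub-community, ordered by community then
#'   sub-community label.
#' @export
subcommunity_summary <- function(profiles) {
  rows <- profiles |>
    dplyr::filter(!is.na(.data$subcommunity))
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      community = character(), subcommunity = character(),
      size = integer(), mean_connections = numeric(),
      mean_pcp_connections = numeric(),
      pct_pcp_within_subcommunity = numeric(),
      mean_transitivity = numeric(), mean_coc = numeric(),
      prop_pcp = numeric(), prop_psychiatrist = numeric(),
      prop_psychologist = numeric(), prop_bh_specialist = numeric()))
  }
  rows |>
    dplyr::group_by(.data$community, .data$subcommunity) |>
    dplyr::summarise(
      size = dplyr::n(),
      mean_connections = mean(.data$degree),
      mean_pcp_connections = mean(.data$degree_to_pcp),
      pct_pcp_within_subcommunity = 100 * mean(
        (.data$degree_to_pcp_same_subcommunity /
           .data$degree_to_pcp)[.data$degree_to_pcp > 0]),
      mean_transitivity = mean(.data$transitivity, na.rm = TRUE),
      mean_coc = mean(.data$mean_coc, na.rm = TRUE),
      prop_pcp = mean(.data$specialty_group == "pcp"),
      prop_psychiatrist = mean(.data$specialty_group == "psychiatrist"),
      prop_psychologist = mean(.data$specialty_group == "psychologist"),
      prop_bh_specialist = mean(.data$specialty_group == "bh_specialist"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$community, .data$subcommunity)
}

#' Per-community ranges of sub-community characteristics
#'
#' Min-max ranges of the sub-community summary within each community,
#' in the shape used to compare communities.
#'
#' @param summary output of [subcommunity_summary()].
#' @param community_modularity optional `community_modularity` tibble from
#'   [nested_subcommunities()] to append the across-sub-community
#'   modularity.
#' @return tibble with one row per community.
#' @export
community_ranges <- function(summary, community_modularity = NULL) {
  out <- summary |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(
      n_subcommunities = dplyr::n(),
      size_min = min(.data$size), size_max = max(.data$size),
      connections_min = min(.data$mean_connections),
      connections_max = max(.data$mean_connections),
      pcp_connections_min = min(.data$mean_pcp_connections),
      pcp_connections_max = max(.data$mean_pcp_connections),
      pct_pcp_within_min = min(.data$pct_pcp_within_subcommunity),
      pct_pcp_within_max = max(.data$pct_pcp_within_subcommunity),
      transitivity_min = min(.data$mean_transitivity),
      transitivity_max = max(.data$mean_transitivity),
      coc_min = min(.data$mean_coc), coc_max = max(.data$mean_coc),
      .groups = "drop"
    )
  if (!is.null(community_modularity)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(community_modularity, "community",
                    "modularity_subcommunities"),
      by = "community")
  }
  out
}
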