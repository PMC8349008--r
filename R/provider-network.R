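#' Count distinct shared patients for every provider pair
#'
#' Two providers "share" a patient when the patient has at least one
#' qualifying claim with each of them anywhere in the study window. By
#' default all claim types naming an individual provider contribute
#' (`edge_source = "all_claims"`); `"outpatient_visits"` restricts the
#' projection to deduplicated outpatient visits.
#'
#' @param claims claims tibble (already filtered to the cohort).
#' @param providers tibble of eligible providers (`provider_id`,
#'   `specialty_group`); rows with specialty `"other"` are dropped.
#' @param edge_source `"all_claims"` or `"outpatient_visits"`.
#' @param config [cohort_config()], used only for the outpatient value set
#'   when `edge_source = "outpatient_visits"`.
#' @return tibble `provider_a`, `provider_b`, `shared_patients` with
#'   `provider_a < provider_b`; only pairs with at least one shared patient
#'   appear.
#' @export
count_shared_patients <- function(claims, providers,
                                  edge_source = c("all_claims",
                                                  "outpatient_visits"),
                                  config = cohort_config()) {
  edge_source <- match.arg(edge_source)
  eligible <- providers$provider_id[providers$specialty_group != "other"]

  links <- if (edge_source == "outpatient_visits") {
    identify_outpatient_visits(claims, config)
  } else {
    dplyr::filter(claims, nzchar(.data$provider_id))
  }

  pp <- links |>
    dplyr::filter(.data$provider_id %in% eligible) |>
    dplyr::distinct(.data$patient_id, .data$provider_id)

  pairs <- dplyr::inner_join(
    pp, pp,
    by = "patient_id", relationship = "many-to-many",
    suffix = c("_a", "_b")
  ) |>
    dplyr::filter(.data$provider_id_a < .data$provider_id_b)

  pairs |>
    dplyr::count(provider_a = .data$provider_id_a,
                 provider_b = .data$provider_id_b,
                 name = "shared_patients") |>
    dplyr::arrange(.data$provider_a, .data$provider_b)
}

#' Build the thresholded provider graph
#'
#' Creates an undirected, unweighted graph whose vertices are the eligible
#' providers and whose edges link pairs sharing at least `min_shared`
#' patients. Shared-patient counts are retained as edge metadata only;
#' community detection and all structural metrics operate on the unweighted
#' graph. Isolated vertices are retained at this stage.
#'
#' @param counts output of [count_shared_patients()].
#' @param providers tibble with `provider_id` and `specialty_group`
#'   (specialty `"other"` rows are dropped).
#' @param min_shared minimum number of distinct shared patients for an edge
#'   (default 3).
#' @return an `igraph` object with vertex attribute `specialty_group`, edge
#'   attribute `shared_patients`, and graph attribute `min_shared`.
#' @export
threshold_graph <- function(counts, providers, min_shared = 3L) {
  stopifnot(min_shared >= 1)
  nodes <- providers |>
    dplyr::filter(.data$specialty_group != "other") |>
    dplyr::distinct(.data$provider_id, .data$specialty_group) |>
    dplyr::arrange(.data$provider_id)
  edges <- counts |>
    dplyr::filter(.data$shared_patients >= min_shared)
  g <- igraph::graph_from_data_frame(
    d = edges, directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  g <- igraph::set_graph_attr(g, "min_shared", as.integer(min_shared))
  g
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest set of mutually reachable
#' providers. Ties in component size are broken in favor of the component
#' containing the lexicographically smallest provider id. The retained
#' fraction of providers (and, when `claims` is supplied, of patients with at
#' least one claim with a retained provider) is attached as graph attributes.
#'
#' @param graph a provider graph from [threshold_graph()].
#' @param claims optional claims tibble for patient-retention reporting.
#' @return the largest-component `igraph`, with graph attributes
#'   `retained_providers`, `provider_fraction` and (if `claims` given)
#'   `patient_fraction`.
#' @export
largest_component <- function(graph, claims = NULL) {
  if (igraph::vcount(graph) == 0) {
    warning("empty graph: largest component is empty", call. = FALSE)
    return(graph)
  }
  comp <- igraph::components(graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie: component holding the smallest provider id
    first_member <- vapply(best, function(ci) {
      min(igraph::V(graph)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(first_member)[1]]
  }
  keep <- igraph::V(graph)[comp$membership == best]
  lcc <- igraph::induced_subgraph(graph, keep)
  lcc <- igraph::set_graph_attr(lcc, "retained_providers",
                                igraph::vcount(lcc))
  lcc <- igraph::set_graph_attr(lcc, "provider_fraction",
                                igraph::vcount(lcc) / igraph::vcount(graph))
  if (!is.null(claims)) {
    pts_all <- unique(claims$patient_id)
    in_lcc <- claims |>
      dplyr::filter(.data$provider_id %in% igraph::V(lcc)$name) |>
      dplyr::distinct(.data$patient_id)
    lcc <- igraph::set_graph_attr(lcc, "patient_fraction",
                                  nrow(in_lcc) / length(pts_all))
  }
  lcc
}

#' Tidy a provider graph into node and edge tables
#'
#' @param graph an `igraph` provider graph.
#' @return list of tibbles `nodes` (`provider_id`, `specialty_group`) and
#'   `edges` (`provider_a`, `provider_b`, `shared_patients`).
#' @export
graph_tables <- function(graph) {
  nodes <- tibble::tibble(
    provider_id = igraph::V(graph)$name,
    specialty_group = igraph::V(graph)$specialty_group
  )
  el <- igraph::as_data_frame(graph, what = "edges")
  edges <- tibble::tibble(
    provider_a = pmin(el$from, el$to),
    provider_b = pmax(el$from, el$to),
    shared_patients = el$shared_patients %||% rep(NA_integer_, nrow(el))
  ) |> dplyr::arrange(.data$provider_a, .data$provider_b)
  list(nodes = nodes, edges = edges)
}
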