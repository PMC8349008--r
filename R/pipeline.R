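#' Pipeline configuration
#'
#' All analysis settings in one place; every default equals the published
#' analysis settings (threshold of 3 shared patients, 10-provider minimum
#' community size, 4-visit continuity floor, 18/65 age bounds, community
#' grouping for the random intercept).
#'
#' @param cohort a [cohort_config()].
#' @param min_shared shared-patient threshold for a network edge.
#' @param edge_source `"all_claims"` or `"outpatient_visits"` (what counts
#'   as sharing a patient).
#' @param min_size minimum providers per community / sub-community.
#' @param min_visits minimum yearly visits for CoC eligibility.
#' @param model_group random-intercept grouping, `"community"` or
#'   `"subcommunity"`.
#' @param seed integer seed recorded in outputs (the analysis itself is
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            min_shared = 3L,
                            edge_source = "all_claims",
                            min_size = 10L,
                            min_visits = 4L,
                            model_group = "community",
                            seed = 1L) {
  structure(
    list(cohort = cohort, min_shared = as.integer(min_shared),
         edge_source = edge_source, min_size = as.integer(min_size),
         min_visits = as.integer(min_visits), model_group = model_group,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Cohort summary table
#'
#' Counts and percentages of retained patients by sex, age band at the first
#' study year, hierarchical diagnosis category, and insurance coverage
#' category (the sample-characteristics table of the analysis).
#'
#' @param patients retained patients (from [apply_cohort_filters()]), with
#'   `diagnosis_category`; insurance is derived from `claims` when not
#'   already present.
#' @param claims the retained claims (for insurance derivation).
#' @param config [cohort_config()] (for the first study year).
#' @return tibble `block`, `level`, `n`, `pct`.
#' @export
cohort_summary <- function(patients, claims, config = cohort_config()) {
  y1 <- min(config$study_years)
  if (!"insurance_category" %in% names(patients) ||
      all(is.na(patients$insurance_category))) {
    patients <- patients |>
      dplyr::select(-dplyr::any_of("insurance_category")) |>
      dplyr::left_join(derive_insurance_category(claims), by = "patient_id")
  }
  age <- y1 - patients$birth_year
  band <- cut(age, breaks = c(-Inf, 29, 40, 51, Inf),
              labels = c("17_29", "30_40", "41_51", "52_63"))
  n_total <- nrow(patients)
  one_block <- function(block, x) {
    tibble::tibble(block = block, level = as.character(x)) |>
      dplyr::count(.data$block, .data$level, name = "n") |>
      dplyr::mutate(pct = round(100 * .data$n / n_total, 1))
  }
  dplyr::bind_rows(
    one_block("sex", patients$sex %||% rep("missing", n_total)),
    one_block("age", band),
    one_block("diagnosis", patients$diagnosis_category),
    one_block("insurance", patients$insurance_category)
  )
}

#' Run the full network analysis pipeline
#'
#' Sequences the complete analysis: cohort filters, outpatient-visit
#' identification, shared-patient counting, graph thresholding and largest
#' connected component, hierarchical community detection, continuity of
#' care, provider profiles, sub-community summaries, size correlations, and
#' the two adjusted mixed models. When `out_dir` is given, writes the seven
#' table artifacts as CSV/TSV plus an audit log of every filter count.
#'
#' @param claims,patients,providers input tibbles (e.g. from
#'   [generate_claims()] or the `read_*` functions).
#' @param config a [pipeline_config()].
#' @param hierarchy diagnosis hierarchy.
#' @param out_dir optional output directory for artifacts.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every intermediate and final object:
#'   `cohort`, `cohort_summary`, `visits`, `counts`, `graph`, `lcc`,
#'   `communities`, `nested`, `coc`, `profiles`, `network_summary`,
#'   `subcommunity_summary`, `community_ranges`, `correlations`,
#'   `unadjusted`, `models`, `audit`.
#' @export
run_pipeline <- function(claims, patients, providers,
                         config = pipeline_config(),
                         hierarchy = default_diagnosis_hierarchy(),
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[psnet] ", ...)
  audit <- list()

  say("cohort filters")
  cohort <- apply_cohort_filters(claims, patients, providers,
                                 config$cohort, hierarchy)
  audit$cohort <- cohort$audit
  tab1 <- cohort_summary(cohort$patients, cohort$claims, config$cohort)

  say("outpatient visits")
  visits <- identify_outpatient_visits(cohort$claims, config$cohort)
  audit$visits <- tibble::tibble(
    criterion = c("outpatient_claims_in_codeset", "deduplicated_visits"),
    n = c(nrow(dplyr::filter(
      cohort$claims, .data$claim_type == "outpatient",
      nzchar(.data$provider_id),
      procedure_code_matcher(config$cohort$outpatient_code_set)(
        .data$procedure_code))),
      nrow(visits)))

  say("shared-patient network (threshold ", config$min_shared, ")")
  counts <- count_shared_patients(cohort$claims, providers,
                                  edge_source = config$edge_source,
                                  config = config$cohort)
  graph <- threshold_graph(counts, providers,
                           min_shared = config$min_shared)
  lcc <- largest_component(graph, claims = cohort$claims)
  audit$network <- tibble::tibble(
    criterion = c("eligible_providers", "providers_with_edges",
                  "lcc_providers"),
    n = c(igraph::vcount(graph),
          sum(igraph::degree(graph) > 0),
          igraph::vcount(lcc)))

  if (igraph::ecount(lcc) == 0) {
    warning("no edges survive the threshold; downstream stages skipped",
            call. = FALSE)
    res <- list(cohort = cohort, cohort_summary = tab1, visits = visits,
                counts = counts, graph = graph, lcc = lcc,
                audit = dplyr::bind_rows(audit, .id = "stage"))
    if (!is.null(out_dir)) write_artifacts(res, out_dir, config)
    return(invisible(res))
  }

  say("community detection")
  communities <- fast_greedy_communities(lcc)
  nested <- nested_subcommunities(lcc, communities,
                                  min_size = config$min_size)

  say("continuity of care")
  coc <- patient_coc(visits, min_visits = config$min_visits)
  audit$coc <- tibble::tibble(
    criterion = c("patient_years_with_visits", "patient_years_eligible"),
    n = c(nrow(coc), sum(coc$eligible)))

  say("provider profiles")
  profiles <- structural_profile(lcc, nested$assignments, cohort$claims,
                                 visits, coc)
  tab2 <- network_summary(profiles)
  tab3 <- subcommunity_summary(profiles)
  ranges <- community_ranges(tab3, nested$community_modularity)

  say("associations")
  correlations <- if (nrow(tab3) >= 3) {
    correlate_size_vs_characteristics(tab3)
  } else NULL
  unadj <- unadjusted_association(profiles)
  models <- coc_model_report(profiles, group = config$model_group)
  audit$model <- tibble::tibble(
    criterion = c("providers_in_model1", "providers_dropped_model1",
                  "providers_in_model2", "providers_dropped_model2"),
    n = c(models$model1$n_used, models$model1$n_dropped,
          models$model2$n_used, models$model2$n_dropped))

  res <- list(cohort = cohort, cohort_summary = tab1, visits = visits,
              counts = counts, graph = graph, lcc = lcc,
              communities = communities, nested = nested, coc = coc,
              profiles = profiles, network_summary = tab2,
              subcommunity_summary = tab3, community_ranges = ranges,
              correlations = correlations, unadjusted = unadj,
              models = models,
              audit = dplyr::bind_rows(audit, .id = "stage"))
  if (!is.null(out_dir)) write_artifacts(res, out_dir, config)
  invisible(res)
}

write_artifacts <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name, tsv = FALSE) {
    if (is.null(x)) return(invisible())
    num <- vapply(x, is.double, logical(1))
    x[num] <- lapply(x[num], function(col) round(col, 6))
    if (tsv) readr::write_tsv(x, file.path(out_dir, name))
    else readr::write_csv(x, file.path(out_dir, name))
  }
  w(res$cohort_summary, "cohort_summary.csv")
  if (!is.null(res$lcc)) {
    gt <- graph_tables(res$lcc)
    w(gt$edges, "edge_list.tsv", tsv = TRUE)
    w(gt$nodes, "nodes.csv")
  }
  if (!is.null(res$nested)) {
    w(res$nested$assignments, "partitions.csv")
    mod <- dplyr::bind_rows(
      tibble::tibble(community = "(overall)",
                     n_providers = nrow(res$communities$membership),
                     modularity_subcommunities =
                       res$communities$modularity,
                     n_subcommunities = res$communities$n_communities),
      res$nested$community_modularity)
    w(mod, "modularity_summary.csv")
  }
  w(res$profiles, "provider_profiles.csv")
  w(res$network_summary, "network_summary.csv")
  w(res$subcommunity_summary, "subcommunity_summary.csv")
  w(res$community_ranges, "community_ranges.csv")
  w(res$correlations, "correlations.csv")
  if (!is.null(res$models)) {
    w(res$models$report, "model_report.csv")
    writeLines(c(
      sprintf("model1: sigma_u=%.6g sigma_e=%.6g std_transitivity=%.6g n=%d dropped=%d",
              res$models$model1$sigma_u, res$models$model1$sigma_e,
              res$models$model1$standardized_transitivity,
              res$models$model1$n_used, res$models$model1$n_dropped),
      sprintf("model2: sigma_u=%.6g sigma_e=%.6g std_transitivity=%.6g n=%d dropped=%d",
              res$models$model2$sigma_u, res$models$model2$sigma_e,
              res$models$model2$standardized_transitivity,
              res$models$model2$n_used, res$models$model2$n_dropped),
      sprintf("seed: %d", config$seed)
    ), file.path(out_dir, "model_summary.txt"))
  }
  w(res$audit, "audit_log.csv")
  invisible()
}
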