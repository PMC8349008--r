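# run code with a locally-seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

category_code_pool <- list(
  schizophrenia_psychotic = c("F20.0", "F25.0", "F29"),
  bipolar = c("F31.9", "F30.2"),
  depression_mood = c("F32.9", "F33.1"),
  anxiety_stress = c("F41.1", "F43.10"),
  other_mental = c("F60.3", "F63.9", "F90.0"),
  substance_use = c("F10.20", "F11.20")
)
comorbidity_codes <- c("I10", "E11.9", "J45.909", "M54.5")
specialty_taxonomy <- c(pcp = "207R00000X", psychiatrist = "2084P0800X",
                        psychologist = "103T00000X",
                        bh_specialist = "104100000X")

#' Configuration for the synthetic-claims generator
#'
#' The defaults emulate, at desk scale, the structure of a two-year state
#' all-payer claims extract for adults with mental illness: five provider
#' communities of five sub-communities each (80 providers per
#' sub-community, 2,000 network-eligible providers total), a specialty mix
#' matching the published network composition (3833 PCP / 823 psychiatrist /
#' 498 psychologist / 3102 behavioral-health specialist out of 8256), 20,000
#' patients with diagnosis and insurance margins matching the published
#' cohort table, and overdispersed outpatient utilization.
#'
#' Locality of care drives the planted community structure: each visit's
#' provider is drawn from the patient's home sub-community with probability
#' `p_within_sub`, else from the home community with (conditional)
#' probability `p_within_com`, else from anywhere; within the chosen pool
#' the patient draws from a personal set of `m_providers` providers whose
#' Zipf-like weights sharpen as `concentration` grows (driving continuity of
#' care upward).
#'
#' @param seed integer RNG seed; identical configurations yield identical
#'   datasets.
#' @param n_communities,subcommunities_per_community,providers_per_subcommunity
#'   planted two-level community structure.
#' @param specialty_mix named probability vector over the four specialty
#'   groups.
#' @param n_patients patient count.
#' @param n_other_providers providers outside the four analytic specialties
#'   (taxonomy mapped to `"other"`), receiving occasional claims.
#' @param p_within_sub,p_within_com locality probabilities (the latter
#'   conditional on leaving the sub-community).
#' @param popularity Zipf exponent for provider volume within a
#'   sub-community: patients pick providers with probability proportional
#'   to rank^(-popularity). 0 gives uniform volumes; the default 1 yields
#'   the heavy-tailed provider volumes seen in claims data (a small core of
#'   high-volume providers carries most patient sharing, so the
#'   shared-patient threshold retains a connected core and excludes a long
#'   tail of low-volume providers).
#' @param visits_mean,visits_size negative-binomial mean and size of yearly
#'   outpatient visit counts per patient.
#' @param concentration nonnegative; 0 gives uniform personal-provider
#'   weights, larger values concentrate visits on one provider.
#' @param m_providers size of each patient's personal provider set.
#' @param diagnosis_probs,insurance_probs,sex_probs named category
#'   probability vectors (defaults: published cohort margins).
#' @param age_range inclusive age range (at the first study year) patients
#'   are drawn from; the default deliberately includes under-18 and 65+
#'   patients so cohort filters have work to do.
#' @param study_years calendar years generated.
#' @param coc_model_params optional parameter list for
#'   [plant_coc_outcome()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_communities = 5L,
                       subcommunities_per_community = 5L,
                       providers_per_subcommunity = 80L,
                       specialty_mix = c(pcp = 3833, psychiatrist = 823,
                                         psychologist = 498,
                                         bh_specialist = 3102) / 8256,
                       n_patients = 20000L,
                       n_other_providers = 100L,
                       p_within_sub = 0.75,
                       p_within_com = 0.8,
                       popularity = 1,
                       visits_mean = 6,
                       visits_size = 1.2,
                       concentration = 1.5,
                       m_providers = 4L,
                       diagnosis_probs = c(
                         schizophrenia_psychotic = 29887,
                         bipolar = 38984,
                         depression_mood = 205378,
                         anxiety_stress = 146790,
                         other_mental = 37031,
                         substance_use = 18732) / 476802,
                       insurance_probs = c(
                         medicaid_only = 161843,
                         medicare_only = 21698,
                         dual = 42514,
                         commercial_only = 223103,
                         commercial_plus_public = 27644) / 476802,
                       sex_probs = c(female = 0.620, male = 0.379,
                                     missing = 0.001),
                       age_range = c(17L, 66L),
                       study_years = c(2016L, 2017L),
                       coc_model_params = NULL) {
  cfg <- list(seed = as.integer(seed),
              n_communities = as.integer(n_communities),
              subcommunities_per_community =
                as.integer(subcommunities_per_community),
              providers_per_subcommunity =
                as.integer(providers_per_subcommunity),
              specialty_mix = specialty_mix,
              n_patients = as.integer(n_patients),
              n_other_providers = as.integer(n_other_providers),
              p_within_sub = p_within_sub,
              p_within_com = p_within_com,
              popularity = popularity,
              visits_mean = visits_mean,
              visits_size = visits_size,
              concentration = concentration,
              m_providers = as.integer(m_providers),
              diagnosis_probs = diagnosis_probs,
              insurance_probs = insurance_probs,
              sex_probs = sex_probs,
              age_range = as.integer(age_range),
              study_years = as.integer(study_years),
              coc_model_params = coc_model_params)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (p in c("specialty_mix", "diagnosis_probs", "insurance_probs",
              "sex_probs")) {
    if (abs(sum(cfg[[p]]) - 1) > 1e-9)
      stop("configuration error: ", p, " must sum to 1", call. = FALSE)
    if (any(cfg[[p]] < 0))
      stop("configuration error: ", p, " has negative entries",
           call. = FALSE)
  }
  counts <- c("n_communities", "subcommunities_per_community",
              "providers_per_subcommunity", "n_patients", "m_providers")
  for (ct in counts) {
    if (cfg[[ct]] < (if (ct == "n_patients") 0 else 1))
      stop("configuration error: ", ct, " must be positive", call. = FALSE)
  }
  if (cfg$m_providers > cfg$providers_per_subcommunity)
    stop("configuration error: m_providers exceeds ",
         "providers_per_subcommunity", call. = FALSE)
  if (cfg$concentration < 0)
    stop("configuration error: concentration must be >= 0", call. = FALSE)
  if ((cfg$popularity %||% 1) < 0)
    stop("configuration error: popularity must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic claims dataset with planted community structure
#'
#' Produces claims, patient and provider tables in the exact dialect read by
#' the cohort functions, together with the planted ground truth. See
#' [sim_config()] for the generative model. Outpatient visit claims carry
#' Evaluation-and-Management procedure codes and behavioral-health diagnosis
#' codes matching each patient's planted category; background pharmacy and
#' facility claims (empty provider id) are added so that diagnosis
#' classification and visit identification face realistic inputs.
#'
#' @param config a [sim_config()].
#' @return list with tibbles `claims`, `patients`, `providers`, and
#'   `ground_truth` (list of `providers` and `patients` planted labels),
#'   plus the `config` used.
#' @export
generate_claims <- function(config = sim_config()) {
  validate_sim_config(config)
  with_local_seed(config$seed, generate_claims_impl(config))
}

generate_claims_impl <- function(cfg) {
  pps <- cfg$providers_per_subcommunity
  spc <- cfg$subcommunities_per_community
  n_sub <- cfg$n_communities * spc
  n_prov <- n_sub * pps

  # providers -----------------------------------------------------------
  sub_of_provider <- rep(seq_len(n_sub), each = pps)
  com_of_provider <- (sub_of_provider - 1L) %/% spc + 1L
  specialty <- sample(names(cfg$specialty_mix), n_prov, TRUE,
                      prob = cfg$specialty_mix)
  provider_id <- sprintf("P%05d", seq_len(n_prov))
  other_ids <- if (cfg$n_other_providers > 0) {
    sprintf("X%05d", seq_len(cfg$n_other_providers))
  } else character(0)
  providers <- tibble::tibble(
    provider_id = c(provider_id, other_ids),
    taxonomy_code = c(specialty_taxonomy[specialty],
                      rep("208600000X", length(other_ids))),
    specialty_group = c(specialty, rep("other", length(other_ids)))
  )

  # patients ------------------------------------------------------------
  n_pat <- cfg$n_patients
  patient_id <- sprintf("M%06d", seq_len(n_pat))
  y1 <- min(cfg$study_years)
  age1 <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n_pat, TRUE)
  home_sub <- sample.int(n_sub, n_pat, TRUE)
  dx_cat <- sample(names(cfg$diagnosis_probs), n_pat, TRUE,
                   prob = cfg$diagnosis_probs)
  insurance <- sample(names(cfg$insurance_probs), n_pat, TRUE,
                      prob = cfg$insurance_probs)
  sex <- sample(names(cfg$sex_probs), n_pat, TRUE, prob = cfg$sex_probs)
  patients <- tibble::tibble(
    patient_id = patient_id,
    birth_year = y1 - age1,
    sex = sex,
    insurance_category = insurance
  )

  # personal provider sets (n_pat x m), locality-driven -----------------
  m <- cfg$m_providers
  u <- matrix(runif(n_pat * m), n_pat, m)
  pool <- matrix("any", n_pat, m)
  pool[u < cfg$p_within_sub] <- "sub"
  pool[u >= cfg$p_within_sub &
         u < cfg$p_within_sub + (1 - cfg$p_within_sub) * cfg$p_within_com] <-
    "com"
  home_sub_m <- matrix(home_sub, n_pat, m)
  home_com_m <- (home_sub_m - 1L) %/% spc + 1L
  # choose the sub-community pool per cell, then a provider inside it with
  # Zipf-like volume weights (rank within sub); ranks map to provider index
  r <- matrix(runif(n_pat * m), n_pat, m)
  sub_pick <- matrix(0L, n_pat, m)
  is_sub <- pool == "sub"
  sub_pick[is_sub] <- home_sub_m[is_sub]
  is_com <- pool == "com"
  sub_pick[is_com] <- (home_com_m[is_com] - 1L) * spc +
    ceiling(r[is_com] * spc)
  is_any <- pool == "any"
  sub_pick[is_any] <- ceiling(r[is_any] * n_sub)
  vol_w <- seq_len(pps)^(-(cfg$popularity %||% 1))
  vol_cdf <- cumsum(vol_w / sum(vol_w))
  rank_pick <- matrix(
    findInterval(runif(n_pat * m), vol_cdf,
                 rightmost.closed = TRUE) + 1L,
    n_pat, m)
  personal <- (sub_pick - 1L) * pps + rank_pick

  w <- seq_len(m)^(-cfg$concentration)
  w <- w / sum(w)

  # outpatient visit claims --------------------------------------------
  visit_rows <- list()
  for (yr in cfg$study_years) {
    n_vis <- rnbinom(n_pat, size = cfg$visits_size, mu = cfg$visits_mean)
    tot <- sum(n_vis)
    if (tot == 0) next
    pat_idx <- rep.int(seq_len(n_pat), n_vis)
    slot <- sample.int(m, tot, TRUE, prob = w)
    prov_idx <- personal[cbind(pat_idx, slot)]
    day <- sample.int(365L, tot, TRUE) - 1L
    first_of_patient <- !duplicated(pat_idx)
    dx_main <- sample_category_codes(dx_cat[pat_idx])
    use_bh <- first_of_patient | runif(tot) < 0.6
    dx1 <- ifelse(use_bh, dx_main,
                  sample(comorbidity_codes, tot, TRUE))
    dx2 <- ifelse(runif(tot) < 0.15,
                  sample(c(comorbidity_codes, "F17.200"), tot, TRUE),
                  "")
    visit_rows[[as.character(yr)]] <- tibble::tibble(
      patient_id = patient_id[pat_idx],
      provider_id = provider_id[prov_idx],
      service_date = as.Date(sprintf("%d-01-01", yr)) + day,
      claim_type = "outpatient",
      procedure_code = sample(c("99212", "99213", "99214", "99215"),
                              tot, TRUE),
      payer = claim_payer(insurance[pat_idx]),
      dx1 = dx1,
      dx2 = dx2
    )
  }

  # background pharmacy and facility claims ----------------------------
  bg_rows <- list()
  for (yr in cfg$study_years) {
    n_rx <- rpois(n_pat, 1.5)
    tot_rx <- sum(n_rx)
    if (tot_rx > 0) {
      idx <- rep.int(seq_len(n_pat), n_rx)
      bg_rows[[paste0("rx", yr)]] <- tibble::tibble(
        patient_id = patient_id[idx],
        provider_id = "",
        service_date = as.Date(sprintf("%d-01-01", yr)) +
          sample.int(365L, tot_rx, TRUE) - 1L,
        claim_type = "pharmacy",
        procedure_code = "",
        payer = claim_payer(insurance[idx]),
        dx1 = "",
        dx2 = ""
      )
    }
    n_fac <- rpois(n_pat, 0.4)
    tot_fac <- sum(n_fac)
    if (tot_fac > 0) {
      idx <- rep.int(seq_len(n_pat), n_fac)
      bg_rows[[paste0("fac", yr)]] <- tibble::tibble(
        patient_id = patient_id[idx],
        provider_id = "",
        service_date = as.Date(sprintf("%d-01-01", yr)) +
          sample.int(365L, tot_fac, TRUE) - 1L,
        claim_type = "outpatient",
        procedure_code = "",
        payer = claim_payer(insurance[idx]),
        dx1 = sample_category_codes(dx_cat[idx]),
        dx2 = ""
      )
    }
  }

  # sparse claims to "other"-specialty providers ------------------------
  if (length(other_ids) > 0 && n_pat > 0) {
    n_oth <- max(1L, round(0.05 * n_pat))
    idx <- sample.int(n_pat, n_oth)
    bg_rows[["other"]] <- tibble::tibble(
      patient_id = patient_id[idx],
      provider_id = sample(other_ids, n_oth, TRUE),
      service_date = as.Date(sprintf("%d-01-01", y1)) +
        sample.int(365L, n_oth, TRUE) - 1L,
      claim_type = "outpatient",
      procedure_code = "99213",
      payer = claim_payer(insurance[idx]),
      dx1 = sample(comorbidity_codes, n_oth, TRUE),
      dx2 = ""
    )
  }

  empty_claims <- tibble::tibble(
    patient_id = character(), provider_id = character(),
    service_date = as.Date(character()), claim_type = character(),
    procedure_code = character(), payer = character(),
    dx1 = character(), dx2 = character())
  claims <- dplyr::bind_rows(c(list(empty_claims), visit_rows, bg_rows)) |>
    dplyr::arrange(.data$patient_id, .data$service_date,
                   .data$provider_id, .data$procedure_code)

  ground_truth <- list(
    providers = tibble::tibble(
      provider_id = provider_id,
      community = paste0("G", com_of_provider),
      subcommunity = paste0("G", com_of_provider, ".",
                            (sub_of_provider - 1L) %% spc + 1L),
      specialty_group = specialty),
    patients = tibble::tibble(
      patient_id = patient_id,
      home_community = paste0("G", (home_sub - 1L) %/% spc + 1L),
      home_subcommunity = paste0("G", (home_sub - 1L) %/% spc + 1L, ".",
                                 (home_sub - 1L) %% spc + 1L),
      diagnosis_category = dx_cat,
      insurance_category = insurance)
  )

  list(claims = claims, patients = patients, providers = providers,
       ground_truth = ground_truth, config = cfg)
}

sample_category_codes <- function(categories) {
  out <- character(length(categories))
  for (cat in unique(categories)) {
    idx <- which(categories == cat)
    out[idx] <- sample(category_code_pool[[cat]], length(idx),
                       replace = TRUE)
  }
  out
}

claim_payer <- function(insurance_category) {
  n <- length(insurance_category)
  out <- character(n)
  out[insurance_category == "medicaid_only"] <- "medicaid"
  out[insurance_category == "medicare_only"] <- "medicare"
  out[insurance_category == "commercial_only"] <- "commercial"
  is_dual <- insurance_category == "dual"
  out[is_dual] <- sample(c("medicaid", "medicare"), sum(is_dual), TRUE)
  is_cp <- insurance_category == "commercial_plus_public"
  out[is_cp] <- sample(c("commercial", "medicaid"), sum(is_cp), TRUE)
  # second claim stream guarantees both payers eventually appear for mixed
  # categories at realistic claim volumes; no per-patient guarantee needed
  out
}

#' Plant a linear-mixed-model outcome on provider profiles
#'
#' Generates provider-level CoC values from the random-intercept linear
#' model \eqn{CoC = I + \beta_1 T + \beta_3 P + \beta_4 S + \beta_5 A_{CoC}
#' + u + e}, with \eqn{u \sim N(0, \sigma_u^2)} per community and
#' \eqn{e \sim N(0, \sigma_e^2)} per provider, clipped to \eqn{[0, 1]} (the
#' clipping fraction is attached as an attribute). Decouples model-recovery
#' testing from the realism of the visit-level generator.
#'
#' @param profiles tibble with `transitivity`, `n_patients`,
#'   `specialty_group`, `community`, and (if `beta_alter_coc` is nonzero)
#'   `alter_mean_coc`.
#' @param params list with `intercept`, `beta_transitivity`,
#'   `beta_n_patients`, `beta_specialty` (named vector for
#'   `bh_specialist`, `psychiatrist`, `psychologist`; PCP is the zero
#'   reference), `beta_alter_coc`, `sigma_u`, `sigma_e`.
#' @param seed RNG seed.
#' @return `profiles` with a new / overwritten `mean_coc` column; attribute
#'   `clipped_fraction` reports the share of values clipped into
#'   \eqn{[0,1]}.
#' @export
plant_coc_outcome <- function(profiles, params, seed = 1L) {
  with_local_seed(seed, {
    beta_s <- params$beta_specialty %||%
      c(bh_specialist = 0, psychiatrist = 0, psychologist = 0)
    s_eff <- ifelse(profiles$specialty_group == "pcp", 0,
                    beta_s[profiles$specialty_group])
    mu <- params$intercept +
      params$beta_transitivity * profiles$transitivity +
      params$beta_n_patients * profiles$n_patients +
      as.numeric(s_eff)
    b5 <- params$beta_alter_coc %||% 0
    if (b5 != 0) mu <- mu + b5 * profiles$alter_mean_coc
    comm <- factor(profiles$community)
    u <- rnorm(nlevels(comm), 0, params$sigma_u %||% 0)
    e <- rnorm(nrow(profiles), 0, params$sigma_e %||% 0)
    raw <- mu + u[as.integer(comm)] + e
    clipped <- pmin(1, pmax(0, raw))
    out <- dplyr::mutate(profiles, mean_coc = clipped)
    attr(out, "clipped_fraction") <- mean(raw != clipped)
    out
  })
}

#' Simulate provider-level profiles for model-recovery experiments
#'
#' Draws provider predictors (transitivity, patient counts, specialty,
#' alter CoC) with realistic marginals and community labels, without running
#' the full claims generator; pair with [plant_coc_outcome()] to study the
#' mixed-model fitter under known truth.
#'
#' @param n_communities,providers_per_community design size.
#' @param seed RNG seed.
#' @return tibble with `provider_id`, `community`, `specialty_group`,
#'   `transitivity`, `n_patients`, `alter_mean_coc`.
#' @export
simulate_provider_profiles <- function(n_communities = 50L,
                                       providers_per_community = 40L,
                                       seed = 1L) {
  with_local_seed(seed, {
    n <- n_communities * providers_per_community
    tibble::tibble(
      provider_id = sprintf("P%05d", seq_len(n)),
      community = rep(paste0("C", seq_len(n_communities)),
                      each = providers_per_community),
      specialty_group = sample(names(specialty_taxonomy), n, TRUE,
                               prob = c(0.46, 0.10, 0.06, 0.38)),
      transitivity = stats::rbeta(n, 6, 4),
      n_patients = rnbinom(n, size = 2, mu = 180) + 1L,
      alter_mean_coc = pmin(1, pmax(0, rnorm(n, 0.30, 0.05)))
    )
  })
}

#' Write a simulated dataset to disk
#'
#' Writes `claims.csv`, `patients.csv`, `providers.csv`,
#' `ground_truth_providers.csv`, `ground_truth_patients.csv` and a
#' `manifest.txt` recording the seed and a hash of the configuration.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the generated dataset list.
#' @export
simulate_claims <- function(config = sim_config(), dir) {
  dat <- generate_claims(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dat$claims, file.path(dir, "claims.csv"))
  readr::write_csv(dat$patients, file.path(dir, "patients.csv"))
  readr::write_csv(dat$providers, file.path(dir, "providers.csv"))
  readr::write_csv(dat$ground_truth$providers,
                   file.path(dir, "ground_truth_providers.csv"))
  readr::write_csv(dat$ground_truth$patients,
                   file.path(dir, "ground_truth_patients.csv"))
  writeLines(c(
    paste("seed:", config$seed),
    paste("config_hash:", rlang::hash(unclass(config))),
    paste("n_claims:", nrow(dat$claims))
  ), file.path(dir, "manifest.txt"))
  invisible(dat)
}
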