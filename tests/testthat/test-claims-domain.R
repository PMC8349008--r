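test_that("provider classification maps known codes and defaults to other", {
  expect_equal(classify_provider("2084P0800X"), "psychiatrist")
  expect_equal(classify_provider("207R00000X"), "pcp")
  expect_equal(classify_provider("103T00000X"), "psychologist")
  expect_equal(classify_provider("104100000X"), "bh_specialist")
  expect_equal(classify_provider(""), "other")
  expect_equal(classify_provider("ZZZZZZZZZZ"), "other")
  # vectorized, order preserved
  expect_equal(classify_provider(c("207R00000X", "", "2084P0800X")),
               c("pcp", "other", "psychiatrist"))
})

test_that("diagnosis hierarchy assigns the highest applicable category", {
  h <- default_diagnosis_hierarchy()
  # schizophrenia outranks depression regardless of claim order
  cl <- claim_rows(c("M1", "M1"), dx1 = c("F32.9", "F20.0"))
  expect_equal(classify_patient_diagnosis(cl, h), "schizophrenia_psychotic")
  expect_equal(classify_patient_diagnosis(cl[2:1, ], h),
               "schizophrenia_psychotic")
  # nicotine dependence alone does not qualify
  expect_true(is.na(classify_patient_diagnosis(
    claim_rows("M1", dx1 = "F17.200"), h)))
  # no diagnoses at all
  expect_true(is.na(classify_patient_diagnosis(
    claim_rows("M1", dx1 = "", dx2 = ""), h)))
  # secondary positions count
  expect_equal(classify_patient_diagnosis(
    claim_rows("M1", dx1 = "I10", dx2 = "F31.9"), h), "bipolar")
  # substance use is the lowest rank
  expect_equal(classify_patient_diagnosis(
    claim_rows(c("M1", "M1"), dx1 = c("F10.20", "F41.1")), h),
    "anxiety_stress")
})

test_that("diagnosis classification is invariant to claim permutation", {
  h <- default_diagnosis_hierarchy()
  set.seed(11)
  codes <- c("F32.9", "F20.0", "F41.1", "I10", "F10.20", "F90.0")
  for (rep in 1:20) {
    cl <- claim_rows(rep("M1", 6), dx1 = sample(codes))
    expect_equal(classify_patient_diagnosis(cl, h),
                 "schizophrenia_psychotic")
  }
})

test_that("malformed ICD codes are skipped with a warning", {
  h <- default_diagnosis_hierarchy()
  cl <- claim_rows(c("M1", "M1"), dx1 = c("banana", "F33.1"))
  expect_warning(out <- classify_patient_diagnosis(cl, h), "malformed")
  expect_equal(out, "depression_mood")
})

test_that("insurance categories derive deterministically from payer sets", {
  cl <- dplyr::bind_rows(
    claim_rows("A", payer = "medicaid"),
    claim_rows("B", payer = c("medicaid", "medicare")),
    claim_rows("C", payer = c("commercial", "medicare")),
    claim_rows("D", payer = "commercial"),
    claim_rows("E", payer = c("commercial", "medicaid", "medicare"))
  )
  got <- derive_insurance_category(cl)
  expect_equal(stats::setNames(got$insurance_category, got$patient_id),
               c(A = "medicaid_only", B = "dual",
                 C = "commercial_plus_public", D = "commercial_only",
                 E = "commercial_plus_public"))
})

make_cohort_inputs <- function() {
  # P1 pcp provider; claims carrying qualifying depression codes
  providers <- provider_rows(c("P1", "P9"), c("pcp", "other"))
  claims <- dplyr::bind_rows(
    claim_rows("young", service_date = "2016-05-01"),
    claim_rows("young", service_date = "2017-05-01"),
    claim_rows("old", service_date = "2016-05-01"),
    claim_rows("only2017", service_date = "2017-03-01"),
    claim_rows("nodx", service_date = "2016-03-01", dx1 = "I10"),
    claim_rows("onlyother", service_date = "2016-03-01",
               provider_id = "P9"),
    claim_rows("ok", service_date = "2016-03-01"),
    claim_rows("nobirth", service_date = "2016-03-01")
  )
  patients <- dplyr::bind_rows(
    patient_rows("young", 1999),    # 17 at start of 2016, 18 in 2017...
    patient_rows("old", 1951),      # 64 at start of 2016, 65 at end
    patient_rows("only2017", 1998), # 18 only in 2017; claims only 2017
    patient_rows("nodx", 1980),
    patient_rows("onlyother", 1980),
    patient_rows("ok", 1980),
    patient_rows("nobirth", NA)
  )
  list(claims = claims, patients = patients, providers = providers)
}

test_that("cohort filters enforce age, diagnosis and provider-type rules", {
  inp <- make_cohort_inputs()
  out <- apply_cohort_filters(inp$claims, inp$patients, inp$providers)
  kept <- sort(out$patients$patient_id)
  # young: 2016 age 17 fails, but 2017 age 18 qualifies (claim present)
  # old: 2016 -> 64 at start but 65 by year-end arithmetic -> excluded
  expect_equal(kept, sort(c("young", "only2017", "ok")))
  expect_true(all(out$claims$patient_id %in% kept))
  audit <- out$audit
  expect_equal(audit$n[audit$criterion == "input_patients"], 7)
  expect_equal(audit$n[audit$criterion == "missing_birth_year"], 1)
  expect_equal(audit$n[audit$criterion == "retained"], 3)
  expect_equal(out$patients$diagnosis_category[
    out$patients$patient_id == "ok"], "depression_mood")
})

test_that("cohort filtering is idempotent", {
  inp <- make_cohort_inputs()
  once <- apply_cohort_filters(inp$claims, inp$patients, inp$providers)
  twice <- apply_cohort_filters(once$claims, once$patients, inp$providers)
  expect_equal(sort(twice$patients$patient_id),
               sort(once$patients$patient_id))
  expect_equal(dplyr::arrange(twice$claims, patient_id, service_date),
               dplyr::arrange(once$claims, patient_id, service_date))
})

test_that("outpatient visits deduplicate per patient-provider-day", {
  cfg <- cohort_config()
  # same pair, same day, two E&M codes -> one visit
  cl <- claim_rows(c("M1", "M1"), provider_id = "P1",
                   service_date = "2016-02-01",
                   procedure_code = c("99213", "99214"))
  expect_equal(nrow(identify_outpatient_visits(cl, cfg)), 1)
  # pharmacy claims never count
  expect_equal(nrow(identify_outpatient_visits(
    claim_rows("M1", claim_type = "pharmacy"), cfg)), 0)
  # codes outside the value set never count
  expect_equal(nrow(identify_outpatient_visits(
    claim_rows("M1", procedure_code = "71020"), cfg)), 0)
  # facility claims (empty provider) never count
  expect_equal(nrow(identify_outpatient_visits(
    claim_rows("M1", provider_id = ""), cfg)), 0)
  # three distinct days -> three visits
  cl3 <- claim_rows(rep("M1", 3),
                    service_date = c("2016-01-01", "2016-01-02",
                                     "2016-01-03"))
  v3 <- identify_outpatient_visits(cl3, cfg)
  expect_equal(nrow(v3), 3)
  expect_equal(unique(v3$year), 2016L)
})

test_that("visit count is bounded by qualifying claims, equal iff no dupes", {
  cfg <- cohort_config()
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    cl <- claim_rows(
      sample(c("A", "B"), n, TRUE),
      provider_id = sample(c("P1", "P2"), n, TRUE),
      service_date = as.Date("2016-01-01") + sample(0:5, n, TRUE))
    v <- identify_outpatient_visits(cl, cfg)
    expect_lte(nrow(v), nrow(cl))
    dup <- anyDuplicated(cl[c("patient_id", "provider_id",
                              "service_date")]) > 0
    expect_equal(nrow(v) == nrow(cl), !dup)
  }
})
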