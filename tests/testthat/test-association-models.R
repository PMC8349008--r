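# textbook correlation formulas, written out as an independent oracle
pearson_oracle <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
}
spearman_oracle <- function(x, y) pearson_oracle(rank(x), rank(y))

fake_summary <- function(size, value) {
  tibble::tibble(community = "C1",
                 subcommunity = sprintf("C1.S%d", seq_along(size)),
                 size = size, mean_connections = value,
                 mean_pcp_connections = value,
                 pct_pcp_within_subcommunity = value,
                 mean_transitivity = value, mean_coc = value,
                 prop_pcp = value, prop_psychiatrist = value,
                 prop_psychologist = value, prop_bh_specialist = value)
}

test_that("size correlations match trivial and hand-computed cases", {
  s <- fake_summary(size = c(10, 20, 30, 40, 50), value = c(10, 20, 30, 40, 50))
  got <- correlate_size_vs_characteristics(s)
  expect_true(all(abs(got$pearson - 1) < 1e-12))
  expect_true(all(abs(got$spearman - 1) < 1e-12))
  s2 <- fake_summary(size = c(10, 20, 30, 40, 50),
                     value = -c(10, 20, 30, 40, 50))
  got2 <- correlate_size_vs_characteristics(s2)
  expect_true(all(abs(got2$pearson + 1) < 1e-12))
  expect_true(all(abs(got2$spearman + 1) < 1e-12))
  # 5-row fixture vs the textbook formulas
  size <- c(14, 87, 250, 483, 1320)
  val <- c(5.2, 30.1, 18.4, 71.0, 8.8)
  s3 <- fake_summary(size, val)
  got3 <- correlate_size_vs_characteristics(s3, "mean_connections")
  expect_equal(got3$pearson, pearson_oracle(size, val), tolerance = 1e-12)
  expect_equal(got3$spearman, spearman_oracle(size, val),
               tolerance = 1e-12)
  # zero-variance characteristic -> undefined
  s4 <- fake_summary(size, rep(3, 5))
  expect_true(is.na(
    correlate_size_vs_characteristics(s4, "mean_coc")$pearson))
})

test_that("unadjusted transitivity-CoC association is computed correctly", {
  prof <- tibble::tibble(transitivity = c(0.1, 0.5, 0.9, 0.3),
                         mean_coc = c(0.1, 0.5, 0.9, 0.3))
  got <- unadjusted_association(prof)
  expect_equal(got$pearson, 1)
  expect_equal(got$spearman, 1)
  # constant transitivity -> flagged undefined
  prof2 <- tibble::tibble(transitivity = rep(0.4, 5),
                          mean_coc = runif(5))
  expect_warning(got2 <- unadjusted_association(prof2), "constant")
  expect_true(is.na(got2$pearson))
  # 10-row fixture against the textbook oracle
  set.seed(12)
  prof3 <- tibble::tibble(transitivity = runif(10),
                          mean_coc = runif(10))
  got3 <- unadjusted_association(prof3)
  expect_equal(got3$pearson,
               pearson_oracle(prof3$transitivity, prof3$mean_coc),
               tolerance = 1e-12)
  expect_equal(got3$spearman,
               spearman_oracle(prof3$transitivity, prof3$mean_coc),
               tolerance = 1e-12)
})

true_params <- list(intercept = 0.25, beta_transitivity = -0.011,
                    beta_n_patients = 6e-6,
                    beta_specialty = c(bh_specialist = 0.061,
                                       psychiatrist = 0.027,
                                       psychologist = 0.034),
                    beta_alter_coc = 0, sigma_u = 0, sigma_e = 0)

test_that("noiseless planted outcomes are recovered exactly", {
  prof <- simulate_provider_profiles(n_communities = 10,
                                     providers_per_community = 30,
                                     seed = 2)
  planted <- plant_coc_outcome(prof, true_params, seed = 3)
  expect_equal(attr(planted, "clipped_fraction"), 0)
  # zero-noise data makes the optimizer grumble; the estimates are exact
  fit <- suppressWarnings(suppressMessages(
    fit_coc_model(planted, include_alter_coc = FALSE)))
  est <- stats::setNames(fit$coefficients$estimate,
                         fit$coefficients$term)
  expect_equal(est[["(Intercept)"]], 0.25, tolerance = 1e-8)
  expect_equal(est[["transitivity"]], -0.011, tolerance = 1e-8)
  expect_equal(est[["n_patients"]], 6e-6, tolerance = 1e-8)
  expect_equal(est[["specialty_groupbh_specialist"]], 0.061,
               tolerance = 1e-8)
  expect_equal(est[["specialty_grouppsychiatrist"]], 0.027,
               tolerance = 1e-8)
  expect_equal(est[["specialty_grouppsychologist"]], 0.034,
               tolerance = 1e-8)
})

test_that("with sigma_u = 0 the mixed fit reproduces ordinary least squares", {
  prof <- simulate_provider_profiles(n_communities = 8,
                                     providers_per_community = 40,
                                     seed = 4)
  params <- utils::modifyList(true_params, list(sigma_e = 0.05))
  planted <- plant_coc_outcome(prof, params, seed = 5)
  fit <- suppressMessages(fit_coc_model(planted))
  ols <- stats::lm(mean_coc ~ transitivity + n_patients +
                     stats::relevel(factor(specialty_group), "pcp"),
                   data = planted)
  expect_equal(unname(fit$coefficients$estimate),
               unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("single-community data falls back to a fixed-intercept fit", {
  prof <- simulate_provider_profiles(n_communities = 1,
                                     providers_per_community = 60,
                                     seed = 6)
  params <- utils::modifyList(true_params, list(sigma_e = 0.03))
  planted <- plant_coc_outcome(prof, params, seed = 7)
  expect_warning(fit <- fit_coc_model(planted), "fewer than 2")
  expect_equal(fit$engine, "lm")
  ols <- stats::lm(mean_coc ~ transitivity + n_patients +
                     stats::relevel(factor(specialty_group), "pcp"),
                   data = planted)
  expect_equal(unname(fit$coefficients$estimate),
               unname(stats::coef(ols)), tolerance = 1e-10)
})

test_that("standardized slope equals raw slope times SD ratio", {
  prof <- simulate_provider_profiles(n_communities = 10,
                                     providers_per_community = 40,
                                     seed = 8)
  params <- utils::modifyList(true_params,
                              list(sigma_u = 0.02, sigma_e = 0.05))
  planted <- plant_coc_outcome(prof, params, seed = 9)
  fit <- fit_coc_model(planted)
  raw <- fit$coefficients$estimate[fit$coefficients$term == "transitivity"]
  expect_equal(fit$standardized_transitivity,
               raw * sd(planted$transitivity) / sd(planted$mean_coc),
               tolerance = 1e-12)
})

test_that("spearman equals pearson on rank-transformed data", {
  set.seed(13)
  x <- rnorm(30)
  y <- x + rnorm(30)
  expect_equal(cor(x, y, method = "spearman"),
               cor(rank(x), rank(y), method = "pearson"),
               tolerance = 1e-12)
  expect_equal(spearman_oracle(x, y),
               cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("tidy and glance expose the model surface", {
  prof <- simulate_provider_profiles(n_communities = 6,
                                     providers_per_community = 30,
                                     seed = 10)
  params <- utils::modifyList(true_params,
                              list(sigma_u = 0.02, sigma_e = 0.05))
  planted <- plant_coc_outcome(prof, params, seed = 11)
  fit <- fit_coc_model(planted)
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate", "std_error", "statistic",
                     "p_value"))
  gl <- generics::glance(fit)
  expect_equal(gl$n_used, 180)
  expect_equal(gl$engine, "lmer")
})
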