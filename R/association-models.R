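#' Correlate sub-community size with network characteristics
#'
#' Pearson and Spearman correlations between the number of providers per
#' sub-community and each structural / composition characteristic, computed
#' over sub-communities with pairwise-complete observations.
#'
#' @param summary output of [subcommunity_summary()].
#' @param characteristics columns of `summary` to correlate with `size`;
#'   defaults to the five structure and four composition measures.
#' @return tibble `characteristic`, `pearson`, `spearman`, `n_complete`.
#'   Zero-variance characteristics yield `NA` coefficients.
#' @export
correlate_size_vs_characteristics <- function(
    summary,
    characteristics = c("mean_connections", "mean_pcp_connections",
                        "pct_pcp_within_subcommunity", "mean_transitivity",
                        "mean_coc", "prop_psychiatrist", "prop_pcp",
                        "prop_psychologist", "prop_bh_specialist")) {
  stopifnot(nrow(summary) >= 3)
  purrr::map_dfr(characteristics, function(ch) {
    x <- summary$size
    y <- summary[[ch]]
    ok <- !is.na(x) & !is.na(y)
    pe <- sp <- NA_real_
    if (sum(ok) >= 3 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
      pe <- cor(x[ok], y[ok], method = "pearson")
      sp <- cor(x[ok], y[ok], method = "spearman")
    }
    tibble::tibble(characteristic = ch, pearson = pe, spearman = sp,
                   n_complete = sum(ok))
  })
}

#' Unadjusted association between transitivity and provider CoC
#'
#' @param profiles provider profile tibble with `transitivity` and
#'   `mean_coc`.
#' @return tibble with `pearson`, `spearman`, `n_complete`; `NA` with a
#'   warning when either variable is constant.
#' @export
unadjusted_association <- function(profiles) {
  ok <- !is.na(profiles$transitivity) & !is.na(profiles$mean_coc)
  stopifnot(sum(ok) >= 3)
  x <- profiles$transitivity[ok]
  y <- profiles$mean_coc[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant variable: correlation undefined", call. = FALSE)
    return(tibble::tibble(pearson = NA_real_, spearman = NA_real_,
                          n_complete = sum(ok)))
  }
  tibble::tibble(pearson = cor(x, y),
                 spearman = cor(x, y, method = "spearman"),
                 n_complete = sum(ok))
}

#' Community random-intercept model of provider continuity of care
#'
#' Fits, by restricted maximum likelihood,
#' \deqn{CoC_{j} = I + \beta_1 T_j + \beta_3 P_j + \beta_4 S_j
#'   [+ \beta_5 A_{CoC,j}] + u_{c(j)} + e_j}
#' where \eqn{T} is the provider's local transitivity, \eqn{P} the number of
#' patients, \eqn{S} the specialty group (PCP reference, three contrasts),
#' \eqn{A_{CoC}} the alter mean CoC (Model 2 only), and \eqn{u} a Gaussian
#' random intercept for the provider's network community. P-values are Wald
#' tests with 1 degree of freedom (normal approximation), matching common
#' large-sample practice; no small-sample correction is applied. Rows with
#' any missing response or predictor are dropped listwise (counted). With
#' fewer than two communities the random intercept is unidentifiable and an
#' ordinary least-squares fit is returned with a warning.
#'
#' @param profiles provider profile tibble (needs `mean_coc`,
#'   `transitivity`, `n_patients`, `specialty_group`, `community`, and
#'   `alter_mean_coc` when `include_alter_coc = TRUE`).
#' @param include_alter_coc include the alter-CoC predictor (Model 2)?
#' @param group grouping column for the random intercept, `"community"`
#'   (default) or `"subcommunity"`.
#' @return object of class `coc_model_fit` with elements `coefficients`
#'   (tibble: `term`, `estimate`, `std_error`, `statistic`, `p_value`),
#'   `sigma_u`, `sigma_e`, `standardized_transitivity` (raw slope times
#'   SD(T)/SD(CoC)), `n_used`, `n_dropped`, `model` (1 or 2), `engine`
#'   (`"lmer"` or `"lm"`), and `fit` (the underlying fitted object).
#' @export
fit_coc_model <- function(profiles, include_alter_coc = FALSE,
                          group = c("community", "subcommunity")) {
  group <- match.arg(group)
  need <- c("mean_coc", "transitivity", "n_patients", "specialty_group",
            group, if (include_alter_coc) "alter_mean_coc")
  stopifnot(all(need %in% names(profiles)))
  dat <- profiles[, need]
  names(dat)[names(dat) == group] <- ".group"
  complete <- complete.cases(dat)
  n_dropped <- sum(!complete)
  dat <- dat[complete, ]
  dat$specialty_group <- stats::relevel(
    factor(dat$specialty_group,
           levels = c("pcp", "bh_specialist", "psychiatrist",
                      "psychologist")),
    ref = "pcp")

  rhs <- paste(c("transitivity", "n_patients", "specialty_group",
                 if (include_alter_coc) "alter_mean_coc"),
               collapse = " + ")
  n_groups <- length(unique(dat$.group))

  if (n_groups < 2) {
    warning("fewer than 2 communities: random intercept unidentifiable, ",
            "falling back to a fixed-intercept model", call. = FALSE)
    fit <- stats::lm(as.formula(paste("mean_coc ~", rhs)), data = dat)
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    sigma_u <- 0
    sigma_e <- stats::sigma(fit)
    engine <- "lm"
  } else {
    fml <- as.formula(paste("mean_coc ~", rhs, "+ (1 | .group)"))
    # predictors deliberately enter on their raw scales (patient counts in
    # patients, transitivity in [0,1]); silence the rescaling advisory only
    fit <- lme4::lmer(fml, data = dat, REML = TRUE,
                      control = lme4::lmerControl(check.scaleX = "ignore"))
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_u <- vc$sdcor[vc$grp == ".group"]
    sigma_e <- vc$sdcor[vc$grp == "Residual"]
    engine <- "lmer"
  }

  z <- est / se
  coefs <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * pnorm(-abs(unname(z)))
  )
  std_t <- unname(est[["transitivity"]]) *
    sd(dat$transitivity) / sd(dat$mean_coc)

  structure(
    list(coefficients = coefs,
         sigma_u = sigma_u,
         sigma_e = sigma_e,
         standardized_transitivity = std_t,
         n_used = nrow(dat),
         n_dropped = n_dropped,
         n_groups = n_groups,
         model = if (include_alter_coc) 2L else 1L,
         group = group,
         engine = engine,
         fit = fit),
    class = "coc_model_fit"
  )
}

#' @export
print.coc_model_fit <- function(x, ...) {
  cat("<coc_model_fit> Model", x$model,
      sprintf("(%s, random intercept: %s)\n", x$engine, x$group))
  cat(sprintf("  n = %d (%d dropped), groups = %d\n",
              x$n_used, x$n_dropped, x$n_groups))
  cat(sprintf("  sigma_u = %.4g, sigma_e = %.4g\n", x$sigma_u, x$sigma_e))
  cat(sprintf("  standardized transitivity slope = %.3f SD(CoC)/SD(T)\n",
              x$standardized_transitivity))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Tidy a fitted CoC model
#'
#' @param x a `coc_model_fit`.
#' @param ... unused.
#' @return tibble `term`, `estimate`, `std_error`, `statistic`, `p_value`.
#' @exportS3Method generics::tidy
tidy.coc_model_fit <- function(x, ...) x$coefficients

#' One-row summary of a fitted CoC model
#'
#' @param x a `coc_model_fit`.
#' @param ... unused.
#' @return tibble with variance components, standardized transitivity
#'   effect, sample sizes and engine.
#' @exportS3Method generics::glance
glance.coc_model_fit <- function(x, ...) {
  tibble::tibble(model = x$model, engine = x$engine,
                 sigma_u = x$sigma_u, sigma_e = x$sigma_e,
                 standardized_transitivity = x$standardized_transitivity,
                 n_used = x$n_used, n_dropped = x$n_dropped,
                 n_groups = x$n_groups)
}

#' Two-model report in the layout of the adjusted-association table
#'
#' Convenience wrapper fitting Model 1 (without alter CoC) and Model 2
#' (with it) and binding the tidied coefficients.
#'
#' @inheritParams fit_coc_model
#' @return list with `model1`, `model2` (`coc_model_fit`s) and `report`
#'   (long tibble of both models' terms).
#' @export
coc_model_report <- function(profiles, group = "community") {
  m1 <- fit_coc_model(profiles, include_alter_coc = FALSE, group = group)
  m2 <- fit_coc_model(profiles, include_alter_coc = TRUE, group = group)
  report <- dplyr::bind_rows(
    dplyr::mutate(tidy(m1), model = 1L),
    dplyr::mutate(tidy(m2), model = 2L)
  )
  list(model1 = m1, model2 = m2, report = report)
}
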