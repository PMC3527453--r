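#' Logistic regression fit with convergence and separation diagnostics
#'
#' Thin wrapper around [stats::glm()] with binomial family that makes the
#' diagnostics the downstream estimators need explicit: the maximum number
#' of iterations and deviance tolerance are fixed (100 iterations,
#' `epsilon = 1e-8`), warnings are captured rather than printed, and
#' complete or quasi-complete separation (fitted probabilities numerically
#' 0 or 1) marks the fit as not converged instead of silently returning
#' diverging estimates.
#'
#' @param formula model formula; the response must be binary.
#' @param data data.frame holding the model variables.
#' @param epsilon convergence tolerance on the change in deviance.
#' @param maxit maximum IRLS iterations.
#' @return Object of class `logistic_fit`: list with `coefficients`,
#'   `vcov`, `converged`, `separation`, `n_used`, `warnings` and the
#'   underlying `glm` object.
#' @examples
#' d <- data.frame(y = rep(c(1, 0), c(30, 70)))
#' fit_logistic(y ~ 1, d)$coefficients  # log(30/70)
#' @export
fit_logistic <- function(formula, data, epsilon = 1e-8, maxit = 100) {
  warn <- character()
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(),
        control = list(epsilon = epsilon, maxit = maxit)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  # separation: glm's own warning, or fitted probabilities driven to the
  # boundary (the deviance can stabilize before glm warns)
  separation <- any(grepl("fitted probabilities numerically 0 or 1",
                          warn, fixed = TRUE)) ||
    any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  structure(list(
    coefficients = coef(fit),
    vcov = vcov(fit),
    converged = isTRUE(fit$converged) && !separation,
    separation = separation,
    n_used = nobs(fit),
    warnings = warn,
    glm = fit
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n=", x$n_used,
      if (!x$converged) "  [NOT CONVERGED]",
      if (x$separation) "  [separation]", "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

# Build the analysis frame for exposure models: status, 0/1 exposure and
# the requested covariates, complete cases only. Covariates that are
# constant on the analysis subset (e.g. smoking within a stratum) are
# dropped - they carry no information and would make the design singular.
.exposure_frame <- function(cohort, combination, covariates, stratum) {
  sub <- stratum_subset(cohort, stratum)
  e <- combination_exposure(sub, combination)
  df <- data.frame(status = sub$subjects$status,
                   exposure = as.integer(e))
  for (cv in covariates) {
    v <- sub$subjects[[cv]]
    if (is.null(v)) stop("unknown covariate: ", cv)
    if (is.character(v)) v <- factor(v)
    df[[cv]] <- v
  }
  df <- df[complete.cases(df), , drop = FALSE]
  keep <- vapply(covariates, function(cv)
    length(unique(df[[cv]])) > 1L, logical(1))
  list(df = df, covariates = covariates[keep])
}

#' Covariate-adjusted odds ratio of a combination
#'
#' Fits `status ~ exposure + covariates` by logistic regression and
#' returns the exponentiated exposure coefficient with its Wald confidence
#' interval. With no covariates this reproduces the crude 2x2 odds ratio
#' exactly (saturated-model identity). Covariates that are constant on the
#' analysis subset are dropped automatically.
#'
#' @param cohort a `snp_cohort`.
#' @param combination a `snp_combination` (or a character specification
#'   parsed against the cohort panel).
#' @param covariates character vector of adjustment columns among
#'   `age`, `gender`, `smoking`, `site` (categoricals are reference-coded
#'   with their first level as reference).
#' @param stratum smoking-stratum selector.
#' @param conf.level confidence level.
#' @return List of class `adjusted_or` with `or`, `ci_lo`, `ci_hi`,
#'   `p`, `n_used` and the underlying `logistic_fit`.
#' @export
adjusted_or <- function(cohort, combination,
                        covariates = c("age", "gender", "smoking", "site"),
                        stratum = "all", conf.level = 0.95) {
  stopifnot(inherits(cohort, "snp_cohort"))
  if (is.character(combination))
    combination <- parse_combination(combination, cohort$panel)
  fr <- .exposure_frame(cohort, combination, covariates, stratum)
  if (length(unique(fr$df$exposure)) < 2L)
    stop("exposure is constant on the analysis subset (rank deficiency)")
  rhs <- paste(c("exposure", fr$covariates), collapse = " + ")
  fit <- fit_logistic(stats::as.formula(paste("status ~", rhs)), fr$df)
  beta <- fit$coefficients["exposure"]
  se <- sqrt(fit$vcov["exposure", "exposure"])
  z <- qnorm(1 - (1 - conf.level) / 2)
  structure(list(
    or = exp(unname(beta)),
    ci_lo = exp(unname(beta) - z * se),
    ci_hi = exp(unname(beta) + z * se),
    p = pchisq((beta / se)^2, df = 1, lower.tail = FALSE),
    n_used = fit$n_used,
    combination = combo_id(combination),
    covariates = fr$covariates,
    fit = fit
  ), class = "adjusted_or")
}

#' @export
print.adjusted_or <- function(x, ...) {
  cat("<adjusted_or> ", x$combination, "\n  OR ",
      format(x$or, digits = 3), " (", format(x$ci_lo, digits = 3), "-",
      format(x$ci_hi, digits = 3), "), p = ", format(x$p, digits = 3),
      ", n = ", x$n_used,
      if (length(x$covariates))
        paste0("\n  adjusted for: ", paste(x$covariates, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Does a combination's odds ratio differ between two smoking strata?
#'
#' Fits the logistic model `status ~ exposure + stratum +
#' exposure:stratum` on the union of two disjoint smoking strata and
#' tests the interaction coefficient with a Wald test. In this
#' covariate-free model `exp(beta_int)` is exactly the ratio of the two
#' stratum-specific odds ratios, so the test asks whether the
#' combination's effect is heterogeneous across strata (e.g. ever smokers
#' versus non-smokers). An adjusted variant is available through
#' `covariates`.
#'
#' @param cohort a `snp_cohort`.
#' @param combination a `snp_combination` or character specification.
#' @param strata length-2 character vector of disjoint stratum selectors;
#'   the second is the reference (default `c("ever", "non")` compares ever
#'   smokers against non-smokers).
#' @param covariates optional adjustment columns (default none, matching
#'   the three-term interaction model).
#' @param conf.level confidence level for the per-stratum ORs.
#' @return List of class `heterogeneity_test` with `beta_int`, `se_int`,
#'   `p_int`, `or_ratio` (`exp(beta_int)`), `or_by_stratum` (data.frame of
#'   crude per-stratum ORs with CIs) and the underlying `logistic_fit`.
#' @export
interaction_test <- function(cohort, combination,
                             strata = c("ever", "non"),
                             covariates = NULL, conf.level = 0.95) {
  stopifnot(inherits(cohort, "snp_cohort"), length(strata) == 2L)
  if (is.character(combination))
    combination <- parse_combination(combination, cohort$panel)
  r1 <- .stratum_rows(cohort, strata[1])
  r2 <- .stratum_rows(cohort, strata[2])
  if (length(intersect(r1, r2)) > 0L)
    stop("strata '", strata[1], "' and '", strata[2], "' overlap")

  e_all <- combination_exposure(cohort, combination)
  build <- function(rows, grp) {
    df <- data.frame(status = cohort$subjects$status[rows],
                     exposure = as.integer(e_all[rows]),
                     grp = grp)
    for (cv in covariates) {
      v <- cohort$subjects[[cv]][rows]
      if (is.character(v)) v <- factor(v)
      df[[cv]] <- v
    }
    df
  }
  df <- rbind(build(r1, 1L), build(r2, 0L))
  df <- df[complete.cases(df), , drop = FALSE]
  for (g in c(0L, 1L))
    if (length(unique(df$exposure[df$grp == g])) < 2L)
      stop("exposure does not vary within stratum '",
           strata[2 - g], "'")
  covs <- covariates[vapply(covariates, function(cv)
    length(unique(df[[cv]])) > 1L, logical(1))]
  rhs <- paste(c("exposure * grp", covs), collapse = " + ")
  fit <- fit_logistic(stats::as.formula(paste("status ~", rhs)), df)
  beta <- fit$coefficients["exposure:grp"]
  se <- sqrt(fit$vcov["exposure:grp", "exposure:grp"])

  or_strata <- do.call(rbind, lapply(c(1L, 0L), function(g) {
    dd <- df[df$grp == g, ]
    a <- sum(dd$exposure == 1L & dd$status == 1L)
    b <- sum(dd$exposure == 1L & dd$status == 0L)
    cc <- sum(dd$exposure == 0L & dd$status == 1L)
    d <- sum(dd$exposure == 0L & dd$status == 0L)
    cbind(data.frame(stratum = strata[2 - g], a = a, b = b, c = cc, d = d),
          odds_ratio_ci(a, b, cc, d, conf.level = conf.level,
                        undefined = "na")[, c("or", "ci_lo", "ci_hi")])
  }))

  structure(list(
    beta_int = unname(beta), se_int = unname(se),
    p_int = unname(pchisq((beta / se)^2, df = 1, lower.tail = FALSE)),
    or_ratio = exp(unname(beta)),
    or_by_stratum = or_strata,
    combination = combo_id(combination),
    strata = strata, covariates = covs, fit = fit
  ), class = "heterogeneity_test")
}

#' @export
print.heterogeneity_test <- function(x, ...) {
  cat("<heterogeneity_test> ", x$combination, " : ", x$strata[1], " vs ",
      x$strata[2], "\n  beta_int = ", format(x$beta_int, digits = 4),
      " (OR ratio ", format(x$or_ratio, digits = 3), "), p = ",
      format(x$p_int, digits = 3), "\n", sep = "")
  print.data.frame(x$or_by_stratum, digits = 3, row.names = FALSE)
  invisible(x)
}
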