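test_that("intercept-only fit recovers the log odds in closed form", {
  d <- data.frame(y = rep(c(1, 0), c(30, 70)))
  fit <- fit_logistic(y ~ 1, d)
  expect_equal(unname(fit$coefficients), log(30 / 70), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$n_used, 100)
})

test_that("perfect separation is flagged rather than silently reported", {
  d <- data.frame(y = rep(c(1, 0), each = 10), x = rep(c(1, 0), each = 10))
  fit <- fit_logistic(y ~ x, d)
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("the unadjusted exposure coefficient equals the crude 2x2 OR", {
  coh <- null_cohort(300, 300, seed = 81)
  cmb <- parse_combination("rs1014971:12,rs9642880:01")
  res <- adjusted_or(coh, cmb, covariates = character(0))
  tab <- two_by_two(coh, cmb)
  crude <- odds_ratio_ci(tab)
  expect_equal(res$or, crude$or, tolerance = 1e-6)
  expect_equal(res$ci_lo, crude$ci_lo, tolerance = 1e-4)
})

test_that("constant exposure is a rank-deficiency error", {
  s <- hand_subjects()
  s$GSTM1 <- 1L
  coh <- snp_cohort(s, mini_panel())
  expect_error(adjusted_or(coh, parse_combination("GSTM1:null", mini_panel()),
                           covariates = character(0)),
               "constant")
})

test_that("adjustment removes planted confounding; the crude OR is biased", {
  cfg <- sim_config(
    strata = list(non = c(cases = 1500, controls = 1500)),
    effects = list(list(combination = "rs1014971:12", stratum = "all",
                        or = 1.5)),
    confounder = list(prob = 0.4, or = 3, freq_factor = 1.5))
  coh <- simulate_cohort(cfg, seed = 42)
  cmb <- parse_combination("rs1014971:12")
  crude <- adjusted_or(coh, cmb, covariates = character(0))
  adj <- adjusted_or(coh, cmb, covariates = "site")
  expect_gt(adj$ci_hi, 1.5)   # adjusted CI covers the planted OR
  expect_lt(adj$ci_lo, 1.5)
  expect_lt(abs(log(adj$or) - log(1.5)),
            abs(log(crude$or) - log(1.5)))  # crude is further from truth
})

test_that("adjusting for independent covariates leaves the OR untouched", {
  cfg <- sim_config(
    strata = list(non = c(cases = 800, controls = 800)),
    effects = list(list(combination = "rs9642880:12", stratum = "all",
                        or = 1.8)))
  coh <- simulate_cohort(cfg, seed = 83)
  cmb <- parse_combination("rs9642880:12")
  crude <- adjusted_or(coh, cmb, covariates = character(0))
  adj <- adjusted_or(coh, cmb, covariates = c("gender", "site"))
  expect_lt(abs(log(adj$or) - log(crude$or)), 0.1)
})

test_that("identical strata give an exactly null interaction", {
  base <- null_cohort(100, 100, seed = 84, panel = mini_panel())
  dup <- base$subjects
  dup$smoking <- "former"
  dup$id <- paste0("X", dup$id)
  both <- snp_cohort(rbind(base$subjects, dup), base$panel)
  it <- interaction_test(both, parse_combination("rs1014971:12", mini_panel()),
                         strata = c("ever", "non"))
  expect_equal(it$beta_int, 0, tolerance = 1e-8)
})

test_that("exp(beta_int) equals the stratum OR ratio in the saturated model", {
  cfg <- sim_config(
    strata = list(non = c(cases = 300, controls = 300),
                  former = c(cases = 300, controls = 300)),
    effects = list(list(combination = "rs1014971:12", stratum = "non",
                        or = 2.0)))
  coh <- simulate_cohort(cfg, seed = 85)
  it <- interaction_test(coh, "rs1014971:12", strata = c("ever", "non"))
  ors <- it$or_by_stratum
  expect_equal(it$or_ratio, ors$or[1] / ors$or[2], tolerance = 1e-6)
  expect_true(all(ors$stratum == c("ever", "non")))
})

test_that("overlapping strata selectors are rejected", {
  coh <- simulate_cohort(sim_config(strata = list(
    former = c(cases = 50, controls = 50),
    current = c(cases = 50, controls = 50))), seed = 86)
  expect_error(interaction_test(coh, "rs1014971:12",
                                strata = c("ever", "current")),
               "overlap")
})

test_that("the interaction test keeps its nominal type-I error", {
  cfg <- sim_config(strata = list(non = c(cases = 150, controls = 150),
                                  former = c(cases = 150, controls = 150)))
  cmb <- parse_combination("rs9642880:12")
  reps <- 1000
  hits <- 0L
  for (r in seq_len(reps)) {
    coh <- simulate_cohort(cfg, seed = 10000 + r)
    p <- interaction_test(coh, cmb, strata = c("ever", "non"))$p_int
    hits <- hits + (p < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(hits / reps - 0.05), 2 * se + 1e-9)
})

test_that("planted stratum heterogeneity is detected with good power", {
  cfg <- sim_config(
    strata = list(non = c(cases = 750, controls = 750),
                  former = c(cases = 750, controls = 750)),
    effects = list(list(combination = "rs1014971:12,rs8102137:12",
                        stratum = "non", or = 2.0)))
  ps <- vapply(1:20, function(r) {
    coh <- simulate_smoker_contrast(cfg, seed = 300 + r)
    interaction_test(coh, "rs1014971:12,rs8102137:12",
                     strata = c("ever", "non"))$p_int
  }, numeric(1))
  expect_lt(median(ps), 0.05)
  expect_gt(mean(ps < 0.05), 0.6)
})
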