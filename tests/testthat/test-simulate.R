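test_that("stratum quotas are met exactly and runs are seed-identical", {
  cfg <- sim_config(strata = list(non = c(cases = 40, controls = 60),
                                  current = c(cases = 25, controls = 15)))
  coh <- simulate_cohort(cfg, seed = 101)
  counts <- cohort_counts(coh)
  expect_equal(counts$cases[counts$stratum == "non"], 40L)
  expect_equal(counts$controls[counts$stratum == "non"], 60L)
  expect_equal(counts$cases[counts$stratum == "current"], 25L)
  expect_equal(counts$controls[counts$stratum == "current"], 15L)

  coh2 <- simulate_cohort(cfg, seed = 101)
  expect_identical(coh$subjects, coh2$subjects)
  # byte-identical after serialization
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_cohort(coh, f1); write_cohort(coh2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(coh$subjects,
                         simulate_cohort(cfg, seed = 102)$subjects))
})

test_that("control allele frequencies match the configured values", {
  coh <- null_cohort(1000, 2000, seed = 103)
  ctrl <- coh$subjects[coh$subjects$status == 0L, ]
  panel <- coh$panel
  for (i in which(panel$type == "snp")) {
    f <- panel$freq[i]
    emp <- mean(ctrl[[panel$name[i]]]) / 2
    se <- sqrt(f * (1 - f) / (2 * nrow(ctrl)))
    expect_lt(abs(emp - f), 3 * se + 1e-9)
  }
  i <- which(panel$type == "binary")
  emp <- mean(ctrl[[panel$name[i]]])
  se <- sqrt(panel$freq[i] * (1 - panel$freq[i]) / nrow(ctrl))
  expect_lt(abs(emp - panel$freq[i]), 3 * se)
})

test_that("simulated controls are consistent with Hardy-Weinberg", {
  ok <- 0L; total <- 0L
  for (r in 1:50) {
    coh <- null_cohort(100, 500, seed = 200 + r)
    h <- hwe_check(coh)
    hc <- h[h$group == "control", ]
    ok <- ok + sum(hc$p > 0.001)
    total <- total + nrow(hc)
  }
  expect_gte(ok / total, 0.99)
})

test_that("a planted conjunction effect attains its conditional OR", {
  cfg <- sim_config(
    strata = list(non = c(cases = 2000, controls = 2000)),
    effects = list(list(combination = "rs1014971:12,rs8102137:12",
                        stratum = "all", or = 2.0)))
  cmb <- parse_combination("rs1014971:12,rs8102137:12")
  covered <- 0L
  for (r in 1:25) {
    coh <- simulate_cohort(cfg, seed = 400 + r)
    est <- adjusted_or(coh, cmb, covariates = character(0))
    covered <- covered + (est$ci_lo <= 2 && 2 <= est$ci_hi)
  }
  expect_gte(covered, 21L)  # ~95% coverage of the planted conditional OR
})

test_that("null cohorts produce null two-way scans", {
  coh <- null_cohort(2500, 2500, seed = 105)
  sc <- combo_scan(coh, 2)
  expect_gte(mean(sc$ci_lo <= 1 & 1 <= sc$ci_hi), 0.90)
})

test_that("infeasible or malformed configurations are rejected", {
  expect_error(sim_config(strata = list()), "named list")
  expect_error(sim_config(strata = list(non = c(cases = 0, controls = 5))),
               "cases >= 1")
  expect_error(sim_config(baseline = 1.5), "baseline")
  expect_error(sim_config(effects = list(
    list(combination = "rs1014971:12", or = -2))), "odds ratio")
  expect_error(sim_config(effects = list(
    list(combination = "rs1014971:12", stratum = "former", or = 2),
    list(combination = "rs1014971:12", stratum = "non", or = 2)),
    strata = list(non = c(cases = 10, controls = 10))),
    "not configured")
  expect_error(sim_config(confounder = list(prob = 0.5, or = 2,
                                            freq_factor = 3)),
               "infeasible")
})

test_that("the smoker-contrast wrapper enforces a two-stratum design", {
  one <- sim_config(strata = list(non = c(cases = 20, controls = 20)),
                    effects = list(list(combination = "rs1014971:12",
                                        stratum = "non", or = 2)))
  expect_error(simulate_smoker_contrast(one, seed = 1), "two configured")
  flat <- sim_config(strata = list(non = c(cases = 20, controls = 20),
                                   former = c(cases = 20, controls = 20)))
  expect_error(simulate_smoker_contrast(flat, seed = 1), "stratum-specific")
  good <- sim_config(strata = list(non = c(cases = 50, controls = 50),
                                   former = c(cases = 50, controls = 50)),
                     effects = list(list(combination = "rs1014971:12",
                                         stratum = "non", or = 2)))
  expect_s3_class(simulate_smoker_contrast(good, seed = 1), "snp_cohort")
})

test_that("YAML scenarios reproduce sim_config objects", {
  scen <- system.file("extdata", "study_scenario.yaml",
                      package = "snpcombo")
  expect_true(nzchar(scen))
  cfg <- read_scenario(scen)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$strata$non, c(cases = 321L, controls = 752L))
  expect_equal(cfg$strata$current, c(cases = 431L, controls = 315L))
  coh <- simulate_cohort(cfg, seed = 9)
  expect_equal(nrow(coh$subjects), 3217L)
})
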