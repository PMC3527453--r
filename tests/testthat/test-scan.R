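test_that("two_by_two tallies exposure against status", {
  coh <- hand_cohort()
  cmb <- parse_combination("rs1014971:12,GSTM1:null", mini_panel())
  # hand tally: exposed cases P1,P2,P4; unexposed case P3; exposed
  # controls none; unexposed controls P5,P6,P7; P8 missing -> dropped
  tab <- two_by_two(coh, cmb, "all")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(3, 0, 1, 3))
  expect_equal(tab$n_dropped, 1L)

  # perfect separation: exposure identical to status
  s <- hand_subjects()[1:6, ]
  s$rs1014971 <- ifelse(s$status == 1, 2L, 0L)
  sep <- snp_cohort(s, mini_panel())
  tsep <- two_by_two(sep, parse_combination("rs1014971:2", mini_panel()))
  expect_equal(tsep$b, 0)
  expect_equal(tsep$c, 0)

  # brute-force row-by-row oracle on a simulated cohort
  coh2 <- null_cohort(150, 150, seed = 21)
  cmb2 <- parse_combination("rs1014971:12,rs9642880:0,GSTM1:1")
  tab2 <- two_by_two(coh2, cmb2, "all")
  s2 <- coh2$subjects
  exp_manual <- vapply(seq_len(nrow(s2)), function(i) {
    g <- c(s2$rs1014971[i], s2$rs9642880[i], s2$GSTM1[i])
    if (anyNA(g)) NA else
      (g[1] %in% 1:2) && (g[2] == 0) && (g[3] == 1)
  }, logical(1))
  expect_equal(tab2$a, sum(exp_manual & s2$status == 1, na.rm = TRUE))
  expect_equal(tab2$b, sum(exp_manual & s2$status == 0, na.rm = TRUE))
  expect_equal(tab2$c, sum(!exp_manual & s2$status == 1, na.rm = TRUE))
  expect_equal(tab2$d, sum(!exp_manual & s2$status == 0, na.rm = TRUE))
})

test_that("odds ratio and Woolf interval match closed forms", {
  r <- odds_ratio_ci(431, 315, 321, 752)
  expect_equal(round(r$or, 2), 3.21)
  expect_equal(round(r$ci_lo, 2), 2.64)
  expect_equal(round(r$ci_hi, 2), 3.90)
  expect_equal(odds_ratio_ci(10, 10, 10, 10)$or, 1.0)
  expect_equal(odds_ratio_ci(20, 5, 10, 40)$or, 16.0)

  # single zero cell: Haldane-Anscombe +0.5 everywhere
  rz <- odds_ratio_ci(0, 5, 10, 40)
  expect_true(rz$corrected)
  expect_equal(rz$or, (0.5 * 40.5) / (5.5 * 10.5))

  # empty margin: undefined
  expect_error(odds_ratio_ci(0, 0, 10, 40), "undefined")
  rna <- odds_ratio_ci(0, 0, 10, 40, undefined = "na")
  expect_true(rna$undefined)
  expect_true(is.na(rna$or))
})

test_that("Wald statistic equals (log OR / SE)^2 and squares the z-test", {
  w <- wald_stat_p(431, 315, 321, 752)
  lor <- log((431 * 752) / (315 * 321))
  se <- sqrt(1 / 431 + 1 / 315 + 1 / 321 + 1 / 752)
  expect_equal(w$wald, (lor / se)^2, tolerance = 1e-12)
  # chi2(1) upper tail == two-sided normal tail of z = lor/se
  expect_equal(w$p_raw, 2 * pnorm(-abs(lor / se)), tolerance = 1e-12)
  expect_equal(wald_stat_p(1, 1, 1, 1)$wald, 0)
  expect_equal(wald_stat_p(10, 10, 10, 10)$p_raw, 1)
})

test_that("Bonferroni correction caps at one", {
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(1e-4, 288), 0.0288)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_equal(bonferroni(c(0.001, 0.9), 10), c(0.01, 1))
  expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
  expect_error(bonferroni(0.5, 0), "m must")
})

test_that("scan scores or excludes exactly the enumerated candidates", {
  coh <- null_cohort(250, 250, seed = 31)
  sc <- combo_scan(coh, 2)
  expect_equal(attr(sc, "m"), 288)
  expect_equal(nrow(sc) + length(attr(sc, "excluded")), 288)
  expect_equal(sc$p_adj, pmin(1, 288 * sc$p_raw))
  expect_equal(sc$rank, seq_len(nrow(sc)))
  # p-ranking is non-decreasing in raw p
  expect_true(all(diff(sc$p_raw) >= 0))
  # low-count flag
  expect_equal(sc$flagged, sc$a < 100 | sc$b < 100)
  # or-metric variant ranks by descending OR
  sor <- combo_scan(coh, 2, metric = "or")
  expect_true(all(diff(sor$or) <= 0))
})

test_that("scan rankings are invariant to row and column order", {
  coh <- null_cohort(200, 200, seed = 33)
  sc <- combo_scan(coh, 2)

  set.seed(1)
  perm <- sample(nrow(coh$subjects))
  shuf <- snp_cohort(coh$subjects[perm, ], coh$panel)
  expect_equal(combo_scan(shuf, 2)$combination, sc$combination)

  rev_panel <- coh$panel[rev(seq_len(nrow(coh$panel))), ]
  rownames(rev_panel) <- NULL
  expect_equal(combo_scan(snp_cohort(coh$subjects, rev_panel), 2)$combination,
               sc$combination)
})

test_that("complement indicators have exactly reciprocal odds ratios", {
  coh <- null_cohort(400, 400, seed = 35)
  sc <- combo_scan(coh, 1)
  df <- as.data.frame(sc)
  combos <- attr(sc, "combinations")
  for (id in df$combination) {
    comp_id <- combo_id(snp_combination(
      complement_indicator(combos[[id]]$indicators[[1]])))
    j <- match(comp_id, df$combination)
    if (is.na(j)) next
    row <- df[df$combination == id, ]
    if (min(row$a, row$b, row$c, row$d) == 0) next  # Haldane-corrected
    expect_equal(row$or * df$or[j], 1, tolerance = 1e-10)
    expect_equal(row$wald, df$wald[j], tolerance = 1e-8)
  }
})

test_that("a planted two-way conjunction is recovered at rank one", {
  cfg <- sim_config(
    strata = list(non = c(cases = 2000, controls = 2000)),
    effects = list(list(combination = "rs1014971:12,rs8102137:12",
                        stratum = "all", or = 2.5)))
  coh <- simulate_cohort(cfg, seed = 91)
  sc <- combo_scan(coh, 2)
  expect_equal(sc$combination[1], "rs1014971:12,rs8102137:12")
  expect_gt(sc$or[1], 2)
  expect_lt(sc$p_adj[1], 0.001)
})

test_that("Woolf intervals attain close to nominal coverage", {
  set.seed(55)
  n <- 1000
  p_ctrl <- 0.3
  p_case <- plogis(qlogis(p_ctrl) + log(2))  # true OR = 2
  hits <- 0L
  for (r in 1:400) {
    a <- rbinom(1, n, p_case); b <- rbinom(1, n, p_ctrl)
    ci <- odds_ratio_ci(a, b, n - a, n - b, undefined = "na")
    hits <- hits + (!is.na(ci$or) && ci$ci_lo <= 2 && 2 <= ci$ci_hi)
  }
  expect_gte(hits / 400, 0.92)
  expect_lte(hits / 400, 0.98)
})

test_that("optimal profile returns one top row per order", {
  coh <- null_cohort(200, 200, seed = 61, panel = mini_panel())
  pr <- optimal_profile(coh, ks = 1:3)
  expect_equal(pr$k, 1:3)
  expect_true(all(c("or", "ci_lo", "ci_hi", "flagged") %in% names(pr)))
})
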