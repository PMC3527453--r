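# Vectorized scoring of 2x2 tables (a = exposed cases, b = exposed controls,
# c = unexposed cases, d = unexposed controls). A table is undefined when a
# full margin is empty before correction; otherwise the Haldane-Anscombe
# +0.5 correction is applied when any single cell is zero.
.score_tables <- function(a, b, c, d, conf.level = 0.95) {
  undefined <- (a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0
  corrected <- !undefined & (a == 0 | b == 0 | c == 0 | d == 0)
  h <- 0.5 * corrected
  a2 <- a + h; b2 <- b + h; c2 <- c + h; d2 <- d + h
  log_or <- log(a2) + log(d2) - log(b2) - log(c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  z <- qnorm(1 - (1 - conf.level) / 2)
  or <- exp(log_or)
  wald <- (log_or / se)^2
  out <- list(
    or = or, ci_lo = exp(log_or - z * se), ci_hi = exp(log_or + z * se),
    se_log = se, wald = wald,
    p_raw = pchisq(wald, df = 1, lower.tail = FALSE),
    corrected = corrected, undefined = undefined
  )
  for (nm in c("or", "ci_lo", "ci_hi", "se_log", "wald", "p_raw"))
    out[[nm]][undefined] <- NA_real_
  out
}

.check_cells <- function(a, b, c, d) {
  if (anyNA(c(a, b, c, d)) || any(c(a, b, c, d) < 0))
    stop("cell counts must be non-negative numbers")
  n <- c(length(a), length(b), length(c), length(d))
  if (length(unique(n)) != 1L) stop("cell vectors must have equal length")
}

#' 2x2 exposure-by-status table for a combination
#'
#' Tallies conjunction exposure against case-control status within a smoking
#' stratum. Subjects with a missing genotype at any member polymorphism have
#' undefined exposure and are dropped from the table (complete-case per
#' combination).
#'
#' @param cohort a `snp_cohort`.
#' @param combination a `snp_combination`.
#' @param stratum smoking-stratum selector, see [stratum_subset()].
#' @return List of class `xtab2x2` with cells `a` (exposed cases), `b`
#'   (exposed controls), `c` (unexposed cases), `d` (unexposed controls)
#'   and `n_dropped` (subjects with undefined exposure).
#' @export
two_by_two <- function(cohort, combination, stratum = "all") {
  stopifnot(inherits(cohort, "snp_cohort"),
            inherits(combination, "snp_combination"))
  sub <- stratum_subset(cohort, stratum)
  e <- combination_exposure(sub, combination)
  st <- sub$subjects$status
  ok <- !is.na(e)
  structure(list(
    a = sum(e[ok] & st[ok] == 1L), b = sum(e[ok] & st[ok] == 0L),
    c = sum(!e[ok] & st[ok] == 1L), d = sum(!e[ok] & st[ok] == 0L),
    n_dropped = sum(!ok), stratum = stratum,
    combination = combo_id(combination)
  ), class = "xtab2x2")
}

#' @export
print.xtab2x2 <- function(x, ...) {
  cat("<2x2> ", x$combination, " [", x$stratum, "]\n", sep = "")
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("cases", "controls")))
  print(m)
  if (x$n_dropped > 0)
    cat(x$n_dropped, "subject(s) dropped (undefined exposure)\n")
  invisible(x)
}

.unpack_cells <- function(a, b, c, d) {
  if (inherits(a, "xtab2x2")) return(list(a = a$a, b = a$b, c = a$c, d = a$d))
  if (is.null(b) && length(a) == 4L)
    return(list(a = a[[1]], b = a[[2]], c = a[[3]], d = a[[4]]))
  list(a = a, b = b, c = c, d = d)
}

#' Odds ratio with Woolf confidence interval
#'
#' Computes `OR = ad/(bc)` with the Woolf (log-scale) interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any single cell
#' is zero the Haldane-Anscombe correction (+0.5 to all four cells) is
#' applied; a table with an entirely empty margin has no defined OR and
#' raises an error (or returns `NA` with `undefined = "na"`). All arguments
#' are vectorized.
#'
#' @param a exposed cases; alternatively an `xtab2x2` from [two_by_two()]
#'   or a length-4 vector `c(a, b, c, d)`.
#' @param b exposed controls.
#' @param c unexposed cases.
#' @param d unexposed controls.
#' @param conf.level confidence level of the interval.
#' @param undefined `"error"` (default) or `"na"` for tables with an empty
#'   margin.
#' @return data.frame with columns `or`, `ci_lo`, `ci_hi`, `se_log`,
#'   `corrected` (Haldane correction applied), `undefined`.
#' @examples
#' odds_ratio_ci(431, 315, 321, 752)  # OR 3.21 (2.64-3.90)
#' @export
odds_ratio_ci <- function(a, b = NULL, c = NULL, d = NULL,
                          conf.level = 0.95,
                          undefined = c("error", "na")) {
  undefined <- match.arg(undefined)
  cell <- .unpack_cells(a, b, c, d)
  .check_cells(cell$a, cell$b, cell$c, cell$d)
  sc <- .score_tables(cell$a, cell$b, cell$c, cell$d, conf.level)
  if (undefined == "error" && any(sc$undefined))
    stop("undefined odds ratio: a margin of the 2x2 table is empty")
  data.frame(or = sc$or, ci_lo = sc$ci_lo, ci_hi = sc$ci_hi,
             se_log = sc$se_log, corrected = sc$corrected,
             undefined = sc$undefined)
}

#' Wald statistic and parametric p-value of a 2x2 odds ratio
#'
#' `wald = (log OR / SE)^2` with the Woolf standard error, referred to the
#' upper tail of the chi-squared distribution with one degree of freedom.
#' Zero-cell handling follows [odds_ratio_ci()].
#'
#' @inheritParams odds_ratio_ci
#' @return data.frame with columns `wald`, `p_raw`, `corrected`,
#'   `undefined`.
#' @export
wald_stat_p <- function(a, b = NULL, c = NULL, d = NULL,
                        undefined = c("error", "na")) {
  undefined <- match.arg(undefined)
  cell <- .unpack_cells(a, b, c, d)
  .check_cells(cell$a, cell$b, cell$c, cell$d)
  sc <- .score_tables(cell$a, cell$b, cell$c, cell$d)
  if (undefined == "error" && any(sc$undefined))
    stop("undefined Wald statistic: a margin of the 2x2 table is empty")
  data.frame(wald = sc$wald, p_raw = sc$p_raw,
             corrected = sc$corrected, undefined = sc$undefined)
}

#' Bonferroni correction
#'
#' @param p_raw raw p-value(s) in `[0, 1]`.
#' @param m number of tests in the family, `m >= 1`.
#' @return `min(1, m * p_raw)`, vectorized.
#' @export
bonferroni <- function(p_raw, m) {
  if (anyNA(p_raw) || any(p_raw < 0 | p_raw > 1))
    stop("p_raw must lie in [0, 1]")
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("m must be a single integer >= 1")
  pmin(1, m * p_raw)
}

# Exposure-by-status cell counts for every column of an exposure matrix,
# optionally on a (resampled) row index.
.tabulate_exposure <- function(E, status, rows = NULL) {
  if (!is.null(rows)) {
    E <- E[rows, , drop = FALSE]
    status <- status[rows]
  }
  ca <- status == 1L
  Eca <- E[ca, , drop = FALSE]
  Eco <- E[!ca, , drop = FALSE]
  list(a = colSums(Eca, na.rm = TRUE), b = colSums(Eco, na.rm = TRUE),
       c = colSums(!Eca, na.rm = TRUE), d = colSums(!Eco, na.rm = TRUE))
}

# Ranking order for scored tables. Metric "p": ascending raw p; "or":
# descending OR. Ties broken by larger |log OR|, then lexicographic id.
.rank_order <- function(sc, ids, metric) {
  key <- switch(metric, p = sc$p_raw, or = -sc$or)
  order(key, -abs(log(sc$or)), ids, na.last = NA)
}

#' Exhaustive scan of k-way combinations
#'
#' Scores every admissible k-way combination of the cohort's panel in a
#' smoking stratum with the crude odds ratio, Woolf confidence interval,
#' Wald statistic and Bonferroni-adjusted p-value, and returns a
#' deterministic ranking. The Bonferroni denominator `m` is the number of
#' enumerated candidates of order `k` (e.g. 288 for two-way scans of the
#' default panel). Combinations whose 2x2 table has an empty margin (no
#' exposed subject in either group, or no unexposed one) have no defined OR;
#' they are excluded from the ranking and listed in
#' `attr(result, "excluded")`.
#'
#' Ranking is by raw p-value (`metric = "p"`, two-sided, so protective
#' ORs below 1 compete on equal terms) or by descending OR
#' (`metric = "or"`); ties are broken by larger absolute log OR, then by
#' the combination identifier. Rows where the exposed-case or
#' exposed-control count falls below `flag_threshold` are flagged, since
#' such ORs rest on few subjects and should be interpreted with caution.
#'
#' @param cohort a `snp_cohort`.
#' @param k combination order, 1-7.
#' @param stratum smoking-stratum selector, see [stratum_subset()].
#' @param metric `"p"` or `"or"`.
#' @param top_n optionally return only the best `top_n` rows.
#' @param conf.level confidence level for the Woolf intervals.
#' @param flag_threshold flag results with `a` or `b` below this count.
#' @return data.frame of class `combo_scan`, one row per scored
#'   combination in rank order, with columns `rank`, `combination`,
#'   `label`, `a`, `b`, `c`, `d`, `or`, `ci_lo`, `ci_hi`, `wald`, `p_raw`,
#'   `p_adj`, `flagged`. Attributes: `k`, `stratum`, `metric`, `m`
#'   (Bonferroni denominator), `excluded` (ids of unscorable candidates),
#'   `combinations` (named list of the scored `snp_combination` objects).
#' @examples
#' coh <- simulate_cohort(sim_config(strata = list(
#'   non = c(cases = 200, controls = 200))), seed = 1)
#' head(combo_scan(coh, k = 1))
#' @export
combo_scan <- function(cohort, k, stratum = "all", metric = c("p", "or"),
                       top_n = NULL, conf.level = 0.95,
                       flag_threshold = 100) {
  stopifnot(inherits(cohort, "snp_cohort"))
  metric <- match.arg(metric)
  sub <- stratum_subset(cohort, stratum)
  combos <- enumerate_combinations(cohort$panel, k)
  ids <- vapply(combos, combo_id, character(1))
  E <- .exposure_matrix(sub$subjects, combos)
  cnt <- .tabulate_exposure(E, sub$subjects$status)
  sc <- .score_tables(cnt$a, cnt$b, cnt$c, cnt$d, conf.level)
  m <- length(combos)
  if (all(sc$undefined)) stop("no scorable combination in stratum '",
                              stratum, "'")
  ord <- .rank_order(sc, ids, metric)
  res <- data.frame(
    rank = seq_along(ord),
    combination = ids[ord],
    label = vapply(combos[ord], combo_label, character(1),
                   panel = cohort$panel),
    a = cnt$a[ord], b = cnt$b[ord], c = cnt$c[ord], d = cnt$d[ord],
    or = sc$or[ord], ci_lo = sc$ci_lo[ord], ci_hi = sc$ci_hi[ord],
    wald = sc$wald[ord], p_raw = sc$p_raw[ord],
    p_adj = bonferroni(sc$p_raw[ord], m),
    flagged = cnt$a[ord] < flag_threshold | cnt$b[ord] < flag_threshold,
    stringsAsFactors = FALSE
  )
  if (!is.null(top_n)) res <- head(res, top_n)
  structure(res,
            k = k, stratum = stratum, metric = metric, m = m,
            excluded = ids[sc$undefined],
            combinations = setNames(combos[ord], ids[ord]),
            class = c("combo_scan", "data.frame"))
}

#' @export
print.combo_scan <- function(x, n = 10L, ...) {
  cat("<combo_scan> k=", attr(x, "k"), " stratum=", attr(x, "stratum"),
      " metric=", attr(x, "metric"), " m=", attr(x, "m"),
      " (", length(attr(x, "excluded")), " excluded)\n", sep = "")
  cols <- c("rank", "label", "a", "b", "or", "ci_lo", "ci_hi", "p_adj",
            "flagged")
  print.data.frame(head(as.data.frame(x)[, cols], n), digits = 3,
                   row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Optimal-OR profile over combination orders
#'
#' For each order `k` in `ks`, runs [combo_scan()] and reports the best
#' combination under the chosen metric, mirroring profile plots of the
#' optimal odds ratio against the number of combined polymorphisms.
#'
#' @inheritParams combo_scan
#' @param ks vector of combination orders.
#' @return data.frame with one row per `k`: the top-ranked combination,
#'   its OR, CI, adjusted p and low-count flag.
#' @export
optimal_profile <- function(cohort, ks = 1:3, stratum = "all",
                            metric = c("p", "or"), flag_threshold = 100) {
  metric <- match.arg(metric)
  rows <- lapply(ks, function(k) {
    top <- combo_scan(cohort, k, stratum, metric,
                      top_n = 1L, flag_threshold = flag_threshold)
    cbind(data.frame(k = k), as.data.frame(top)[, c(
      "combination", "label", "a", "b", "or", "ci_lo", "ci_hi",
      "p_raw", "p_adj", "flagged")])
  })
  do.call(rbind, rows)
}
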