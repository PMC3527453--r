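#' Bootstrap stability of the top-ranked combinations
#'
#' Assesses how stable the ranks of the original top combinations are:
#' the stratum's cases and controls are resampled with replacement at
#' their original sizes (stratified bootstrap, preserving the case-control
#' balance), the full k-way scan is repeated on each replicate with
#' identical settings, and for each of the original top `n_top`
#' combinations the number of replicates in which it re-enters the top
#' lists of the requested sizes is counted.
#'
#' Replicate tables with a zero cell are scored with the Haldane-Anscombe
#' correction, consistent with [combo_scan()]; a combination that is
#' wholly unexposed (or unrepresented) within a replicate has no defined
#' OR there and simply cannot enter that replicate's top lists (tallied in
#' `attr(result, "n_undefined")`).
#'
#' @inheritParams combo_scan
#' @param B number of bootstrap replicates.
#' @param sizes top-list sizes to tally membership in.
#' @param n_top number of original top combinations that are tracked.
#' @param seed optional integer seed; with a fixed seed the report is
#'   reproducible bit-for-bit.
#' @param resample `"stratified"` (the bootstrap) or `"none"`
#'   (identity resampling, a diagnostic path in which every original top
#'   combination trivially reappears in every replicate).
#' @return data.frame of class `stability_report` with one row per
#'   original top combination (`rank`, `combination`, `label`, `or`) and
#'   one count column per requested size (`top10`, `top20`, ...). Counts
#'   are monotone non-decreasing across the list sizes. Attributes: `B`,
#'   `sizes`, `seed`, `k`, `stratum`, `metric`, `n_undefined`.
#' @examples
#' coh <- simulate_cohort(sim_config(strata = list(
#'   non = c(cases = 150, controls = 150))), seed = 1)
#' bootstrap_stability(coh, k = 1, stratum = "non", B = 20, seed = 7)
#' @export
bootstrap_stability <- function(cohort, k, stratum = "all", B = 500,
                                sizes = c(10, 20, 50), n_top = 10,
                                metric = c("p", "or"), seed = NULL,
                                resample = c("stratified", "none")) {
  stopifnot(inherits(cohort, "snp_cohort"), B >= 1)
  metric <- match.arg(metric)
  resample <- match.arg(resample)
  sizes <- sort(unique(as.integer(sizes)))
  if (!is.null(seed)) set.seed(seed)

  sub <- stratum_subset(cohort, stratum)
  status <- sub$subjects$status
  ca_rows <- which(status == 1L)
  co_rows <- which(status == 0L)
  if (length(ca_rows) < 1L || length(co_rows) < 1L)
    stop("stratum '", stratum, "' has no cases or no controls to resample")

  combos <- enumerate_combinations(cohort$panel, k)
  ids <- vapply(combos, combo_id, character(1))
  E <- .exposure_matrix(sub$subjects, combos)
  cnt <- .tabulate_exposure(E, status)
  sc <- .score_tables(cnt$a, cnt$b, cnt$c, cnt$d)
  ord <- .rank_order(sc, ids, metric)
  if (length(ord) == 0L) stop("original scan has no scorable combination")
  n_top <- min(n_top, length(ord))
  top_idx <- ord[seq_len(n_top)]
  top_ids <- ids[top_idx]

  counts <- matrix(0L, n_top, length(sizes),
                   dimnames = list(top_ids, paste0("top", sizes)))
  n_undefined <- 0L
  for (b in seq_len(B)) {
    idx <- if (resample == "none") seq_along(status) else
      c(sample(ca_rows, replace = TRUE), sample(co_rows, replace = TRUE))
    cb <- .tabulate_exposure(E, status, idx)
    sb <- .score_tables(cb$a, cb$b, cb$c, cb$d)
    n_undefined <- n_undefined + sum(sb$undefined)
    ob <- .rank_order(sb, ids, metric)
    ranked <- ids[ob]
    for (si in seq_along(sizes)) {
      inlist <- top_ids %in% head(ranked, sizes[si])
      counts[, si] <- counts[, si] + inlist
    }
  }

  res <- data.frame(
    rank = seq_len(n_top), combination = top_ids,
    label = vapply(combos[top_idx], combo_label, character(1),
                   panel = cohort$panel),
    or = sc$or[top_idx], stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(counts, row.names = NULL))
  structure(res, B = B, sizes = sizes, seed = seed, k = k,
            stratum = stratum, metric = metric, n_undefined = n_undefined,
            class = c("stability_report", "data.frame"))
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> B=", attr(x, "B"), " k=", attr(x, "k"),
      " stratum=", attr(x, "stratum"), "\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 3, row.names = FALSE)
  invisible(x)
}

# Wald statistics for P hypergeometric draws of the exposed-case cell under
# case-control label permutation with all four margins fixed.
.perm_wald <- function(P, n_case, n_ctrl, n_exposed) {
  a <- rhyper(P, n_case, n_ctrl, n_exposed)
  b <- n_exposed - a
  c <- n_case - a
  d <- n_ctrl - b
  corr <- 0.5 * (a == 0 | b == 0 | c == 0 | d == 0)
  a <- a + corr; b <- b + corr; c <- c + corr; d <- d + corr
  log_or <- log(a) + log(d) - log(b) - log(c)
  log_or^2 / (1 / a + 1 / b + 1 / c + 1 / d)
}

#' Permutation calibration of the parametric chi-squared(1) p-values
#'
#' For each combination, the case-control labels of the subjects with
#' defined exposure are permuted `P` times while the exposure column is
#' held fixed, and the Wald statistic is recomputed on each permuted 2x2
#' table. If the chi-squared(1) reference is adequate, the mean of the
#' permuted statistics is approximately 1 and their variance approximately
#' 2, and the permutation p-value `(r + 1) / (P + 1)` (with `r` the number
#' of permuted statistics at or above the observed one) is close to the
#' parametric tail probability. With sparse exposure - rare high-order
#' conjunctions - the approximation degrades, which is exactly what this
#' report is designed to reveal.
#'
#' Because the exposure column is fixed and the permutation only reassigns
#' labels, all four margins of the permuted table are fixed and the table
#' is determined by its exposed-case cell, whose permutation distribution
#' is hypergeometric; the statistics are therefore drawn directly from
#' that distribution, which is equivalent to explicit label shuffling.
#' Permuted tables with a zero cell are scored with the Haldane-Anscombe
#' correction, consistent with [combo_scan()]. A combination that is
#' wholly unexposed (or lacks cases or controls) after dropping undefined
#' subjects contributes no statistic; its row is `NA` and counted in the
#' `skipped` column.
#'
#' @param cohort a `snp_cohort`.
#' @param combinations a `snp_combination`, a list of them, or character
#'   identifiers parsed against the cohort panel (see
#'   [parse_combination()]).
#' @param P number of permutations.
#' @param stratum smoking-stratum selector.
#' @param seed optional integer seed for reproducibility.
#' @return data.frame of class `calibration_report`, one row per
#'   combination: `combination`, `wald_obs`, `p_raw`, `p_perm`,
#'   `mean_stat`, `var_stat`, `skipped`. Attributes `P`, `stratum`,
#'   `seed`.
#' @examples
#' coh <- simulate_cohort(sim_config(strata = list(
#'   non = c(cases = 100, controls = 100))), seed = 1)
#' cmb <- parse_combination("rs1014971:01,rs9642880:01", coh$panel)
#' permutation_calibration(coh, cmb, P = 2000, seed = 3)
#' @export
permutation_calibration <- function(cohort, combinations, P = 10000,
                                    stratum = "all", seed = NULL) {
  stopifnot(inherits(cohort, "snp_cohort"), P >= 1)
  if (inherits(combinations, "snp_combination"))
    combinations <- list(combinations)
  if (is.character(combinations))
    combinations <- lapply(combinations, parse_combination,
                           panel = cohort$panel)
  if (!is.null(seed)) set.seed(seed)

  sub <- stratum_subset(cohort, stratum)
  status <- sub$subjects$status
  rows <- lapply(combinations, function(cmb) {
    e <- combination_exposure(sub, cmb)
    ok <- !is.na(e)
    e <- e[ok]; st <- status[ok]
    n_case <- sum(st == 1L); n_ctrl <- sum(st == 0L); n_exp <- sum(e)
    a <- sum(e & st == 1L); b <- sum(e & st == 0L)
    obs <- .score_tables(a, b, n_case - a, n_ctrl - b)
    if (obs$undefined) {
      return(data.frame(combination = combo_id(cmb), wald_obs = NA_real_,
                        p_raw = NA_real_, p_perm = NA_real_,
                        mean_stat = NA_real_, var_stat = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    w <- .perm_wald(P, n_case, n_ctrl, n_exp)
    data.frame(combination = combo_id(cmb), wald_obs = obs$wald,
               p_raw = obs$p_raw,
               p_perm = (sum(w >= obs$wald) + 1) / (P + 1),
               mean_stat = mean(w), var_stat = var(w),
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), P = P, stratum = stratum, seed = seed,
            class = c("calibration_report", "data.frame"))
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("<calibration_report> P=", attr(x, "P"), " stratum=",
      attr(x, "stratum"), "\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}
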