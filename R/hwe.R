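#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square test (1 df) comparing observed genotype counts of a
#' biallelic locus to the counts expected under Hardy-Weinberg proportions
#' at the allele frequency estimated from the same sample. When the
#' estimated allele frequency is 0 or 1 the expected counts equal the
#' observed ones, so the statistic is 0 (monomorphic-after-estimation
#' convention).
#'
#' @param n_AA count of one homozygote (genotype code 0).
#' @param n_Aa heterozygote count (code 1). May be omitted if `n_AA` is a
#'   length-3 vector of counts.
#' @param n_aa other homozygote count (code 2).
#' @return List with elements `chi2`, `p` (upper chi-squared(1) tail),
#'   `df = 1`, and `maf` (estimated frequency of the second allele).
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions: chi2 = 0
#' hwe_test(30, 40, 30)  # chi2 = 4
#' @export
hwe_test <- function(n_AA, n_Aa = NULL, n_aa = NULL) {
  if (is.null(n_Aa) && length(n_AA) == 3L) {
    counts <- as.numeric(n_AA)
  } else {
    counts <- c(n_AA, n_Aa, n_aa)
  }
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0))
    stop("genotype counts must be three non-negative numbers")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  q <- (2 * counts[3] + counts[2]) / (2 * n)  # frequency of allele 'a'
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  dev <- (counts - expected)^2
  chi2 <- sum(ifelse(expected > 0, dev / expected, 0))
  # numerically exact zero for monomorphic samples
  if (q == 0 || q == 1) chi2 <- 0
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L, maf = q)
}

#' Hardy-Weinberg checks across a cohort
#'
#' Runs [hwe_test()] for every biallelic SNP of the panel, separately for
#' cases and controls (binary polymorphisms carry no genotype-proportion
#' information and are skipped).
#'
#' @param cohort a `snp_cohort`.
#' @param stratum smoking-stratum selector, see [stratum_subset()].
#' @return data.frame with columns `poly`, `group`, `n_AA`, `n_Aa`, `n_aa`,
#'   `maf`, `chi2`, `p`.
#' @export
hwe_check <- function(cohort, stratum = "all") {
  stopifnot(inherits(cohort, "snp_cohort"))
  s <- stratum_subset(cohort, stratum)$subjects
  snps <- cohort$panel$name[cohort$panel$type == "snp"]
  rows <- list()
  for (nm in snps) {
    for (grp in c("control", "case")) {
      g <- s[[nm]][s$status == (grp == "case")]
      counts <- c(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                  sum(g == 2L, na.rm = TRUE))
      if (sum(counts) == 0) next
      h <- hwe_test(counts)
      rows[[length(rows) + 1L]] <- data.frame(
        poly = nm, group = grp, n_AA = counts[1], n_Aa = counts[2],
        n_aa = counts[3], maf = h$maf, chi2 = h$chi2, p = h$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
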