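#' Default polymorphism panel
#'
#' Metadata for the seven-polymorphism bladder-cancer risk panel: six
#' biallelic SNPs validated in genome-wide association studies (rs1014971,
#' rs11892031, rs1495741, rs710521, rs8102137, rs9642880) and the GSTM1
#' homozygous deletion, which is scored as a binary present/null
#' polymorphism.
#'
#' Biallelic SNPs are coded as minor-allele counts 0/1/2; the `ref`/`alt`
#' columns give the major and minor allele used to render genotype labels
#' such as `"rs9642880 [G/T, T/T]"`. For the binary deletion polymorphism
#' code 0 means at least one gene copy present and code 1 means the
#' homozygous null genotype; `ref`/`alt` are `NA`.
#'
#' The `freq` column is the control-population frequency used by the
#' synthetic-data generator: the minor-allele frequency for SNPs and the
#' null-genotype frequency for the deletion. Values for rs1014971,
#' rs9642880 and rs710521 are back-calculated from reported non-smoking
#' control genotype frequencies (C/C 40%, G/T+T/T 71%, A/A+A/G 93%); the
#' remaining entries are literature-typical European frequencies.
#'
#' @param names optional character vector selecting a subset of the panel
#'   (in panel order).
#' @return A data.frame with columns `name`, `type` (`"snp"` or `"binary"`),
#'   `ref`, `alt` and `freq`, one row per polymorphism.
#' @examples
#' default_panel()
#' default_panel(c("rs1014971", "GSTM1"))
#' @export
default_panel <- function(names = NULL) {
  panel <- data.frame(
    name = c("rs1014971", "rs11892031", "rs1495741", "rs710521",
             "rs8102137", "rs9642880", "GSTM1"),
    type = c(rep("snp", 6L), "binary"),
    ref  = c("C", "A", "A", "A", "C", "G", NA),
    alt  = c("T", "C", "G", "G", "T", "T", NA),
    # sqrt(0.40) = 0.632 major C for rs1014971 -> minor T 0.368, etc.
    freq = c(0.368, 0.080, 0.220, 0.265, 0.340, 0.461, 0.500),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    miss <- setdiff(names, panel$name)
    if (length(miss) > 0L)
      stop("unknown polymorphism(s): ", paste(miss, collapse = ", "))
    panel <- panel[panel$name %in% names, , drop = FALSE]
    rownames(panel) <- NULL
  }
  panel
}

.check_panel <- function(panel) {
  req <- c("name", "type")
  if (!is.data.frame(panel) || !all(req %in% names(panel)))
    stop("panel must be a data.frame with at least columns 'name' and 'type'")
  if (anyDuplicated(panel$name))
    stop("duplicated polymorphism names in panel")
  if (!all(panel$type %in% c("snp", "binary")))
    stop("panel type must be 'snp' or 'binary'")
  if (is.null(panel$ref)) panel$ref <- NA_character_
  if (is.null(panel$alt)) panel$alt <- NA_character_
  panel
}

.geno_domain <- function(type) {
  switch(type, snp = 0:2, binary = 0:1,
         stop("unknown genotype domain: ", type))
}

#' Smoking-stratum case/control counts of the motivating bladder-cancer study
#'
#' Numbers of urinary bladder cancer cases and cancer-free controls with
#' known smoking habits in the motivating multi-centre European case-control
#' study (1,494 cases, 1,723 controls), by smoking stratum. The `ever`
#' row pools former and current smokers; non-smokers are the reference
#' group for smoking odds ratios and attributable-risk calculations.
#'
#' @format A data.frame with columns `stratum`, `cases`, `controls`.
#' @examples
#' # crude current-smoker OR vs non-smokers
#' odds_ratio_ci(431, 315, 321, 752)
#' @export
ubc_smoking_counts <- data.frame(
  stratum  = c("non", "former", "current", "ever"),
  cases    = c(321L, 742L, 431L, 1173L),
  controls = c(752L, 656L, 315L, 971L),
  stringsAsFactors = FALSE
)
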