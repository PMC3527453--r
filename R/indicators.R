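#' Risk indicators: binary genotype splits of one polymorphism
#'
#' A risk indicator designates a subset of genotype codes of a single
#' polymorphism as "exposed". For a biallelic SNP coded by minor-allele
#' count the admissible subsets are the order-respecting (contiguous)
#' proper subsets `{0}`, `{0,1}`, `{1,2}`, `{2}` - the dominant and
#' recessive codings of either allele; a binary polymorphism has `{0}`
#' and `{1}`.
#'
#' @param poly polymorphism name.
#' @param codes integer vector of genotype codes forming the risk set.
#' @param type `"snp"` or `"binary"`.
#' @return An object of class `risk_indicator`.
#' @examples
#' risk_indicator("rs9642880", c(1, 2), "snp")  # minor-allele carriers
#' @export
risk_indicator <- function(poly, codes, type = c("snp", "binary")) {
  type <- match.arg(type)
  dom <- .geno_domain(type)
  codes <- sort(unique(as.integer(codes)))
  if (length(codes) == 0L || length(codes) >= length(dom) ||
      !all(codes %in% dom))
    stop("risk set must be a non-empty proper subset of {",
         paste(dom, collapse = ","), "}")
  if (length(codes) > 1L && any(diff(codes) != 1L))
    stop("risk set must be contiguous in the genotype ordering (no {0,2})")
  structure(list(poly = as.character(poly), codes = codes, type = type),
            class = "risk_indicator")
}

#' @rdname risk_indicator
#' @param x a `risk_indicator`.
#' @return `indicator_id()`: a compact identifier such as `"rs9642880:12"`.
#' @export
indicator_id <- function(x) {
  paste0(x$poly, ":", paste(x$codes, collapse = ""))
}

#' Complement of a risk indicator
#'
#' Returns the indicator whose risk set is the complement of `x`'s within
#' the genotype domain (always admissible: the complement of a contiguous
#' proper subset is contiguous).
#'
#' @param x a `risk_indicator`.
#' @export
complement_indicator <- function(x) {
  stopifnot(inherits(x, "risk_indicator"))
  risk_indicator(x$poly, setdiff(.geno_domain(x$type), x$codes), x$type)
}

#' Enumerate the admissible risk indicators of one polymorphism
#'
#' A biallelic SNP yields exactly four indicators, in deterministic order
#' `{0}`, `{0,1}`, `{1,2}`, `{2}`; a binary polymorphism yields `{0}`, `{1}`.
#'
#' @param poly polymorphism name.
#' @param type `"snp"` or `"binary"`.
#' @return List of `risk_indicator` objects.
#' @export
enumerate_indicators <- function(poly, type = c("snp", "binary")) {
  type <- match.arg(type)
  sets <- switch(type,
    snp    = list(0L, c(0L, 1L), c(1L, 2L), 2L),
    binary = list(0L, 1L)
  )
  lapply(sets, function(s) risk_indicator(poly, s, type))
}

#' A k-way combination of risk indicators
#'
#' A combination is a conjunction of risk indicators on distinct
#' polymorphisms: a subject is exposed when every member indicator is true,
#' and has undefined exposure when any member genotype is missing.
#' Indicators are stored sorted by polymorphism name, so the identifier and
#' exposure are invariant to the order in which they are supplied.
#'
#' @param indicators a list of [risk_indicator()] objects (a single
#'   indicator is also accepted).
#' @return An object of class `snp_combination`.
#' @examples
#' cmb <- snp_combination(list(
#'   risk_indicator("rs9642880", c(1, 2), "snp"),
#'   risk_indicator("rs1014971", 0, "snp")))
#' combo_id(cmb)
#' @export
snp_combination <- function(indicators) {
  if (inherits(indicators, "risk_indicator")) indicators <- list(indicators)
  if (!is.list(indicators) || length(indicators) < 1L ||
      !all(vapply(indicators, inherits, logical(1), "risk_indicator")))
    stop("indicators must be a non-empty list of risk_indicator objects")
  polys <- vapply(indicators, function(i) i$poly, character(1))
  if (anyDuplicated(polys))
    stop("all indicators of a combination must reference distinct polymorphisms")
  indicators <- indicators[order(polys)]
  structure(list(indicators = indicators), class = "snp_combination")
}

#' @rdname snp_combination
#' @param x a `snp_combination`.
#' @return `combo_id()`: the canonical identifier, member indicator ids
#'   joined by `","` in polymorphism-name order.
#' @export
combo_id <- function(x) {
  paste(vapply(x$indicators, indicator_id, character(1)), collapse = ",")
}

#' @rdname snp_combination
#' @return `combo_order()`: the number of member indicators k.
#' @export
combo_order <- function(x) length(x$indicators)

#' Count the k-way combinations of a polymorphism panel
#'
#' Closed-form size of the exhaustive enumeration over `n_snps` biallelic
#' SNPs (4 indicators each) and `n_binary` binary polymorphisms
#' (2 indicators each): the sum over the number `j` of binary members of
#' `C(n_snps, k-j) 4^(k-j) C(n_binary, j) 2^j`. For the six-SNP + GSTM1
#' panel this gives 26 singletons, 288 two-way and 1,760 three-way
#' combinations.
#'
#' @param n_snps number of biallelic SNPs in the panel.
#' @param n_binary number of binary polymorphisms.
#' @param k combination order, `1 <= k <= n_snps + n_binary`.
#' @return Integer count.
#' @examples
#' count_combinations(6, 1, 2)  # 288
#' count_combinations(6, 1, 3)  # 1760
#' @export
count_combinations <- function(n_snps, n_binary, k) {
  stopifnot(n_snps >= 0, n_binary >= 0)
  if (k < 1 || k > n_snps + n_binary)
    stop("k must satisfy 1 <= k <= n_snps + n_binary")
  j <- max(0, k - n_snps):min(k, n_binary)
  sum(choose(n_snps, k - j) * 4^(k - j) * choose(n_binary, j) * 2^j)
}

#' Enumerate all k-way combinations of a panel
#'
#' Materializes the exhaustive list counted by [count_combinations()], in
#' deterministic order (polymorphism subsets in [utils::combn()] order of
#' the panel rows; within a subset, indicator assignments vary the first
#' polymorphism fastest, each in [enumerate_indicators()] order).
#'
#' @param panel polymorphism metadata; see [default_panel()].
#' @param k combination order.
#' @return List of `snp_combination` objects.
#' @export
enumerate_combinations <- function(panel, k) {
  panel <- .check_panel(panel)
  if (k < 1 || k > nrow(panel))
    stop("k must satisfy 1 <= k <= number of panel polymorphisms")
  ind_lists <- lapply(seq_len(nrow(panel)), function(i)
    enumerate_indicators(panel$name[i], panel$type[i]))
  poly_sets <- combn(seq_len(nrow(panel)), k, simplify = FALSE)
  out <- vector("list", count_combinations(
    sum(panel$type == "snp"), sum(panel$type == "binary"), k))
  pos <- 0L
  for (ps in poly_sets) {
    grid <- expand.grid(lapply(ps, function(i) seq_along(ind_lists[[i]])),
                        KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(grid))) {
      inds <- lapply(seq_along(ps), function(j)
        ind_lists[[ps[j]]][[grid[r, j]]])
      pos <- pos + 1L
      out[[pos]] <- snp_combination(inds)
    }
  }
  out
}

# Indicator truth values for the subject table: TRUE/FALSE, NA where the
# genotype is missing (NA %in% codes would silently give FALSE).
.indicator_values <- function(subjects, ind) {
  g <- subjects[[ind$poly]]
  if (is.null(g)) stop("polymorphism not in cohort: ", ind$poly)
  v <- g %in% ind$codes
  v[is.na(g)] <- NA
  v
}

# n x m exposure matrix for a list of combinations; complete-case per
# combination (exposure NA iff any member genotype missing).
.exposure_matrix <- function(subjects, combos) {
  inds <- list()
  for (cmb in combos)
    for (i in cmb$indicators) inds[[indicator_id(i)]] <- i
  M <- vapply(inds, function(i) .indicator_values(subjects, i),
              logical(nrow(subjects)))
  if (is.null(dim(M))) M <- matrix(M, nrow = nrow(subjects),
                                   dimnames = list(NULL, names(inds)))
  E <- matrix(NA, nrow(subjects), length(combos))
  for (j in seq_along(combos)) {
    idx <- vapply(combos[[j]]$indicators, indicator_id, character(1))
    kk <- length(idx)
    # all-TRUE test with NA propagation
    E[, j] <- rowSums(M[, idx, drop = FALSE]) == kk
  }
  E
}

#' Exposure of each subject under a combination
#'
#' @param cohort a `snp_cohort`.
#' @param combination a `snp_combination`.
#' @return Logical vector, one element per subject: `TRUE` when every
#'   member indicator is true, `NA` when any member genotype is missing.
#' @export
combination_exposure <- function(cohort, combination) {
  stopifnot(inherits(cohort, "snp_cohort"),
            inherits(combination, "snp_combination"))
  drop(.exposure_matrix(cohort$subjects, list(combination)))
}

#' Parse a combination from its text form
#'
#' Accepts the canonical identifier grammar
#' `"<poly>:<risk set>"` joined by commas, where the risk set is either the
#' digit codes (`"rs1014971:12"`), `+`-separated genotype strings rendered
#' with the panel alleles (`"rs9642880:GT+TT"` or `"rs9642880:G/T+T/T"`), or
#' `null`/`present` for a binary polymorphism (`"GSTM1:null"`).
#'
#' @param text combination specification.
#' @param panel polymorphism metadata providing names, types and alleles.
#' @return A `snp_combination`.
#' @examples
#' combo_id(parse_combination("rs9642880:GT+TT,GSTM1:null"))
#' @export
parse_combination <- function(text, panel = default_panel()) {
  panel <- .check_panel(panel)
  toks <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  inds <- lapply(toks, function(tok) {
    parts <- strsplit(trimws(tok), ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("cannot parse indicator '", tok, "' (expect poly:riskset)")
    i <- match(parts[1], panel$name)
    if (is.na(i)) stop("unknown polymorphism: ", parts[1])
    risk_indicator(panel$name[i],
                   .parse_risk_set(parts[2], panel[i, ]),
                   panel$type[i])
  })
  snp_combination(inds)
}

.parse_risk_set <- function(txt, meta) {
  txt <- trimws(txt)
  if (meta$type == "binary") {
    low <- tolower(txt)
    if (low %in% c("null", "1")) return(1L)
    if (low %in% c("present", "0")) return(0L)
    stop("cannot parse risk set '", txt, "' for binary polymorphism ",
         meta$name)
  }
  if (grepl("^[0-2]+$", txt))
    return(as.integer(strsplit(txt, "")[[1]]))
  genos <- toupper(gsub("/", "", strsplit(txt, "+", fixed = TRUE)[[1]]))
  if (is.na(meta$ref) || is.na(meta$alt))
    stop("panel has no allele labels for ", meta$name,
         "; use digit codes instead")
  vapply(genos, function(g) {
    if (!grepl("^[ACGT]{2}$", g))
      stop("cannot parse genotype '", g, "' for ", meta$name)
    code <- sum(strsplit(g, "")[[1]] == meta$alt)
    if (code == 0L && !all(strsplit(g, "")[[1]] == meta$ref))
      stop("genotype '", g, "' does not match alleles ",
           meta$ref, "/", meta$alt, " of ", meta$name)
    as.integer(code)
  }, integer(1), USE.NAMES = FALSE)
}

#' Human-readable labels for indicators and combinations
#'
#' Renders the genotype groupings in the conventional report style, e.g.
#' `"rs9642880 [G/T, T/T]"` or `"GSTM1 null"`, with combinations joined by
#' `" x "`.
#'
#' @param x a `risk_indicator` or `snp_combination`.
#' @param panel panel metadata providing allele labels.
#' @return Character scalar.
#' @export
indicator_label <- function(x, panel = default_panel()) {
  stopifnot(inherits(x, "risk_indicator"))
  if (x$type == "binary")
    return(paste(x$poly, if (identical(x$codes, 1L)) "null" else "present"))
  i <- match(x$poly, panel$name)
  ref <- if (!is.na(i)) panel$ref[i] else NA
  alt <- if (!is.na(i)) panel$alt[i] else NA
  if (is.na(ref) || is.na(alt))
    return(paste0(x$poly, " {", paste(x$codes, collapse = ","), "}"))
  geno <- vapply(x$codes, function(k)
    paste(c(rep(ref, 2 - k), rep(alt, k)), collapse = "/"), character(1))
  paste0(x$poly, " [", paste(geno, collapse = ", "), "]")
}

#' @rdname indicator_label
#' @export
combo_label <- function(x, panel = default_panel()) {
  stopifnot(inherits(x, "snp_combination"))
  paste(vapply(x$indicators, indicator_label, character(1), panel = panel),
        collapse = " x ")
}

#' @export
print.risk_indicator <- function(x, ...) {
  cat("<risk_indicator>", indicator_id(x), "\n")
  invisible(x)
}

#' @export
print.snp_combination <- function(x, ...) {
  cat("<snp_combination k=", combo_order(x), "> ", combo_id(x), "\n", sep = "")
  invisible(x)
}
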