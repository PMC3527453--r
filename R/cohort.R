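#' Construct a case-control cohort object
#'
#' Validates a subject-level table against a polymorphism panel and wraps it
#' as a `snp_cohort`. Genotypes must already be numerically coded
#' (minor-allele counts 0/1/2 for SNPs, 0 = present / 1 = null for binary
#' deletion polymorphisms); use [read_cohort()] to load allele-string tables.
#'
#' @param subjects data.frame with columns `id`, `status` (1 = case,
#'   0 = control, or `"case"`/`"control"`), `smoking` (`"non"`, `"former"`,
#'   `"current"`, `"unknown"`), `age`, `gender`, `site`, plus one genotype
#'   column per panel row. Missing genotypes are `NA`.
#' @param panel polymorphism metadata as returned by [default_panel()].
#' @return An object of class `snp_cohort`: a list with elements `subjects`
#'   (the validated data.frame) and `panel`.
#' @examples
#' coh <- simulate_cohort(sim_config(strata = list(
#'   non = c(cases = 30, controls = 30))), seed = 1)
#' snp_cohort(coh$subjects, coh$panel)
#' @export
snp_cohort <- function(subjects, panel = default_panel()) {
  panel <- .check_panel(panel)
  required <- c("id", "status", "smoking", "age", "gender", "site")
  miss <- setdiff(required, names(subjects))
  if (length(miss) > 0L)
    stop("format error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(panel$name, names(subjects))
  if (length(miss) > 0L)
    stop("format error: missing polymorphism column(s): ",
         paste(miss, collapse = ", "))

  subjects$id <- as.character(subjects$id)

  # status: accept 0/1 or case/control labels
  st <- subjects$status
  if (is.character(st) || is.factor(st)) {
    st <- tolower(as.character(st))
    st <- ifelse(st %in% c("case", "1"), 1L,
                 ifelse(st %in% c("control", "0"), 0L, NA_integer_))
  } else {
    st <- as.integer(st)
    st[!st %in% c(0L, 1L)] <- NA_integer_
  }
  if (anyNA(st))
    stop("validation error: status must be 0/1 (or case/control); bad rows: ",
         .row_list(which(is.na(st))))
  subjects$status <- st

  smoking <- tolower(as.character(subjects$smoking))
  smoking[is.na(smoking) | smoking == ""] <- "unknown"
  bad <- !smoking %in% c("non", "former", "current", "unknown")
  if (any(bad))
    stop("validation error: smoking must be non/former/current/unknown; ",
         "bad rows: ", .row_list(which(bad)))
  subjects$smoking <- factor(smoking,
                             levels = c("non", "former", "current", "unknown"))

  subjects$age <- as.numeric(subjects$age)

  for (i in seq_len(nrow(panel))) {
    nm <- panel$name[i]
    g <- suppressWarnings(as.integer(subjects[[nm]]))
    dom <- .geno_domain(panel$type[i])
    bad <- !is.na(subjects[[nm]]) & (is.na(g) | !g %in% dom)
    if (any(bad))
      stop("validation error: genotype codes for ", nm,
           " outside {", paste(dom, collapse = ","), "}; bad rows: ",
           .row_list(which(bad)))
    subjects[[nm]] <- g
  }
  rownames(subjects) <- NULL
  structure(list(subjects = subjects, panel = panel), class = "snp_cohort")
}

.row_list <- function(rows, max = 5L) {
  shown <- paste(head(rows, max), collapse = ", ")
  if (length(rows) > max)
    shown <- paste0(shown, ", ... (", length(rows), " rows)")
  shown
}

#' Read a subject-level cohort table
#'
#' Loads a tab-separated table with one row per subject and returns a
#' validated [snp_cohort()]. Two genotype dialects are supported:
#' `"count"` (numeric codes 0/1/2, or 0/1 for binary polymorphisms, with
#' `present`/`null` also accepted for the latter) and `"alleles"` (genotype
#' strings such as `"A/A"` or `"AG"`). In the alleles dialect the minor
#' allele of each SNP is determined from the controls of the loaded cohort
#' and genotype codes count that minor allele; the derived orientation is
#' stored in the returned panel so report labels match the data.
#'
#' @param path path to a UTF-8 TSV file with a header row; required columns
#'   `id`, `status`, `smoking`, `age`, `gender`, `site` plus one column per
#'   panel polymorphism.
#' @param panel polymorphism metadata; see [default_panel()].
#' @param dialect `"count"` or `"alleles"`.
#' @param na missing-value token in the file.
#' @return A `snp_cohort`.
#' @seealso [write_cohort()], [validation_report()]
#' @examples
#' tsv <- system.file("extdata", "synthetic_cohort_example.tsv",
#'                    package = "snpcombo")
#' read_cohort(tsv)
#' @export
read_cohort <- function(path, panel = default_panel(),
                        dialect = c("count", "alleles"), na = "NA") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  panel <- .check_panel(panel)
  df <- read.delim(path, sep = "\t", header = TRUE, na.strings = na,
                   colClasses = "character", check.names = FALSE,
                   stringsAsFactors = FALSE)
  required <- c("id", "status", "smoking", "age", "gender", "site")
  miss <- setdiff(c(required, panel$name), names(df))
  if (length(miss) > 0L)
    stop("format error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))

  if (dialect == "alleles") {
    status <- tolower(df$status)
    is_control <- status %in% c("0", "control")
    for (i in seq_len(nrow(panel))) {
      nm <- panel$name[i]
      if (panel$type[i] == "snp") {
        mapped <- .map_allele_column(df[[nm]], nm, is_control)
        df[[nm]] <- mapped$codes
        panel$ref[i] <- mapped$ref
        panel$alt[i] <- mapped$alt
      } else {
        df[[nm]] <- .map_binary_column(df[[nm]], nm)
      }
    }
  } else {
    for (i in seq_len(nrow(panel))) {
      nm <- panel$name[i]
      if (panel$type[i] == "binary") df[[nm]] <- .map_binary_column(df[[nm]], nm)
    }
  }
  snp_cohort(df, panel)
}

# Map "X/Y" (or "XY") genotype strings to minor-allele counts, orienting the
# minor allele by its frequency among controls.
.map_allele_column <- function(x, name, is_control) {
  toks <- toupper(gsub("/", "", trimws(x)))
  ok <- is.na(toks) | grepl("^[ACGT]{2}$", toks)
  if (!all(ok))
    stop("validation error: unmappable genotype string(s) for ", name,
         " (expect e.g. 'A/G'); bad rows: ", .row_list(which(!ok)))
  a1 <- substr(toks, 1, 1)
  a2 <- substr(toks, 2, 2)
  alleles <- sort(unique(stats::na.omit(c(a1, a2))))
  if (length(alleles) > 2L)
    stop("validation error: more than two alleles observed for ", name, ": ",
         paste(alleles, collapse = ", "))
  if (length(alleles) == 1L) alleles <- c(alleles, alleles)
  ctrl <- is_control & !is.na(toks)
  n2 <- sum(a1[ctrl] == alleles[2]) + sum(a2[ctrl] == alleles[2])
  n1 <- sum(a1[ctrl] == alleles[1]) + sum(a2[ctrl] == alleles[1])
  # minor allele = rarer in controls; deterministic tie-break on sort order
  minor <- if (n2 <= n1) alleles[2] else alleles[1]
  major <- setdiff(alleles, minor)[1]
  if (is.na(major)) major <- minor
  codes <- (a1 == minor) + (a2 == minor)
  list(codes = as.integer(codes), ref = major, alt = minor)
}

.map_binary_column <- function(x, name) {
  toks <- tolower(trimws(as.character(x)))
  out <- ifelse(is.na(toks), NA_integer_,
                ifelse(toks %in% c("null", "1"), 1L,
                       ifelse(toks %in% c("present", "0"), 0L, NA_integer_)))
  bad <- !is.na(toks) & is.na(out)
  if (any(bad))
    stop("validation error: unmappable code(s) for binary polymorphism ",
         name, " (expect present/null or 0/1); bad rows: ",
         .row_list(which(bad)))
  out
}

#' Write a cohort as a TSV file
#'
#' Serializes the subject table in the `"count"` genotype dialect read back
#' by [read_cohort()]; missing values are written as `NA`.
#'
#' @param cohort a `snp_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "snp_cohort"))
  write.table(cohort$subjects, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

# Row indices of a smoking-stratum selector. "all" keeps every subject
# (including unknown smoking); the named strata exclude unknowns.
.stratum_rows <- function(cohort, stratum) {
  smoking <- cohort$subjects$smoking
  rows <- switch(stratum,
    all     = seq_along(smoking),
    non     = which(smoking == "non"),
    former  = which(smoking == "former"),
    current = which(smoking == "current"),
    ever    = which(smoking %in% c("former", "current")),
    stop("unknown stratum selector: ", stratum,
         " (use all/non/former/current/ever)")
  )
  if (length(rows) == 0L) stop("stratum '", stratum, "' is empty")
  rows
}

#' Subset a cohort to a smoking stratum
#'
#' @param cohort a `snp_cohort`.
#' @param stratum one of `"all"`, `"non"`, `"former"`, `"current"`,
#'   `"ever"` (former + current). Subjects with unknown smoking habits are
#'   retained only under `"all"`.
#' @return A `snp_cohort` restricted to the selected subjects.
#' @export
stratum_subset <- function(cohort, stratum) {
  stopifnot(inherits(cohort, "snp_cohort"))
  rows <- .stratum_rows(cohort, stratum)
  out <- cohort
  out$subjects <- cohort$subjects[rows, , drop = FALSE]
  rownames(out$subjects) <- NULL
  out
}

#' Case/control tallies by smoking stratum
#'
#' @param cohort a `snp_cohort`.
#' @return data.frame with one row per stratum (`non`, `former`, `current`,
#'   `ever`, `unknown`, `total`) and columns `cases`, `controls`.
#' @export
cohort_counts <- function(cohort) {
  stopifnot(inherits(cohort, "snp_cohort"))
  s <- cohort$subjects
  tally <- function(rows) c(cases = sum(s$status[rows] == 1L),
                            controls = sum(s$status[rows] == 0L))
  strata <- list(
    non     = which(s$smoking == "non"),
    former  = which(s$smoking == "former"),
    current = which(s$smoking == "current"),
    ever    = which(s$smoking %in% c("former", "current")),
    unknown = which(s$smoking == "unknown"),
    total   = seq_len(nrow(s))
  )
  out <- do.call(rbind, lapply(strata, tally))
  data.frame(stratum = rownames(out), cases = out[, "cases"],
             controls = out[, "controls"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cohort validation report
#'
#' Summarizes the loaded cohort: subject counts, per-stratum tallies, how
#' many subjects are excluded from smoking-stratified analyses because of
#' unknown smoking habits, and per-polymorphism missing-genotype counts.
#'
#' @param cohort a `snp_cohort`.
#' @return A list suitable for JSON serialization; see
#'   [write_validation_report()].
#' @export
validation_report <- function(cohort) {
  stopifnot(inherits(cohort, "snp_cohort"))
  s <- cohort$subjects
  counts <- cohort_counts(cohort)
  missing_geno <- vapply(cohort$panel$name,
                         function(nm) sum(is.na(s[[nm]])), integer(1))
  list(
    n_subjects = nrow(s),
    n_cases = sum(s$status == 1L),
    n_controls = sum(s$status == 0L),
    excluded_from_stratified = list(
      cases = sum(s$status == 1L & s$smoking == "unknown"),
      controls = sum(s$status == 0L & s$smoking == "unknown")
    ),
    strata = counts,
    missing_genotypes = as.list(missing_geno)
  )
}

#' @rdname validation_report
#' @param report a list from [validation_report()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.snp_cohort <- function(x, ...) {
  s <- x$subjects
  cat("<snp_cohort> ", nrow(s), " subjects (",
      sum(s$status == 1L), " cases / ", sum(s$status == 0L),
      " controls), ", nrow(x$panel), " polymorphisms\n", sep = "")
  tab <- table(s$smoking)
  cat("  smoking:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
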