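#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates everything [simulate_cohort()] needs: per-stratum
#' case/control quotas, control-population genotype frequencies, planted
#' conjunction effects, the covariate model and an optional confounding
#' switch.
#'
#' The defaults reproduce the structure of the motivating bladder-cancer
#' study: smoking-stratum quotas 321/752 (non), 742/656 (former), 431/315
#' (current) cases/controls, the seven-polymorphism panel of
#' [default_panel()] with its control genotype frequencies, and no planted
#' effects.
#'
#' @param strata named list of per-stratum quotas, each `c(cases = ,
#'   controls = )`; names among `non`, `former`, `current`.
#' @param panel polymorphism metadata with a `freq` column (minor-allele
#'   frequency for SNPs, null-genotype frequency for binary
#'   polymorphisms); see [default_panel()].
#' @param effects list of planted effects, each a list with elements
#'   `combination` (a `snp_combination` or character specification),
#'   `stratum` (`"all"` or a stratum name) and `or` (target conditional
#'   odds ratio of the conjunction exposure).
#' @param baseline baseline disease probability of an unexposed subject in
#'   the source population; kept small (rare-disease regime) so that
#'   sampled controls track the configured Hardy-Weinberg frequencies.
#' @param age list with `case` and `control` elements, each
#'   `c(mean = , sd = )` years.
#' @param gender named probability vector of gender categories.
#' @param sites named probability vector of study-site categories
#'   (ignored when `confounder` is set, which takes over the site label).
#' @param confounder `NULL`, or a list with `prob` (prevalence of the
#'   confounding stratum), `or` (its odds ratio on disease) and
#'   `freq_factor` (multiplier on every genotype frequency inside it);
#'   the confounding stratum is exposed through the `site` column, so
#'   adjusting for `site` recovers the planted conditional effect while
#'   the crude OR is biased.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()], [read_scenario()]
#' @export
sim_config <- function(strata = list(non = c(cases = 321, controls = 752),
                                     former = c(cases = 742, controls = 656),
                                     current = c(cases = 431, controls = 315)),
                       panel = default_panel(),
                       effects = list(),
                       baseline = 0.05,
                       age = list(case = c(mean = 66, sd = 10),
                                  control = c(mean = 63, sd = 11)),
                       gender = c(male = 0.8, female = 0.2),
                       sites = c(A = 0.35, B = 0.15, C = 0.20, D = 0.30),
                       confounder = NULL) {
  panel <- .check_panel(panel)
  if (is.null(panel$freq) || anyNA(panel$freq) ||
      any(panel$freq <= 0 | panel$freq >= 1))
    stop("panel must carry genotype frequencies in (0, 1)")

  if (!is.list(strata) || length(strata) < 1L || is.null(names(strata)))
    stop("strata must be a named list of c(cases, controls) quotas")
  if (!all(names(strata) %in% c("non", "former", "current")))
    stop("stratum names must be among non/former/current")
  for (nm in names(strata)) {
    q <- strata[[nm]]
    if (length(q) != 2L || anyNA(q) || any(q < 1) ||
        !all(c("cases", "controls") %in% names(q)))
      stop("stratum '", nm, "' must give c(cases >= 1, controls >= 1)")
    strata[[nm]] <- c(cases = as.integer(q[["cases"]]),
                      controls = as.integer(q[["controls"]]))
  }

  if (length(baseline) != 1L || baseline <= 0 || baseline >= 1)
    stop("baseline disease probability must lie in (0, 1)")

  effects <- lapply(effects, function(ef) {
    if (is.null(ef$combination) || is.null(ef$or))
      stop("each effect needs 'combination' and 'or'")
    if (is.character(ef$combination))
      ef$combination <- parse_combination(ef$combination, panel)
    stopifnot(inherits(ef$combination, "snp_combination"))
    if (is.null(ef$stratum)) ef$stratum <- "all"
    if (!ef$stratum %in% c("all", names(strata)))
      stop("effect stratum '", ef$stratum, "' is not configured")
    if (length(ef$or) != 1L || is.na(ef$or) || ef$or <= 0)
      stop("effect odds ratio must be > 0")
    ef
  })

  if (!is.null(confounder)) {
    need <- c("prob", "or", "freq_factor")
    if (!is.list(confounder) || !all(need %in% names(confounder)))
      stop("confounder needs elements prob, or, freq_factor")
    if (confounder$prob <= 0 || confounder$prob >= 1)
      stop("confounder prob must lie in (0, 1)")
    if (confounder$or <= 0) stop("confounder or must be > 0")
    if (any(panel$freq * confounder$freq_factor >= 1))
      stop("infeasible configuration: confounder freq_factor pushes a ",
           "genotype frequency to 1 or beyond")
  }

  if (abs(sum(gender) - 1) > 1e-8 || abs(sum(sites) - 1) > 1e-8)
    stop("gender and site probabilities must each sum to 1")

  structure(list(strata = strata, panel = panel, effects = effects,
                 baseline = baseline, age = age, gender = gender,
                 sites = sites, confounder = confounder),
            class = "sim_config")
}

# Genotypes under Hardy-Weinberg (SNPs: minor-allele count ~ Binomial(2, f);
# binary: null genotype ~ Bernoulli(f)); freq_mult optionally scales every
# frequency per subject (confounding stratum).
.draw_genotypes <- function(n, panel, freq_mult = NULL) {
  out <- vector("list", nrow(panel))
  names(out) <- panel$name
  for (i in seq_len(nrow(panel))) {
    f <- panel$freq[i]
    if (!is.null(freq_mult)) f <- f * freq_mult
    out[[i]] <- if (panel$type[i] == "snp") rbinom(n, 2L, f)
                else rbinom(n, 1L, f)
  }
  as.data.frame(out, optional = TRUE)
}

# One smoking stratum: retrospective (case-control) sampling by
# oversampling the source population until the case and control quotas
# fill. Disease status follows a logistic model in the planted conjunction
# exposures, so each planted effect holds with its exact conditional OR;
# case-control ascertainment preserves odds ratios.
.sim_stratum <- function(n_ca, n_co, effects, config) {
  panel <- config$panel
  conf <- config$confounder

  if (length(effects) == 0L && is.null(conf)) {
    n <- n_ca + n_co
    G <- .draw_genotypes(n, panel)
    return(list(G = G, status = rep(c(1L, 0L), c(n_ca, n_co)),
                z = rep(0L, n)))
  }

  alpha <- qlogis(config$baseline)
  got_ca <- list(); got_co <- list()
  need_ca <- n_ca; need_co <- n_co
  guard <- 0L
  while (need_ca > 0L || need_co > 0L) {
    guard <- guard + 1L
    if (guard > 1000L)
      stop("infeasible configuration: case/control quotas not fillable")
    # batch sized so one or two passes usually fill both quotas
    m <- max(2000L,
             ceiling(1.3 * need_ca / config$baseline + 1.3 * need_co))
    z <- if (is.null(conf)) rep(0L, m) else rbinom(m, 1L, conf$prob)
    mult <- if (is.null(conf)) NULL else
      ifelse(z == 1L, conf$freq_factor, 1)
    G <- .draw_genotypes(m, panel, mult)
    eta <- rep(alpha, m)
    if (!is.null(conf)) eta <- eta + log(conf$or) * z
    for (ef in effects) {
      e <- drop(.exposure_matrix(G, list(ef$combination)))
      eta <- eta + log(ef$or) * e
    }
    st <- rbinom(m, 1L, plogis(eta))
    if (need_ca > 0L) {
      take <- head(which(st == 1L), need_ca)
      if (length(take)) {
        got_ca[[length(got_ca) + 1L]] <- cbind(G[take, , drop = FALSE],
                                               .z = z[take])
        need_ca <- need_ca - length(take)
      }
    }
    if (need_co > 0L) {
      take <- head(which(st == 0L), need_co)
      if (length(take)) {
        got_co[[length(got_co) + 1L]] <- cbind(G[take, , drop = FALSE],
                                               .z = z[take])
        need_co <- need_co - length(take)
      }
    }
  }
  ca <- do.call(rbind, got_ca)
  co <- do.call(rbind, got_co)
  all <- rbind(ca, co)
  list(G = all[, panel$name, drop = FALSE],
       status = rep(c(1L, 0L), c(n_ca, n_co)),
       z = all$.z)
}

#' Generate a synthetic case-control cohort
#'
#' Draws a cohort with the statistical structure the scanning pipeline
#' assumes: control-population genotypes in Hardy-Weinberg equilibrium at
#' the configured frequencies, per-stratum case/control quotas filled by
#' retrospective sampling, and disease status generated from a logistic
#' model in the planted conjunction exposures so that each planted
#' (combination, stratum) pair attains its target conditional odds ratio.
#' Covariates (age by status, gender, study site) are attached per the
#' configuration. Two runs with the same seed are identical.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return A `snp_cohort`.
#' @examples
#' cfg <- sim_config(strata = list(non = c(cases = 50, controls = 50)))
#' simulate_cohort(cfg, seed = 1)
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  blocks <- list()
  for (nm in names(config$strata)) {
    q <- config$strata[[nm]]
    eff <- Filter(function(ef) ef$stratum %in% c("all", nm), config$effects)
    blk <- .sim_stratum(q[["cases"]], q[["controls"]], eff, config)
    n <- nrow(blk$G)
    age_par <- ifelse(blk$status == 1L,
                      config$age$case[["mean"]], config$age$control[["mean"]])
    age_sd <- ifelse(blk$status == 1L,
                     config$age$case[["sd"]], config$age$control[["sd"]])
    sub <- data.frame(
      status = blk$status,
      smoking = nm,
      age = round(rnorm(n, age_par, age_sd), 1),
      gender = sample(names(config$gender), n, replace = TRUE,
                      prob = config$gender),
      site = if (is.null(config$confounder))
        sample(names(config$sites), n, replace = TRUE, prob = config$sites)
      else paste0("site", blk$z + 1L),
      stringsAsFactors = FALSE
    )
    blocks[[nm]] <- cbind(sub, blk$G)
  }
  subjects <- do.call(rbind, blocks)
  subjects <- cbind(id = sprintf("S%05d", seq_len(nrow(subjects))), subjects,
                    stringsAsFactors = FALSE)
  rownames(subjects) <- NULL
  snp_cohort(subjects, config$panel)
}

#' Generate a cohort with planted stratum heterogeneity
#'
#' Convenience wrapper around [simulate_cohort()] for the
#' smoker/non-smoker contrast scenario: the configuration must define at
#' least two smoking strata and plant stratum-specific effects (so that
#' the same combination carries different odds ratios across strata, the
#' situation [interaction_test()] is designed to detect). A configuration
#' with a single stratum, or without any stratum-specific effect, is
#' rejected.
#'
#' @inheritParams simulate_cohort
#' @return A `snp_cohort`.
#' @export
simulate_smoker_contrast <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$strata) < 2L)
    stop("smoker-contrast scenario needs at least two configured strata")
  if (!any(vapply(config$effects, function(ef) ef$stratum != "all",
                  logical(1))))
    stop("smoker-contrast scenario needs at least one stratum-specific ",
         "planted effect")
  simulate_cohort(config, seed)
}

#' Read a simulation scenario from a YAML file
#'
#' The scenario schema mirrors the [sim_config()] arguments: mappings
#' `strata` (stratum name to `{cases, controls}`), optional `freq`
#' (polymorphism name to control frequency, overriding the panel
#' defaults), `effects` (sequence of `{combination, stratum, or}` with the
#' combination in [parse_combination()] grammar), and optional scalars /
#' mappings `baseline`, `age`, `gender`, `sites`, `confounder`.
#'
#' @param path YAML scenario file.
#' @param panel panel metadata the scenario refers to.
#' @return A `sim_config`.
#' @examples
#' scen <- system.file("extdata", "study_scenario.yaml",
#'                     package = "snpcombo")
#' cfg <- read_scenario(scen)
#' @export
read_scenario <- function(path, panel = default_panel()) {
  sc <- yaml::read_yaml(path)
  panel <- .check_panel(panel)
  if (!is.null(sc$freq)) {
    i <- match(names(sc$freq), panel$name)
    if (anyNA(i)) stop("scenario freq refers to unknown polymorphism(s): ",
                       paste(names(sc$freq)[is.na(i)], collapse = ", "))
    panel$freq[i] <- unlist(sc$freq)
  }
  args <- list(panel = panel)
  if (!is.null(sc$strata))
    args$strata <- lapply(sc$strata, function(q)
      c(cases = q$cases, controls = q$controls))
  if (!is.null(sc$effects))
    args$effects <- lapply(sc$effects, function(ef)
      list(combination = ef$combination,
           stratum = if (is.null(ef$stratum)) "all" else ef$stratum,
           or = ef$or))
  for (nm in c("baseline", "confounder"))
    if (!is.null(sc[[nm]])) args[[nm]] <- sc[[nm]]
  if (!is.null(sc$age))
    args$age <- lapply(sc$age, function(a) c(mean = a$mean, sd = a$sd))
  for (nm in c("gender", "sites"))
    if (!is.null(sc[[nm]])) args[[nm]] <- unlist(sc[[nm]])
  do.call(sim_config, args)
}
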