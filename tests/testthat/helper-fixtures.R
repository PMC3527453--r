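# Small programmatic fixtures shared across the suite.

mini_panel <- function() default_panel(c("rs1014971", "rs9642880", "GSTM1"))

hand_subjects <- function() {
  data.frame(
    id = paste0("P", 1:8),
    status = c(1, 1, 1, 1, 0, 0, 0, 0),
    smoking = c("non", "former", "current", "non",
                "non", "former", "current", "unknown"),
    age = c(60, 65, 70, 55, 58, 62, 67, 59),
    gender = rep(c("male", "female"), 4),
    site = rep(c("A", "B"), each = 4),
    rs1014971 = c(2, 1, 0, 2, 0, 1, 0, NA),
    rs9642880 = c(1, 2, 1, 0, 0, 1, 2, 1),
    GSTM1     = c(1, 1, 0, 1, 0, 0, 1, 0),
    stringsAsFactors = FALSE
  )
}

hand_cohort <- function() snp_cohort(hand_subjects(), mini_panel())

# Null cohort: genotypes independent of status, one smoking stratum.
null_cohort <- function(n_cases, n_controls, seed,
                        panel = default_panel()) {
  simulate_cohort(
    sim_config(strata = list(non = c(cases = n_cases,
                                     controls = n_controls)),
               panel = panel),
    seed = seed)
}
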