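# Small shared fixtures, built in code.

# A compact multi-cohort configuration for fast model-fitting tests:
# 4 cohorts, two with full covariates, one age-only, one without metadata.
small_config <- function(seed = 1, ...) {
  defaults <- list(
    n_cohorts = 4,
    cohort_sizes = c(24, 40, 30, 24),
    ec_fractions = c(0.5, 0.45, 0.6, 0.75),
    cohort_ids = c("c1", "c2", "c3", "c4"),
    n_taxa = 60,
    missingness_plan = list(
      c1 = c("age", "bmi", "ethnicity", "ph"),
      c2 = c("age", "bmi", "ethnicity", "ph"),
      c3 = "age",
      c4 = character(0)),
    sequencing_depth_mean = 4000,
    seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# One-point random-forest-only grid for speed.
rf_only_spec <- function(...) {
  model_spec(grids = list(rf = data.frame(ntree = 100, mtry_frac = 0.33)),
             ...)
}

# Tiny taxonomy for aggregation tests.
toy_taxonomy <- data.frame(
  taxon = c("t1", "t2", "t3", "t4", "t5"),
  genus = c("Lactobacillus", "Lactobacillus", "Prevotella", NA, "Blautia"),
  parent = c(NA, NA, NA, "Clostridiaceae", NA),
  stringsAsFactors = FALSE
)
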