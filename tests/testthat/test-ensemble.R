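# a cohort whose label is a deterministic threshold of one taxon feature
separable_unit <- function(n = 40, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  noise <- matrix(rnorm(n * 5), n, 5)
  taxa <- cbind(marker = x, noise)
  colnames(taxa) <- paste0("f", 1:6)
  list(cohort_id = "toy", taxa = taxa, kept = colnames(taxa), cov = NULL,
       covs = character(0), labels = ifelse(x > 0, "EC", "benign"),
       use_taxa = TRUE)
}

test_that("a separable cohort reaches out-of-fold F1 of 1 with a tree learner", {
  spec <- rf_only_spec(folds = 5, repeats = 1, seed = 2)
  tuned <- tune_local_model(separable_unit(), "rf", spec)
  expect_equal(tuned$oof_f1, 1)
  expect_identical(tuned$best_params$ntree, 100)
})

test_that("randomized labels stay inside the permutation-null band", {
  f1s <- vapply(1:3, function(s) {
    unit <- separable_unit(seed = s)
    set.seed(1000 + s)
    unit$labels <- sample(unit$labels)
    spec <- rf_only_spec(folds = 5, repeats = 1, seed = s)
    tune_local_model(unit, "rf", spec)$oof_f1
  }, numeric(1))
  expect_lt(mean(f1s), 0.7)  # balanced-null F1 centers near 0.5
})

test_that("tuning is deterministic given seed and grid", {
  unit <- separable_unit(seed = 4)
  spec <- model_spec(grids = list(rf = data.frame(ntree = c(50, 100),
                                                  mtry_frac = 0.33)),
                     folds = 3, repeats = 1, seed = 9)
  t1 <- tune_local_model(unit, "rf", spec)
  t2 <- tune_local_model(unit, "rf", spec)
  expect_identical(t1$best_params, t2$best_params)
  expect_identical(t1$grid_f1, t2$grid_f1)
  p1 <- predict_learner(t1$model, unit$taxa)
  p2 <- predict_learner(t2$model, unit$taxa)
  expect_identical(p1, p2)
})

test_that("late integration builds one local model per usable training cohort", {
  st <- simulate_multicohort(small_config(seed = 21))
  spec <- rf_only_spec(variant = "late_covariates_microbiome",
                       folds = 3, repeats = 1, seed = 3)
  fit <- fit_ensemble(st, spec)
  expect_setequal(names(fit$locals), c("c2", "c3", "c4"))
  # covariates restricted to the held-out cohort's availability (c1: all)
  expect_identical(fit$locals$c3$unit$covs, "age")       # c3 records age only
  expect_identical(fit$locals$c4$unit$covs, character(0))  # taxa-only model
  # covariates-only variant: the metadata-free cohort is skipped
  spec_d <- rf_only_spec(variant = "late_covariates",
                         folds = 3, repeats = 1, seed = 3)
  expect_message(fit_d <- fit_ensemble(st, spec_d), "skipped")
  expect_setequal(names(fit_d$locals), c("c2", "c3"))
  # LOSO covariate restriction: held-out c4 has no covariates at all
  fit_h4 <- fit_ensemble(st, spec, held_out = "c4")
  for (l in fit_h4$locals) expect_identical(l$unit$covs, character(0))
})

test_that("ensemble probabilities are the mean of local probabilities", {
  st <- simulate_multicohort(small_config(seed = 22))
  spec <- rf_only_spec(variant = "late_microbiome", folds = 3, repeats = 1,
                       seed = 5)
  fit <- fit_ensemble(st, spec)
  pred <- predict_ensemble(fit, st$cohorts$c1)
  lp <- attr(pred, "local_probabilities")
  expect_equal(pred$probability, unname(rowMeans(lp)))
  expect_identical(pred$label, ifelse(pred$probability >= 0.5, "EC", "benign"))
  # averaging is invariant to cohort order
  fit_r <- fit
  fit_r$locals <- rev(fit_r$locals)
  fit_r$oof_f1 <- rev(fit_r$oof_f1)
  pred_r <- predict_ensemble(fit_r, st$cohorts$c1)
  expect_equal(pred_r$probability, pred$probability)
  # single local model: the ensemble is that model
  fit_1 <- fit
  fit_1$locals <- fit$locals["c2"]
  pred_1 <- predict_ensemble(fit_1, st$cohorts$c1)
  expect_equal(pred_1$probability, unname(lp[, "c2"]))
})

test_that("removing a training cohort only removes that local model", {
  st <- simulate_multicohort(small_config(seed = 23))
  spec <- rf_only_spec(variant = "late_microbiome", folds = 3, repeats = 1,
                       seed = 7)
  fit_all <- fit_ensemble(st, spec)
  st_less <- st
  st_less$cohorts <- st$cohorts[c("c1", "c3", "c4")]
  fit_less <- fit_ensemble(st_less, spec)
  expect_setequal(names(fit_less$locals), c("c3", "c4"))
  for (cid in c("c3", "c4")) {
    p_all <- predict_learner(fit_all$locals[[cid]]$tuned$rf$model,
                             fit_all$locals[[cid]]$unit$taxa)
    p_less <- predict_learner(fit_less$locals[[cid]]$tuned$rf$model,
                              fit_less$locals[[cid]]$unit$taxa)
    expect_identical(p_all, p_less)
  }
})

test_that("early integration pools training cohorts into a single model", {
  st <- simulate_multicohort(small_config(seed = 24))
  spec <- rf_only_spec(variant = "early_raw", folds = 3, repeats = 1, seed = 2)
  fit <- fit_ensemble(st, spec)
  expect_identical(names(fit$locals), "pooled")
  expect_null(fit$combat_model)
  n_train <- sum(vapply(st$cohorts[c("c2", "c3", "c4")], function(c)
    nrow(c$counts), integer(1)))
  expect_equal(length(fit$locals$pooled$unit$labels), n_train)
  spec_b <- rf_only_spec(variant = "early_batch_corrected", folds = 3,
                         repeats = 1, seed = 2)
  fit_b <- fit_ensemble(st, spec_b)
  expect_s3_class(fit_b$combat_model, "batch_model")
  ev <- evaluate_ensemble(fit_b, st)
  expect_equal(ev$report$n, nrow(st$cohorts$c1$counts))
})

test_that("LOSO produces per-study and pooled reports", {
  st <- simulate_multicohort(small_config(seed = 25))
  spec <- rf_only_spec(variant = "late_microbiome", folds = 3, repeats = 1,
                       seed = 11)
  lo <- loso_validate(st, spec)
  expect_setequal(names(lo$per_study), names(st$cohorts))
  total <- sum(vapply(st$cohorts, function(c) nrow(c$counts), integer(1)))
  expect_equal(lo$pooled$n, total)
  expect_true(lo$pooled$auroc >= 0 && lo$pooled$auroc <= 1)
  st2 <- st
  st2$cohorts <- st$cohorts[1:2]
  expect_error(loso_validate(st2, spec), ">= 3")
})
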