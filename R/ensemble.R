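ensemble_variants <- c("early_raw", "early_batch_corrected",
                       "late_microbiome", "late_covariates",
                       "late_covariates_ph", "late_covariates_microbiome")

#' Default hyperparameter grids for the three base-learner families
#'
#' Bagged trees (random forest), boosted trees (xgboost) and a
#' single-hidden-layer network (nnet). Deliberately small; any data.frame
#' grid with the same columns is accepted by [model_spec()].
#'
#' @export
default_grids <- function() {
  list(
    rf = expand.grid(ntree = 200, mtry_frac = c(0.1, 0.33)),
    xgb = expand.grid(nrounds = c(50, 100), max_depth = 3, eta = 0.3),
    nnet = expand.grid(size = c(2, 5), decay = 0.1, maxit = 150)
  )
}

#' Minimal one-point grids (for quick runs and simulations)
#' @export
reduced_grids <- function() {
  list(
    rf = data.frame(ntree = 200, mtry_frac = 0.33),
    xgb = data.frame(nrounds = 50, max_depth = 3, eta = 0.3),
    nnet = data.frame(size = 3, decay = 0.1, maxit = 150)
  )
}

#' Ensemble model specification
#'
#' @param variant integration strategy: early integration on pooled taxon
#'   features, raw (`"early_raw"`) or batch-corrected
#'   (`"early_batch_corrected"`); late integration with one local model per
#'   training cohort using taxa only (`"late_microbiome"`), covariates only
#'   (`"late_covariates"`), covariates plus vaginal pH
#'   (`"late_covariates_ph"`), or covariates plus taxa
#'   (`"late_covariates_microbiome"`).
#' @param grids named list of per-family hyperparameter grids
#'   (see [default_grids()]).
#' @param folds,repeats stratified cross-validation folds and repeats for
#'   tuning (defaults 5 and 3).
#' @param threshold classification threshold; probability >= threshold is
#'   called EC.
#' @param smote rebalance classes with SMOTE-NC inside training folds.
#' @param combine `"average"`: the three tuned families are averaged within
#'   each training unit before cross-cohort averaging; `"best"`: only the
#'   family with the best out-of-fold F1 is kept per unit.
#' @param weight_by_f1 weight cross-cohort averaging by each local model's
#'   out-of-fold F1 instead of the default unweighted mean.
#' @param protect_disease protect the disease label during batch correction
#'   (early_batch_corrected only).
#' @param prevalence_threshold,pseudocount feature-engineering settings.
#' @param seed seed for fold assignment, rebalancing and learner fits.
#' @export
model_spec <- function(variant = "late_covariates_microbiome",
                       grids = default_grids(), folds = 5, repeats = 3,
                       threshold = 0.5, smote = TRUE,
                       combine = c("average", "best"),
                       weight_by_f1 = FALSE, protect_disease = TRUE,
                       prevalence_threshold = 0.05, pseudocount = 0.5,
                       seed = 1) {
  variant <- match.arg(variant, ensemble_variants)
  combine <- match.arg(combine)
  stopifnot(folds >= 2, repeats >= 1, length(grids) >= 1,
            all(vapply(grids, nrow, integer(1)) >= 1))
  structure(list(
    variant = variant, grids = grids, folds = folds, repeats = repeats,
    threshold = threshold, smote = smote, combine = combine,
    weight_by_f1 = weight_by_f1, protect_disease = protect_disease,
    prevalence_threshold = prevalence_threshold, pseudocount = pseudocount,
    seed = seed
  ), class = "model_spec")
}

variant_uses_taxa <- function(variant) {
  variant %in% c("early_raw", "early_batch_corrected", "late_microbiome",
                 "late_covariates_microbiome")
}

variant_covariates <- function(variant) {
  switch(variant,
         late_covariates = c("age", "bmi", "ethnicity"),
         late_covariates_ph = c("age", "bmi", "ethnicity", "ph"),
         late_covariates_microbiome = c("age", "bmi", "ethnicity"),
         character(0))
}

# ---- base learners (uniform fit/predict-probability interface) -----------

model_complexity <- function(family, params) {
  switch(family,
         rf = params$ntree * params$mtry_frac,
         xgb = params$nrounds * params$max_depth,
         nnet = params$size)
}

fit_learner <- function(family, params, X, y, seed = 1) {
  y <- as.integer(y)  # 1 = EC
  if (length(unique(y)) < 2) {
    return(structure(list(constant = mean(y)), class = "constant_learner"))
  }
  set.seed(seed)
  fit <- switch(family,
    rf = randomForest::randomForest(
      x = X, y = factor(y, levels = c(0, 1)),
      ntree = params$ntree,
      mtry = max(1, round(params$mtry_frac * ncol(X)))),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    nnet = {
      ctr <- colMeans(X)
      scl <- pmax(apply(X, 2, stats::sd), 1e-8)
      Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
      net <- nnet::nnet(Xs, y, size = params$size, decay = params$decay,
                        maxit = params$maxit, entropy = TRUE, trace = FALSE)
      list(net = net, center = ctr, scale = scl)
    },
    stop("unknown learner family: ", family))
  structure(list(family = family, fit = fit, params = params,
                 features = colnames(X)), class = "base_learner")
}

predict_learner <- function(model, X) {
  if (inherits(model, "constant_learner")) {
    return(rep(model$constant, nrow(X)))
  }
  X <- X[, model$features, drop = FALSE]
  switch(model$family,
    rf = unname(stats::predict(model$fit, X, type = "prob")[, "1"]),
    xgb = unname(stats::predict(model$fit,
                                xgboost::xgb.DMatrix(X, nthread = 1))),
    nnet = {
      Xs <- sweep(sweep(X, 2, model$fit$center), 2, model$fit$scale, "/")
      as.numeric(stats::predict(model$fit$net, Xs))
    })
}

# ---- cross-validation plumbing -------------------------------------------

# Stratified fold assignment; when a class has fewer members than folds the
# assignment degrades gracefully to as-stratified-as-possible (round-robin).
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

encode_mixed <- function(taxa, cov, cat_levels) {
  parts <- list()
  if (!is.null(taxa)) parts$taxa <- as.matrix(taxa)
  if (!is.null(cov) && ncol(cov) > 0) {
    for (cv in names(cov)) {
      if (is.numeric(cov[[cv]])) {
        parts[[cv]] <- matrix(cov[[cv]], ncol = 1,
                              dimnames = list(NULL, cv))
      } else {
        lv <- cat_levels[[cv]]
        if (length(lv) > 1) {
          m <- vapply(lv[-1], function(l) as.numeric(cov[[cv]] == l),
                      numeric(nrow(cov)))
          m <- matrix(m, nrow = nrow(cov),
                      dimnames = list(NULL, paste0(cv, "_", lv[-1])))
          parts[[cv]] <- m
        }
      }
    }
  }
  do.call(cbind, parts)
}

# Fold-local preprocessing: impute covariates (fit on the training part
# only), rebalance the training part only, encode both parts numerically.
prepare_fold <- function(unit, train_idx, val_idx, spec, seed) {
  cov_tr <- cov_val <- NULL
  n_syn <- 0L
  taxa_tr <- if (!is.null(unit$taxa)) unit$taxa[train_idx, , drop = FALSE]
  taxa_val <- if (!is.null(unit$taxa) && length(val_idx)) {
    unit$taxa[val_idx, , drop = FALSE]
  }
  imp <- NULL
  if (!is.null(unit$cov) && ncol(unit$cov) > 0) {
    cov_tr <- unit$cov[train_idx, , drop = FALSE]
    imp <- mice_impute(cov_tr, predictors = taxa_tr, seed = seed)
    cov_tr <- imp$completed
    if (length(val_idx)) {
      cov_val <- unit$cov[val_idx, , drop = FALSE]
      cov_val <- impute_apply(imp$models, cov_val, predictors = taxa_val)
    }
  }
  y_tr <- as.integer(unit$labels[train_idx] == "EC")
  cat_levels <- if (is.null(cov_tr)) list() else {
    lapply(cov_tr[!vapply(cov_tr, is.numeric, logical(1))],
           function(x) sort(unique(as.character(x))))
  }
  if (spec$smote && length(unique(y_tr)) == 2 && min(table(y_tr)) >= 2) {
    mixed <- as.data.frame(if (is.null(taxa_tr)) cov_tr else
      if (is.null(cov_tr)) taxa_tr else cbind(as.data.frame(taxa_tr), cov_tr))
    sm <- smote_nc(mixed, y_tr, seed = seed)
    n_syn <- sm$n_synthetic
    y_tr <- as.integer(sm$labels)
    aug <- sm$features
    if (!is.null(taxa_tr)) {
      taxa_tr <- as.matrix(aug[, colnames(unit$taxa), drop = FALSE])
      cov_aug <- aug[, setdiff(names(aug), colnames(unit$taxa)), drop = FALSE]
    } else cov_aug <- aug
    if (!is.null(cov_tr)) cov_tr <- cov_aug
  }
  X_tr <- encode_mixed(taxa_tr, cov_tr, cat_levels)
  X_val <- if (length(val_idx)) encode_mixed(taxa_val, cov_val, cat_levels)
  list(X_tr = X_tr, y_tr = y_tr, X_val = X_val, imp = imp,
       cat_levels = cat_levels, n_synthetic = n_syn)
}

#' Tune one base-learner family on one training unit
#'
#' Grid search under repeated stratified cross-validation with in-fold
#' imputation and rebalancing, scored by mean out-of-fold F1 at the spec's
#' threshold; ties broken toward the simpler model, then grid order. The
#' best configuration is refit on the full unit.
#'
#' @param unit a training unit (list with `taxa`, `cov`, `labels`).
#' @param family `"rf"`, `"xgb"` or `"nnet"`.
#' @param spec a [model_spec()].
#' @return list with `model`, `oof_f1`, `grid_f1`, `best_params`.
#' @export
tune_local_model <- function(unit, family, spec) {
  grid <- spec$grids[[family]]
  y <- as.integer(unit$labels == "EC")
  n <- length(y)
  n_grid <- nrow(grid)
  f1s <- matrix(NA_real_, n_grid, spec$repeats)
  audit <- integer(0)
  for (r in seq_len(spec$repeats)) {
    fold <- stratified_folds(unit$labels, spec$folds, spec$seed + 1000 * r)
    oof <- matrix(NA_real_, n, n_grid)
    for (f in sort(unique(fold))) {
      tr <- which(fold != f); va <- which(fold == f)
      fseed <- spec$seed + 1000 * r + f
      prep <- prepare_fold(unit, tr, va, spec, fseed)
      audit <- c(audit, prep$n_synthetic)
      for (g in seq_len(n_grid)) {
        m <- fit_learner(family, grid[g, , drop = FALSE],
                         prep$X_tr, prep$y_tr, seed = fseed + 17 * g)
        oof[va, g] <- predict_learner(m, prep$X_val)
      }
    }
    for (g in seq_len(n_grid)) {
      f1s[g, r] <- f1_score(oof[, g], y == 1, spec$threshold)
    }
  }
  mean_f1 <- rowMeans(f1s)
  cmplx <- vapply(seq_len(n_grid), function(g) {
    model_complexity(family, grid[g, , drop = FALSE])
  }, numeric(1))
  best <- order(-mean_f1, cmplx, seq_len(n_grid))[1]

  full <- prepare_fold(unit, seq_len(n), integer(0), spec, spec$seed)
  model <- fit_learner(family, grid[best, , drop = FALSE],
                       full$X_tr, full$y_tr, seed = spec$seed + 1)
  list(model = model, oof_f1 = mean_f1[best], grid_f1 = mean_f1,
       best_params = grid[best, , drop = FALSE],
       imp = full$imp, cat_levels = full$cat_levels,
       smote_audit = audit)
}

# Build one training unit from a cohort for a given variant, restricted to
# covariates observable in the held-out cohort.
make_unit <- function(cohort, use_taxa, covs, spec, taxonomy) {
  covs <- intersect(covs, cohort$available_covariates)
  taxa <- kept <- NULL
  if (use_taxa) {
    genus <- aggregate_to_genus(cohort$counts, taxonomy)
    filt <- prevalence_filter(genus, spec$prevalence_threshold)
    kept <- attr(filt, "kept")
    taxa <- clr_transform(filt, spec$pseudocount)
  }
  cov <- if (length(covs)) cohort$covariates[, covs, drop = FALSE] else NULL
  if (is.null(taxa) && is.null(cov)) return(NULL)
  list(cohort_id = cohort$cohort_id, taxa = taxa, kept = kept, cov = cov,
       covs = covs, labels = cohort$labels, use_taxa = use_taxa)
}

fit_unit_models <- function(unit, spec) {
  fams <- names(spec$grids)
  tuned <- lapply(fams, function(fm) tune_local_model(unit, fm, spec))
  names(tuned) <- fams
  oof <- vapply(tuned, `[[`, numeric(1), "oof_f1")
  keep <- if (spec$combine == "best") names(which.max(oof)) else fams
  list(unit = unit, tuned = tuned[keep], oof_f1 = oof,
       mean_oof_f1 = mean(oof[keep]))
}

#' Fit an integration-strategy ensemble on a multi-cohort study
#'
#' The held-out cohort is excluded from every fitting step (feature
#' filters, imputation, rebalancing, batch correction and tuning all see
#' training cohorts only). Early variants pool the training cohorts into one
#' matrix of taxon features (the batch-corrected variant adjusts them with
#' the empirical-Bayes batch model first); late variants fit one local model
#' per training cohort. Covariates are restricted to those available in the
#' held-out cohort, matching leave-one-study-out retraining; a cohort
#' lacking every covariate contributes a taxa-only model when the variant
#' includes taxa, and is skipped (with a message) otherwise.
#'
#' @param study a `multicohort_study`.
#' @param spec a [model_spec()].
#' @param held_out overrides the study's held-out designation.
#' @return a `fitted_ensemble`.
#' @export
fit_ensemble <- function(study, spec, held_out = NULL) {
  if (is.null(held_out)) held_out <- study$held_out
  stopifnot(held_out %in% names(study$cohorts))
  train_ids <- setdiff(names(study$cohorts), held_out)
  use_taxa <- variant_uses_taxa(spec$variant)
  covs <- intersect(variant_covariates(spec$variant),
                    study$cohorts[[held_out]]$available_covariates)
  early <- spec$variant %in% c("early_raw", "early_batch_corrected")

  combat_model <- NULL
  if (early) {
    pool <- pool_cohorts(study, train_ids)
    genus <- aggregate_to_genus(pool$counts, study$taxonomy)
    filt <- prevalence_filter(genus, spec$prevalence_threshold)
    taxa <- clr_transform(filt, spec$pseudocount)
    if (spec$variant == "early_batch_corrected") {
      protect <- if (spec$protect_disease) {
        data.frame(label = factor(pool$labels))
      } else NULL
      cb <- fit_apply_combat(taxa, pool$batch, protect = protect)
      taxa <- cb$adjusted
      combat_model <- cb$model
    }
    unit <- list(cohort_id = "pooled", taxa = taxa,
                 kept = attr(filt, "kept"), cov = NULL,
                 covs = character(0), labels = pool$labels,
                 use_taxa = TRUE)
    locals <- list(pooled = fit_unit_models(unit, spec))
  } else {
    if (length(train_ids) < 2) stop("late integration needs >= 2 training cohorts")
    locals <- list()
    for (cid in train_ids) {
      unit <- make_unit(study$cohorts[[cid]], use_taxa, covs, spec,
                        study$taxonomy)
      if (is.null(unit)) {
        message("cohort ", cid, " has no usable features for variant ",
                spec$variant, "; skipped")
        next
      }
      locals[[cid]] <- fit_unit_models(unit, spec)
    }
    if (length(locals) == 0) stop("no training cohort usable for variant")
  }
  structure(list(
    variant = spec$variant, spec = spec, locals = locals,
    combat_model = combat_model, held_out = held_out,
    taxonomy = study$taxonomy,
    oof_f1 = vapply(locals, `[[`, numeric(1), "mean_oof_f1")
  ), class = "fitted_ensemble")
}

predict_local <- function(local, cohort, fitted) {
  unit <- local$unit
  spec <- fitted$spec
  taxa <- NULL
  if (unit$use_taxa) {
    genus <- aggregate_to_genus(cohort$counts, fitted$taxonomy)
    filt <- apply_feature_filter(genus, unit$kept)
    taxa <- clr_transform(filt, spec$pseudocount)
    if (!is.null(fitted$combat_model)) {
      taxa <- apply_combat(fitted$combat_model, taxa)
    }
  }
  probs <- vapply(local$tuned, function(t) {
    cov <- NULL
    if (length(unit$covs)) {
      cov <- cohort$covariates[, unit$covs, drop = FALSE]
      cov <- impute_apply(t$imp$models, cov, predictors = taxa)
    }
    X <- encode_mixed(taxa, cov, t$cat_levels)
    predict_learner(t$model, X)
  }, numeric(nrow(cohort$counts)))
  rowMeans(matrix(probs, nrow = nrow(cohort$counts)))
}

#' Predict a cohort with a fitted ensemble
#'
#' Every applicable local model scores each sample; the ensemble probability
#' is their arithmetic mean (optionally weighted by out-of-fold F1), and the
#' hard label is EC iff the averaged probability is >= the spec's threshold.
#'
#' @param fitted a `fitted_ensemble`.
#' @param cohort a `cohort_dataset`.
#' @return a `prediction_set` data.frame with per-model probabilities, the
#'   averaged probability, and the hard label.
#' @export
predict_ensemble <- function(fitted, cohort) {
  if (length(fitted$locals) == 0) stop("no applicable local model")
  local_probs <- vapply(fitted$locals, predict_local,
                        numeric(nrow(cohort$counts)),
                        cohort = cohort, fitted = fitted)
  local_probs <- matrix(local_probs, nrow = nrow(cohort$counts),
                        dimnames = list(cohort$sample_ids,
                                        names(fitted$locals)))
  w <- if (fitted$spec$weight_by_f1) {
    f1 <- fitted$oof_f1
    if (sum(f1) == 0) rep(1 / length(f1), length(f1)) else f1 / sum(f1)
  } else rep(1 / ncol(local_probs), ncol(local_probs))
  avg <- as.numeric(local_probs %*% w)
  out <- data.frame(sample_id = cohort$sample_ids,
                    probability = avg,
                    label = ifelse(avg >= fitted$spec$threshold, "EC", "benign"),
                    stringsAsFactors = FALSE)
  attr(out, "local_probabilities") <- local_probs
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Evaluate a fitted ensemble on its held-out cohort
#'
#' @param fitted a `fitted_ensemble`.
#' @param study the study it was fitted on.
#' @export
evaluate_ensemble <- function(fitted, study) {
  cohort <- study$cohorts[[fitted$held_out]]
  pred <- predict_ensemble(fitted, cohort)
  rep <- metric_report(pred$probability, cohort$labels == "EC",
                       threshold = fitted$spec$threshold)
  rep$cohort <- fitted$held_out
  list(report = rep, predictions = pred)
}

#' Leave-one-study-out validation
#'
#' Each cohort in turn is held out; the ensemble is retrained on the rest,
#' restricted to the covariates available in the held-out cohort, and its
#' predictions are scored. Pooled metrics concatenate all out-of-study
#' predictions (micro-pooling of confusion counts and of scores for AUROC);
#' per-study reports are also returned. A single-class held-out cohort gets
#' an undefined AUROC flag but its other metrics are still computed.
#'
#' @param study a `multicohort_study` with >= 3 cohorts.
#' @param spec a [model_spec()].
#' @export
loso_validate <- function(study, spec) {
  ids <- names(study$cohorts)
  if (length(ids) < 3) stop("LOSO needs >= 3 cohorts")
  per_study <- list()
  probs <- truth <- c()
  for (h in ids) {
    fitted <- fit_ensemble(study, spec, held_out = h)
    ev <- evaluate_ensemble(fitted, study)
    per_study[[h]] <- ev$report
    probs <- c(probs, ev$predictions$probability)
    truth <- c(truth, study$cohorts[[h]]$labels == "EC")
  }
  pooled <- metric_report(probs, truth, threshold = spec$threshold)
  list(per_study = per_study, pooled = pooled,
       predictions = data.frame(probability = probs, truth = truth))
}
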