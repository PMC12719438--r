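#' SMOTE-NC minority oversampling for mixed feature types
#'
#' Synthetic minority samples by k-nearest-neighbour interpolation:
#' numeric features are interpolated between a minority seed point and one
#' of its k nearest minority neighbours with uniform lambda in \[0, 1\];
#' categorical features take the majority vote among the seed's k
#' neighbours (ties broken toward the seed's own value). The neighbour
#' distance is squared-Euclidean on numeric features plus, for every
#' differing categorical feature, the squared median of the numeric
#' features' standard deviations (the standard nominal penalty).
#'
#' @param features data.frame; numeric columns and factor/character columns.
#' @param labels two-class vector; the rarer class is oversampled.
#' @param k_neighbors neighbours considered, default 5, clipped to
#'   (minority size - 1).
#' @param target_ratio desired minority/majority ratio after augmentation,
#'   default 1.
#' @param seed RNG seed.
#' @return list with `features` (original rows then synthetic rows),
#'   `labels`, and `n_synthetic`.
#' @export
smote_nc <- function(features, labels, k_neighbors = 5, target_ratio = 1,
                     seed = 1) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels))
  tab <- table(labels)
  if (length(tab) != 2) stop("need exactly two classes")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  n_target <- round(target_ratio * n_maj)
  n_syn <- max(0, n_target - n_min)
  if (n_syn == 0) {
    return(list(features = features, labels = labels, n_synthetic = 0L))
  }
  if (n_min < 2) stop("minority class smaller than 2")
  k <- min(k_neighbors, n_min - 1)

  num_cols <- vapply(features, is.numeric, logical(1))
  cat_cols <- !num_cols
  Xm <- features[labels == minority, , drop = FALSE]
  Xnum <- as.matrix(Xm[, num_cols, drop = FALSE])
  if (any(!is.finite(Xnum))) stop("numeric features must be finite")
  pen <- if (any(num_cols)) {
    stats::median(apply(as.matrix(features[, num_cols, drop = FALSE]), 2,
                        stats::sd))^2
  } else 1

  d2 <- as.matrix(stats::dist(Xnum))^2
  if (any(cat_cols)) {
    for (cv in names(features)[cat_cols]) {
      v <- as.character(Xm[[cv]])
      d2 <- d2 + pen * outer(v, v, "!=")
    }
  }
  diag(d2) <- Inf

  set.seed(seed)
  seeds_idx <- sample(rep_len(seq_len(n_min), n_syn))
  syn <- vector("list", n_syn)
  for (s in seq_len(n_syn)) {
    i <- seeds_idx[s]
    nn <- order(d2[i, ])[seq_len(k)]
    j <- nn[sample.int(k, 1)]
    lambda <- stats::runif(1)
    row <- Xm[i, , drop = FALSE]
    if (any(num_cols)) {
      row[num_cols] <- Xm[i, num_cols] + lambda * (Xm[j, num_cols] - Xm[i, num_cols])
    }
    if (any(cat_cols)) {
      for (cv in names(features)[cat_cols]) {
        votes <- table(as.character(Xm[[cv]][nn]))
        top <- names(votes)[votes == max(votes)]
        row[[cv]] <- if (as.character(Xm[[cv]][i]) %in% top) {
          as.character(Xm[[cv]][i])
        } else top[1]
      }
    }
    syn[[s]] <- row
  }
  syn <- do.call(rbind, syn)
  rownames(syn) <- paste0("synthetic_", seq_len(n_syn))
  list(features = rbind(features, syn),
       labels = c(labels, rep(minority, n_syn)),
       n_synthetic = n_syn)
}

col_mode <- function(x) {
  tb <- table(as.character(x))
  names(tb)[which.max(tb)]
}

# Reduce a wide fully-observed predictor block to a few principal
# components so the chained-equation models stay full rank on small cohorts.
reduce_predictors <- function(predictors, n, rotation = NULL, center = NULL) {
  if (is.null(predictors)) return(list(x = NULL, rotation = NULL, center = NULL))
  P <- as.matrix(predictors)
  k <- min(5, ncol(P), n - 2)
  if (is.null(rotation)) {
    if (ncol(P) <= k) {
      colnames(P) <- paste0("pred_pc", seq_len(ncol(P)))
      return(list(x = P, rotation = NULL, center = NULL))
    }
    pc <- stats::prcomp(P, center = TRUE, scale. = FALSE)
    rotation <- pc$rotation[, seq_len(k), drop = FALSE]
    center <- pc$center
  }
  x <- sweep(P, 2, center) %*% rotation
  colnames(x) <- paste0("pred_pc", seq_len(ncol(x)))
  list(x = x, rotation = rotation, center = center)
}

#' Chained-equation imputation of missing covariates
#'
#' Single-completion multivariate imputation by chained equations: missing
#' cells are initialized at the column mean (numeric) or mode (categorical),
#' then each incomplete covariate in turn is regressed on all other
#' covariates plus an optional fully-observed predictor block (e.g. the
#' microbiome CLR features, reduced to principal components), cycling
#' `n_iterations` times. Numeric covariates use a linear model, categorical
#' ones one-vs-rest logistic models; imputations are the conditional
#' mean/most-probable class, so the completion is deterministic. Observed
#' cells are never altered. The per-covariate models from the final cycle
#' are frozen in the result for test-time application via [impute_apply()].
#'
#' @param covariates data.frame with possibly-missing cells.
#' @param predictors optional fully-observed numeric matrix (same rows).
#' @param n_iterations chained cycles, default 5.
#' @param seed kept for interface stability; the conditional-mean completion
#'   is deterministic.
#' @return list with `completed` data.frame and `models` (frozen state).
#' @export
mice_impute <- function(covariates, predictors = NULL, n_iterations = 5,
                        seed = 1) {
  covariates <- as.data.frame(covariates)
  n <- nrow(covariates)
  all_missing <- vapply(covariates, function(x) all(is.na(x)), logical(1))
  if (any(all_missing)) {
    stop("covariate(s) entirely missing: ",
         paste(names(covariates)[all_missing], collapse = ", "),
         "; exclude them for this cohort instead of imputing")
  }
  red <- reduce_predictors(predictors, n)
  miss_frac <- vapply(covariates, function(x) mean(is.na(x)), numeric(1))
  targets <- names(covariates)[miss_frac > 0]
  targets <- targets[order(miss_frac[targets])]

  init <- list()
  completed <- covariates
  for (cv in names(covariates)) {
    if (is.numeric(covariates[[cv]])) {
      init[[cv]] <- mean(covariates[[cv]], na.rm = TRUE)
    } else {
      completed[[cv]] <- as.character(completed[[cv]])
      init[[cv]] <- col_mode(completed[[cv]][!is.na(completed[[cv]])])
    }
    if (anyNA(completed[[cv]])) {
      completed[[cv]][is.na(completed[[cv]])] <- init[[cv]]
    }
  }
  cat_levels <- lapply(completed[!vapply(completed, is.numeric, logical(1))],
                       function(x) sort(unique(x)))
  if (length(targets) == 0) {
    return(list(completed = completed,
                models = list(targets = character(0), init = init,
                              cat_levels = cat_levels,
                              rotation = red$rotation, center = red$center,
                              n_iterations = n_iterations)))
  }

  models <- list()
  for (it in seq_len(n_iterations)) {
    for (cv in targets) {
      obs <- !is.na(covariates[[cv]])
      rhs <- design_for(completed, cv, red$x, cat_levels)
      models[[cv]] <- fit_impute_model(covariates[[cv]][obs],
                                       rhs[obs, , drop = FALSE],
                                       numeric_target = is.numeric(covariates[[cv]]))
      pred <- predict_impute_model(models[[cv]], rhs[!obs, , drop = FALSE])
      completed[[cv]][!obs] <- pred
    }
  }
  list(completed = completed,
       models = list(targets = targets, fits = models, init = init,
                     covariate_names = names(covariates),
                     cat_levels = cat_levels,
                     rotation = red$rotation, center = red$center,
                     n_iterations = n_iterations))
}

design_for <- function(completed, target, pred_x, cat_levels) {
  others <- setdiff(names(completed), target)
  X <- matrix(1, nrow(completed), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in others) {
    v <- completed[[cv]]
    if (is.numeric(v)) {
      X <- cbind(X, stats::setNames(data.frame(v), cv))
    } else {
      lv <- cat_levels[[cv]]
      for (l in lv[-1]) {
        X <- cbind(X, stats::setNames(data.frame(as.numeric(v == l)),
                                      paste0(cv, "_", l)))
      }
    }
  }
  X <- as.matrix(X)
  if (!is.null(pred_x)) X <- cbind(X, pred_x)
  X
}

fit_impute_model <- function(y, X, numeric_target) {
  if (numeric_target) {
    fit <- stats::lm.fit(X, y)
    coefs <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    list(type = "linear", coef = coefs, cols = colnames(X))
  } else {
    y <- as.character(y)
    lv <- sort(unique(y))
    cf <- lapply(lv, function(l) {
      fit <- suppressWarnings(
        stats::glm.fit(X, as.numeric(y == l),
                       family = stats::binomial()))
      ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    })
    names(cf) <- lv
    list(type = "logistic", coef = cf, levels = lv, cols = colnames(X))
  }
}

predict_impute_model <- function(model, X) {
  X <- X[, model$cols, drop = FALSE]
  if (model$type == "linear") {
    as.numeric(X %*% model$coef)
  } else {
    scores <- vapply(model$coef, function(cf) as.numeric(X %*% cf),
                     numeric(nrow(X)))
    scores <- matrix(scores, nrow = nrow(X))
    model$levels[max.col(scores, ties.method = "first")]
  }
}

#' Apply frozen imputation models to new data
#'
#' Initializes missing cells with the training means/modes and cycles the
#' frozen per-covariate models, never altering observed cells.
#'
#' @param models the `models` element returned by [mice_impute()].
#' @param covariates new data.frame with the same covariate columns.
#' @param predictors optional predictor matrix matching the training block.
#' @export
impute_apply <- function(models, covariates, predictors = NULL) {
  covariates <- as.data.frame(covariates)
  red_x <- if (!is.null(models$rotation)) {
    sweep(as.matrix(predictors), 2, models$center) %*% models$rotation
  } else if (!is.null(predictors)) {
    P <- as.matrix(predictors)
    colnames(P) <- NULL
    P
  } else NULL
  if (!is.null(red_x)) colnames(red_x) <- paste0("pred_pc", seq_len(ncol(red_x)))
  completed <- covariates
  for (cv in names(covariates)) {
    if (!is.numeric(completed[[cv]])) {
      completed[[cv]] <- as.character(completed[[cv]])
    }
    if (anyNA(completed[[cv]])) {
      completed[[cv]][is.na(completed[[cv]])] <- models$init[[cv]]
    }
  }
  for (it in seq_len(models$n_iterations)) {
    for (cv in models$targets) {
      obs <- !is.na(covariates[[cv]])
      if (all(obs)) next
      rhs <- design_for(completed, cv, red_x, models$cat_levels)
      pred <- predict_impute_model(models$fits[[cv]],
                                   rhs[!obs, , drop = FALSE])
      completed[[cv]][!obs] <- pred
    }
  }
  completed
}
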