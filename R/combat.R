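#' Empirical-Bayes location-scale batch correction
#'
#' Parametric empirical-Bayes adjustment of continuous (CLR-scale) features
#' across batches: features are standardized preserving a protected design
#' (by default the disease label), per-batch per-feature location and scale
#' are estimated, shrunk toward batch-level priors (normal prior on the
#' location, inverse-gamma on the scale, hyperparameters by method of
#' moments), then subtracted/rescaled and the grand mean and protected
#' effects restored.
#'
#' The returned `batch_model` carries the frozen standardization parameters,
#' so a batch unseen at fit time (e.g. a held-out cohort) can be adjusted
#' later with [apply_combat()] without touching its labels: its own batch
#' term is estimated from its features alone against the frozen reference.
#'
#' @param features samples x features numeric matrix.
#' @param batch factor/character of batch labels (>= 2 batches, >= 2 samples
#'   each).
#' @param protect optional data.frame of biological covariates whose effects
#'   must be preserved (e.g. a disease label); `NULL` disables protection.
#' @param eb use empirical-Bayes shrinkage (TRUE) or raw per-batch
#'   location/scale (FALSE).
#' @param var_floor lower bound applied to per-batch variances (guards
#'   zero-variance features; its use is recorded in the model).
#' @return list with `adjusted` (corrected matrix) and `model`
#'   (a `batch_model`).
#' @export
fit_apply_combat <- function(features, batch, protect = NULL, eb = TRUE,
                             var_floor = 1e-8) {
  Y <- as.matrix(features)
  batch <- factor(batch)
  stopifnot(nrow(Y) == length(batch))
  if (nlevels(batch) < 2) stop("need >= 2 batches")
  nb <- table(batch)
  if (any(nb < 2)) stop("single-sample batch: ",
                        paste(names(nb)[nb < 2], collapse = ", "))
  n <- nrow(Y)
  B <- stats::model.matrix(~ 0 + batch)
  if (!is.null(protect)) {
    protect <- as.data.frame(protect)
    C <- stats::model.matrix(~ ., data = protect)[, -1, drop = FALSE]
    X <- cbind(B, C)
  } else {
    C <- NULL
    X <- B
  }
  if (qr(X)$rank < ncol(X)) {
    stop("batch + protected design is rank deficient (confounded)")
  }
  beta <- qr.coef(qr(X), Y)
  gamma_hat0 <- beta[seq_len(nlevels(batch)), , drop = FALSE]
  alpha <- as.numeric(crossprod(as.numeric(nb) / n, gamma_hat0))
  prot_part <- if (is.null(C)) 0 else C %*% beta[-seq_len(nlevels(batch)), , drop = FALSE]
  resid <- Y - X %*% beta
  sigma2 <- colSums(resid^2) / n
  floored <- sigma2 < var_floor
  sigma2 <- pmax(sigma2, var_floor)
  sigma <- sqrt(sigma2)

  Z <- sweep(Y - prot_part, 2, alpha) |> sweep(2, sigma, "/")
  est <- estimate_batch_effects(Z, batch, eb, var_floor)

  adjusted <- Z
  for (b in levels(batch)) {
    i <- batch == b
    adjusted[i, ] <- sweep(
      sweep(Z[i, , drop = FALSE], 2, est$gamma_star[b, ]),
      2, sqrt(est$delta2_star[b, ]), "/")
  }
  adjusted <- sweep(adjusted, 2, sigma, "*") |> sweep(2, alpha, "+")
  adjusted <- adjusted + prot_part

  model <- structure(list(
    alpha = alpha, sigma = sigma, eb = eb, var_floor = var_floor,
    feature_names = colnames(Y), batches = levels(batch),
    gamma_hat = est$gamma_hat, delta2_hat = est$delta2_hat,
    gamma_star = est$gamma_star, delta2_star = est$delta2_star,
    hyper = est$hyper, n_floored = sum(floored)
  ), class = "batch_model")
  list(adjusted = adjusted, model = model)
}

estimate_batch_effects <- function(Z, batch, eb, var_floor) {
  lv <- levels(batch)
  m <- ncol(Z)
  gamma_hat <- delta2_hat <- matrix(0, length(lv), m,
                                    dimnames = list(lv, colnames(Z)))
  for (b in lv) {
    zb <- Z[batch == b, , drop = FALSE]
    gamma_hat[b, ] <- colMeans(zb)
    delta2_hat[b, ] <- pmax(apply(zb, 2, stats::var), var_floor)
  }
  if (!eb) {
    return(list(gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                gamma_star = gamma_hat, delta2_star = delta2_hat,
                hyper = NULL))
  }
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  hyper <- list()
  for (b in lv) {
    nb <- sum(batch == b)
    g <- gamma_hat[b, ]; d2 <- delta2_hat[b, ]
    gbar <- mean(g); tau2 <- stats::var(g)
    v <- mean(d2); s2 <- stats::var(d2)
    # inverse-gamma hyperparameters by method of moments
    lambda <- (2 * s2 + v^2) / max(s2, 1e-12)
    theta <- (v * s2 + v^3) / max(s2, 1e-12)
    zb <- Z[batch == b, , drop = FALSE]
    g_star <- g; d2_star <- d2
    for (it in 1:100) {
      g_new <- (nb * tau2 * g + d2_star * gbar) / (nb * tau2 + d2_star)
      ssr <- colSums(sweep(zb, 2, g_new)^2)
      d2_new <- (theta + 0.5 * ssr) / (nb / 2 + lambda - 1)
      d2_new <- pmax(d2_new, var_floor)
      if (max(abs(g_new - g_star), abs(d2_new - d2_star)) < 1e-8) {
        g_star <- g_new; d2_star <- d2_new; break
      }
      g_star <- g_new; d2_star <- d2_new
    }
    gamma_star[b, ] <- g_star
    delta2_star[b, ] <- d2_star
    hyper[[b]] <- list(gamma_bar = gbar, tau2 = tau2,
                       lambda = lambda, theta = theta)
  }
  list(gamma_hat = gamma_hat, delta2_hat = delta2_hat,
       gamma_star = gamma_star, delta2_star = delta2_star, hyper = hyper)
}

#' Adjust a new batch against a frozen batch model
#'
#' Standardizes the new batch with the model's frozen grand mean and pooled
#' scale, estimates the batch's own location/scale per feature (empirical
#' Bayes against priors estimated from this batch's own effect distribution,
#' matching the fit-time procedure), and removes them. No label or protected
#' covariate of the new batch is used.
#'
#' @param model a `batch_model` from [fit_apply_combat()].
#' @param features samples x features matrix for the new batch (columns must
#'   match the model's feature set).
#' @export
apply_combat <- function(model, features) {
  Y <- as.matrix(features)
  stopifnot(inherits(model, "batch_model"),
            identical(colnames(Y), model$feature_names))
  if (nrow(Y) < 2) stop("single-sample batch cannot be adjusted")
  Z <- sweep(Y, 2, model$alpha) |> sweep(2, model$sigma, "/")
  batch <- factor(rep("new", nrow(Y)))
  est <- estimate_batch_effects(Z, batch, model$eb, model$var_floor)
  adj <- sweep(sweep(Z, 2, est$gamma_star["new", ]),
               2, sqrt(est$delta2_star["new", ]), "/")
  sweep(adj, 2, model$sigma, "*") |> sweep(2, model$alpha, "+")
}

#' Serialize a batch model as JSON for audit
#'
#' @param model a `batch_model`.
#' @param path output path.
#' @export
write_batch_model <- function(model, path) {
  jsonlite::write_json(
    list(alpha = model$alpha, sigma = model$sigma,
         batches = model$batches, eb = model$eb,
         gamma_hat = apply(model$gamma_hat, 1, identity, simplify = FALSE),
         delta2_hat = apply(model$delta2_hat, 1, identity, simplify = FALSE),
         gamma_star = apply(model$gamma_star, 1, identity, simplify = FALSE),
         delta2_star = apply(model$delta2_star, 1, identity, simplify = FALSE),
         hyper = model$hyper, n_floored = model$n_floored),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
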