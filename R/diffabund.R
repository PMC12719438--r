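#' Holm step-down multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "holm"`: sort
#' p-values ascending, multiply the k-th by `m - k + 1`, enforce
#' monotonicity, cap at 1.
#'
#' @param pvals numeric vector in \[0, 1\].
#' @export
holm_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "holm")
}

#' Bias-corrected covariate-adjusted differential abundance
#'
#' A log-linear differential-abundance procedure that corrects for unequal
#' per-sample sampling fractions (library-size bias) before testing, in the
#' spirit of ANCOM-BC. The sampling-fraction offset of each sample is
#' estimated as a median across taxa, which is robust to the minority of
#' truly differential taxa:
#'
#' 1. `y = ln(counts + pseudocount)`;
#' 2. initialize per-sample offsets `delta_j` as the median over taxa of
#'    `y_ij - mean_i(y_i.)` (deviation from the taxon mean);
#' 3. iterate: regress `y_ij - delta_j` on the design per taxon; push the
#'    per-coefficient median across taxa into the offsets (the offsets and
#'    coefficients are only jointly identified, and anchoring the median
#'    coefficient at zero — most taxa assumed null — is the bias
#'    correction); re-estimate `delta_j` from the per-sample median
#'    residual; stop when `max |change in delta| < tol` (default 1e-6) or
#'    after `max_iter` iterations;
#' 4. Wald z on the coefficient of interest per taxon;
#' 5. Holm step-down across taxa.
#'
#' Complete cases on the design are used; samples with missing covariates
#' are dropped with a message.
#'
#' @param counts samples x taxa count matrix.
#' @param design data.frame of covariates including the variable of interest.
#' @param term name of the design column to test (default `"label"`); for a
#'   factor, the coefficient of its second level is tested.
#' @param pseudocount offset for the log transform, default 0.5.
#' @param min_prevalence taxa present (count > 0) in less than this fraction
#'   of the analyzed samples are screened out before testing (default 0.05):
#'   near-all-zero taxa have degenerate variance estimates and dominate the
#'   family-wise error if tested. Screened taxa appear in the result with NA
#'   statistics and do not count toward the Holm family.
#' @param tol,max_iter convergence control for the offset iteration.
#' @return a `da_result` list: `table` (per-taxon lfc, se, z, p, p_holm),
#'   `offsets` (per-sample bias estimates), `coefficients` (all terms),
#'   `converged`, `iterations`, `trace`.
#' @export
fit_bias_corrected_da <- function(counts, design, term = "label",
                                  pseudocount = 0.5, min_prevalence = 0.05,
                                  tol = 1e-6, max_iter = 100) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  }
  all_taxa <- colnames(counts)
  design <- as.data.frame(design)
  stopifnot(nrow(counts) == nrow(design), term %in% names(design))
  cc <- stats::complete.cases(design)
  if (!all(cc)) {
    message(sum(!cc), " sample(s) dropped for missing covariates")
    counts <- counts[cc, , drop = FALSE]
    design <- design[cc, , drop = FALSE]
  }
  lab <- design[[term]]
  if (length(unique(lab)) < 2) stop("term has a single level")
  if (is.factor(lab) || is.character(lab) || is.logical(lab)) {
    if (min(table(lab)) < 2) stop("need >= 2 samples per class")
  }
  X <- stats::model.matrix(~ ., data = design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design not full rank on complete cases")
  screened <- colMeans(counts > 0) < min_prevalence
  counts <- counts[, !screened, drop = FALSE]
  if (ncol(counts) == 0) stop("no taxon passes the prevalence screen")
  n <- nrow(counts); m <- ncol(counts)
  y <- log(counts + pseudocount)

  # locate the tested coefficient
  term_cols <- which(attr(X, "assign") == match(term, names(design)))
  test_col <- term_cols[1]

  delta <- apply(sweep(y, 2, colMeans(y)), 1, stats::median)
  delta <- delta - mean(delta)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  XtXinv <- chol2inv(chol(crossprod(X)))
  damp <- 1
  center_beta <- function(delta, beta) {
    # The offsets and the coefficients are only jointly identified: any
    # design-aligned shift can move between them. Anchor the median
    # coefficient across taxa at zero (most taxa are assumed null), pushing
    # the median into the per-sample offsets; this is the bias correction.
    med_coef <- apply(beta[-1, , drop = FALSE], 1, stats::median)
    delta + as.numeric(X[, -1, drop = FALSE] %*% med_coef)
  }
  for (iter in seq_len(max_iter)) {
    yc <- y - delta
    beta <- qr.coef(qx, yc)              # p x m
    resid <- yc - X %*% beta
    delta_ctr <- center_beta(delta, beta)
    med <- apply(resid, 1, stats::median)
    delta_new <- delta_ctr + damp * med
    delta_new <- delta_new - mean(delta_new)
    step <- max(abs(delta_new - delta))
    # the median update can cycle; halve the step when progress stalls
    if (length(trace) && step > 0.9 * trace[length(trace)]) {
      damp <- max(damp / 2, 0.1)
    }
    trace <- c(trace, step)
    delta <- delta_new
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("offset iteration did not converge; max step ",
            signif(trace[length(trace)], 3))
  }
  yc <- y - delta
  beta <- qr.coef(qx, yc)
  med_coef <- apply(beta[-1, , drop = FALSE], 1, stats::median)
  beta[-1, ] <- sweep(beta[-1, , drop = FALSE], 1, med_coef)
  delta <- delta + as.numeric(X[, -1, drop = FALSE] %*% med_coef)
  yc <- y - delta
  resid <- yc - X %*% beta
  df <- n - qx$rank
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtXinv[test_col, test_col])
  lfc <- beta[test_col, ]
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(
    taxon = all_taxa, lfc = NA_real_, se = NA_real_, z = NA_real_,
    p = NA_real_, p_holm = NA_real_, screened = screened,
    row.names = NULL, stringsAsFactors = FALSE
  )
  idx <- match(colnames(counts), all_taxa)
  tab$lfc[idx] <- lfc
  tab$se[idx] <- se
  tab$z[idx] <- z
  tab$p[idx] <- p
  tab$p_holm[idx] <- holm_adjust(p)
  structure(list(
    table = tab, offsets = delta, coefficients = beta,
    converged = converged, iterations = iter, trace = trace,
    term = term, df = df
  ), class = "da_result")
}

#' Write a differential-abundance result as TSV, JSON and an edge list
#'
#' The edge list (term, taxon, sign) records every taxon significant at the
#' given Holm-adjusted level, mirroring a multivariate-association network.
#'
#' @param res a `da_result`.
#' @param path base output path; writes `<path>.tsv`, `<path>.json` and
#'   `<path>_edges.tsv`.
#' @param alpha significance level on Holm-adjusted p for the edge list.
#' @export
write_da_result <- function(res, path, alpha = 0.05) {
  utils::write.table(res$table, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(table = res$table, converged = res$converged,
         iterations = res$iterations, term = res$term),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sig <- res$table[which(res$table$p_holm <= alpha), ]
  edges <- data.frame(term = res$term, taxon = sig$taxon,
                      sign = ifelse(sig$lfc > 0, "+", "-"))
  utils::write.table(edges, paste0(path, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
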