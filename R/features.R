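#' Aggregate a taxon count table to the genus level
#'
#' Columns of the count matrix are summed within genus. Taxa unassigned at
#' the genus rank are grouped under their nearest resolved ancestor label
#' (e.g. a family), prefixed with `"unclassified_"`, so per-sample totals are
#' conserved exactly.
#'
#' @param counts samples x taxa non-negative matrix with column names.
#' @param taxonomy data.frame with one row per taxon: columns `taxon`
#'   (matching `colnames(counts)`), `genus` (NA when unassigned) and
#'   `parent` (nearest resolved ancestor label, used when genus is NA).
#' @return samples x genera count matrix.
#' @export
aggregate_to_genus <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have taxon column names")
  if (!all(colnames(counts) %in% taxonomy$taxon)) {
    stop("taxonomy does not cover every column of counts")
  }
  tx <- taxonomy[match(colnames(counts), taxonomy$taxon), ]
  group <- ifelse(is.na(tx$genus) | tx$genus == "",
                  paste0("unclassified_", tx$parent), tx$genus)
  groups <- unique(group)
  out <- vapply(groups, function(g) {
    rowSums(counts[, group == g, drop = FALSE])
  }, numeric(nrow(counts)))
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), groups))
  out
}

#' Filter taxa by prevalence
#'
#' Removes taxa present (count > 0) in fewer than `threshold` of samples;
#' taxa whose presence fraction equals the threshold exactly are kept. The
#' sample set is unchanged. Returns the filtered matrix with the surviving
#' feature list attached as `attr(, "kept")`, so a filter learned on training
#' data can be frozen and re-applied to test data via [apply_feature_filter()].
#'
#' @param counts samples x taxa matrix.
#' @param threshold required presence fraction in (0, 1); default 0.05.
#' @export
prevalence_filter <- function(counts, threshold = 0.05) {
  counts <- as.matrix(counts)
  stopifnot(threshold > 0, threshold < 1)
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  prev <- colMeans(counts > 0)
  keep <- prev >= threshold
  out <- counts[, keep, drop = FALSE]
  attr(out, "kept") <- colnames(counts)[keep]
  out
}

#' Re-apply a frozen feature list to a new count table
#'
#' Features in `kept` absent from `counts` are filled with zero counts, so a
#' model trained on the frozen list always sees its full feature set.
#'
#' @param counts samples x taxa matrix.
#' @param kept character vector of feature names (from [prevalence_filter()]).
#' @export
apply_feature_filter <- function(counts, kept) {
  counts <- as.matrix(counts)
  out <- matrix(0, nrow(counts), length(kept),
                dimnames = list(rownames(counts), kept))
  common <- intersect(kept, colnames(counts))
  out[, common] <- counts[, common]
  out
}

#' Centered log-ratio transform
#'
#' `clr(x)_i = ln(x_i + c) - mean_j ln(x_j + c)` per sample, with pseudocount
#' `c` to admit zero counts. Each transformed row sums to zero. Scale
#' invariance (multiplying a sample's counts by a positive constant leaving
#' the transform unchanged) holds exactly only in the limit of a vanishing
#' pseudocount, i.e. approximately for large counts.
#'
#' @param counts samples x taxa non-negative matrix.
#' @param pseudocount positive offset added before taking logs; default 0.5
#'   (the half-count convention).
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(pseudocount > 0, all(counts >= 0))
  logx <- log(counts + pseudocount)
  sweep(logx, 1, rowMeans(logx))
}

#' Total-sum scaling to relative abundances
#'
#' @param counts samples x taxa matrix; every sample total must be positive.
#' @export
relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    bad <- rownames(counts)[totals <= 0]
    if (is.null(bad)) bad <- which(totals <= 0)
    stop("zero-total sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 1, totals, "/")
}

#' Build a model-ready feature matrix from one cohort
#'
#' Fixed pipeline order: genus aggregation, then prevalence filtering (on the
#' data at hand, or a frozen list), then CLR. Covariate columns, when
#' requested and available in the cohort, are appended after the taxon block
#' with categorical covariates one-hot encoded against recorded levels.
#'
#' @param cohort a `cohort_dataset` (see [simulate_multicohort()]).
#' @param covariates character vector of covariate names to append
#'   (subset of age, bmi, ethnicity, ph); silently restricted to those the
#'   cohort actually records.
#' @param prevalence_threshold presence fraction for the taxon filter.
#' @param pseudocount CLR pseudocount.
#' @param frozen a previous `feature_matrix`'s `frozen` element; when given,
#'   its feature list and encoding are re-applied instead of refit.
#' @return a `feature_matrix`: list with `values` (numeric matrix), `kinds`
#'   (per-column tag), `labels`, `covariate_data` (raw covariate frame for
#'   imputation/rebalancing), and `frozen` (the reusable preprocessing state).
#' @export
build_feature_matrix <- function(cohort, covariates = character(),
                                 prevalence_threshold = 0.05,
                                 pseudocount = 0.5, frozen = NULL) {
  genus <- aggregate_to_genus(cohort$counts, cohort$taxonomy)
  if (is.null(frozen)) {
    filtered <- prevalence_filter(genus, prevalence_threshold)
    kept <- attr(filtered, "kept")
    covariates <- intersect(covariates, cohort$available_covariates)
    cat_levels <- lapply(cohort$covariates[intersect(covariates, c("ethnicity", "ph"))],
                         function(x) levels(factor(x)))
  } else {
    kept <- frozen$kept
    filtered <- apply_feature_filter(genus, kept)
    covariates <- intersect(frozen$covariates, cohort$available_covariates)
    cat_levels <- frozen$cat_levels
    pseudocount <- frozen$pseudocount
  }
  values <- clr_transform(filtered, pseudocount)
  kinds <- rep("taxon", ncol(values))
  cov_df <- NULL
  if (length(covariates)) {
    cov_df <- cohort$covariates[, covariates, drop = FALSE]
    for (cv in covariates) {
      if (cv %in% c("age", "bmi")) {
        values <- cbind(values, matrix(cov_df[[cv]], ncol = 1,
                                       dimnames = list(NULL, cv)))
        kinds <- c(kinds, "numeric_covariate")
      } else {
        lv <- cat_levels[[cv]]
        for (l in lv[-1]) {  # first level is the reference
          col <- as.numeric(cov_df[[cv]] == l)
          values <- cbind(values, matrix(col, ncol = 1,
                                         dimnames = list(NULL, paste0(cv, "_", l))))
          kinds <- c(kinds, "categorical_covariate")
        }
      }
    }
  }
  rownames(values) <- cohort$sample_ids
  structure(list(
    values = values,
    kinds = stats::setNames(kinds, colnames(values)),
    labels = cohort$labels,
    sample_ids = cohort$sample_ids,
    covariate_data = cov_df,
    frozen = list(kept = kept, covariates = covariates,
                  cat_levels = cat_levels, pseudocount = pseudocount,
                  prevalence_threshold = prevalence_threshold)
  ), class = "feature_matrix")
}

#' Write a feature matrix as TSV plus a sidecar JSON of feature kinds
#'
#' @param fm a `feature_matrix`.
#' @param path TSV output path; the sidecar is written at `<path>.json`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(sample_id = fm$sample_ids, label = fm$labels,
                   fm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(kinds = as.list(fm$kinds), frozen_filter = fm$frozen$kept,
         pseudocount = fm$frozen$pseudocount,
         prevalence_threshold = fm$frozen$prevalence_threshold),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
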