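#' Simulation configuration for a multi-cohort vaginal-microbiome study
#'
#' Defaults mirror the five published cohorts the pipeline was designed
#' around: sample counts 22/149/36/27/31 with 12/69/8/23/23 EC cases
#' (265 samples, 135 EC / 130 benign overall), covariates available in
#' three cohorts, age only in the fourth ("chao") and none in the fifth
#' ("gressel"), EC cases older and heavier with higher vaginal pH, a small
#' set of Peptoniphilus-like taxa enriched in EC across cohorts,
#' cohort-specific batch effects, and a flatter EC base composition so
#' alpha diversity is higher in cases.
#'
#' @param n_cohorts number of cohorts.
#' @param cohort_sizes samples per cohort.
#' @param ec_fractions EC fraction per cohort.
#' @param cohort_ids cohort names.
#' @param n_taxa number of species-level taxa.
#' @param n_ec_enriched_taxa taxa enriched in EC.
#' @param ec_log_fold_change natural-log enrichment of those taxa in EC.
#' @param batch_effect_sd SD of the per-cohort log-normal batch effect.
#' @param covariate_effect_sizes named vector: log-scale composition effect
#'   per SD of age/bmi and for non-White ethnicity.
#' @param missingness_plan named list: covariates recorded per cohort.
#' @param diversity_shift flattening of the EC base composition (>= 0);
#'   larger values raise expected EC Shannon diversity.
#' @param covariate_label_shift scales the EC-vs-benign differences in the
#'   covariate distributions (1 = the published cohorts' demographics,
#'   0 = covariates carry no disease signal).
#' @param sequencing_depth_mean mean library size.
#' @param theta Dirichlet concentration mass (overdispersion control).
#' @param seed master seed; per-cohort child seeds derive from it by a fixed
#'   splitting rule so adding a cohort leaves earlier cohorts unchanged.
#' @export
sim_config <- function(
    n_cohorts = 5,
    cohort_sizes = c(22, 149, 36, 27, 31),
    ec_fractions = c(12, 69, 8, 23, 23) / c(22, 149, 36, 27, 31),
    cohort_ids = c("antonio", "walsh", "tsementzi", "chao", "gressel"),
    n_taxa = 120,
    n_ec_enriched_taxa = 5,
    ec_log_fold_change = 1.5,
    batch_effect_sd = 1.0,
    covariate_effect_sizes = c(age = 0.3, bmi = 0.2, ethnicity = 0.3),
    missingness_plan = list(
      antonio = c("age", "bmi", "ethnicity", "ph"),
      walsh = c("age", "bmi", "ethnicity", "ph"),
      tsementzi = c("age", "bmi", "ethnicity", "ph"),
      chao = "age",
      gressel = character(0)),
    diversity_shift = 0.4,
    covariate_label_shift = 1,
    sequencing_depth_mean = 10000,
    theta = 50,
    seed = 1) {
  stopifnot(length(cohort_sizes) == n_cohorts,
            length(ec_fractions) == n_cohorts,
            length(cohort_ids) == n_cohorts,
            all(ec_fractions >= 0 & ec_fractions <= 1),
            all(cohort_sizes >= 1),
            n_ec_enriched_taxa <= n_taxa, n_ec_enriched_taxa >= 0,
            batch_effect_sd >= 0, diversity_shift >= 0,
            sequencing_depth_mean > 0)
  if (is.null(names(missingness_plan))) names(missingness_plan) <- cohort_ids
  structure(list(
    n_cohorts = n_cohorts, cohort_sizes = cohort_sizes,
    ec_fractions = ec_fractions, cohort_ids = cohort_ids,
    n_taxa = n_taxa, n_ec_enriched_taxa = n_ec_enriched_taxa,
    ec_log_fold_change = ec_log_fold_change,
    batch_effect_sd = batch_effect_sd,
    covariate_effect_sizes = covariate_effect_sizes,
    missingness_plan = missingness_plan,
    diversity_shift = diversity_shift,
    covariate_label_shift = covariate_label_shift,
    sequencing_depth_mean = sequencing_depth_mean,
    theta = theta, seed = seed
  ), class = "sim_config")
}

child_seed <- function(seed, i) {
  (abs(seed) * 1009 + 7919 * i) %% 2147483647L
}

#' Random bifurcating phylogeny over the simulated taxa
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed RNG seed.
#' @return a Newick string with positive branch lengths and leaf names
#'   `taxon_001`, `taxon_002`, ...
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) stop("need at least 2 taxa for a tree")
  set.seed(seed)
  tr <- ape::rtree(n_taxa, tip.label = taxon_ids(n_taxa))
  tr$edge.length <- pmax(tr$edge.length, 1e-3)
  ape::write.tree(tr)
}

taxon_ids <- function(n) sprintf("taxon_%03d", seq_len(n))

# Global taxonomic structure shared by all cohorts: a dominant
# Lactobacillus-like genus, a Peptoniphilus-like genus carrying the EC
# enrichment, assorted other genera, and ~10% of taxa unassigned at genus.
make_taxonomy <- function(n_taxa, n_enriched) {
  ids <- taxon_ids(n_taxa)
  n_lacto <- min(8, n_taxa)
  genus <- character(n_taxa)
  genus[seq_len(n_lacto)] <- "Lactobacillus"
  enr_idx <- integer(0)
  if (n_enriched > 0) {
    enr_idx <- n_lacto + seq_len(min(n_enriched, n_taxa - n_lacto))
    genus[enr_idx] <- "Peptoniphilus"
  }
  rest <- which(genus == "")
  if (length(rest)) {
    other_names <- sprintf("Genus%02d", seq_len(max(1, ceiling(length(rest) / 4))))
    genus[rest] <- rep(other_names, length.out = length(rest))
  }
  unassigned <- rest[seq_along(rest) %% 10 == 0]
  parent <- rep(NA_character_, n_taxa)
  genus_out <- genus
  genus_out[unassigned] <- NA
  parent[unassigned] <- paste0("Family_", genus[unassigned])
  data.frame(taxon = ids, genus = genus_out, parent = parent,
             species = paste0(genus, "_", ids), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Simulate a multi-cohort study
#'
#' Dirichlet-multinomial generative model. Each cohort draws a log-normal
#' batch effect on the base log-composition; EC samples receive
#' `ec_log_fold_change` on the enriched taxa and a flattened base
#' (`diversity_shift`) so their expected Shannon index is higher; age, BMI
#' and ethnicity are drawn from cohort- and label-specific distributions (EC
#' older and heavier) and couple to composition linearly on the
#' log-relative-abundance scale; vaginal pH is a noisy decreasing function
#' of the Lactobacillus-like genus' relative abundance, dichotomized at 4.5;
#' counts are multinomial at negative-binomial library sizes around the
#' stated mean. Covariates outside each cohort's missingness plan are
#' entirely NA; within-plan pH has label-dependent missingness.
#'
#' @param config a [sim_config()].
#' @param held_out cohort id designated as the held-out evaluation set
#'   (default the first cohort).
#' @return a `multicohort_study`: named list of `cohort_dataset`s plus the
#'   shared taxonomy, tree and config.
#' @export
simulate_multicohort <- function(config = sim_config(), held_out = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(held_out)) held_out <- config$cohort_ids[1]
  stopifnot(held_out %in% config$cohort_ids)
  training <- config$cohort_ids != held_out
  if (any(training & config$cohort_sizes < 2)) {
    stop("training cohort with < 2 samples would be single-class: ",
         paste(config$cohort_ids[training & config$cohort_sizes < 2],
               collapse = ", "))
  }

  set.seed(config$seed)
  taxonomy <- make_taxonomy(config$n_taxa, config$n_ec_enriched_taxa)
  enriched <- taxonomy$taxon[which(!is.na(taxonomy$genus) &
                                     taxonomy$genus == "Peptoniphilus")]
  lacto <- which(!is.na(taxonomy$genus) & taxonomy$genus == "Lactobacillus")
  eta0 <- stats::rnorm(config$n_taxa, 0, 1.5)
  eta0[lacto] <- stats::rnorm(length(lacto), 4.0, 0.5)
  loadings <- lapply(config$covariate_effect_sizes, function(s) {
    stats::rnorm(config$n_taxa)
  })
  tree_seed <- child_seed(config$seed, 0)
  newick <- simulate_tree(config$n_taxa, seed = tree_seed)

  cohorts <- list()
  for (i in seq_len(config$n_cohorts)) {
    cid <- config$cohort_ids[i]
    cohorts[[cid]] <- simulate_cohort(
      config, i, eta0, loadings, enriched, lacto, taxonomy)
  }
  structure(list(
    cohorts = cohorts, held_out = held_out, taxonomy = taxonomy,
    tree_newick = newick,
    tree = ape::read.tree(text = newick),
    enriched_taxa = enriched, config = config
  ), class = "multicohort_study")
}

simulate_cohort <- function(config, i, eta0, loadings, enriched, lacto,
                            taxonomy) {
  cid <- config$cohort_ids[i]
  n <- config$cohort_sizes[i]
  set.seed(child_seed(config$seed, i))
  n_ec <- round(n * config$ec_fractions[i])
  labels <- sample(rep(c("EC", "benign"), c(n_ec, n - n_ec)))
  is_ec <- labels == "EC"

  batch <- stats::rnorm(config$n_taxa, 0, config$batch_effect_sd)
  shift <- config$covariate_label_shift
  age_mu <- c(benign = 49, EC = 49 + 12 * shift) + stats::rnorm(1, 0, 3)
  bmi_mu <- c(benign = 30, EC = 30 + 5 * shift) + stats::rnorm(1, 0, 2)
  p_white <- c(benign = 0.72, EC = min(1, 0.72 + 0.13 * shift))
  age <- stats::rnorm(n, age_mu[labels], 10)
  bmi <- pmax(16, stats::rnorm(n, bmi_mu[labels], 7))
  ethnicity <- ifelse(stats::runif(n) < p_white[labels], "White", "Other")

  es <- config$covariate_effect_sizes
  enr_idx <- match(enriched, taxonomy$taxon)
  eta <- matrix(0, n, config$n_taxa)
  for (j in seq_len(n)) {
    base <- (eta0 + batch) / (1 + config$diversity_shift * is_ec[j])
    eff <- 0
    if (!is.na(es["age"])) eff <- eff + es[["age"]] * (age[j] - 55) / 10 * loadings[["age"]]
    if (!is.na(es["bmi"])) eff <- eff + es[["bmi"]] * (bmi[j] - 32) / 8 * loadings[["bmi"]]
    if (!is.na(es["ethnicity"])) {
      eff <- eff + es[["ethnicity"]] * (ethnicity[j] == "Other") * loadings[["ethnicity"]]
    }
    eta[j, ] <- base + eff
    if (is_ec[j] && length(enr_idx)) {
      eta[j, enr_idx] <- eta[j, enr_idx] + config$ec_log_fold_change
    }
  }
  alpha <- exp(eta)
  alpha <- sweep(alpha, 1, rowSums(alpha), "/") * config$theta
  depths <- pmax(500L, stats::rnbinom(n, mu = config$sequencing_depth_mean,
                                      size = 10))
  counts <- matrix(0L, n, config$n_taxa,
                   dimnames = list(sprintf("%s_s%03d", cid, seq_len(n)),
                                   taxon_ids(config$n_taxa)))
  for (j in seq_len(n)) {
    g <- stats::rgamma(config$n_taxa, shape = alpha[j, ], rate = 1)
    g[g <= 0 | !is.finite(g)] <- 1e-12
    p <- g / sum(g)
    counts[j, ] <- stats::rmultinom(1, depths[j], p)
  }
  # guard: no empty sample (depth floor makes this all but impossible)
  empty <- rowSums(counts) == 0
  if (any(empty)) counts[empty, 1] <- 1L

  lacto_rel <- rowSums(counts[, lacto, drop = FALSE]) / rowSums(counts)
  ph_cont <- 6.3 - 2.4 * lacto_rel + stats::rnorm(n, 0, 0.5)
  ph <- ifelse(ph_cont <= 4.5, "<=4.5", ">4.5")

  avail <- config$missingness_plan[[cid]]
  if (is.null(avail)) avail <- character(0)
  cov <- data.frame(age = age, bmi = bmi, ethnicity = ethnicity, ph = ph,
                    stringsAsFactors = FALSE)
  # label-dependent (MAR) missingness for pH where recorded
  if ("ph" %in% avail) {
    p_na <- ifelse(is_ec, 0.12, 0.05)
    cov$ph[stats::runif(n) < p_na] <- NA
  }
  for (cv in setdiff(names(cov), avail)) cov[[cv]] <- NA
  structure(list(
    cohort_id = cid, counts = counts, taxonomy = taxonomy,
    labels = labels, covariates = cov,
    available_covariates = avail,
    sample_ids = rownames(counts)
  ), class = "cohort_dataset")
}

#' Write a simulated study to disk
#'
#' Per-cohort counts as TSV (rows = samples, header = taxon ids), metadata
#' as CSV with literal NA, the shared taxonomy as TSV, the tree as Newick,
#' and a JSON manifest listing cohorts and the held-out designation.
#'
#' @param study a `multicohort_study`.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cid in names(study$cohorts)) {
    co <- study$cohorts[[cid]]
    utils::write.table(
      data.frame(sample_id = co$sample_ids, co$counts, check.names = FALSE),
      file.path(dir, paste0(cid, "_counts.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- data.frame(sample_id = co$sample_ids, label = co$labels,
                       co$covariates, stringsAsFactors = FALSE)
    utils::write.csv(meta, file.path(dir, paste0(cid, "_metadata.csv")),
                     row.names = FALSE, na = "NA")
  }
  utils::write.table(study$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(study$tree_newick, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(cohorts = names(study$cohorts), held_out = study$held_out,
         enriched_taxa = study$enriched_taxa,
         config = study$config[setdiff(names(study$config),
                                       "missingness_plan")],
         missingness_plan = study$config$missingness_plan),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a study previously written by [write_study()]
#'
#' @param dir directory containing the study files.
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  taxonomy <- utils::read.delim(file.path(dir, "taxonomy.tsv"),
                                stringsAsFactors = FALSE)
  newick <- readLines(file.path(dir, "tree.nwk"))
  cohorts <- list()
  for (cid in manifest$cohorts) {
    cts <- utils::read.delim(file.path(dir, paste0(cid, "_counts.tsv")),
                             check.names = FALSE)
    counts <- as.matrix(cts[, -1, drop = FALSE])
    rownames(counts) <- cts$sample_id
    meta <- utils::read.csv(file.path(dir, paste0(cid, "_metadata.csv")),
                            stringsAsFactors = FALSE)
    avail <- as.character(unlist(manifest$missingness_plan[[cid]]))
    cohorts[[cid]] <- structure(list(
      cohort_id = cid, counts = counts, taxonomy = taxonomy,
      labels = meta$label,
      covariates = meta[, c("age", "bmi", "ethnicity", "ph")],
      available_covariates = avail,
      sample_ids = meta$sample_id
    ), class = "cohort_dataset")
  }
  structure(list(
    cohorts = cohorts, held_out = manifest$held_out, taxonomy = taxonomy,
    tree_newick = newick, tree = ape::read.tree(text = newick),
    enriched_taxa = manifest$enriched_taxa, config = manifest$config
  ), class = "multicohort_study")
}

#' Pool cohorts into one count matrix with label and batch vectors
#'
#' @param study a `multicohort_study`.
#' @param cohort_ids cohorts to pool (default all).
#' @export
pool_cohorts <- function(study, cohort_ids = names(study$cohorts)) {
  cos <- study$cohorts[cohort_ids]
  counts <- do.call(rbind, lapply(cos, `[[`, "counts"))
  labels <- unlist(lapply(cos, `[[`, "labels"), use.names = FALSE)
  batch <- rep(cohort_ids, vapply(cos, function(c) nrow(c$counts), integer(1)))
  covariates <- do.call(rbind, lapply(cos, `[[`, "covariates"))
  rownames(covariates) <- NULL
  list(counts = counts, labels = labels, batch = batch,
       covariates = covariates)
}
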