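test_that("genus aggregation conserves totals and groups unassigned taxa", {
  counts <- matrix(c(3, 4, 2, 1, 5,
                     0, 2, 0, 7, 1,
                     1, 1, 1, 1, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("s", 1:3), toy_taxonomy$taxon))
  out <- aggregate_to_genus(counts, toy_taxonomy)
  expect_setequal(colnames(out),
                  c("Lactobacillus", "Prevotella", "unclassified_Clostridiaceae",
                    "Blautia"))
  expect_equal(out["s1", "Lactobacillus"], 7)            # 3 + 4
  expect_equal(out["s1", "unclassified_Clostridiaceae"], 1)
  expect_equal(rowSums(out), rowSums(counts))            # conservation
  # all-distinct genera: output equals input
  tx <- data.frame(taxon = c("a", "b"), genus = c("G1", "G2"), parent = NA)
  m <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(aggregate_to_genus(m, tx)), unname(m))
  expect_error(aggregate_to_genus(m, toy_taxonomy), "cover")
})

test_that("prevalence filter keeps taxa exactly at the threshold", {
  m <- matrix(0, 20, 2, dimnames = list(NULL, c("at", "never")))
  m[1, "at"] <- 5  # present in 1/20 = 5% exactly
  out <- prevalence_filter(m, 0.05)
  expect_identical(colnames(out), "at")   # kept at threshold, absent removed

  m2 <- matrix(0, 40, 4, dimnames = list(NULL, c("p1", "p2", "p3", "p10")))
  m2[1, "p1"] <- 1; m2[1:2, "p2"] <- 1; m2[1:3, "p3"] <- 1; m2[1:10, "p10"] <- 1
  out2 <- prevalence_filter(m2, 0.05)
  expect_setequal(colnames(out2), c("p2", "p3", "p10"))  # 1/40 < 5% removed
  expect_equal(nrow(out2), 40)

  refit <- apply_feature_filter(m2, c("p2", "gone"))
  expect_equal(unname(refit[, "gone"]), rep(0, 40))
})

test_that("CLR transform matches the closed form and centers rows", {
  expect_equal(unname(clr_transform(matrix(c(5, 5, 5), 1))), matrix(0, 1, 3))
  m <- (log(1.5) + log(4.5)) / 2
  expect_equal(unname(clr_transform(matrix(c(1, 4), 1), pseudocount = 0.5)),
               matrix(c(log(1.5) - m, log(4.5) - m), 1), tolerance = 1e-12)
  set.seed(3)
  x <- matrix(rpois(60, 30), 6, 10)
  expect_lt(max(abs(rowSums(clr_transform(x)))), 1e-9)
  # approximate scale invariance at large counts
  big <- matrix(rpois(20, 1e5), 2, 10)
  expect_equal(clr_transform(big), clr_transform(big * 4L), tolerance = 1e-3)
})

test_that("relative abundance normalizes rows and names zero-total samples", {
  expect_equal(unname(relative_abundance(matrix(c(2, 2), 1))),
               matrix(c(0.5, 0.5), 1))
  expect_equal(unname(relative_abundance(matrix(c(0, 5), 1))),
               matrix(c(0, 1), 1))
  set.seed(4)
  r <- matrix(runif(30), 3, 10)
  expect_lt(max(abs(rowSums(relative_abundance(r)) - 1)), 1e-12)
  bad <- rbind(ok = c(1, 1), empty = c(0, 0))
  expect_error(relative_abundance(bad), "empty")
})

test_that("feature matrix has a centered taxon block and a reusable frozen state", {
  st <- simulate_multicohort(small_config(seed = 2))
  co <- st$cohorts$c1
  fm <- build_feature_matrix(co, covariates = c("age", "bmi", "ethnicity"))
  taxa_cols <- names(fm$kinds)[fm$kinds == "taxon"]
  expect_lt(max(abs(rowSums(fm$values[, taxa_cols]))), 1e-9)
  expect_true(all(c("age", "bmi") %in% colnames(fm$values)))
  expect_true(any(fm$kinds == "categorical_covariate"))
  # frozen re-application yields the same feature set on another cohort
  fm2 <- build_feature_matrix(st$cohorts$c2, frozen = fm$frozen)
  expect_identical(colnames(fm2$values)[fm2$kinds == "taxon"], taxa_cols)
  # permuting samples permutes outputs identically
  perm <- sample(nrow(co$counts))
  co_p <- co
  co_p$counts <- co$counts[perm, ]
  co_p$covariates <- co$covariates[perm, ]
  co_p$sample_ids <- co$sample_ids[perm]
  fm_p <- build_feature_matrix(co_p, covariates = c("age", "bmi", "ethnicity"))
  expect_equal(unname(fm_p$values), unname(fm$values[perm, ]))
})

test_that("feature matrices round-trip through TSV with a sidecar", {
  st <- simulate_multicohort(small_config(seed = 2))
  fm <- build_feature_matrix(st$cohorts$c1)
  path <- file.path(withr::local_tempdir(), "fm.tsv")
  write_feature_matrix(fm, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(back), nrow(fm$values))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_identical(side$frozen_filter, fm$frozen$kept)
})
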