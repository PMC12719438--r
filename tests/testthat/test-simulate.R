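test_that("default configuration reproduces the published cohort structure", {
  st <- simulate_multicohort(sim_config(seed = 1))
  sizes <- vapply(st$cohorts, function(c) nrow(c$counts), integer(1))
  ecs <- vapply(st$cohorts, function(c) sum(c$labels == "EC"), integer(1))
  expect_equal(unname(sizes), c(22, 149, 36, 27, 31))
  expect_equal(unname(ecs), c(12, 69, 8, 23, 23))
  expect_equal(sum(sizes), 265)
  expect_equal(sum(ecs), 135)
  expect_equal(sum(sizes) - sum(ecs), 130)
  expect_true(all(unlist(lapply(st$cohorts, function(c) rowSums(c$counts))) > 0))
  expect_true(all(unlist(lapply(st$cohorts, function(c) c$counts)) >= 0))
})

test_that("covariate availability matches the missingness plan exactly", {
  st <- simulate_multicohort(sim_config(seed = 2))
  chao <- st$cohorts$chao$covariates
  expect_false(anyNA(chao$age))
  expect_true(all(is.na(chao$bmi)) && all(is.na(chao$ethnicity)) &&
                all(is.na(chao$ph)))
  gressel <- st$cohorts$gressel$covariates
  expect_true(all(is.na(gressel)))
  walsh <- st$cohorts$walsh$covariates
  expect_false(anyNA(walsh$age) || anyNA(walsh$bmi) || anyNA(walsh$ethnicity))
  expect_true(anyNA(walsh$ph))  # label-dependent pH missingness
})

test_that("simulation is deterministic and cohort-stable under the seed rule", {
  a <- simulate_multicohort(sim_config(seed = 7))
  b <- simulate_multicohort(sim_config(seed = 7))
  expect_identical(a$cohorts$walsh$counts, b$cohorts$walsh$counts)
  expect_identical(a$cohorts$chao$covariates, b$cohorts$chao$covariates)
  expect_identical(a$tree_newick, b$tree_newick)
  c <- simulate_multicohort(sim_config(seed = 8))
  expect_false(identical(a$cohorts$walsh$counts, c$cohorts$walsh$counts))
})

test_that("EC cases carry the planted ecological structure", {
  diffs <- vapply(1:20, function(s) {
    st <- simulate_multicohort(small_config(seed = 300 + s))
    pool <- pool_cohorts(st)
    sh <- shannon_index(relative_abundance(pool$counts))
    mean(sh[pool$labels == "EC"]) - mean(sh[pool$labels == "benign"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
  # EC older and heavier where covariates are recorded
  st <- simulate_multicohort(sim_config(seed = 4))
  w <- st$cohorts$walsh
  expect_gt(mean(w$covariates$age[w$labels == "EC"]),
            mean(w$covariates$age[w$labels == "benign"]))
  expect_gt(mean(w$covariates$bmi[w$labels == "EC"]),
            mean(w$covariates$bmi[w$labels == "benign"]))
})

test_that("batch effects produce detectable cohort clustering", {
  hits <- vapply(1:10, function(s) {
    cfg <- small_config(seed = 400 + s, batch_effect_sd = 1)
    st <- simulate_multicohort(cfg)
    pool <- pool_cohorts(st)
    idx <- seq(1, nrow(pool$counts), by = 2)  # thin for speed
    bc <- beta_distance(pool$counts[idx, ], "bray_curtis")
    pm <- permanova_marginal(bc, data.frame(cohort = pool$batch[idx]),
                             n_perm = 99, seed = s)
    pm$p_value[1] <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("simulated trees are bifurcating, reproducible and seed-sensitive", {
  expect_error(simulate_tree(1), "at least 2")
  cherry <- ape::read.tree(text = simulate_tree(2, seed = 1))
  expect_equal(length(cherry$tip.label), 2)
  tr <- ape::read.tree(text = simulate_tree(8, seed = 3))
  expect_equal(length(tr$tip.label), 8)
  expect_equal(nrow(tr$edge), 2 * 8 - 2)
  expect_true(all(tr$edge.length > 0))
  expect_identical(simulate_tree(8, seed = 3), simulate_tree(8, seed = 3))
  topo <- vapply(1:20, function(s) simulate_tree(8, seed = s), character(1))
  expect_gt(length(unique(topo)), 1)
})

test_that("a study round-trips through its on-disk representation", {
  st <- simulate_multicohort(small_config(seed = 5))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_study(dir)
  expect_identical(names(back$cohorts), names(st$cohorts))
  expect_equal(back$cohorts$c1$counts, st$cohorts$c1$counts)
  expect_identical(back$cohorts$c1$labels, st$cohorts$c1$labels)
  expect_equal(back$cohorts$c2$covariates$age, st$cohorts$c2$covariates$age)
  expect_identical(back$held_out, st$held_out)
  expect_identical(ape::write.tree(back$tree), ape::write.tree(st$tree))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_cohorts = 2, cohort_sizes = c(10, 10, 10),
                          ec_fractions = c(0.5, 0.5),
                          cohort_ids = c("a", "b")))
  expect_error(sim_config(n_taxa = 10, n_ec_enriched_taxa = 11))
  cfg <- small_config(seed = 1, cohort_sizes = c(1, 40, 30, 24))
  expect_error(simulate_multicohort(cfg, held_out = "c2"), "single-class")
})
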