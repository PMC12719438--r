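# minimal permutation enumerator used only as a test oracle
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (pos in seq_len(n)) out[[length(out) + 1]] <- append(p, n, pos - 1L)
  }
  out
}

test_that("Shannon index matches direct evaluation", {
  expect_equal(shannon_index(c(1)), 0)
  expect_equal(shannon_index(rep(0.25, 4)), log(4))
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(shannon_index(c(0.7, 0.3, 0)), -(0.7 * log(0.7) + 0.3 * log(0.3)))
  expect_error(shannon_index(c(-0.1, 1.1)), "negative")
  m <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(shannon_index(m), c(0, log(2)))
})

test_that("distances satisfy identity, symmetry and bounds", {
  set.seed(21)
  x <- matrix(rpois(8 * 12, 15), 8, 12,
              dimnames = list(paste0("s", 1:8), sprintf("taxon_%03d", 1:12)))
  tree <- ape::read.tree(text = simulate_tree(12, seed = 9))
  for (metric in c("bray_curtis", "jaccard", "jensen_shannon",
                   "unifrac_unweighted", "unifrac_weighted")) {
    dm <- beta_distance(x, metric, tree = tree)
    expect_equal(diag(dm$d), rep(0, 8), ignore_attr = TRUE)
    expect_equal(dm$d, t(dm$d))
    expect_true(all(dm$d >= 0))
    expect_true(all(dm$d <= 1 + 1e-12))
  }
  # identical samples -> 0; disjoint support -> 1 for BC and Jaccard
  y <- rbind(a = c(2, 2, 0, 0), b = c(2, 2, 0, 0), c = c(0, 0, 3, 1))
  colnames(y) <- sprintf("taxon_%03d", 1:4)
  bc <- beta_distance(y, "bray_curtis")$d
  jc <- beta_distance(y, "jaccard")$d
  expect_equal(bc["a", "b"], 0)
  expect_equal(bc["a", "c"], 1)
  expect_equal(jc["a", "c"], 1)
  # counts (2,2) vs (1,3): BC = (1+1)/8 on counts = 0.25 on proportions
  z <- rbind(c(2, 2), c(1, 3)); colnames(z) <- c("t1", "t2")
  expect_equal(beta_distance(z, "bray_curtis")$d[1, 2], 0.25)
})

test_that("weighted UniFrac equals an edge-by-edge hand summation", {
  # ((A:1,B:2):1,(C:3,D:1):2); with explicit proportions
  tree <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  p <- rbind(s1 = c(A = 0.5, B = 0.3, C = 0.2, D = 0.0),
             s2 = c(A = 0.1, B = 0.1, C = 0.4, D = 0.4))
  # oracle: enumerate the six edges with their descendant tip sets by hand
  edges <- list(
    list(b = 1, tips = c("A", "B")), list(b = 1, tips = "A"),
    list(b = 2, tips = "B"), list(b = 2, tips = c("C", "D")),
    list(b = 3, tips = "C"), list(b = 1, tips = "D"))
  num <- den <- 0
  for (e in edges) {
    a1 <- sum(p["s1", e$tips]); a2 <- sum(p["s2", e$tips])
    num <- num + e$b * abs(a1 - a2)
    den <- den + e$b * (a1 + a2)
  }
  dm <- beta_distance(p, "unifrac_weighted", tree = tree)
  expect_equal(dm$d["s1", "s2"], num / den, tolerance = 1e-12)

  # unweighted: unshared branch length over covered branch length
  pres <- rbind(s1 = c(A = 1, B = 1, C = 1, D = 0),
                s2 = c(A = 0, B = 1, C = 1, D = 1))
  # unique to one sample: A's edge (1) + D's edge (1); covered: all 10
  dmu <- beta_distance(pres, "unifrac_unweighted", tree = tree)
  expect_equal(dmu$d["s1", "s2"], 2 / 10, tolerance = 1e-12)
  expect_error(beta_distance(p, "unifrac_weighted"), "tree")
})

test_that("weighted UniFrac on a star tree reduces to Manhattan/2", {
  tree <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  set.seed(5)
  p <- matrix(rgamma(8, 1), 2, 4, dimnames = list(c("x", "y"), c("A", "B", "C", "D")))
  p <- p / rowSums(p)
  dm <- beta_distance(p, "unifrac_weighted", tree = tree)
  expect_equal(dm$d["x", "y"], sum(abs(p[1, ] - p[2, ])) / 2, tolerance = 1e-12)
})

test_that("UniFrac agrees with phyloseq on random data", {
  skip_if_not_installed("phyloseq")
  set.seed(8)
  x <- matrix(rpois(6 * 10, 25), 6, 10,
              dimnames = list(paste0("s", 1:6), sprintf("taxon_%03d", 1:10)))
  tree <- ape::read.tree(text = simulate_tree(10, seed = 2))
  ps <- phyloseq::phyloseq(phyloseq::otu_table(x, taxa_are_rows = FALSE),
                           phyloseq::phy_tree(tree))
  dw <- beta_distance(x, "unifrac_weighted", tree = tree)$d
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(dw, ref[rownames(dw), colnames(dw)], tolerance = 1e-10)
  du <- beta_distance(x, "unifrac_unweighted", tree = tree)$d
  refu <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  expect_equal(du, refu[rownames(du), colnames(du)], tolerance = 1e-10)
})

test_that("marginal PERMANOVA matches adonis2 sums of squares and F", {
  skip_if_not_installed("vegan")
  set.seed(9)
  n <- 30
  y <- matrix(rpois(n * 15, 10), n, 15)
  des <- data.frame(g = factor(rep(c("a", "b"), 15)), age = rnorm(n))
  bc <- beta_distance(y, "bray_curtis")
  pm <- permanova_marginal(bc, des, n_perm = 99, seed = 4)
  ad <- vegan::adonis2(as.dist(bc$d) ~ g + age, data = des, by = "margin",
                       permutations = 99)
  expect_equal(pm$ss[1:2], ad$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(pm$r2[1:2], ad$R2[1:2], tolerance = 1e-10)
  expect_equal(pm$pseudo_f[1:2], ad$F[1:2], tolerance = 1e-10)
  # single-term case: R2 of term plus residual is 1
  pm1 <- permanova_marginal(bc, des["g"], n_perm = 99, seed = 4)
  expect_equal(sum(pm1$r2), 1)
})

test_that("permutation p at n = 4 equals exhaustive enumeration", {
  d <- matrix(c(0, 1, 4, 5,
                1, 0, 3, 4,
                4, 3, 0, 1,
                5, 4, 1, 0), 4, 4)
  g <- factor(c("a", "a", "b", "b"))
  pm <- permanova_marginal(d, data.frame(g = g), n_perm = "exhaustive")
  # brute-force oracle from the classic within-group formulation:
  # SS_T = sum_{i<j} d^2 / n, SS_W = sum_groups sum_{i<j in g} d^2 / n_g
  f_of <- function(gg) {
    ss_t <- sum(d[upper.tri(d)]^2) / 4
    ss_w <- 0
    for (lv in unique(gg)) {
      idx <- which(gg == lv)
      sub <- d[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
    ((ss_t - ss_w) / 1) / (ss_w / 2)
  }
  perms <- list()
  k <- 0
  for (p in combinat_perms(4)) { k <- k + 1; perms[[k]] <- p }
  f_obs <- f_of(g)
  f_all <- vapply(perms, function(p) f_of(g[p]), numeric(1))
  p_oracle <- mean(f_all >= f_obs - 1e-12)
  expect_equal(pm$p_value[1], p_oracle)
  expect_equal(pm$pseudo_f[1], f_obs, tolerance = 1e-10)
})

test_that("complete-case handling drops samples with missing covariates", {
  set.seed(2)
  y <- matrix(rpois(10 * 6, 10), 10, 6)
  bc <- beta_distance(y, "bray_curtis")
  des <- data.frame(g = factor(rep(c("a", "b"), 5)), age = c(NA, rnorm(9)))
  expect_message(pm <- permanova_marginal(bc, des, n_perm = 99), "dropped")
  expect_equal(attr(pm, "n_samples"), 9)
  expect_error(permanova_marginal(bc, data.frame(k = rep(1, 10))), "constant")
})
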