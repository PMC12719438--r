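#' Shannon alpha diversity
#'
#' `H = -sum(p_i * ln(p_i))` over a vector (or rows of a matrix) of relative
#' abundances, with natural log and the convention `0 * ln(0) = 0`.
#'
#' @param proportions vector summing to 1, or a samples x taxa matrix of
#'   relative abundances (one index per row).
#' @export
shannon_index <- function(proportions) {
  f <- function(p) {
    if (any(p < 0)) stop("negative proportions")
    p <- p[p > 0]
    -sum(p * log(p))
  }
  if (is.matrix(proportions)) apply(proportions, 1, f) else f(proportions)
}

metric_names <- c("bray_curtis", "jaccard", "jensen_shannon",
                  "unifrac_unweighted", "unifrac_weighted")

#' Pairwise beta-diversity distance matrix
#'
#' Standard definitions: Bray-Curtis `sum|x - y| / sum(x + y)`; Jaccard on
#' presence/absence sets; Jensen-Shannon divergence with natural log
#' (returned as its square root by default, which is a metric); unweighted
#' UniFrac = branch length unique to one sample over branch length covered by
#' either; weighted (normalized) UniFrac = `sum(b_e |A_e - B_e|) /
#' sum(b_e (A_e + B_e))` where `A_e` is the relative abundance descending
#' edge `e`.
#'
#' @param abundances samples x taxa matrix. Counts are accepted and
#'   normalized internally for the abundance-weighted metrics;
#'   presence/absence is derived internally for jaccard and unweighted
#'   UniFrac.
#' @param metric one of `"bray_curtis"`, `"jaccard"`, `"jensen_shannon"`,
#'   `"unifrac_unweighted"`, `"unifrac_weighted"`.
#' @param tree an [ape::phylo] covering all taxa; required for UniFrac.
#' @param jsd_sqrt return the square root of the Jensen-Shannon divergence
#'   (a true metric) rather than the divergence itself; default TRUE.
#' @return a `dist_matrix`: list with `d` (symmetric matrix, zero diagonal),
#'   `ids`, `metric_name`.
#' @export
beta_distance <- function(abundances, metric, tree = NULL, jsd_sqrt = TRUE) {
  metric <- match.arg(metric, metric_names)
  x <- as.matrix(abundances)
  n <- nrow(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (grepl("unifrac", metric)) {
    if (is.null(tree)) stop("UniFrac requires a phylogenetic tree")
    if (!all(colnames(x) %in% tree$tip.label)) {
      stop("taxa missing from tree: ",
           paste(setdiff(colnames(x), tree$tip.label), collapse = ", "))
    }
    d <- unifrac_dist(x, tree, weighted = metric == "unifrac_weighted")
  } else {
    if (metric != "jaccard") x <- relative_abundance(x)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- switch(metric,
        bray_curtis = sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ]),
        jaccard = {
          a <- x[i, ] > 0; b <- x[j, ] > 0
          u <- sum(a | b)
          if (u == 0) 0 else 1 - sum(a & b) / u
        },
        jensen_shannon = {
          jsd <- jensen_shannon_div(x[i, ], x[j, ])
          if (jsd_sqrt) sqrt(jsd) else jsd
        })
    }
  }
  dimnames(d) <- list(ids, ids)
  structure(list(d = d, ids = ids, metric_name = metric),
            class = "dist_matrix")
}

jensen_shannon_div <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  max(0, (kl(p, m) + kl(q, m)) / 2)
}

# Edge incidence: samples x edges matrix of the relative abundance (or
# presence) descending each edge of the tree.
edge_abundance <- function(x, tree) {
  n_tip <- length(tree$tip.label)
  x <- x[, tree$tip.label, drop = FALSE]
  desc <- edge_tip_map(tree)
  a <- matrix(0, nrow(x), nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    a[, e] <- rowSums(x[, desc[[e]], drop = FALSE])
  }
  a
}

# For each edge, the tip indices descending it (postorder accumulation).
edge_tip_map <- function(tree) {
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(children[[as.character(node)]],
                  function(e) tips_below(tree$edge[e, 2])))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) tips_below(tree$edge[e, 2]))
}

unifrac_dist <- function(x, tree, weighted) {
  n <- nrow(x)
  b <- tree$edge.length
  if (weighted) {
    p <- relative_abundance(x)
    A <- edge_abundance(p, tree)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      denom <- sum(b * (A[i, ] + A[j, ]))
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else
        sum(b * abs(A[i, ] - A[j, ])) / denom
    }
  } else {
    P <- edge_abundance((x > 0) * 1, tree) > 0
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      either <- P[i, ] | P[j, ]
      denom <- sum(b[either])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else
        sum(b[xor(P[i, ], P[j, ])]) / denom
    }
  }
  d
}

#' Write a distance matrix as square TSV with sample ids
#'
#' @param dm a `dist_matrix`.
#' @param path output path.
#' @export
write_dist_matrix <- function(dm, path) {
  utils::write.table(data.frame(sample_id = dm$ids, dm$d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Gower-centered inner-product matrix of squared distances.
gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  ctr <- diag(n) - matrix(1 / n, n, n)
  ctr %*% a %*% ctr
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Marginal PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA in the McArdle-Anderson trace form. Each
#' term's marginal sum of squares is the drop in explained sum of squares
#' when that term is removed from the otherwise full model (no sequential
#' decomposition), with the pseudo-F using the full-model residual. P-values
#' come from free permutation of observations; ties `F* = F_obs` count
#' toward the numerator and the observed statistic is included, so
#' `p = (1 + #(F* >= F)) / (1 + n_perm)`. No multiple-testing correction is
#' applied across terms.
#'
#' Samples with missing values in any tested term are dropped (complete-case
#' analysis) with a message.
#'
#' @param dist a `dist_matrix` from [beta_distance()], or a square matrix.
#' @param design data.frame of terms (factors or numerics), rows aligned
#'   with the distance matrix.
#' @param n_perm number of permutations (>= 99), or `"exhaustive"` to
#'   enumerate all `n!` relabelings (n <= 8).
#' @param seed RNG seed for the permutations.
#' @return a `permanova_result` data.frame: one row per term plus a residual
#'   row, with df, SS, R2, pseudo-F and permutation p.
#' @export
permanova_marginal <- function(dist, design, n_perm = 999, seed = 1) {
  d <- if (inherits(dist, "dist_matrix")) dist$d else as.matrix(dist)
  design <- as.data.frame(design)
  stopifnot(nrow(design) == nrow(d))
  cc <- stats::complete.cases(design)
  if (!all(cc)) {
    message(sum(!cc), " sample(s) dropped for missing covariates")
    d <- d[cc, cc, drop = FALSE]
    design <- design[cc, , drop = FALSE]
  }
  n <- nrow(d)
  terms <- names(design)
  for (t in terms) {
    v <- design[[t]]
    if (length(unique(v)) < 2) stop("constant term: ", t)
  }
  G <- gower_center(d)
  ss_total <- sum(diag(G))

  hat <- function(cols) {
    X <- if (length(cols) == 0) {
      matrix(1, n, 1)
    } else {
      stats::model.matrix(~ ., data = design[, cols, drop = FALSE])
    }
    q <- qr(X)
    if (q$rank < ncol(X)) {
      X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
      q <- qr(X)
    }
    Q <- qr.Q(q)
    list(H = tcrossprod(Q), rank = q$rank)
  }
  full <- hat(terms)
  if (full$rank >= n) stop("rank-deficient residual: design saturates samples")
  reduced <- lapply(terms, function(t) hat(setdiff(terms, t)))
  df_res <- n - full$rank

  ss_model <- function(H, Gm) sum(H * Gm)  # tr(H G), both symmetric
  stat_for <- function(Gm) {
    ssf <- ss_model(full$H, Gm)
    ss_res <- sum(diag(Gm)) - ssf
    ss_t <- vapply(seq_along(terms), function(k) {
      ssf - ss_model(reduced[[k]]$H, Gm)
    }, numeric(1))
    df_t <- vapply(seq_along(terms), function(k) {
      full$rank - reduced[[k]]$rank
    }, numeric(1))
    list(ss = ss_t, df = df_t, f = (ss_t / df_t) / (ss_res / df_res),
         ss_res = ss_res)
  }
  obs <- stat_for(G)

  if (identical(n_perm, "exhaustive")) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    f_perm <- vapply(perms, function(p) stat_for(G[p, p])$f,
                     numeric(length(terms)))
    f_perm <- matrix(f_perm, nrow = length(terms))
    pvals <- rowMeans(f_perm >= obs$f - 1e-12)
    n_used <- length(perms)
  } else {
    stopifnot(n_perm >= 99)
    set.seed(seed)
    exceed <- numeric(length(terms))
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      fb <- stat_for(G[p, p])$f
      exceed <- exceed + (fb >= obs$f - 1e-12)
    }
    pvals <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  }

  res <- data.frame(
    term = c(terms, "residual"),
    df = c(obs$df, df_res),
    ss = c(obs$ss, obs$ss_res),
    r2 = c(obs$ss, obs$ss_res) / ss_total,
    pseudo_f = c(obs$f, NA),
    p_value = c(pvals, NA),
    stringsAsFactors = FALSE
  )
  attr(res, "n_permutations") <- n_used
  attr(res, "n_samples") <- n
  attr(res, "scheme") <- "free permutation of observations"
  class(res) <- c("permanova_result", "data.frame")
  res
}
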