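# mean-absolute-difference Gini oracle: G = sum|xi-xj| / (2 n^2 mean)
gini_mad <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

test_that("gini hits the closed-form anchors and errors on degenerate input", {
  expect_equal(gini(c(1, 1, 1, 1)), 0, tolerance = 1e-12)
  expect_equal(gini(c(1, 0, 0, 0)), 0.75, tolerance = 1e-12)  # 1 - 1/n
  for (n in c(2, 10, 137))
    expect_equal(gini(c(5, rep(0, n - 1))), 1 - 1 / n, tolerance = 1e-12)
  expect_error(gini(c(0, 0)), "positive")
  expect_error(gini(c(-1, 2)), "non-negative")
})

test_that("gini agrees with the mean-absolute-difference oracle and is scale invariant", {
  set.seed(23)
  for (i in 1:50) {
    x <- stats::rexp(sample(3:40, 1)) * sample(c(1, 100), 1)
    expect_equal(gini(x), gini_mad(x), tolerance = 1e-12)
    expect_equal(gini(x * 17.3), gini(x), tolerance = 1e-12)
  }
})

test_that("convergent recombination profile counts distinct nt variants per level", {
  rows <- data.frame(
    cdr3_aa = c("CAAF", "CAAF", "CAAF", "CTTF", "CGGF"),
    count = c(2, 1, 1, 3, 1),
    cdr3_nt = c("TGTGCAGCATTT", "TGTGCTGCATTT", "TGTGCCGCATTT",
                "TGTACAACATTT", "TGTGGAGGATTT"))
  r <- repertoire(rows)
  sh <- data.table::data.table(cdr3_aa = c("CAAF", "CTTF", "CGGF"),
                               sharing = c(3L, 1L, 1L))
  data.table::setattr(sh, "N", 3L)
  prof <- convergent_recombination(r, sh)
  expect_equal(prof[sharing == 3, mean_nt_variants], 3)   # alone in level
  expect_equal(prof[sharing == 1, mean_nt_variants], 1)   # two singles
  # all-single-variant repertoire gives a constant profile of 1
  r1 <- repertoire(data.frame(cdr3_aa = c("CAAF", "CTTF"), count = 1,
                              cdr3_nt = c("TGTGCAGCATTT", "TGTACAACATTT")))
  prof1 <- convergent_recombination(r1, sh)
  expect_true(all(prof1$mean_nt_variants == 1))
  expect_error(convergent_recombination(rep_from_counts(c(CAAF = 1)), sh),
               "nucleotide")
  det <- nt_variant_detail(r, "CAAF")
  expect_equal(nrow(det), 3)
  expect_equal(sum(det$fraction), 1)
})

test_that("subsample connectivity curve is monotone over nested top-N prefixes", {
  set.seed(47)
  seqs <- seq_set_with_neighbors(400, lens = 6:12)
  counts <- stats::setNames(sample(1:50, length(seqs), TRUE), seqs)
  r <- rep_from_counts(counts)
  cur <- subsample_connectivity_curve(r, c(50, 150, 300), mode = "top")
  expect_equal(cur$summary$size, c(50, 150, 300))
  expect_true(all(diff(cur$summary$mean) >= 0))
  # two sequences at distance 1 cluster at size 2
  r2 <- rep_from_counts(c(CAAAF = 2, CAAWF = 1))
  c2 <- subsample_connectivity_curve(r2, 2, mode = "top")
  expect_equal(c2$summary$mean, 2)
  # random mode is seeded and averaged over replicates
  cr <- subsample_connectivity_curve(r, c(100, 200), mode = "random",
                                     reps = 3, seed = 9)
  expect_equal(nrow(cr$detail), 6)
  cr2 <- subsample_connectivity_curve(r, c(100, 200), mode = "random",
                                      reps = 3, seed = 9)
  expect_equal(cr$detail, cr2$detail)
  expect_error(subsample_connectivity_curve(r, 1e6), "exceeds")
})

# exhaustive-enumeration Fisher oracle over all tables with the observed margins
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  lp <- function(x) lchoose(m, x) + lchoose(n, k - x) - lchoose(N, k)
  xs <- max(0, k - n):min(k, m)
  probs <- exp(lp(xs))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}

test_that("fisher exact matches enumeration and the trivial no-association table", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_value, 1.0)
  set.seed(3)
  for (i in 1:200) {
    tab <- matrix(sample(1:15, 4, TRUE), 2, 2)
    res <- fisher_exact_2x2(tab)
    expect_equal(res$p_value, fisher_oracle(tab), tolerance = 1e-12)
    expect_equal(res$odds_ratio,
                 tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2, 2)), "negative")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "margins")
})

test_that("paired rank test matches exhaustive sign-flip enumeration", {
  # constant shift on 10 distinct pairs -> minimal exact p = 2 / 2^10
  a <- c(1, 3, 6, 10, 15, 21, 28, 36, 45, 55)
  res <- paired_rank_test(a, a + 2)
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 2^10, tolerance = 1e-12)
  # all ties -> flagged undefined
  expect_true(paired_rank_test(a, a)$degenerate)
  # random fixtures incl. tied magnitudes, n 5..12
  set.seed(17)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    x <- stats::rnorm(n)
    y <- x + sample(c(-2, -1, 1, 1, 2), n, TRUE) * 0.5  # ties in |d| likely
    expect_equal(paired_rank_test(x, y)$p_value, wilcox_oracle(x, y),
                 tolerance = 1e-12)
  }
  # large-n path agrees with the normal-approximation reference
  set.seed(18)
  x <- stats::rnorm(60); y <- x + stats::rnorm(60, 0.3)
  ref <- suppressWarnings(stats::wilcox.test(y, x, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(paired_rank_test(x, y, exact_max = 25)$p_value, ref$p.value,
               tolerance = 1e-9)
})

test_that("gini and clustered nodes move oppositely under oligoclonal expansion", {
  cf <- default_mouse_config()
  res <- t(vapply(1:6, function(s) {
    r <- generate_repertoire(cf, 6000, seed = 100 + s)
    p <- perturb_repertoire(r, "oligoclonal", n_expand = 30, seed = s)
    top <- top_clonotypes(r, 500); ptop <- top_clonotypes(p, 500)
    c(dg = repertoire_gini(ptop) - repertoire_gini(top),
      dc = clustered_node_count(build_network(ptop)) -
           clustered_node_count(build_network(top)))
  }, c(dg = 0, dc = 0)))
  expect_true(all(res[, "dg"] > 0))          # inequality rises every seed
  expect_lt(mean(res[, "dc"]), 0)            # connectivity falls on average
  expect_lt(stats::cor(res[, "dg"], res[, "dc"], method = "spearman"), 1)
  # direction of the association across repertoires: G vs clustered nodes < 0
  g <- c(); cn <- c()
  for (s in 1:6) {
    r <- generate_repertoire(cf, 6000, seed = 200 + s)
    p <- perturb_repertoire(r, "oligoclonal", n_expand = 30, seed = s)
    for (rep_ in list(r, p)) {
      top <- top_clonotypes(rep_, 500)
      g <- c(g, repertoire_gini(top))
      cn <- c(cn, clustered_node_count(build_network(top)))
    }
  }
  expect_lt(stats::cor(g, cn, method = "spearman"), 0)
})
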