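make_cohort <- function(universes, ids = NULL, species = "mouse") {
  if (is.null(ids)) ids <- sprintf("m%02d", seq_along(universes))
  cohort(mapply(function(u, id) rep_from_counts(stats::setNames(rep(1, length(u)), u), id = id),
                universes, ids, SIMPLIFY = FALSE), species = species)
}

test_that("sharing levels match a brute-force membership scan", {
  set.seed(13)
  pool <- unique(rand_aa(120, 6:10))
  universes <- lapply(1:10, function(i) sample(pool, 40))
  co <- make_cohort(universes)
  sh <- sharing_levels(co)
  expect_equal(attr(sh, "N"), 10)
  qs <- sample(pool, 100)
  brute <- vapply(qs, function(q)
    sum(vapply(universes, function(u) q %in% u, TRUE)), 0L)
  scored <- sharing_levels(co, qs)
  expect_equal(scored$sharing[match(qs, scored$cdr3_aa)], unname(brute))
  # absent sequences score 0; present ones score >= 1
  out <- sharing_levels(co, c("WWWWWWWW", pool[1]))
  expect_equal(out[out$cdr3_aa == "WWWWWWWW", sharing], 0L)
  expect_gte(out[out$cdr3_aa == pool[1], sharing], 1L)
  expect_true(all(sh$sharing >= 1 & sh$sharing <= 10))
})

test_that("sharing is presence-based: invariant under abundance rescaling, floor configurable", {
  r1 <- rep_from_counts(c(CASSF = 100, CATF = 1), id = "a")
  r2 <- rep_from_counts(c(CASSF = 1), id = "b")
  co <- cohort(list(r1, r2))
  sh <- sharing_levels(co)
  expect_equal(sh[cdr3_aa == "CASSF", sharing], 2L)
  r1s <- rep_from_counts(c(CASSF = 1000, CATF = 10), id = "a")
  expect_equal(sharing_levels(cohort(list(r1s, r2))), sh)
  # count floor excludes low-count presence
  shf <- sharing_levels(co, count_floor = 2)
  expect_equal(shf[cdr3_aa == "CASSF", sharing], 1L)
  # leave-self-out drops the individual's own repertoire
  shl <- sharing_levels(co, c("CASSF", "CATF"), leave_out = "a")
  expect_equal(shl$sharing[match(c("CASSF", "CATF"), shl$cdr3_aa)], c(1L, 0L))
})

test_that("cross-species fractions hit the trivial bounds", {
  a <- make_cohort(list(c("AAA", "CCC"), c("AAA", "DDD")))
  b_disjoint <- make_cohort(list(c("WWW"), c("YYY")), ids = c("h1", "h2"))
  x <- cross_species_sharing(a, b_disjoint)
  expect_true(all(x$fractions$frac_in_other == 0))
  expect_length(x$shared, 0)
  b_super <- make_cohort(list(c("AAA", "CCC", "DDD", "EEE")), ids = "h1")
  x2 <- cross_species_sharing(a, b_super)
  expect_true(all(x2$fractions$frac_in_other == 1))
  expect_setequal(x2$shared, c("AAA", "CCC", "DDD"))
})

test_that("cs_public applies both thresholds and shrinks monotonically", {
  a <- make_cohort(list(c("AAA", "FFF"), c("AAA", "FFF"), c("AAA", "CCC")))
  b <- make_cohort(list(c("AAA", "FFF"), c("AAA", "DDD")), ids = c("h1", "h2"))
  # default-style scheme: a-threshold 2 of 3, b-threshold all (2)
  sc <- category_scheme(public_min_a = 2, public_min_b = NA)
  expect_identical(cs_public(a, b, sc), "AAA")
  # loosening b to 1 admits FFF as well
  expect_setequal(cs_public(a, b, category_scheme(2, 1)), c("AAA", "FFF"))
  # tightening shrinks: subset relation over nested thresholds
  loose <- cs_public(a, b, category_scheme(1, 1))
  tight <- cs_public(a, b, category_scheme(3, 2))
  expect_true(all(tight %in% loose))
  expect_error(cs_public(a, b, category_scheme(4, 1)), "exceeds")
})

test_that("cross-species categories partition sequences", {
  cat4 <- cross_species_categories(c(28, 28, 3, 3), 28,
                                   c(11, 10, 11, 2), 11,
                                   category_scheme(25, NA))
  expect_equal(as.character(cat4),
               c("cs_public", "public_a_only", "public_b_only", "not_public"))
})

test_that("cumulative frequency is additive mass", {
  r <- rep_from_counts(c(A = 6, C = 3, D = 1))
  expect_equal(cumulative_frequency(r, c("A", "D")), 0.7)
  expect_equal(cumulative_frequency(r, c("A", "C", "D")), 1.0)
  expect_equal(cumulative_frequency(r, "ZZZ"), 0.0)
})

test_that("frequency-by-sharing profiles conserve subset mass", {
  universes <- list(c("AAA", "FFF"), c("AAA", "CCC"), c("AAA", "FFF"))
  co <- make_cohort(universes)
  sh <- sharing_levels(co)
  r <- rep_from_counts(c(AAA = 4, FFF = 4, WWW = 2))
  prof <- frequency_by_sharing_profile(r, sh)
  expect_equal(prof$sharing, 0:3)
  expect_equal(sum(prof$frequency), 1)
  expect_equal(prof$frequency[prof$sharing == 3], 0.4)  # AAA
  expect_equal(prof$frequency[prof$sharing == 0], 0.2)  # WWW unseen
  # on a top-N subset the profile sums to the accumulated frequency
  top <- top_clonotypes(r, 2)
  prof2 <- frequency_by_sharing_profile(top, sh)
  expect_equal(sum(prof2$frequency), accumulated_frequency(top))
})

test_that("degree-sharing correlation behaves and matches a direct formula", {
  set.seed(91)
  seqs <- seq_set_with_neighbors(250, lens = 6:12)
  net <- build_network(seqs)
  deg <- node_degree(net)
  # synthetic sharing identical to degree -> R = 1
  sh1 <- data.table::data.table(cdr3_aa = names(deg), sharing = unname(deg))
  data.table::setattr(sh1, "N", max(deg))
  if (stats::sd(deg) > 0) {
    r1 <- degree_sharing_correlation(net, sh1)
    expect_equal(r1$estimate, 1, tolerance = 1e-12)
    # permuted sharing -> near-zero correlation, and agreement with cor()
    sh2 <- data.table::copy(sh1)[, sharing := sample(sharing)]
    r2 <- degree_sharing_correlation(net, sh2, method = "spearman")
    s <- sh2$sharing[match(names(deg), sh2$cdr3_aa)]
    expect_equal(r2$estimate, stats::cor(deg, s, method = "spearman"),
                 tolerance = 1e-12)
    expect_lt(abs(r2$estimate), 0.25)
  }
  # zero-variance sharing flags degenerate
  sh0 <- data.table::data.table(cdr3_aa = names(deg), sharing = 1L)
  expect_true(degree_sharing_correlation(net, sh0)$degenerate)
})

test_that("abundance_degree_r2 is the squared pearson of log abundance vs degree", {
  r <- rep_from_counts(stats::setNames(c(8, 4, 2, 1),
                                       c("AAAA", "AAAT", "AATT", "GGGG")))
  net <- build_network(r)
  deg <- node_degree(net)[net$nodes$cdr3_aa]
  expect_equal(abundance_degree_r2(net),
               stats::cor(log10(net$nodes$abundance), deg)^2,
               tolerance = 1e-12)
  expect_error(abundance_degree_r2(build_network(c("AAAA", "AAAT"))),
               "abundance")
})

test_that("two-cohort sharing table writes scores and categories", {
  a <- make_cohort(list(c("AAA", "FFF"), c("AAA")))
  b <- make_cohort(list(c("AAA")), ids = "h1")
  path <- tempfile(fileext = ".tsv")
  out <- write_sharing_table(c("AAA", "FFF", "WWW"), a, b, path,
                             category_scheme(2, NA))
  expect_true(file.exists(path))
  expect_equal(out$s_a, c(2L, 1L, 0L))
  expect_equal(as.character(out$category[1]), "cs_public")
})
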