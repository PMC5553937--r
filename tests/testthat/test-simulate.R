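test_that("degenerate no-deletion no-insertion config is deterministic", {
  cf <- simulation_config(
    species = "toy",
    v_segments = c(V1 = "TGTGCCAGC"),       # CAS
    d_segments = c(D1 = "GGGACA"),          # GT in frame
    j_segments = c(J1 = "GAACAGTACTTT"),    # EQYF
    del_mean = c(v = 0, d5 = 0, d3 = 0, j = 0), ins_mean = c(0, 0))
  d <- simulate_rearrangements(cf, 5, seed = 1)
  expect_equal(unique(d$cdr3_nt), "TGTGCCAGCGGGACAGAACAGTACTTT")
  expect_equal(unique(d$cdr3_aa), "CASGTEQYF")
})

test_that("every emitted rearrangement is productive and translates cleanly", {
  d <- simulate_rearrangements(default_mouse_config(), 2000, seed = 5)
  expect_true(all(nchar(d$cdr3_nt) %% 3 == 0))
  expect_false(any(grepl("*", d$cdr3_aa, fixed = TRUE)))
  expect_true(all(startsWith(d$cdr3_aa, "C")))      # conserved cysteine
  expect_true(all(endsWith(d$cdr3_aa, "F")))        # J anchor phenylalanine
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(d$cdr3_nt)))
  expect_identical(aa, d$cdr3_aa)
  expect_true(all(d$v_gene %in% names(default_mouse_config()$v_segments)))
})

test_that("pathological configs error after bounded attempts", {
  # J head of a lone F codon preceded by V ending mid-frame never yields
  # an in-frame product: force frame violation via ins of length 1 always
  cf <- simulation_config(
    species = "bad",
    v_segments = c(V1 = "TGTG"),  # 4 + 1 + 3 nt: never in frame
    d_segments = c(D1 = "G"),
    j_segments = c(J1 = "TTT"),
    del_mean = c(v = 0, d5 = 0, d3 = 0, j = 0), ins_mean = c(0, 0))
  expect_error(simulate_rearrangements(cf, 10, max_tries = 3),
               "productive")
})

test_that("repertoire generation is seed-reproducible and aggregates nt variants", {
  cf <- default_mouse_config()
  r1 <- generate_repertoire(cf, 3000, seed = 9)
  r2 <- generate_repertoire(cf, 3000, seed = 9)
  expect_equal(r1$clonotypes, r2$clonotypes)
  expect_equal(r1$nt_variants, r2$nt_variants)
  expect_false(identical(generate_repertoire(cf, 3000, seed = 10)$clonotypes,
                         r1$clonotypes))
  # n = 1 works
  expect_equal(n_clonotypes(generate_repertoire(cf, 1, seed = 1)), 1)
  # convergent recombination arises: some clonotypes carry >= 2 nt variants
  nv <- r1$nt_variants[, .(n = data.table::uniqueN(cdr3_nt)), by = cdr3_aa]
  expect_gt(sum(nv$n >= 2), 0)
})

test_that("config round-trips through its JSON file form", {
  cf <- default_human_config()
  path <- tempfile(fileext = ".json")
  write_simulation_config(cf, path)
  cf2 <- read_simulation_config(path)
  expect_equal(cf2, cf)
  r1 <- generate_repertoire(cf, 500, seed = 3)
  r2 <- generate_repertoire(cf2, 500, seed = 3)
  expect_identical(r1$clonotypes, r2$clonotypes)
  # germline FASTA export is readable and complete
  fa <- tempfile(fileext = ".fasta")
  write_germline_fasta(cf, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(seqs), length(cf$v_segments) + length(cf$d_segments) +
                 length(cf$j_segments))
})

test_that("collapsed sequence space yields near-total sharing", {
  cf <- toy_config(del_mean = c(v = 0, d5 = 0.2, d3 = 0.2, j = 0))
  co <- generate_cohort(cf, 2, 1500, seed = 8)
  sh <- sharing_levels(co)
  expect_gt(mean(sh$sharing == 2), 0.5)
})

test_that("sharing level tracks exact generation probability on a toy config", {
  cf <- toy_config()
  pg <- enumerate_generation_probabilities(cf)
  expect_equal(sum(pg$p_gen), 1, tolerance = 1e-9)
  # the enumeration is itself checked against simulation frequencies
  sim <- estimate_generation_frequency(cf, 20000, seed = 12)
  m <- merge(pg, sim, by = "cdr3_aa", all.x = TRUE)
  m[is.na(n_generated), n_generated := 0L]
  top <- m[p_gen > 0.005]
  expect_equal(top$n_generated / 20000, top$p_gen, tolerance = 0.15)
  # cohort sharing correlates with analytic p_gen
  co <- generate_cohort(cf, 10, 400, seed = 13)
  sh <- sharing_levels(co)
  mm <- merge(sh, pg, by = "cdr3_aa")
  expect_gt(stats::cor(mm$sharing, mm$p_gen, method = "spearman"), 0.5)
})

test_that("two-species cohorts produce a J-restricted CS-public set", {
  two <- generate_two_species(default_mouse_config(), default_human_config(),
                              n_a = 6, n_b = 5, n_clonotypes = 4000,
                              seed = 14)
  sc <- category_scheme(public_min_a = 5, public_min_b = 4)
  cs <- cs_public(two$a, two$b, sc)
  expect_gt(length(cs), 0)
  # CS-publics are dominated by the homologous J heads (mTRBJ1 / mTRBJ2)
  ju <- data.table::rbindlist(lapply(two$a$repertoires,
                                     function(r) r$j_usage[cdr3_aa %in% cs]))
  tot <- ju[, .(count = sum(count)), by = gene]
  expect_gt(sum(tot[gene %in% c("mTRBJ1", "mTRBJ2"), count]) / sum(tot$count),
            0.8)
  # cross-species fraction rises with sharing level
  x <- cross_species_sharing(two$a, two$b)
  fr <- x$fractions[n >= 5]
  expect_gt(stats::cor(fr$sharing, fr$frac_in_other, method = "spearman"), 0)
})

test_that("perturbation: none is identity; oligoclonal expands chosen clones", {
  r <- generate_repertoire(default_mouse_config(), 2000, seed = 15)
  expect_identical(perturb_repertoire(r, "none"), r)
  p <- perturb_repertoire(r, "oligoclonal", n_expand = 20, seed = 2)
  expect_equal(n_clonotypes(p), n_clonotypes(r))
  expect_gte(sum(p$clonotypes$total_count), sum(r$clonotypes$total_count))
  expect_gt(repertoire_gini(p), repertoire_gini(r))
  p2 <- perturb_repertoire(r, "oligoclonal", n_expand = 20, seed = 2)
  expect_identical(p$clonotypes, p2$clonotypes)
})

test_that("cluster J-homogeneity exceeds V-homogeneity on simulated networks", {
  r <- generate_repertoire(default_mouse_config(), 20000, seed = 16)
  net <- build_network(top_clonotypes(r, 800))
  cl <- network_clusters(net)
  cl <- cl[n_nodes >= 3]
  skipped <- nrow(cl) == 0
  expect_false(skipped)
  hj <- vapply(cl$cluster_id, function(id)
    cluster_dominant_gene(net, id, "J")$fraction, 0)
  hv <- vapply(cl$cluster_id, function(id)
    cluster_dominant_gene(net, id, "V")$fraction, 0)
  expect_gt(mean(hj), mean(hv))
})
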