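AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_aa <- function(n, lens = 8:20) {
  vapply(sample(lens, n, replace = TRUE),
         function(L) paste(sample(AA20, L, replace = TRUE), collapse = ""),
         "")
}

# one random single edit (substitution / deletion / insertion)
mutate1 <- function(s) {
  L <- nchar(s)
  p <- sample(L, 1)
  switch(sample(3, 1),
         paste0(substr(s, 1, p - 1), sample(AA20, 1), substr(s, p + 1, L)),
         paste0(substr(s, 1, p - 1), substr(s, p + 1, L)),
         paste0(substr(s, 1, p), sample(AA20, 1), substr(s, p + 1, L)))
}

# a set of unique sequences with planted distance-1 structure
seq_set_with_neighbors <- function(n, lens = 8:20, mut_frac = 0.5) {
  base <- unique(rand_aa(ceiling(n * (1 - mut_frac / 2)), lens))
  mut <- vapply(sample(base, ceiling(n * mut_frac), replace = TRUE),
                mutate1, "")
  unique(c(base, mut))
}

# repertoire from a named count vector
rep_from_counts <- function(counts, id = "r1", v = NULL, j = NULL,
                            nt = NULL) {
  rows <- data.frame(cdr3_aa = names(counts), count = as.numeric(counts))
  if (!is.null(v)) rows$v_gene <- v
  if (!is.null(j)) rows$j_gene <- j
  if (!is.null(nt)) rows$cdr3_nt <- nt
  repertoire(rows, individual_id = id)
}

# all-pairs DP-Levenshtein edge set via base R adist (independent oracle)
oracle_edges <- function(seqs) {
  D <- utils::adist(seqs, seqs)
  idx <- which(D == 1 & upper.tri(D), arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(from = character(), to = character()))
  e <- data.frame(from = pmin(seqs[idx[, 1]], seqs[idx[, 2]]),
                  to = pmax(seqs[idx[, 1]], seqs[idx[, 2]]),
                  stringsAsFactors = FALSE)
  e[order(e$from, e$to), , drop = FALSE]
}

expect_same_edges <- function(net, seqs) {
  oe <- oracle_edges(seqs)
  expect_equal(nrow(net$edges), nrow(oe))
  if (nrow(oe)) {
    expect_identical(net$edges$from, oe$from)
    expect_identical(net$edges$to, oe$to)
  }
}

# exhaustive sign-flip Wilcoxon signed-rank oracle (two-sided)
wilcox_oracle <- function(a, b) {
  d <- b - a
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  flips <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(flips, 1, function(f) sum(r[f]))
  p_lo <- mean(Ws <= W + 1e-9); p_hi <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# tiny two-segment toy config for exact enumeration tests
toy_config <- function(ins_mean = c(0, 0), del_mean = c(v = 1, d5 = 0.5,
                                                        d3 = 0.5, j = 1)) {
  simulation_config(
    species = "toy",
    v_segments = c(V1 = "TGTGCCAGCAGT", V2 = "TGTGCCTGG"),
    v_weights = c(0.7, 0.3),
    d_segments = c(D1 = "GGGACAGGG"),
    j_segments = c(J1 = "AGCTATGAACAGTACTTT", J2 = "AACACTTTGTTT"),
    j_weights = c(0.6, 0.4),
    del_mean = del_mean, ins_mean = ins_mean)
}
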