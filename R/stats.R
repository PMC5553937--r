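#' Gini inequality coefficient of clone abundances
#'
#' Measures repertoire evenness: 0 when every clonotype has equal
#' abundance, approaching 1 (exactly 1 - 1/n) when a single clonotype
#' dominates and all others are at zero. Computed with the sorted-vector
#' formula `G = sum_i (2i - n - 1) x_(i) / (n sum x)` (x ascending), which
#' equals the mean-absolute-difference definition
#' `G = sum_{i,j} |x_i - x_j| / (2 n^2 mean(x))`.
#'
#' @param abundances numeric vector of non-negative abundances with at
#'   least one positive entry. Scale-invariant.
#' @return G in [0, 1].
#' @export
gini <- function(abundances) {
  x <- as.numeric(abundances)
  if (any(is.na(x)) || any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0) stop("at least one abundance must be positive")
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Gini of a repertoire's clonotype abundances
#'
#' Convenience wrapper computing [gini()] over the clonotype counts of a
#' repertoire or subset (e.g. the top-1000 clonotypes).
#' @param rep a `tcr_repertoire`.
#' @export
repertoire_gini <- function(rep) gini(rep$clonotypes$total_count)

#' Convergent recombination profile
#'
#' Convergent recombination is the independent generation of the same
#' amino-acid CDR3 from distinct nucleotide rearrangements. This profiles
#' it against publicness: clonotypes are grouped by their sharing level in
#' a reference cohort and the mean number of distinct nucleotide variants
#' per amino-acid clonotype is reported per level.
#'
#' @param rep a `tcr_repertoire` whose clonotypes carry nucleotide
#'   variants.
#' @param sharing a sharing table from [sharing_levels()]; clonotypes
#'   absent from it get level 0.
#' @return data.table (`sharing`, `n_clonotypes`, `mean_nt_variants`).
#' @export
convergent_recombination <- function(rep, sharing) {
  if (!nrow(rep$nt_variants)) stop("repertoire carries no nucleotide data")
  nv <- rep$nt_variants[, .(n_nt = uniqueN(cdr3_nt)), by = cdr3_aa]
  nv <- nv[rep$clonotypes[, .(cdr3_aa)], on = "cdr3_aa"]
  nv[is.na(n_nt), n_nt := 1L]  # clonotypes lacking nt rows count as one variant
  nv[, sharing := sharing$sharing[match(cdr3_aa, sharing$cdr3_aa)]]
  nv[is.na(sharing), sharing := 0L]
  out <- nv[, .(n_clonotypes = .N, mean_nt_variants = mean(n_nt)),
            by = sharing]
  setorder(out, sharing)
  out[]
}

#' Nucleotide-variant expansion detail for named clonotypes
#'
#' Per-clonotype stacked view of the distinct nucleotide sequences
#' encoding it, with each variant's share of the clonotype's reads.
#'
#' @param rep a `tcr_repertoire` with nucleotide variants.
#' @param seqs CDR3 AA sequences of interest.
#' @return data.table (`cdr3_aa`, `cdr3_nt`, `count`, `fraction`).
#' @export
nt_variant_detail <- function(rep, seqs) {
  if (!nrow(rep$nt_variants)) stop("repertoire carries no nucleotide data")
  out <- rep$nt_variants[cdr3_aa %in% seqs]
  out[, fraction := count / sum(count), by = cdr3_aa]
  setorder(out, cdr3_aa, -count, cdr3_nt)
  out[]
}

#' Clustered-node counts under subsampling
#'
#' For each requested sample size, selects clonotypes (most abundant, or
#' seeded uniform random), builds the distance-1 network and counts
#' clustered nodes. Random mode averages over `reps` independent
#' replicates; top mode is deterministic so replicates are collapsed to
#' one.
#'
#' @param rep a `tcr_repertoire`.
#' @param sizes integer sample sizes (each <= number of clonotypes).
#' @param mode `"top"` or `"random"`.
#' @param reps replicates for random mode (default 10).
#' @param seed base seed for random mode.
#' @return list with `detail` (size, replicate, clustered_nodes) and
#'   `summary` (size, mean, se, n); `se` is sample SD divided by sqrt(n).
#' @export
subsample_connectivity_curve <- function(rep, sizes, mode = c("top", "random"),
                                         reps = 10, seed = 1) {
  mode <- match.arg(mode)
  if (any(sizes > nrow(rep$clonotypes)))
    stop("a requested size exceeds the number of unique clonotypes")
  if (mode == "top") reps <- 1L
  detail <- rbindlist(lapply(sizes, function(sz) {
    rbindlist(lapply(seq_len(reps), function(r) {
      sub <- if (mode == "top") top_clonotypes(rep, sz)
             else random_clonotypes(rep, sz, seed = seed, replicate = r)
      data.table(size = sz, replicate = r,
                 clustered_nodes = clustered_node_count(build_network(sub)))
    }))
  }))
  summary <- detail[, .(
    mean = mean(clustered_nodes),
    se = if (.N > 1) stats::sd(clustered_nodes) / sqrt(.N) else 0,
    n = .N), by = size]
  list(detail = detail[], summary = summary[])
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided exact p-value by the probability-mass method: the sum of
#' hypergeometric probabilities (over all tables with the observed
#' margins) not exceeding the observed table's probability. The sample
#' odds ratio ad/bc is reported (not the conditional MLE).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `p_value`, `odds_ratio` and the observed table.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (any(c(a + b, c + d, a + c, b + d) == 0))
    stop("all margins must be positive")
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p),
       odds_ratio = (a * d) / (b * c),
       table = tab)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired test on `values_b - values_a`. Zero differences are
#' dropped (their number is reported); if all differences are zero the
#' result is flagged undefined. For n <= `exact_max` non-zero pairs the
#' exact null distribution of the signed-rank statistic is computed by
#' convolution over the actual (possibly tied, mid-) ranks, so ties are
#' handled exactly; beyond that a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param values_a,values_b paired numeric vectors of equal length >= 5.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list with `p_value`, `statistic` (W = sum of positive-difference
#'   ranks), `n` (non-zero pairs), `n_zero`, `exact`, `degenerate`.
#' @export
paired_rank_test <- function(values_a, values_b, exact_max = 25) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 5)
  d <- as.numeric(values_b) - as.numeric(values_a)
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p_value = NA_real_, statistic = NA_real_, n = 0L,
                n_zero = n_zero, exact = NA, degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of 2W over all 2^n sign assignments
    r2 <- as.integer(round(2 * r))
    dist <- .signed_rank_distribution(r2)
    w2 <- as.integer(round(2 * W))
    p_lo <- sum(dist$prob[dist$w <= w2])
    p_hi <- sum(dist$prob[dist$w >= w2])
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(p_value = p, statistic = W, n = n, n_zero = n_zero, exact = exact,
       degenerate = FALSE)
}

# Null distribution of twice the signed-rank statistic for given doubled
# ranks: convolution of independent {0, r} contributions.
.signed_rank_distribution <- function(r2) {
  total <- sum(r2)
  counts <- numeric(total + 1)  # index w+1 for w in 0..total
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  data.frame(w = 0:total, prob = counts / sum(counts))
}
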