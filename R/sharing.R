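#' Sharing levels of CDR3 sequences in a reference cohort
#'
#' The sharing level of a sequence is the number of cohort individuals
#' whose repertoire contains it — from 1 (private, found in a single
#' individual) to N (public, found in all N). Presence means at least
#' `count_floor` reads (default 1). Sequences queried but absent from the
#' cohort get sharing level 0.
#'
#' @param cohort a `tcr_cohort`.
#' @param seqs optional character vector of sequences to score; default all
#'   sequences occurring in the cohort.
#' @param count_floor minimum total count for presence (default 1).
#' @param leave_out optional `individual_id` excluded from the count
#'   (leave-self-out scoring).
#' @return data.table (`cdr3_aa`, `sharing`) with attribute `N` = number of
#'   individuals counted.
#' @export
sharing_levels <- function(cohort, seqs = NULL, count_floor = 1,
                           leave_out = NULL) {
  stopifnot(inherits(cohort, "tcr_cohort"), length(cohort$repertoires) >= 1)
  reps <- cohort$repertoires
  if (!is.null(leave_out)) reps <- reps[setdiff(names(reps), leave_out)]
  present <- rbindlist(lapply(reps, function(r)
    r$clonotypes[total_count >= count_floor, .(cdr3_aa)]))
  tab <- present[, .(sharing = .N), by = cdr3_aa]
  if (!is.null(seqs)) {
    out <- data.table(cdr3_aa = unique(as.character(seqs)))
    out[, sharing := tab$sharing[match(cdr3_aa, tab$cdr3_aa)]]
    out[is.na(sharing), sharing := 0L]
  } else {
    out <- tab
    setorder(out, -sharing, cdr3_aa)
  }
  setattr(out, "N", length(reps))
  out[]
}

#' Sharing-category thresholds
#'
#' Default scheme mirrors the mouse/human reference convention:
#' mouse-public = found in at least 25 of the 28 mice; human-public =
#' found in all 11 young subjects; cross-species (CS-) public = both;
#' relatively private = shared by 0-5 of the 11 humans.
#'
#' @param public_min_a,public_min_b minimum sharing for publicness in
#'   cohort a (mouse-style, default 25) and cohort b (human-style, default
#'   `NA` meaning "all individuals").
#' @param relatively_private_max maximum sharing for the relatively-private
#'   label (default 5).
#' @export
category_scheme <- function(public_min_a = 25, public_min_b = NA,
                            relatively_private_max = 5) {
  structure(list(public_min_a = public_min_a, public_min_b = public_min_b,
                 relatively_private_max = relatively_private_max),
            class = "category_scheme")
}

.resolve_min <- function(min, N) {
  m <- if (is.na(min)) N else min
  if (m > N) stop("publicness threshold ", m, " exceeds cohort size ", N)
  m
}

#' Cross-species sharing categories
#'
#' Partitions sequences into the four mutually exclusive categories of the
#' two-cohort comparison: public in both ("cs_public"), public only in
#' cohort a, public only in cohort b, or neither.
#'
#' @param s_a,s_b sharing levels in cohorts a and b.
#' @param N_a,N_b cohort sizes.
#' @param scheme a [category_scheme()].
#' @return factor with levels `cs_public`, `public_a_only`,
#'   `public_b_only`, `not_public`.
#' @export
cross_species_categories <- function(s_a, N_a, s_b, N_b,
                                     scheme = category_scheme()) {
  min_a <- .resolve_min(scheme$public_min_a, N_a)
  min_b <- .resolve_min(scheme$public_min_b, N_b)
  pa <- s_a >= min_a; pb <- s_b >= min_b
  factor(ifelse(pa & pb, "cs_public",
         ifelse(pa, "public_a_only",
         ifelse(pb, "public_b_only", "not_public"))),
         levels = c("cs_public", "public_a_only", "public_b_only",
                    "not_public"))
}

#' Cross-species sharing curve
#'
#' For each sharing level in cohort a, the fraction of its sequences found
#' in at least one individual of cohort b, plus the global intersection of
#' the two amino-acid sequence universes.
#'
#' @param cohort_a,cohort_b two `tcr_cohort`s.
#' @param count_floor presence floor passed to [sharing_levels()].
#' @return list with `fractions` (data.table `sharing`, `n`,
#'   `frac_in_other`) and `shared` (character vector of sequences present
#'   in both cohorts).
#' @export
cross_species_sharing <- function(cohort_a, cohort_b, count_floor = 1) {
  sa <- sharing_levels(cohort_a, count_floor = count_floor)
  sb <- sharing_levels(cohort_b, count_floor = count_floor)
  in_b <- sa$cdr3_aa %in% sb$cdr3_aa
  fr <- data.table(sharing = sa$sharing, in_other = in_b)[
    , .(n = .N, frac_in_other = mean(in_other)), by = sharing]
  setorder(fr, sharing)
  list(fractions = fr[], shared = intersect(sa$cdr3_aa, sb$cdr3_aa))
}

#' Cross-species public sequences
#'
#' The set of sequences public (or nearly so) in both cohorts under the
#' scheme's thresholds — with the default scheme, sequences found in at
#' least 25 of 28 mice and in all 11 young humans.
#'
#' @param cohort_a,cohort_b two `tcr_cohort`s (a = mouse-style threshold,
#'   b = all-individuals threshold by default).
#' @param scheme a [category_scheme()].
#' @param count_floor presence floor.
#' @return character vector of CS-public sequences (sorted).
#' @export
cs_public <- function(cohort_a, cohort_b, scheme = category_scheme(),
                      count_floor = 1) {
  sa <- sharing_levels(cohort_a, count_floor = count_floor)
  sb <- sharing_levels(cohort_b, count_floor = count_floor)
  min_a <- .resolve_min(scheme$public_min_a, attr(sa, "N"))
  min_b <- .resolve_min(scheme$public_min_b, attr(sb, "N"))
  sort(intersect(sa[sharing >= min_a, cdr3_aa],
                 sb[sharing >= min_b, cdr3_aa]))
}

#' Cumulative frequency of a sequence set in a repertoire
#'
#' Sum of relative clonotype abundances over the given sequences; 0 if
#' none is present.
#'
#' @param rep a `tcr_repertoire`.
#' @param seqs character vector of CDR3 AA sequences.
#' @return fraction in [0, 1].
#' @export
cumulative_frequency <- function(rep, seqs) {
  tot <- sum(rep$clonotypes$total_count)
  if (tot == 0) return(0)
  sum(rep$clonotypes[cdr3_aa %in% seqs, total_count]) / tot
}

#' Frequency of a repertoire subset by sharing level
#'
#' Partitions the subset's frequency mass (relative to the full parent
#' repertoire) across reference-cohort sharing levels 0..N. The profile
#' sums to the subset's accumulated frequency.
#'
#' @param rep_subset a subset from [top_clonotypes()] et al. (or a full
#'   repertoire, whose accumulated frequency is 1).
#' @param sharing a sharing table from [sharing_levels()].
#' @return data.table (`sharing`, `frequency`) covering levels 0..N.
#' @export
frequency_by_sharing_profile <- function(rep_subset, sharing) {
  N <- attr(sharing, "N")
  acc <- attr(rep_subset, "accumulated_frequency")
  if (is.null(acc)) acc <- 1
  clon <- copy(rep_subset$clonotypes)
  clon[, sharing := sharing$sharing[match(cdr3_aa, sharing$cdr3_aa)]]
  clon[is.na(sharing), sharing := 0L]
  sub_total <- sum(clon$total_count)
  prof <- clon[, .(mass = sum(total_count)), by = sharing]
  out <- data.table(sharing = 0:N)
  out[, frequency := 0]
  out[prof, frequency := i.mass / sub_total * acc, on = "sharing"]
  out[]
}

#' Correlation between node degree and sharing level
#'
#' Correlates each node's degree in the similarity network with its sharing
#' level in a reference cohort. Both Pearson (the default, mirroring
#' R/R-squared style reporting) and Spearman are exposed.
#'
#' @param net a `tcr_network`.
#' @param sharing a sharing table from [sharing_levels()]; nodes absent
#'   from it get sharing 0.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `p_value`, `method`, `n`; `estimate` is
#'   `NA` (flagged via `degenerate = TRUE`) if either variable has zero
#'   variance.
#' @export
degree_sharing_correlation <- function(net, sharing,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  deg <- node_degree(net)
  s <- sharing$sharing[match(names(deg), sharing$cdr3_aa)]
  s[is.na(s)] <- 0L
  if (length(deg) < 3) stop("need at least 3 nodes")
  if (stats::sd(deg) == 0 || stats::sd(s) == 0)
    return(list(estimate = NA_real_, p_value = NA_real_, method = method,
                n = length(deg), degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(deg, s, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(deg), degenerate = FALSE)
}

#' R-squared of log-abundance vs degree
#'
#' Squared product-moment correlation between log10 clonotype abundance
#' and node degree; quantifies how little of the network connectivity is
#' explained by abundance.
#'
#' @param net a `tcr_network` built from a repertoire (abundances needed).
#' @return R-squared in [0, 1], `NA` if degenerate.
#' @export
abundance_degree_r2 <- function(net) {
  ab <- net$nodes$abundance
  if (all(is.na(ab))) stop("network carries no abundance data")
  deg <- node_degree(net)[net$nodes$cdr3_aa]
  x <- log10(ab)
  if (stats::sd(x) == 0 || stats::sd(deg) == 0) return(NA_real_)
  stats::cor(x, deg)^2
}

#' Write a two-cohort sharing table as TSV
#'
#' @param seqs sequences to score.
#' @param cohort_a,cohort_b reference cohorts.
#' @param path output path.
#' @param scheme a [category_scheme()] used for the category column.
#' @export
write_sharing_table <- function(seqs, cohort_a, cohort_b, path,
                                scheme = category_scheme()) {
  sa <- sharing_levels(cohort_a, seqs)
  sb <- sharing_levels(cohort_b, seqs)
  out <- data.table(cdr3_aa = sa$cdr3_aa,
                    s_a = sa$sharing, N_a = attr(sa, "N"),
                    s_b = sb$sharing[match(sa$cdr3_aa, sb$cdr3_aa)],
                    N_b = attr(sb, "N"))
  out[, category := cross_species_categories(s_a, N_a[1], s_b, N_b[1],
                                             scheme)]
  fwrite(out, path, sep = "\t")
  invisible(out[])
}
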