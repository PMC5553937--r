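ANNOTATION_CATEGORIES <- c("autoimmune", "tumor", "allograft", "pathogen")

#' Construct annotation records
#'
#' Annotations are externally curated CDR3 sequences with a free-text
#' label (e.g. a disease model) and one of four categories. The
#' `self_related` flag is derived deterministically from the category:
#' autoimmune, tumor and allograft reactivities are self or self-like,
#' pathogen immunity is non-self.
#'
#' @param cdr3_aa character vector of CDR3 AA sequences.
#' @param label free-text annotation labels.
#' @param category one of `"autoimmune"`, `"tumor"`, `"allograft"`,
#'   `"pathogen"` per record.
#' @return data.table (`cdr3_aa`, `label`, `category`, `self_related`).
#' @export
annotation_records <- function(cdr3_aa, label, category) {
  category <- match.arg(as.character(category), ANNOTATION_CATEGORIES,
                        several.ok = TRUE)
  stopifnot(length(cdr3_aa) == length(label),
            length(cdr3_aa) == length(category),
            all(grepl(AA_REGEX, cdr3_aa)))
  data.table(cdr3_aa = as.character(cdr3_aa), label = as.character(label),
             category = category,
             self_related = category %in% c("autoimmune", "tumor",
                                            "allograft"))
}

#' Read an annotation list from TSV
#' @param path TSV with columns `cdr3_aa`, `label`, `category`.
#' @export
read_annotations <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  stopifnot(all(c("cdr3_aa", "label", "category") %in% names(dt)))
  annotation_records(dt$cdr3_aa, dt$label, dt$category)
}

#' Link annotated sequences to a similarity network
#'
#' Each annotation is classified as `identical` (equal to a network node),
#' `distance1` (at Levenshtein distance 1 from at least one node) or
#' `unlinked`. The linked cluster is the matched node's cluster in the
#' identical case; in the distance-1 case, when several clustered nodes
#' match, the largest cluster wins, ties broken by the lexicographically
#' smallest member node — all candidate clusters are also reported.
#' Annotations whose only matches are isolated nodes are linked but carry
#' no cluster (`linked_to_clustered = FALSE`).
#'
#' @param net a `tcr_network`.
#' @param annotations records from [annotation_records()].
#' @return data.table with one row per annotation: `cdr3_aa`, `label`,
#'   `category`, `self_related`, `status`, `cluster_id`,
#'   `linked_to_clustered`, `n_matches`, `candidate_clusters`
#'   (comma-separated).
#' @export
link_annotations <- function(net, annotations) {
  stopifnot(nrow(annotations) >= 1)
  ann <- copy(annotations)
  nodes <- net$nodes$cdr3_aa
  memb <- cluster_membership(net)
  csize <- table(memb[!is.na(memb)])

  matches <- .dist1_pairs(unique(ann$cdr3_aa), nodes)

  link_one <- function(q) {
    if (q %in% nodes) {
      cl <- memb[[q]]
      return(list(status = "identical", cluster_id = cl,
                  linked_to_clustered = !is.na(cl),
                  n_matches = 1L,
                  candidate_clusters = if (is.na(cl)) "" else as.character(cl)))
    }
    hit <- matches[query == q, target]
    if (!length(hit))
      return(list(status = "unlinked", cluster_id = NA_integer_,
                  linked_to_clustered = FALSE, n_matches = 0L,
                  candidate_clusters = ""))
    cls <- memb[hit]
    clustered_hits <- hit[!is.na(cls)]
    if (!length(clustered_hits))
      return(list(status = "distance1", cluster_id = NA_integer_,
                  linked_to_clustered = FALSE, n_matches = length(hit),
                  candidate_clusters = ""))
    cand <- sort(unique(memb[clustered_hits]))
    ord <- order(-as.integer(csize[as.character(memb[clustered_hits])]),
                 clustered_hits)
    list(status = "distance1",
         cluster_id = memb[[clustered_hits[ord[1]]]],
         linked_to_clustered = TRUE, n_matches = length(hit),
         candidate_clusters = paste(cand, collapse = ","))
  }
  res <- rbindlist(lapply(ann$cdr3_aa, link_one))
  cbind(ann, res)
}

# Distance-exactly-1 (query, target) pairs via the deletion-variant index
# over both sets; distance-0 pairs (query equal to a target) are excluded
# (they are the "identical" case, handled separately).
.dist1_pairs <- function(query, targets) {
  empty <- data.table(query = character(), target = character())
  if (!length(query) || !length(targets)) return(empty)
  qk <- as.data.table(deletion_keys_cpp(query))
  tk <- as.data.table(deletion_keys_cpp(targets))
  cand <- qk[tk, on = "key", allow.cartesian = TRUE, nomatch = NULL][
    , .(query = query[id], target = targets[i.id])]
  cand <- unique(cand[query != target])
  if (!nrow(cand)) return(empty)
  cand[is_dist1_cpp(query, target)]
}

#' Self vs non-self enrichment of network-linked annotations
#'
#' Builds the 2x2 table of annotation counts, network-clustered vs not,
#' by self-related vs non-self, and applies [fisher_exact_2x2()].
#' "Clustered" means linked (identical or distance 1) to a node inside a
#' cluster. The complementary (non-overlapping) row holds all remaining
#' annotations. The overall self-related percentages of the clustered set
#' and of the full list are reported alongside.
#'
#' @param linkage result of [link_annotations()].
#' @return list with `table`, `p_value`, `odds_ratio`,
#'   `pct_self_clustered`, `pct_self_all`, `degenerate`.
#' @export
category_enrichment <- function(linkage) {
  clustered <- linkage$linked_to_clustered
  self <- linkage$self_related
  tab <- matrix(c(sum(clustered & self), sum(clustered & !self),
                  sum(!clustered & self), sum(!clustered & !self)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("clustered", "unclustered"),
                                c("self", "nonself")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  res <- if (degenerate) list(p_value = NA_real_, odds_ratio = NA_real_)
         else fisher_exact_2x2(tab)
  list(table = tab, p_value = res$p_value, odds_ratio = res$odds_ratio,
       pct_self_clustered = if (sum(clustered)) mean(self[clustered]) else NA,
       pct_self_all = mean(self),
       degenerate = degenerate)
}

#' Per-cluster annotation listing
#'
#' @param linkage result of [link_annotations()].
#' @return data.table of linked annotations grouped by cluster, mirroring
#'   the side lists of annotated networks.
#' @export
cluster_annotation_listing <- function(linkage) {
  out <- linkage[linked_to_clustered == TRUE,
                 .(cdr3_aa, label, category, status, cluster_id)]
  setorder(out, cluster_id, cdr3_aa)
  out[]
}
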