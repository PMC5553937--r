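#' @useDynLib tcrnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

AA_ALPHABET_20 <- c("A","C","D","E","F","G","H","I","K","L",
                    "M","N","P","Q","R","S","T","V","W","Y")
AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Construct a repertoire from clonotype rows
#'
#' A repertoire is one individual's collection of CDR3 amino-acid
#' clonotypes. Rows with identical `cdr3_aa` are aggregated into a single
#' clonotype: counts are summed, V/J gene usage is tallied, and distinct
#' CDR3 nucleotide variants are recorded with their counts. Rows whose
#' `cdr3_aa` is empty, contains a stop (`*`) or any non-standard amino-acid
#' letter, or whose count is not a positive number, are dropped and counted
#' in the load report (`load_report(rep)`).
#'
#' @param rows data.frame with columns `cdr3_aa`, `count`, and optionally
#'   `v_gene`, `j_gene`, `cdr3_nt`.
#' @param individual_id identifier for the individual.
#' @param metadata named list (species, cell subset, condition, ...).
#' @return An object of class `tcr_repertoire`: a list with elements
#'   `individual_id`, `metadata`, `clonotypes` (data.table `cdr3_aa`,
#'   `total_count`), `v_usage`/`j_usage` (long data.tables `cdr3_aa`,
#'   `gene`, `count`) and `nt_variants` (data.table `cdr3_aa`, `cdr3_nt`,
#'   `count`).
#' @export
repertoire <- function(rows, individual_id = "individual", metadata = list()) {
  rows <- as.data.table(rows)
  stopifnot(all(c("cdr3_aa", "count") %in% names(rows)))
  n_input <- nrow(rows)
  rows[, cdr3_aa := as.character(cdr3_aa)]
  rows[, count := suppressWarnings(as.numeric(count))]

  bad_aa <- is.na(rows$cdr3_aa) | !grepl(AA_REGEX, rows$cdr3_aa)
  bad_count <- is.na(rows$count) | rows$count <= 0
  keep <- !bad_aa & !bad_count
  report <- list(
    n_rows = n_input,
    n_loaded = sum(keep),
    n_dropped_invalid_aa = sum(bad_aa),
    n_dropped_nonpositive_count = sum(bad_count & !bad_aa)
  )
  rows <- rows[keep]

  clon <- rows[, .(total_count = sum(count)), by = cdr3_aa]
  setorder(clon, -total_count, cdr3_aa)

  tally <- function(col) {
    if (!col %in% names(rows)) return(data.table(cdr3_aa = character(),
                                                 gene = character(),
                                                 count = numeric()))
    x <- rows[!is.na(get(col)) & nzchar(get(col)),
              .(count = sum(count)), by = .(cdr3_aa, gene = get(col))]
    setorder(x, cdr3_aa, -count, gene)
    x
  }
  nt <- if ("cdr3_nt" %in% names(rows)) {
    x <- rows[!is.na(cdr3_nt) & nzchar(cdr3_nt),
              .(count = sum(count)), by = .(cdr3_aa, cdr3_nt)]
    setorder(x, cdr3_aa, -count, cdr3_nt)
    x
  } else data.table(cdr3_aa = character(), cdr3_nt = character(),
                    count = numeric())

  rep <- structure(list(individual_id = as.character(individual_id),
                        metadata = metadata,
                        clonotypes = clon,
                        v_usage = tally("v_gene"),
                        j_usage = tally("j_gene"),
                        nt_variants = nt),
                   class = "tcr_repertoire")
  attr(rep, "load_report") <- report
  rep
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s: %d clonotypes, %s reads\n",
              x$individual_id, nrow(x$clonotypes),
              format(sum(x$clonotypes$total_count), big.mark = ",")))
  invisible(x)
}

#' Number of unique clonotypes in a repertoire
#' @param rep a `tcr_repertoire`.
#' @export
n_clonotypes <- function(rep) nrow(rep$clonotypes)

#' Load report of a repertoire
#'
#' Counts of input rows kept and dropped (invalid amino-acid sequence,
#' non-positive count) when the repertoire was constructed.
#' @param rep a `tcr_repertoire`.
#' @export
load_report <- function(rep) attr(rep, "load_report")

#' Clonotype relative frequencies
#'
#' @param rep a `tcr_repertoire`.
#' @return named numeric vector of `total_count / sum(total_count)` per
#'   clonotype; sums to 1.
#' @export
clonotype_frequencies <- function(rep) {
  f <- rep$clonotypes$total_count / sum(rep$clonotypes$total_count)
  names(f) <- rep$clonotypes$cdr3_aa
  f
}

#' Per-clonotype detail
#'
#' @param rep a `tcr_repertoire`.
#' @param cdr3 amino-acid sequence of the clonotype.
#' @return list with `cdr3_aa`, `total_count`, `v_usage` and `j_usage`
#'   (named count vectors), and `nt_variants` (data.table).
#' @export
clonotype_info <- function(rep, cdr3) {
  i <- match(cdr3, rep$clonotypes$cdr3_aa)
  if (is.na(i)) stop("clonotype not found: ", cdr3)
  as_vec <- function(dt) {
    x <- dt[cdr3_aa == cdr3]
    stats::setNames(x$count, x$gene)
  }
  list(cdr3_aa = cdr3,
       total_count = rep$clonotypes$total_count[i],
       v_usage = as_vec(rep$v_usage),
       j_usage = as_vec(rep$j_usage),
       nt_variants = rep$nt_variants[cdr3_aa == cdr3])
}

.col_maps <- list(
  tsv  = c(cdr3_aa = "cdr3_aa", count = "count",
           v_gene = "v_gene", j_gene = "j_gene", cdr3_nt = "cdr3_nt"),
  airr = c(cdr3_aa = "junction_aa", count = "duplicate_count",
           v_gene = "v_call", j_gene = "j_call", cdr3_nt = "junction")
)

#' Read a clonotype table
#'
#' Reads a per-individual clonotype table in either the package's plain TSV
#' dialect (columns `cdr3_aa`, `count`, `v_gene`, `j_gene`, optional
#' `cdr3_nt`) or AIRR Rearrangement TSV (`junction_aa`, `duplicate_count`,
#' `v_call`, `j_call`, optional `junction`). Rows are aggregated to
#' amino-acid clonotypes; invalid rows are dropped and reported (see
#' [load_report()]).
#'
#' @param path file path.
#' @param format `"tsv"` or `"airr"`.
#' @param individual_id defaults to the file name without extension.
#' @param metadata named list attached to the repertoire.
#' @return a [repertoire()].
#' @export
read_repertoire <- function(path, format = c("tsv", "airr"),
                            individual_id = NULL, metadata = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  map <- .col_maps[[format]]
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = intersect(unname(map[c("cdr3_aa","v_gene","j_gene","cdr3_nt")]),
                          names(fread(path, nrows = 0)))))
  required <- map[c("cdr3_aa", "count")]
  missing <- setdiff(unname(required), names(dt))
  if (length(missing))
    stop("missing required column(s) in ", format, " input: ",
         paste(missing, collapse = ", "))
  present <- map[unname(map) %in% names(dt)]
  rows <- dt[, unname(present), with = FALSE]
  setnames(rows, unname(present), names(present))
  if (is.null(individual_id))
    individual_id <- sub("\\.[^.]*$", "", basename(path))
  repertoire(rows, individual_id = individual_id, metadata = metadata)
}

#' Write a repertoire as a clonotype table
#'
#' Writes one row per (clonotype, nt variant, V, J) combination when the
#' detail is available, else one row per clonotype, in the selected dialect.
#' Reading the file back yields an identical repertoire.
#'
#' @param rep a `tcr_repertoire`.
#' @param path output file path.
#' @param format `"tsv"` or `"airr"`.
#' @export
write_repertoire <- function(rep, path, format = c("tsv", "airr")) {
  format <- match.arg(format)
  rows <- .repertoire_rows(rep)
  map <- .col_maps[[format]]
  out <- rows[, names(map)[names(map) %in% names(rows)], with = FALSE]
  setnames(out, old = names(out), new = unname(map[names(out)]))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

# Disaggregate a repertoire to writable rows. Counts cannot always be
# apportioned jointly across (nt, V, J); we emit the dominant V/J per
# clonotype alongside per-nt counts, which round-trips exactly for
# repertoires whose clonotypes carry a single V and J (the common case and
# everything the simulator emits), and preserves AA counts in general.
.repertoire_rows <- function(rep) {
  rows <- if (nrow(rep$nt_variants)) {
    copy(rep$nt_variants)
  } else {
    rep$clonotypes[, .(cdr3_aa, count = total_count)]
  }
  dom <- function(us, col) {
    if (!nrow(us)) return(invisible(NULL))
    d <- us[order(cdr3_aa, -count, gene), .(g = gene[1]), by = cdr3_aa]
    rows[d, (col) := i.g, on = "cdr3_aa"]
  }
  dom(rep$v_usage, "v_gene")
  dom(rep$j_usage, "j_gene")
  setcolorder(rows, intersect(c("cdr3_aa", "count", "v_gene", "j_gene",
                                "cdr3_nt"), names(rows)))
  rows[]
}

#' Top-N clonotypes by abundance
#'
#' Returns the `min(n, n_clonotypes)` most abundant clonotypes, ordered by
#' total count descending with ties broken by `cdr3_aa` ascending, so the
#' selection is deterministic across runs and platforms. The subset's
#' accumulated frequency (its share of the repertoire's total counts) is
#' attached as attribute `accumulated_frequency`.
#'
#' @param rep a `tcr_repertoire`.
#' @param n number of clonotypes (>= 1).
#' @return a `tcr_repertoire` restricted to the selected clonotypes.
#' @export
top_clonotypes <- function(rep, n) {
  stopifnot(n >= 1)
  clon <- rep$clonotypes[order(-total_count, cdr3_aa)]
  sel <- clon$cdr3_aa[seq_len(min(n, nrow(clon)))]
  subset_repertoire(rep, sel)
}

#' Seeded uniform random subset of clonotypes
#'
#' Samples `n` clonotypes uniformly without replacement over unique
#' amino-acid sequences (not abundance-weighted). `replicate` offsets the
#' seed so independent replicates (`seed + replicate - 1`) can be drawn.
#'
#' @param rep a `tcr_repertoire`.
#' @param n subset size; must not exceed the number of unique clonotypes.
#' @param seed integer seed.
#' @param replicate replicate index (>= 1).
#' @return a `tcr_repertoire` restricted to the sampled clonotypes.
#' @export
random_clonotypes <- function(rep, n, seed, replicate = 1L) {
  if (n > nrow(rep$clonotypes))
    stop("n exceeds the number of unique clonotypes")
  sel <- withr_seed(seed + replicate - 1L, {
    sample(sort(rep$clonotypes$cdr3_aa), n)
  })
  subset_repertoire(rep, sel)
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Restrict a repertoire to a set of clonotypes
#'
#' @param rep a `tcr_repertoire`.
#' @param seqs character vector of CDR3 AA sequences to keep.
#' @return a `tcr_repertoire`; attribute `accumulated_frequency` holds the
#'   kept share of the parent's total counts.
#' @export
subset_repertoire <- function(rep, seqs) {
  total <- sum(rep$clonotypes$total_count)
  out <- structure(list(
    individual_id = rep$individual_id,
    metadata = rep$metadata,
    clonotypes = rep$clonotypes[cdr3_aa %in% seqs][order(-total_count, cdr3_aa)],
    v_usage = rep$v_usage[cdr3_aa %in% seqs],
    j_usage = rep$j_usage[cdr3_aa %in% seqs],
    nt_variants = rep$nt_variants[cdr3_aa %in% seqs]),
    class = "tcr_repertoire")
  attr(out, "accumulated_frequency") <-
    sum(out$clonotypes$total_count) / total
  attr(out, "load_report") <- attr(rep, "load_report")
  out
}

#' Accumulated frequency of a repertoire subset
#' @param rep a subset produced by [top_clonotypes()], [random_clonotypes()]
#'   or [subset_repertoire()].
#' @export
accumulated_frequency <- function(rep) attr(rep, "accumulated_frequency")

#' Construct a cohort of repertoires
#'
#' A cohort is the named, ordered collection of individual repertoires over
#' which sharing levels are computed.
#'
#' @param repertoires list of `tcr_repertoire` with unique `individual_id`s.
#' @param name cohort name.
#' @param species species label.
#' @return an object of class `tcr_cohort`.
#' @export
cohort <- function(repertoires, name = "cohort", species = "unknown") {
  stopifnot(length(repertoires) >= 1,
            all(vapply(repertoires, inherits, TRUE, "tcr_repertoire")))
  ids <- vapply(repertoires, `[[`, "", "individual_id")
  if (anyDuplicated(ids)) stop("individual_id values must be unique in a cohort")
  names(repertoires) <- ids
  structure(list(name = name, species = species, repertoires = repertoires),
            class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  cat(sprintf("<tcr_cohort> %s (%s): %d individuals\n",
              x$name, x$species, length(x$repertoires)))
  invisible(x)
}

#' Read a directory of clonotype tables as a cohort
#'
#' @param dir directory containing one table per individual.
#' @param format `"tsv"` or `"airr"`.
#' @param pattern file-name regexp, default all `.tsv` files.
#' @param name,species passed to [cohort()].
#' @export
read_cohort <- function(dir, format = c("tsv", "airr"), pattern = "\\.tsv$",
                        name = basename(dir), species = "unknown") {
  format <- match.arg(format)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no files matching ", pattern, " in ", dir)
  cohort(lapply(files, read_repertoire, format = format),
         name = name, species = species)
}
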