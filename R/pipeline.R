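.as_cohort <- function(x, format = "tsv", name = "cohort") {
  if (inherits(x, "tcr_cohort")) return(x)
  read_cohort(x, format = format, name = name)
}

#' Per-individual network summaries for top-N vs random-N selections
#'
#' For every individual: build the similarity network of the N most
#' frequent clonotypes and of N randomly chosen clonotypes (averaged over
#' `random_reps` seeded replicates), count clustered nodes and edges, and
#' tabulate mean degree and mean betweenness as a function of
#' reference-cohort sharing level. Reproduces the figure-level tables of
#' the abundance-selection comparison.
#'
#' @param cohort a `tcr_cohort` or directory of TSVs.
#' @param reference reference cohort for sharing levels (default: the
#'   cohort itself).
#' @param n selection size (default 1000).
#' @param random_reps replicates of the random selection.
#' @param seed base seed for the random selections.
#' @param out_dir optional directory to write the tables as CSV.
#' @return list of data.tables: `network_summary` (individual, condition,
#'   replicate, clustered_nodes, edges, accumulated_frequency),
#'   `degree_by_sharing`, `betweenness_by_sharing` (individual, condition,
#'   sharing, mean value).
#' @export
run_figure1 <- function(cohort, reference = NULL, n = 1000,
                        random_reps = 10, seed = 1, out_dir = NULL) {
  cohort <- .as_cohort(cohort)
  reference <- if (is.null(reference)) cohort else .as_cohort(reference)
  sharing <- sharing_levels(reference)

  one <- function(rep_, condition, replicate) {
    sub <- if (condition == "top") top_clonotypes(rep_, n)
           else random_clonotypes(rep_, min(n, n_clonotypes(rep_)),
                                  seed = seed, replicate = replicate)
    net <- build_network(sub)
    deg <- node_degree(net)
    btw <- node_betweenness(net)
    s <- sharing$sharing[match(names(deg), sharing$cdr3_aa)]
    s[is.na(s)] <- 0L
    list(summary = data.table(
           individual = rep_$individual_id, condition = condition,
           replicate = replicate,
           clustered_nodes = clustered_node_count(net),
           edges = edge_count(net),
           accumulated_frequency = accumulated_frequency(sub)),
         by_sharing = data.table(
           individual = rep_$individual_id, condition = condition,
           replicate = replicate, sharing = s, degree = deg,
           betweenness = btw))
  }
  res <- list()
  for (rep_ in cohort$repertoires) {
    res[[length(res) + 1L]] <- one(rep_, "top", 1L)
    for (r in seq_len(random_reps))
      res[[length(res) + 1L]] <- one(rep_, "random", r)
  }
  summary <- rbindlist(lapply(res, `[[`, "summary"))
  nodes <- rbindlist(lapply(res, `[[`, "by_sharing"))
  degree_by_sharing <- nodes[, .(mean_degree = mean(degree)),
                             by = .(individual, condition, sharing)]
  betweenness_by_sharing <- nodes[, .(mean_betweenness = mean(betweenness)),
                                  by = .(individual, condition, sharing)]
  out <- list(network_summary = summary,
              degree_by_sharing = degree_by_sharing[order(condition, individual, sharing)],
              betweenness_by_sharing = betweenness_by_sharing[order(condition, individual, sharing)])
  .write_tables(out, out_dir)
  out
}

#' Cross-species sharing tables and CS-public analysis
#'
#' Computes the per-sharing-level cross-species sharing curves in both
#' directions, the CS-public sequence set under the scheme, and — from the
#' top-N network of every individual in both cohorts — the mean node
#' degree within each of the four sharing categories (CS-public, public in
#' one species only, not public).
#'
#' @param cohort_a,cohort_b the two species' cohorts (or directories).
#' @param scheme a [category_scheme()].
#' @param n selection size for the per-individual networks.
#' @param out_dir optional output directory.
#' @return list: `curve_a`, `curve_b` (sharing curves), `cs_public`
#'   (character vector), `category_degree` (individual, species, category,
#'   mean_degree, n_nodes).
#' @export
run_figure2 <- function(cohort_a, cohort_b, scheme = category_scheme(),
                        n = 1000, out_dir = NULL) {
  cohort_a <- .as_cohort(cohort_a); cohort_b <- .as_cohort(cohort_b)
  xa <- cross_species_sharing(cohort_a, cohort_b)
  xb <- cross_species_sharing(cohort_b, cohort_a)
  cs <- cs_public(cohort_a, cohort_b, scheme)
  sa <- sharing_levels(cohort_a); sb <- sharing_levels(cohort_b)
  Na <- attr(sa, "N"); Nb <- attr(sb, "N")

  cat_degree <- function(coh, species) {
    rbindlist(lapply(coh$repertoires, function(rep_) {
      net <- build_network(top_clonotypes(rep_, n))
      deg <- node_degree(net)
      s_a <- sa$sharing[match(names(deg), sa$cdr3_aa)]; s_a[is.na(s_a)] <- 0L
      s_b <- sb$sharing[match(names(deg), sb$cdr3_aa)]; s_b[is.na(s_b)] <- 0L
      data.table(individual = rep_$individual_id, species = species,
                 category = cross_species_categories(s_a, Na, s_b, Nb,
                                                     scheme),
                 degree = deg)[, .(mean_degree = mean(degree),
                                   n_nodes = .N),
                               by = .(individual, species, category)]
    }))
  }
  out <- list(curve_a = xa$fractions, curve_b = xb$fractions,
              cs_public = cs,
              shared_count = length(xa$shared),
              category_degree = rbind(cat_degree(cohort_a, cohort_a$species),
                                      cat_degree(cohort_b, cohort_b$species)))
  .write_tables(out[c("curve_a", "curve_b", "category_degree")], out_dir)
  out
}

#' Evenness vs connectivity across repertoire conditions
#'
#' For each individual of each condition cohort: the Gini coefficient of
#' its top-N clonotype abundances, the clustered-node and edge counts of
#' the top-N network, and the frequency-by-sharing-level profile of the
#' top-N subset against the reference cohort.
#'
#' @param cohorts named list of `tcr_cohort`s (conditions).
#' @param reference reference cohort for sharing (default: first
#'   condition).
#' @param n selection size (default 1000).
#' @param out_dir optional output directory.
#' @return list: `gini_vs_clustered` (condition, individual, gini,
#'   clustered_nodes, edges) and `sharing_profile` (condition, individual,
#'   sharing, frequency).
#' @export
run_figure5 <- function(cohorts, reference = NULL, n = 1000,
                        out_dir = NULL) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1)
  cohorts <- lapply(cohorts, .as_cohort)
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("condition", seq_along(cohorts))
  reference <- if (is.null(reference)) cohorts[[1]] else .as_cohort(reference)
  sharing <- sharing_levels(reference)

  rows <- list(); profs <- list()
  for (cond in names(cohorts)) for (rep_ in cohorts[[cond]]$repertoires) {
    sub <- top_clonotypes(rep_, n)
    net <- build_network(sub)
    rows[[length(rows) + 1L]] <- data.table(
      condition = cond, individual = rep_$individual_id,
      gini = repertoire_gini(sub),
      clustered_nodes = clustered_node_count(net),
      edges = edge_count(net))
    prof <- frequency_by_sharing_profile(sub, sharing)
    profs[[length(profs) + 1L]] <- data.table(
      condition = cond, individual = rep_$individual_id, prof)
  }
  out <- list(gini_vs_clustered = rbindlist(rows),
              sharing_profile = rbindlist(profs))
  .write_tables(out, out_dir)
  out
}

.write_tables <- function(tables, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    if (is.data.frame(tables[[nm]]))
      fwrite(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  invisible(out_dir)
}

# ---- command-line entry point -------------------------------------------

.cli_args <- function(args) {
  flags <- list()
  i <- 1L
  pos <- character()
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      flags[[substring(a, 3)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(cmd = if (length(pos)) pos[1] else "help", flags = flags)
}

#' Command-line interface
#'
#' Subcommands: `build-net` (TSV in, GraphML/SIF + attribute CSV out),
#' `simulate` (write a synthetic cohort as TSVs), `sharing` (score a query
#' table against one or two reference cohort directories), `gini`,
#' `fig1` / `fig2` / `fig5` (figure-level table pipelines). Invoke as
#' `Rscript -e 'tcrnet::tcrnet_cli()' -- <subcommand> --flag value ...`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return invisibly, the computed object.
#' @export
tcrnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- .cli_args(args)
  fl <- parsed$flags
  get_flag <- function(name, default = NULL) {
    if (!is.null(fl[[name]])) fl[[name]] else default
  }
  seed <- as.integer(get_flag("seed", "1"))
  out <- switch(parsed$cmd,
    "build-net" = {
      rep_ <- read_repertoire(get_flag("input"),
                              format = get_flag("format", "tsv"))
      sel <- strsplit(get_flag("select", "top:1000"), ":", fixed = TRUE)[[1]]
      sub <- if (sel[1] == "top") top_clonotypes(rep_, as.integer(sel[2]))
             else random_clonotypes(rep_, as.integer(sel[2]), seed = seed)
      net <- build_network(sub, provenance = paste(sel, collapse = ":"))
      fmt <- get_flag("export", "graphml")
      base <- get_flag("out", "network")
      export_graph(net, paste0(base, ".", fmt), format = fmt)
      write_node_attributes(net, paste0(base, "_nodes.csv"))
      message(sprintf("%d nodes, %d edges, %d clustered",
                      nrow(net$nodes), edge_count(net),
                      clustered_node_count(net)))
      net
    },
    "simulate" = {
      cf <- if (!is.null(fl$config)) read_simulation_config(fl$config)
            else default_mouse_config()
      coh <- generate_cohort(cf, as.integer(get_flag("individuals", "5")),
                             as.integer(get_flag("size", "5000")), seed)
      dir.create(get_flag("out", "sim"), recursive = TRUE,
                 showWarnings = FALSE)
      for (r in coh$repertoires)
        write_repertoire(r, file.path(get_flag("out", "sim"),
                                      paste0(r$individual_id, ".tsv")))
      message(sprintf("wrote %d repertoires to %s",
                      length(coh$repertoires), get_flag("out", "sim")))
      coh
    },
    "sharing" = {
      rep_ <- read_repertoire(get_flag("query"))
      ref <- read_cohort(get_flag("reference"))
      if (!is.null(fl$reference2)) {
        ref2 <- read_cohort(fl$reference2)
        write_sharing_table(rep_$clonotypes$cdr3_aa, ref, ref2,
                            get_flag("out", "sharing.tsv"))
      } else {
        s <- sharing_levels(ref, rep_$clonotypes$cdr3_aa)
        fwrite(s, get_flag("out", "sharing.tsv"), sep = "\t")
        s
      }
    },
    "gini" = {
      rep_ <- read_repertoire(get_flag("input"))
      g <- repertoire_gini(rep_)
      message(sprintf("gini %.6f over %d clonotypes", g,
                      n_clonotypes(rep_)))
      g
    },
    "fig1" = run_figure1(get_flag("cohort"),
                         reference = get_flag("reference"),
                         n = as.integer(get_flag("n", "1000")),
                         seed = seed, out_dir = get_flag("out", "fig1")),
    "fig2" = run_figure2(get_flag("cohort-a"), get_flag("cohort-b"),
                         n = as.integer(get_flag("n", "1000")),
                         out_dir = get_flag("out", "fig2")),
    "fig5" = {
      dirs <- strsplit(get_flag("cohorts"), ",", fixed = TRUE)[[1]]
      run_figure5(as.list(dirs),
                  reference = get_flag("reference"),
                  n = as.integer(get_flag("n", "1000")),
                  out_dir = get_flag("out", "fig5"))
    },
    {
      message("usage: tcrnet_cli(): build-net | simulate | sharing | gini | fig1 | fig2 | fig5")
      invisible(NULL)
    })
  invisible(out)
}
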