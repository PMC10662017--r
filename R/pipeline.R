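# End-to-end orchestration: parse -> min-reads -> sample filters ->
# taxon filters -> normalization -> prevalence -> associations ->
# concordance -> network, with per-phase provenance and a removal ledger.

#' Pipeline stage names, in execution order
#' @export
PIPELINE_STAGES <- c("min_reads", "load_filter", "batch_filter",
                     "statistical_filter", "literature_filter",
                     "normalize", "prevalence", "associate", "concord",
                     "network")

#' Pipeline configuration
#'
#' Inputs may be given in memory (`cohorts`: a list like the output of
#' [generate_cohort_pair()]) or as paths (`cohort_paths`: named list of
#' `list(table_prefix =, metadata =, expression =)` read with
#' [read_count_table()] and `read.delim`). Every stochastic step derives
#' its seed from `seed`.
#'
#' @param cohorts In-memory cohort list (two cohorts, discovery first).
#' @param cohort_paths On-disk alternative to `cohorts`.
#' @param filter A [filter_config()]; deny/spare lists live here.
#' @param min_read_threshold Minimum supporting reads (strict `>`).
#' @param bio_vars,adj_vars Covariates preserved/removed by normalization.
#' @param rarefy_depth `"min"` or an integer depth.
#' @param alpha Concordance significance cutoff on BH q-values.
#' @param quantile_grid Quantiles for the multi-threshold survival scan.
#' @param tail_fraction Per-tail fraction for network edge selection.
#' @param stages Character vector of enabled stages (default: all, in
#'   order); disabled stages are skipped and marked in the ledger.
#' @param seed Global seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohorts = NULL, cohort_paths = NULL,
                            filter = filter_config(),
                            min_read_threshold = 5L,
                            bio_vars = "cancer_type",
                            adj_vars = c("sequencing_site",
                                         "preservation_method"),
                            rarefy_depth = "min",
                            alpha = 0.05,
                            quantile_grid = seq(0.1, 0.9, by = 0.1),
                            tail_fraction = 0.025,
                            stages = PIPELINE_STAGES,
                            seed = 1L) {
  if (is.null(cohorts) && is.null(cohort_paths))
    stop("provide cohorts (in memory) or cohort_paths")
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(cohorts = cohorts, cohort_paths = cohort_paths,
                 filter = filter,
                 min_read_threshold = as.integer(min_read_threshold),
                 bio_vars = bio_vars, adj_vars = adj_vars,
                 rarefy_depth = rarefy_depth, alpha = alpha,
                 quantile_grid = quantile_grid,
                 tail_fraction = tail_fraction,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()] and
#' [filter_config()]; `deny_list` / `spare_list` may be file paths
#' (read with [read_taxon_list()]).
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  fc_args <- y$filter %||% list()
  for (k in c("deny_list", "spare_list")) {
    if (is.character(fc_args[[k]]) && length(fc_args[[k]]) == 1 &&
        file.exists(fc_args[[k]]))
      fc_args[[k]] <- read_taxon_list(fc_args[[k]])
  }
  fc <- do.call(filter_config, fc_args)
  args <- y[setdiff(names(y), "filter")]
  args$filter <- fc
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("cohorts"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

.write_stamped <- function(df, path, hash, seed) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.load_cohorts <- function(config) {
  if (!is.null(config$cohorts)) {
    ch <- config$cohorts
    return(ch[setdiff(names(ch), "truth")])
  }
  lapply(config$cohort_paths, function(p) {
    expr <- NULL
    if (!is.null(p$expression)) {
      e <- utils::read.delim(p$expression, check.names = FALSE)
      expr <- as.matrix(e[, -1, drop = FALSE])
      rownames(expr) <- e[[1]]
    }
    list(table = read_count_table(p$table_prefix),
         metadata = utils::read.delim(p$metadata,
                                      stringsAsFactors = FALSE),
         expression = expr)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order on each cohort, then the
#' cross-cohort concordance and network stages, writing every result as a
#' TSV whose first line embeds the configuration hash and seed. A removal
#' ledger (`removal_log.tsv`) accounts for the reads and samples lost at
#' each phase. Messages go to stderr; output files carry no timestamps so
#' identical config + seed reproduce the run directory byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @param until Last stage to execute (default: all).
#' @return Invisibly, a list with the final per-cohort state and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir, until = "network") {
  if (!until %in% PIPELINE_STAGES) stop("unknown stage: ", until)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  seed <- config$seed
  note <- function(...) message("[tumormicro] ", ...)
  stamp <- function(df, name) .write_stamped(df, file.path(out_dir, name),
                                             hash, seed)
  enabled <- config$stages
  todo <- PIPELINE_STAGES[seq_len(match(until, PIPELINE_STAGES))]
  ledger <- list()
  mark <- function(cohort, phase, status, detail = "") {
    ledger[[length(ledger) + 1]] <<- data.frame(
      cohort = cohort, phase = phase, status = status, detail = detail)
  }

  cohorts <- .load_cohorts(config)
  if (length(cohorts) < 1) stop("no cohorts to process")
  state <- list()

  for (nm in names(cohorts)) {
    ch <- cohorts[[nm]]
    tab <- ch$table
    md <- ch$metadata
    reads0 <- sum(tab$counts)

    run_stage <- function(phase) phase %in% enabled && phase %in% todo

    if (run_stage("min_reads")) {
      tab <- apply_min_reads(tab, config$min_read_threshold)
      mark(nm, "min_reads", "run",
           sprintf("reads %d -> %d", reads0, sum(tab$counts)))
    } else mark(nm, "min_reads", "skipped")

    if (run_stage("load_filter")) {
      r <- filter_microbial_load(tab, config$filter)
      tab <- r$table
      mark(nm, "load_filter", "run",
           sprintf("removed %d sample(s)", nrow(r$removed)))
    } else mark(nm, "load_filter", "skipped")

    if (run_stage("batch_filter")) {
      r <- filter_small_batches(tab, md, config$filter)
      tab <- r$table
      mark(nm, "batch_filter", "run",
           sprintf("removed %d sample(s)", nrow(r$removed)))
    } else mark(nm, "batch_filter", "skipped")

    calls <- NULL
    if (run_stage("statistical_filter") || run_stage("literature_filter")) {
      calls <- classify_contaminants(tab, md, config$filter, seed = seed)
      if (!run_stage("statistical_filter"))
        calls$flagged_statistical[] <- FALSE
      if (!run_stage("literature_filter"))
        calls$flagged_literature[] <- FALSE
      calls$final_contaminant <-
        (calls$flagged_statistical | calls$flagged_literature) &
        !calls$spared
      tab <- remove_taxa(tab, calls)
      stamp(calls, paste0("contaminant_calls_", nm, ".tsv"))
      mark(nm, "statistical_filter",
           if (run_stage("statistical_filter")) "run" else "skipped",
           sprintf("%d taxa flagged", sum(calls$flagged_statistical)))
      mark(nm, "literature_filter",
           if (run_stage("literature_filter")) "run" else "skipped",
           sprintf("%d taxa flagged, %d spared",
                   sum(calls$flagged_literature), sum(calls$spared)))
    } else {
      mark(nm, "statistical_filter", "skipped")
      mark(nm, "literature_filter", "skipped")
    }

    norm <- NULL
    if (run_stage("normalize")) {
      norm <- voom_transform(tab, md, config$bio_vars, config$adj_vars)
      norm <- snm_normalize(norm, md)
      vals <- data.frame(taxon = taxon_names(tab), norm$values,
                         check.names = FALSE)
      stamp(vals, paste0("normalized_", nm, ".tsv"))
      mark(nm, "normalize", "run")
    } else mark(nm, "normalize", "skipped")

    prev <- NULL
    if (run_stage("prevalence")) {
      rar <- rarefy(tab, config$rarefy_depth, seed = seed)
      prev <- prevalence(rar)
      pdf_ <- data.frame(taxon = taxon_names(rar),
                         prev$presence * 1L, check.names = FALSE)
      stamp(pdf_, paste0("prevalence_", nm, ".tsv"))
      mark(nm, "prevalence", "run",
           sprintf("depth %d", prev$rarefaction_depth))
    } else mark(nm, "prevalence", "skipped")

    assoc <- NULL
    if (run_stage("associate") && !is.null(prev)) {
      pv <- prev
      rownames(pv$presence) <- taxon_names(tab)[
        match(rownames(prev$presence), rownames(tab$counts))]
      assoc <- survival_associations(pv, md, cohort = nm)
      stamp(assoc, paste0("associations_", nm, ".tsv"))
      mark(nm, "associate", "run", sprintf("%d tests", nrow(assoc)))
    } else mark(nm, "associate", "skipped")

    state[[nm]] <- list(table = tab, metadata = md, norm = norm,
                        prevalence = prev, associations = assoc,
                        expression = ch$expression)
    note("cohort ", nm, ": ", nrow(tab$counts), " taxa, ",
         ncol(tab$counts), " samples retained")
  }

  concordant <- NULL
  if ("concord" %in% enabled && "concord" %in% todo &&
      length(state) >= 2 && !is.null(state[[1]]$associations)) {
    concordant <- concordance_intersect(state[[1]]$associations,
                                        state[[2]]$associations,
                                        alpha = config$alpha)
    stamp(concordant, "concordant_associations.tsv")
    mark("both", "concord", "run", sprintf("%d concordant", nrow(concordant)))
  } else mark("both", "concord", "skipped")

  if ("network" %in% enabled && "network" %in% todo &&
      length(state) >= 2 && !is.null(state[[1]]$norm) &&
      !is.null(state[[1]]$expression)) {
    logcpm <- function(m) {
      lib <- colSums(m)
      log2(sweep(m + 0.5, 2, lib + 1, "/") * 1e6)
    }
    net_state <- lapply(state[1:2], function(s) {
      micro <- s$norm$values
      rownames(micro) <- taxon_names(s$table)
      list(micro = micro, genes = logcpm(s$expression))
    })
    pa <- correlate_microbes_genes(net_state[[1]]$micro,
                                   net_state[[1]]$genes)
    pb <- correlate_microbes_genes(net_state[[2]]$micro,
                                   net_state[[2]]$genes)
    pairs <- pair_correlations(pa, pb)
    edges <- concordant_edge_select(pairs, config$tail_fraction)
    if (nrow(edges)) {
      net <- build_network(edges)
      stamp(edges, "network_edges.tsv")
      stamp(net$nodes, "network_centrality.tsv")
      mark("both", "network", "run",
           sprintf("%d edges, %d nodes", nrow(edges), nrow(net$nodes)))
    } else mark("both", "network", "run", "no concordant edges")
  } else mark("both", "network", "skipped")

  log_df <- do.call(rbind, ledger)
  stamp(log_df, "removal_log.tsv")
  invisible(list(state = state, concordant = concordant,
                 removal_log = log_df, out_dir = out_dir,
                 config_hash = hash))
}
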