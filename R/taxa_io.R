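# Taxon count tables: parsing classifier reports, rank aggregation,
# minimum-read masking, and TSV round-trip.

#' Recognized taxonomic rank ladder
#'
#' Ordered from root toward the leaves. "domain" and "kingdom" are both
#' accepted (Kraken2 uses D for domain and K for kingdom depending on the
#' database build).
#'
#' @export
TAXON_RANKS <- c("root", "domain", "kingdom", "phylum", "class", "order",
                 "family", "genus", "species", "strain")

# Kraken2 rank-code letter -> rank name. Suffixed sublevels (S1, G2, ...)
# map to the strain-ward side of their base rank.
.rank_code_map <- c(U = "unclassified", R = "root", D = "domain",
                    K = "kingdom", P = "phylum", C = "class", O = "order",
                    F = "family", G = "genus", S = "species")

.rank_from_code <- function(code) {
  base <- substr(code, 1L, 1L)
  sub <- substr(code, 2L, nchar(code))
  out <- unname(.rank_code_map[base])
  out[is.na(out)] <- "unclassified"
  # S1, S2... are strains/subspecies; other suffixed codes keep the base rank
  out[base == "S" & nzchar(sub)] <- "strain"
  out
}

#' Parse a Kraken2-style report
#'
#' Reads the standard 6-column Kraken2 report (percentage, clade reads,
#' direct reads, rank code, taxid, indented name). The indentation of the
#' name column encodes tree depth (two spaces per level) and is preserved
#' as a `depth` column so lineages can be reconstructed.
#'
#' @param path Path to a report file.
#' @return A data.frame with columns `taxid`, `name`, `rank_code`, `rank`,
#'   `clade_reads`, `direct_reads`, `depth`. Empty file gives zero rows.
#' @export
parse_kraken_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(taxid = integer(), name = character(),
                      rank_code = character(), rank = character(),
                      clade_reads = integer(), direct_reads = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- which(nf < 6L)[1L]
    stop("malformed report line ", bad, " in ", path,
         ": expected >= 6 tab-separated fields, got ", nf[bad])
  }
  clade_reads <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  direct_reads <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  taxid <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  bad <- which(is.na(clade_reads) | is.na(direct_reads) | is.na(taxid))
  if (length(bad)) {
    stop("non-integer count or taxid at report line ", bad[1L], " in ", path)
  }
  rank_code <- trimws(vapply(fields, `[[`, "", 4L))
  raw_name <- vapply(fields, `[[`, "", 6L)
  indent <- nchar(raw_name) - nchar(sub("^ +", "", raw_name))
  data.frame(taxid = taxid,
             name = sub("^ +", "", raw_name),
             rank_code = rank_code,
             rank = .rank_from_code(rank_code),
             clade_reads = clade_reads,
             direct_reads = direct_reads,
             depth = as.integer(indent %/% 2L),
             stringsAsFactors = FALSE)
}

#' Parse a Bracken abundance table
#'
#' Standard Bracken output: name, taxonomy_id, taxonomy_lvl,
#' kraken_assigned_reads, added_reads, new_est_reads, fraction_total_reads.
#'
#' @param path Path to a Bracken TSV.
#' @return data.frame with columns `taxid`, `name`, `rank_code`, `rank`,
#'   `clade_reads` (new_est_reads), `direct_reads` (kraken_assigned_reads).
#' @export
parse_bracken <- function(path) {
  if (!file.exists(path)) stop("Bracken file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "taxonomy_id", "taxonomy_lvl", "kraken_assigned_reads",
            "new_est_reads")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("Bracken file missing columns: ", paste(missing, collapse = ", "))
  }
  data.frame(taxid = as.integer(df$taxonomy_id),
             name = df$name,
             rank_code = df$taxonomy_lvl,
             rank = .rank_from_code(df$taxonomy_lvl),
             clade_reads = as.integer(df$new_est_reads),
             direct_reads = as.integer(df$kraken_assigned_reads),
             depth = NA_integer_,
             stringsAsFactors = FALSE)
}

# Reconstruct parent links from report row order + depth: the parent of a
# row is the nearest preceding row with strictly smaller depth.
.lineage_from_report <- function(report) {
  n <- nrow(report)
  parent <- rep(NA_integer_, n)
  if (n > 0L && !all(is.na(report$depth))) {
    stack <- integer(0)  # row indices of current ancestor path
    for (i in seq_len(n)) {
      d <- report$depth[i]
      while (length(stack) && report$depth[stack[length(stack)]] >= d) {
        stack <- stack[-length(stack)]
      }
      if (length(stack)) parent[i] <- report$taxid[stack[length(stack)]]
      stack <- c(stack, i)
    }
  }
  data.frame(taxid = report$taxid, name = report$name, rank = report$rank,
             parent_taxid = parent, stringsAsFactors = FALSE)
}

#' Construct a taxon count table
#'
#' @param counts Non-negative integer matrix, taxa (rownames = taxid) by
#'   samples (colnames = sample ids).
#' @param lineages data.frame with columns `taxid`, `name`, `rank`,
#'   `parent_taxid` covering at least every row taxid.
#' @param human_reads Named non-negative integer vector, one entry per
#'   sample column.
#' @return An object of class `taxon_count_table`.
#' @export
taxon_count_table <- function(counts, lineages, human_reads) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"  # counts stay integral-valued
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("counts must have taxid rownames")
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    stop("counts must have sample colnames")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample names: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (nrow(counts) > 0 && (any(counts < 0) || any(counts != round(counts))))
    stop("counts must be non-negative integers")
  miss <- setdiff(rownames(counts), as.character(lineages$taxid))
  if (length(miss))
    stop("no lineage entry for taxid(s): ", paste(miss, collapse = ", "))
  hm <- setdiff(colnames(counts), names(human_reads))
  if (length(hm))
    stop("no human_reads entry for sample(s): ", paste(hm, collapse = ", "))
  human_reads <- human_reads[colnames(counts)]
  structure(list(counts = counts,
                 lineages = lineages[!duplicated(lineages$taxid), ,
                                     drop = FALSE],
                 human_reads = human_reads),
            class = "taxon_count_table")
}

#' @export
print.taxon_count_table <- function(x, ...) {
  cat("taxon_count_table:", nrow(x$counts), "taxa x", ncol(x$counts),
      "samples\n")
  if (nrow(x$counts)) {
    rk <- table(x$lineages$rank[match(rownames(x$counts),
                                      as.character(x$lineages$taxid))])
    cat("ranks:", paste(names(rk), rk, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.taxon_count_table <- function(x) dim(x$counts)

#' Taxon names for the rows of a count table
#' @param table A `taxon_count_table`.
#' @return Character vector parallel to the rows of `table$counts`.
#' @export
taxon_names <- function(table) {
  table$lineages$name[match(rownames(table$counts),
                            as.character(table$lineages$taxid))]
}

#' Count matrix keyed by taxon name
#'
#' Convenience accessor for downstream analyses that address taxa by name
#' rather than taxid.
#'
#' @param table A `taxon_count_table`.
#' @return The counts matrix with taxon names as rownames.
#' @export
named_counts <- function(table) {
  m <- table$counts
  rownames(m) <- taxon_names(table)
  m
}

#' Assemble a count table from parsed reports
#'
#' Takes clade read counts at the requested rank from each sample's parsed
#' report (clade reads make per-rank tables self-consistent with Bracken's
#' read redistribution). Human reads are taken from the Homo sapiens entry
#' (taxid 9606) of each report unless supplied explicitly.
#'
#' @param reports Named list, sample id -> parsed report data.frame
#'   (from [parse_kraken_report()] or [parse_bracken()]).
#' @param level Rank to tabulate at (default "species").
#' @param human_reads Optional named vector overriding per-report Homo
#'   sapiens clade counts.
#' @return A [taxon_count_table()].
#' @export
build_count_table <- function(reports, level = "species",
                              human_reads = NULL) {
  if (length(reports) == 0L) stop("need at least one report")
  if (is.null(names(reports)) || any(!nzchar(names(reports))))
    stop("reports must be a named list (names = sample ids)")
  if (anyDuplicated(names(reports)))
    stop("duplicate sample names: ",
         paste(unique(names(reports)[duplicated(names(reports))]),
               collapse = ", "))
  if (!level %in% TAXON_RANKS) stop("unknown rank: ", level)

  samples <- names(reports)
  # human reads live in human_reads, not in the microbial matrix
  sel <- lapply(reports, function(r)
    r[r$rank == level & r$taxid != 9606L, , drop = FALSE])
  taxids <- unique(unlist(lapply(sel, function(r) r$taxid)))
  if (length(taxids) == 0L)
    warning("no taxa at rank '", level, "'; returning empty table")
  counts <- matrix(0, nrow = length(taxids), ncol = length(samples),
                   dimnames = list(as.character(taxids), samples))
  for (s in samples) {
    r <- sel[[s]]
    if (nrow(r)) counts[as.character(r$taxid), s] <- r$clade_reads
  }
  lineages <- do.call(rbind, lapply(reports, .lineage_from_report))
  lineages <- lineages[!duplicated(lineages$taxid), , drop = FALSE]
  if (length(taxids)) {
    # ensure every tabulated taxid has a lineage row even if depth was absent
    miss <- setdiff(as.character(taxids), as.character(lineages$taxid))
    if (length(miss)) {
      add <- do.call(rbind, lapply(reports, function(r) {
        r[as.character(r$taxid) %in% miss,
          c("taxid", "name", "rank"), drop = FALSE]
      }))
      add <- add[!duplicated(add$taxid), , drop = FALSE]
      add$parent_taxid <- NA_integer_
      lineages <- rbind(lineages, add)
    }
  }
  hr <- vapply(reports, function(r) {
    h <- r$clade_reads[r$taxid == 9606L]
    if (length(h)) as.numeric(h[1L]) else NA_real_
  }, numeric(1))
  if (!is.null(human_reads)) {
    hr[names(human_reads)] <- human_reads
  }
  if (anyNA(hr))
    stop("no Homo sapiens (taxid 9606) entry and no human_reads supplied ",
         "for sample(s): ", paste(samples[is.na(hr)], collapse = ", "))
  taxon_count_table(counts, lineages, hr)
}

# Walk parent links to the ancestor of `taxid` at `target_rank`;
# NA if none before the root.
.ancestor_at_rank <- function(taxid, target_rank, lineages) {
  idx <- match(taxid, lineages$taxid)
  seen <- 0L
  while (!is.na(idx)) {
    if (identical(lineages$rank[idx], target_rank)) return(lineages$taxid[idx])
    idx <- match(lineages$parent_taxid[idx], lineages$taxid)
    seen <- seen + 1L
    if (seen > nrow(lineages)) stop("lineage cycle detected at taxid ", taxid)
  }
  NA_integer_
}

#' Aggregate a count table to a coarser taxonomic rank
#'
#' Sums the counts of all descendant rows into their ancestor at
#' `target_rank`. Rows with no ancestor at that rank are routed to an
#' explicit "unclassified-at-rank" row rather than dropped, so per-sample
#' totals are conserved exactly.
#'
#' @param table A `taxon_count_table`.
#' @param target_rank Rank name from [TAXON_RANKS].
#' @return A `taxon_count_table` whose rows are taxa at `target_rank`
#'   (plus possibly the unclassified row, taxid `-1`).
#' @export
aggregate_lineage <- function(table, target_rank) {
  if (!target_rank %in% TAXON_RANKS) stop("unknown rank: ", target_rank)
  lin <- table$lineages
  anc <- vapply(as.integer(rownames(table$counts)),
                .ancestor_at_rank, integer(1),
                target_rank = target_rank, lineages = lin)
  key <- ifelse(is.na(anc), -1L, anc)
  agg <- rowsum(table$counts, group = key, reorder = TRUE)
  new_lin <- lin[lin$taxid %in% key, , drop = FALSE]
  if (any(key == -1L)) {
    new_lin <- rbind(new_lin,
                     data.frame(taxid = -1L,
                                name = paste0("unclassified-at-", target_rank),
                                rank = target_rank,
                                parent_taxid = NA_integer_))
  }
  # keep full ancestry so further aggregation still works
  new_lin <- rbind(new_lin, lin[!lin$taxid %in% new_lin$taxid, , drop = FALSE])
  out <- taxon_count_table(agg, new_lin, table$human_reads)
  out
}

#' Minimum supporting-read inclusion rule
#'
#' Entries with `count <= threshold` are set to zero (the inclusion rule is
#' a strict "greater than"); rows left all-zero are removed. By default the
#' rule is applied per (taxon, sample) entry; `scope = "taxon_total"`
#' instead drops whole taxa whose cohort-wide total fails the rule.
#'
#' @param table A `taxon_count_table`.
#' @param threshold Minimum supporting reads (default 5; strict `>`).
#' @param scope `"entry"` (default) or `"taxon_total"`.
#' @return Filtered `taxon_count_table`.
#' @export
apply_min_reads <- function(table, threshold = 5L,
                            scope = c("entry", "taxon_total")) {
  scope <- match.arg(scope)
  stopifnot(threshold >= 0)
  counts <- table$counts
  if (scope == "entry") {
    counts[counts <= threshold] <- 0
  } else {
    counts[rowSums(counts) <= threshold, ] <- 0
  }
  keep <- rowSums(counts) > 0
  taxon_count_table(counts[keep, , drop = FALSE], table$lineages,
                    table$human_reads)
}

#' Write a count table as TSV files
#'
#' Writes `<prefix>_counts.tsv` (taxid rows x sample columns),
#' `<prefix>_lineage.tsv`, and `<prefix>_samples.tsv` (human read counts).
#'
#' @param table A `taxon_count_table`.
#' @param prefix Path prefix for the three files.
#' @return `prefix`, invisibly.
#' @export
write_count_table <- function(table, prefix) {
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  cdf <- data.frame(taxid = rownames(table$counts), table$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, paste0(prefix, "_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(table$lineages, paste0(prefix, "_lineage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  sdf <- data.frame(sample = names(table$human_reads),
                    human_reads = as.numeric(table$human_reads))
  utils::write.table(sdf, paste0(prefix, "_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(prefix)
}

#' Read a count table written by [write_count_table()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `taxon_count_table` identical to the one written.
#' @export
read_count_table <- function(prefix) {
  cf <- paste0(prefix, "_counts.tsv")
  if (!file.exists(cf)) stop("missing file: ", cf)
  cdf <- utils::read.delim(cf, check.names = FALSE, stringsAsFactors = FALSE,
                           encoding = "UTF-8")
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- as.character(cdf$taxid)
  lineages <- utils::read.delim(paste0(prefix, "_lineage.tsv"),
                                stringsAsFactors = FALSE, encoding = "UTF-8",
                                quote = "")
  sdf <- utils::read.delim(paste0(prefix, "_samples.tsv"),
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  hr <- stats::setNames(sdf$human_reads, sdf$sample)
  if (nrow(counts) == 0 && ncol(counts) == 0) {
    counts <- matrix(0, 0, nrow(sdf),
                     dimnames = list(character(0), sdf$sample))
  }
  taxon_count_table(counts, lineages, hr)
}
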