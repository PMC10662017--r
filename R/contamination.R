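# Four-phase contaminant removal: microbial-load sample filter, small-batch
# sample filter, frequency-based statistical taxon filter, and literature
# deny/spare lists.

#' Contaminant-filter configuration
#'
#' @param max_load_ratio Samples whose total microbial reads exceed this
#'   fraction of their human reads are discarded (default 0.20, strict `>`).
#' @param min_batch_size Batches with fewer samples than this are removed
#'   (default 10; "fewer than" so exactly 10 is kept).
#' @param batch_fields Metadata columns whose value tuple defines a batch.
#' @param contaminant_p_threshold Screening p-value for the frequency test
#'   (default 0.10, the cited tool's default; no multiplicity correction —
#'   this is a screen, not an inference).
#' @param deny_list Character vector of taxon names flagged as common
#'   sequencing contaminants.
#' @param spare_list Character vector of taxon names with literature
#'   precedence as commensals; sparing overrides denial and the statistical
#'   flag.
#' @param n_permutations Permutations for the frequency test.
#' @param match_rank `"species"` for exact name matching only, or
#'   `"genus_prefix"` to also match the leading (genus) word of a name.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_load_ratio = 0.20,
                          min_batch_size = 10L,
                          batch_fields = c("sequencing_site",
                                           "preservation_method",
                                           "flow_cell"),
                          contaminant_p_threshold = 0.10,
                          deny_list = character(),
                          spare_list = character(),
                          n_permutations = 1000L,
                          match_rank = c("species", "genus_prefix")) {
  stopifnot(max_load_ratio > 0, min_batch_size >= 1,
            contaminant_p_threshold > 0, contaminant_p_threshold < 1)
  structure(list(max_load_ratio = max_load_ratio,
                 min_batch_size = as.integer(min_batch_size),
                 batch_fields = batch_fields,
                 contaminant_p_threshold = contaminant_p_threshold,
                 deny_list = deny_list,
                 spare_list = spare_list,
                 n_permutations = as.integer(n_permutations),
                 match_rank = match.arg(match_rank)),
            class = "filter_config")
}

#' Read a deny/spare taxon list
#'
#' One taxon name per line; `#` starts a comment; blank lines ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of taxon names.
#' @export
read_taxon_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Microbial-load sample filter
#'
#' Discards samples whose total microbial read count exceeds
#' `max_load_ratio` of their human-aligned reads; such samples are extreme
#' outliers most consistent with heavy contamination or failed host
#' depletion.
#'
#' @param table A `taxon_count_table` with positive `human_reads`.
#' @param config A [filter_config()].
#' @return List with `table` (surviving samples, column order preserved)
#'   and `removed` (data.frame of sample, ratio).
#' @export
filter_microbial_load <- function(table, config = filter_config()) {
  hr <- table$human_reads
  if (any(hr <= 0)) {
    stop("human_reads must be > 0 (ratio undefined) for sample(s): ",
         paste(names(hr)[hr <= 0], collapse = ", "))
  }
  load <- colSums(table$counts)
  ratio <- load / hr
  drop <- ratio > config$max_load_ratio
  removed <- data.frame(sample = names(ratio)[drop],
                        ratio = unname(ratio[drop]))
  keep <- !drop
  list(table = taxon_count_table(table$counts[, keep, drop = FALSE],
                                 table$lineages, hr[keep]),
       removed = removed)
}

#' Small-batch sample filter
#'
#' Groups samples into batches by the tuple of `batch_fields` values and
#' removes every sample in a batch smaller than `min_batch_size`; small
#' batches preclude reliable within-batch contaminant checks.
#'
#' @param table A `taxon_count_table`.
#' @param metadata data.frame with a `sample` column and the batch fields.
#' @param config A [filter_config()].
#' @return List with `table` and `removed` (data.frame sample, batch, size).
#' @export
filter_small_batches <- function(table, metadata, config = filter_config()) {
  miss <- setdiff(config$batch_fields, names(metadata))
  if (length(miss))
    stop("metadata missing batch field(s): ", paste(miss, collapse = ", "))
  samples <- colnames(table$counts)
  md <- metadata[match(samples, metadata$sample), , drop = FALSE]
  if (anyNA(md$sample))
    stop("metadata missing sample(s): ",
         paste(samples[is.na(md$sample)], collapse = ", "))
  vals <- md[, config$batch_fields, drop = FALSE]
  if (anyNA(vals) || any(vals == "", na.rm = TRUE)) {
    warning("missing batch field values; affected samples grouped under ",
            "an explicit 'missing' batch key")
    vals[is.na(vals) | vals == ""] <- "missing"
  }
  key <- do.call(paste, c(vals, sep = "|"))
  sz <- table(key)
  drop <- sz[key] < config$min_batch_size
  removed <- data.frame(sample = samples[drop], batch = key[drop],
                        size = as.integer(sz[key][drop]))
  keep <- !drop
  list(table = taxon_count_table(table$counts[, keep, drop = FALSE],
                                 table$lineages, table$human_reads[keep]),
       removed = removed)
}

#' Frequency-based contaminant test for one taxon
#'
#' Reagent contaminants contribute a roughly fixed mass of nucleic acid, so
#' their relative abundance scales inversely with input concentration. On
#' log(abundance) vs log(concentration) over samples where both are
#' positive, two fixed-slope least-squares models are compared: the
#' contaminant model (slope -1, free intercept) and the non-contaminant
#' model (slope 0, free intercept). The statistic
#' `lambda = SS1 / (SS1 + SS0)` is referred to its permutation distribution
#' (concentration labels permuted); the p-value is the fraction of
#' permutations in which the contaminant model fits at least as well as
#' observed.
#'
#' @param abundance Per-sample relative abundance of one taxon.
#' @param concentration Per-sample input RNA concentration.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed for the permutation draw.
#' @return Two-sided tail probability, or `NA` when fewer than 5 samples
#'   have both values positive, or when concentration is constant.
#' @export
frequency_contaminant_test <- function(abundance, concentration,
                                       n_permutations = 1000L, seed = 1L) {
  ok <- !is.na(abundance) & !is.na(concentration) &
    abundance > 0 & concentration > 0
  if (sum(ok) < 5L) return(NA_real_)
  y <- log(abundance[ok])
  x <- log(concentration[ok])
  if (length(unique(x)) < 2L) return(NA_real_)
  ssc <- function(v) sum((v - mean(v))^2)
  ss0 <- ssc(y)                 # slope 0: residuals after centering y
  lam_obs <- ssc(y + x) / (ssc(y + x) + ss0)  # slope -1 residual = y + x
  set.seed(seed)
  n <- length(x)
  idx <- vapply(seq_len(n_permutations), function(i) sample.int(n),
                integer(n))
  z <- y + matrix(x[idx], nrow = n)   # permuted-slope(-1) residual vectors
  ss1 <- colSums(z^2) - colSums(z)^2 / n
  perm <- ss1 / (ss1 + ss0)
  # smaller lambda = contaminant model fits better
  (sum(perm <= lam_obs) + 1) / (n_permutations + 1)
}

.match_taxon_list <- function(names, lineage_names, list_names,
                              genus_prefix = FALSE) {
  ln <- tolower(list_names)
  hit <- tolower(names) %in% ln
  if (genus_prefix) {
    genus <- tolower(sub(" .*$", "", names))
    hit <- hit | genus %in% ln
  }
  # match against any ancestor name in the lineage chain
  if (!is.null(lineage_names)) {
    hit <- hit | vapply(lineage_names, function(ch) {
      any(tolower(ch) %in% ln)
    }, logical(1))
  }
  hit
}

# full chain of ancestor names for each row taxid
.lineage_name_chains <- function(table) {
  lin <- table$lineages
  lapply(as.integer(rownames(table$counts)), function(tid) {
    out <- character(0)
    idx <- match(tid, lin$taxid)
    steps <- 0L
    while (!is.na(idx) && steps <= nrow(lin)) {
      out <- c(out, lin$name[idx])
      idx <- match(lin$parent_taxid[idx], lin$taxid)
      steps <- steps + 1L
    }
    out
  })
}

#' Classify taxa as contaminants
#'
#' Combines the frequency-based statistical flag (p below the screening
#' threshold) with literature deny/spare lists. A taxon is a final
#' contaminant when it is flagged statistically or by the deny list and is
#' not on the spare list. When `cohort_col` is given the statistical test
#' is run separately within each cohort and a taxon is flagged if it
#' screens positive in any cohort (the reported p is the minimum across
#' cohorts).
#'
#' @param table Species-level `taxon_count_table`.
#' @param metadata data.frame with `sample` and `concentration` columns
#'   (input RNA concentration), plus the cohort column if used.
#' @param config A [filter_config()].
#' @param cohort_col Optional metadata column naming the cohort of each
#'   sample.
#' @param seed Seed for the permutation test.
#' @return data.frame with columns `taxid`, `name`, `p_value`,
#'   `flagged_statistical`, `flagged_literature`, `spared`,
#'   `final_contaminant`.
#' @export
classify_contaminants <- function(table, metadata, config = filter_config(),
                                  cohort_col = NULL, seed = 1L) {
  if (!"concentration" %in% names(metadata))
    stop("metadata must contain a 'concentration' column")
  samples <- colnames(table$counts)
  md <- metadata[match(samples, metadata$sample), , drop = FALSE]
  rel <- relative_abundance(table, include_human = FALSE)
  groups <- if (is.null(cohort_col)) list(all = samples) else
    split(samples, md[[cohort_col]])

  ntax <- nrow(table$counts)
  pmat <- matrix(NA_real_, ntax, length(groups))
  for (g in seq_along(groups)) {
    idx <- match(groups[[g]], samples)
    conc <- md$concentration[idx]
    for (i in seq_len(ntax)) {
      pmat[i, g] <- frequency_contaminant_test(
        rel[i, idx], conc, n_permutations = config$n_permutations,
        seed = seed + i)
    }
  }
  p <- apply(pmat, 1, function(v) if (all(is.na(v))) NA_real_ else
    min(v, na.rm = TRUE))
  flagged_stat <- !is.na(p) & p < config$contaminant_p_threshold

  nm <- taxon_names(table)
  chains <- .lineage_name_chains(table)
  gp <- config$match_rank == "genus_prefix"
  flagged_lit <- .match_taxon_list(nm, chains, config$deny_list,
                                   genus_prefix = gp)
  spared <- .match_taxon_list(nm, chains, config$spare_list,
                              genus_prefix = gp)
  data.frame(taxid = as.integer(rownames(table$counts)),
             name = nm,
             p_value = p,
             flagged_statistical = flagged_stat,
             flagged_literature = flagged_lit,
             spared = spared,
             final_contaminant = (flagged_stat | flagged_lit) & !spared,
             stringsAsFactors = FALSE)
}

#' Remove contaminant taxa from a count table
#'
#' @param table A `taxon_count_table`.
#' @param calls data.frame from [classify_contaminants()] (only
#'   `taxid` and `final_contaminant` are used).
#' @return `taxon_count_table` with contaminant rows removed; all other
#'   entries untouched.
#' @export
remove_taxa <- function(table, calls) {
  bad <- as.character(calls$taxid[calls$final_contaminant])
  keep <- !rownames(table$counts) %in% bad
  if (!any(keep)) warning("all taxa flagged as contaminants; empty table")
  taxon_count_table(table$counts[keep, , drop = FALSE], table$lineages,
                    table$human_reads)
}
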