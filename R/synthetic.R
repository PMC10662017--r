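# Fully synthetic cohorts — taxon counts, metadata, expression, survival —
# with planted contamination, batch, survival, and microbe-gene correlation
# structure, so every downstream stage runs offline with known truth.

#' Specification for a synthetic cohort
#'
#' Defaults describe a mid-sized tumor RNA-seq cohort: 100 samples,
#' 200 detectable taxa with negative-binomial counts (dispersion 0.5),
#' 30 reagent-style contaminants whose expected relative abundance scales
#' as 1/concentration with 10% lognormal noise, a 2-fold-per-unit (log2
#' shift 2.0) technical batch effect on half the taxa in FFPE samples, and
#' administrative censoring tuned to roughly 40% observed deaths.
#'
#' @param n_samples Samples per cohort.
#' @param n_taxa Number of microbial taxa.
#' @param n_genes Number of genes in the expression matrix.
#' @param n_contaminants Taxa planted as 1/concentration contaminants.
#' @param contaminant_cv Lognormal noise CV on contaminant abundance.
#' @param batch_effect_size Log2 shift applied to `batch_taxa_fraction` of
#'   taxa in FFPE-preserved samples (the planted technical effect).
#' @param batch_taxa_fraction Fraction of taxa carrying the batch shift.
#' @param bio_effect_size Log2 shift applied to a recorded taxon subset in
#'   the first cancer type (the planted biological effect to preserve).
#' @param bio_taxa_fraction Fraction of taxa carrying the biology shift.
#' @param planted_survival_taxa Named numeric vector: taxon name ->
#'   true log hazard ratio of presence (empty by default).
#' @param planted_hub List `list(n_genes =, rho =)` or `NULL`: one microbe
#'   truly correlated with `n_genes` genes at Spearman ~`rho`.
#' @param cancer_types,cancer_props Cancer-type labels and mixing
#'   proportions.
#' @param concentration_meanlog,concentration_sdlog Lognormal parameters
#'   of input RNA concentration.
#' @param nb_dispersion Negative-binomial dispersion of baseline counts.
#' @param baseline_mu_meanlog Mean of log baseline per-taxon expected
#'   count.
#' @param censor_horizon Administrative censoring time, days.
#' @param baseline_hazard Per-day exponential event rate at presence = 0.
#' @param seed Integer seed recorded in every output.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_samples = 100L, n_taxa = 200L, n_genes = 200L,
                         n_contaminants = 30L, contaminant_cv = 0.10,
                         batch_effect_size = 2.0,
                         batch_taxa_fraction = 0.5,
                         bio_effect_size = 1.0,
                         bio_taxa_fraction = 0.25,
                         planted_survival_taxa = numeric(),
                         planted_hub = NULL,
                         cancer_types = c("LUAD", "SARC", "COAD"),
                         cancer_props = c(0.4, 0.35, 0.25),
                         concentration_meanlog = log(10),
                         concentration_sdlog = 0.8,
                         nb_dispersion = 0.5,
                         baseline_mu_meanlog = log(20),
                         censor_horizon = 1825,
                         baseline_hazard = 0.51 / 1825,
                         seed = 1L) {
  if (n_contaminants > n_taxa)
    stop("more contaminants than taxa")
  stopifnot(length(cancer_types) == length(cancer_props),
            abs(sum(cancer_props) - 1) < 1e-8)
  structure(as.list(environment()), class = "fixture_spec")
}

# deterministic planted structure shared by both cohorts of a pair:
# derived only from the fixture_spec (not the per-cohort noise seed)
.planted_truth <- function(spec) {
  taxa <- paste0("taxon_", seq_len(spec$n_taxa))
  genes <- paste0("gene_", seq_len(spec$n_genes))
  contam <- if (spec$n_contaminants > 0)
    taxa[seq_len(spec$n_contaminants)] else character()
  free <- setdiff(taxa, c(contam, names(spec$planted_survival_taxa)))
  n_batch <- round(spec$batch_taxa_fraction * spec$n_taxa)
  batch_taxa <- free[seq_len(min(n_batch, length(free)))]
  n_bio <- round(spec$bio_taxa_fraction * spec$n_taxa)
  bio_taxa <- rev(free)[seq_len(min(n_bio, length(free)))]
  hub <- NULL
  if (!is.null(spec$planted_hub)) {
    hub_taxon <- setdiff(free, c(batch_taxa, bio_taxa))
    hub_taxon <- if (length(hub_taxon)) hub_taxon[1] else free[1]
    hub <- list(microbe = hub_taxon,
                genes = genes[seq_len(min(spec$planted_hub$n_genes,
                                          spec$n_genes))],
                rho = spec$planted_hub$rho)
  }
  surv <- spec$planted_survival_taxa
  if (length(surv) && is.null(names(surv)))
    names(surv) <- taxa[spec$n_taxa - seq_along(surv) + 1L]
  list(taxa = taxa, genes = genes, contaminants = contam,
       batch_taxa = batch_taxa, bio_taxa = bio_taxa,
       survival = surv, hub = hub)
}

# synthetic lineage: species grouped into 20 genera under one domain
.synthetic_lineages <- function(taxa) {
  n <- length(taxa)
  genus_of <- ((seq_len(n) - 1L) %% 20L) + 1L
  sp <- data.frame(taxid = 1000L + seq_len(n),
                   name = taxa,
                   rank = "species",
                   parent_taxid = 100L + genus_of)
  gn <- data.frame(taxid = 100L + seq_len(20L),
                   name = paste0("Genus", seq_len(20L)),
                   rank = "genus", parent_taxid = 2L)
  top <- data.frame(taxid = c(1L, 2L, 3L, 9606L),
                    name = c("root", "Bacteria", "Eukaryota",
                             "Homo sapiens"),
                    rank = c("root", "domain", "domain", "species"),
                    parent_taxid = c(NA_integer_, 1L, 1L, 3L))
  rbind(top, gn, sp)
}

#' Generate one synthetic cohort
#'
#' @param spec A [fixture_spec()].
#' @param cohort Cohort label (also the sequencing-site value, so the
#'   cohort label is usable as an SNM technical variable).
#' @param seed Noise seed for this cohort (defaults to `spec$seed`); the
#'   planted truth depends only on `spec`, so two cohorts with different
#'   seeds share truth but not noise.
#' @return List with `table` (a `taxon_count_table` keyed by taxon name),
#'   `metadata`, `expression` (genes x samples counts), `truth`
#'   (data.frame ledger of every planted parameter).
#' @export
generate_cohort <- function(spec, cohort = "A", seed = spec$seed) {
  set.seed(seed)
  tr <- .planted_truth(spec)
  n <- spec$n_samples
  samples <- paste0(cohort, "_s", seq_len(n))

  md <- data.frame(
    sample = samples,
    cohort = cohort,
    cancer_type = sample(spec$cancer_types, n, replace = TRUE,
                         prob = spec$cancer_props),
    sequencing_site = paste0("site_", cohort),
    preservation_method = sample(c("FF", "FFPE"), n, replace = TRUE,
                                 prob = c(0.75, 0.25)),
    flow_cell = sample(paste0("FC", 1:3), n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)),
    concentration = stats::rlnorm(n, spec$concentration_meanlog,
                                  spec$concentration_sdlog),
    human_reads = round(stats::rlnorm(n, log(5e6), 0.3)),
    age_at_collection = round(stats::rnorm(n, 62, 10)),
    bmi = round(stats::rnorm(n, 27, 5), 1),
    stringsAsFactors = FALSE)

  # expected counts: baseline lognormal per taxon, constant across samples
  mu_t <- stats::rlnorm(spec$n_taxa, spec$baseline_mu_meanlog, 1)
  names(mu_t) <- tr$taxa
  mu <- matrix(mu_t, spec$n_taxa, n,
               dimnames = list(tr$taxa, samples))
  size <- 1 / spec$nb_dispersion
  # technical batch shift (FFPE samples, batch taxa) and biological shift
  ffpe <- md$preservation_method == "FFPE"
  mu[tr$batch_taxa, ffpe] <- mu[tr$batch_taxa, ffpe] *
    2^spec$batch_effect_size
  bio_grp <- md$cancer_type == spec$cancer_types[1]
  mu[tr$bio_taxa, bio_grp] <- mu[tr$bio_taxa, bio_grp] *
    2^spec$bio_effect_size
  # hub microbe rides a latent lognormal factor the hub genes share
  z <- stats::rnorm(n)
  if (!is.null(tr$hub)) mu[tr$hub$microbe, ] <- mu_t[tr$hub$microbe] * 10 *
      exp(z)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                   spec$n_taxa, n, dimnames = dimnames(mu))
  # planted survival taxa: explicit ~50% presence, and when present the
  # counts are well supported so the presence call survives minimum-read
  # masking and rarefaction downstream
  if (length(tr$survival)) {
    for (tx in names(tr$survival)) {
      here <- stats::runif(n) < 0.5
      counts[tx, ] <- ifelse(here,
                             6L + stats::rnbinom(n, mu = 25, size = size),
                             0L)
    }
  }
  # contaminants: expected relative abundance proportional to
  # 1/concentration, lognormal noise of the requested CV, Poisson counts
  if (length(tr$contaminants)) {
    k <- mu_t[tr$contaminants] * exp(spec$concentration_meanlog)
    cmu <- outer(k, 1 / md$concentration) *
      matrix(stats::rlnorm(length(k) * n, 0, spec$contaminant_cv),
             length(k), n)
    counts[tr$contaminants, ] <- stats::rpois(length(cmu), cmu)
  }

  table <- taxon_count_table(
    `rownames<-`(counts, as.character(1000L + seq_len(spec$n_taxa))),
    .synthetic_lineages(tr$taxa),
    stats::setNames(md$human_reads, samples))

  # survival: exponential times, hazard scaled by planted presences,
  # administrative censoring at the horizon
  lp <- rep(0, n)
  if (length(tr$survival)) {
    for (tx in names(tr$survival)) {
      lp <- lp + tr$survival[[tx]] * (counts[tx, ] > 0)
    }
  }
  t_event <- stats::rexp(n, rate = spec$baseline_hazard * exp(lp))
  md$os_days <- round(pmin(t_event, spec$censor_horizon))
  md$os_event <- t_event <= spec$censor_horizon

  # expression: NB counts; hub genes share the hub's latent factor
  mu_g <- stats::rlnorm(spec$n_genes, log(500), 1)
  logmu <- matrix(log(mu_g), spec$n_genes, n,
                  dimnames = list(tr$genes, samples))
  if (!is.null(tr$hub)) {
    rho <- tr$hub$rho
    b <- rho / sqrt(1 - rho^2)
    eg <- matrix(stats::rnorm(length(tr$hub$genes) * n), ncol = n)
    logmu[tr$hub$genes, ] <- logmu[tr$hub$genes, ] +
      0.8 * (b * matrix(z, length(tr$hub$genes), n, byrow = TRUE) + eg)
  }
  expression <- matrix(stats::rnbinom(length(logmu), mu = exp(logmu),
                                      size = 5),
                       spec$n_genes, n, dimnames = dimnames(logmu))

  truth <- rbind(
    if (length(tr$contaminants))
      data.frame(kind = "contaminant", unit = tr$contaminants,
                 value = NA_real_),
    if (length(tr$batch_taxa))
      data.frame(kind = "batch_taxon", unit = tr$batch_taxa,
                 value = spec$batch_effect_size),
    if (length(tr$bio_taxa))
      data.frame(kind = "bio_taxon", unit = tr$bio_taxa,
                 value = spec$bio_effect_size),
    if (length(tr$survival))
      data.frame(kind = "survival_taxon", unit = names(tr$survival),
                 value = unname(tr$survival)),
    if (!is.null(tr$hub))
      rbind(data.frame(kind = "hub_microbe", unit = tr$hub$microbe,
                       value = tr$hub$rho),
            data.frame(kind = "hub_gene", unit = tr$hub$genes,
                       value = tr$hub$rho)),
    data.frame(kind = "seed", unit = cohort, value = seed))

  list(table = table, metadata = md, expression = expression, truth = truth)
}

#' Generate a discovery/validation cohort pair
#'
#' Two cohorts with independent noise but identical planted truth,
#' mirroring a two-dataset design where the cohort label doubles as the
#' sequencing-site technical variable.
#'
#' @param spec A [fixture_spec()].
#' @param labels Two cohort labels.
#' @return List with elements named by `labels` (each as in
#'   [generate_cohort()]) plus `truth`.
#' @export
generate_cohort_pair <- function(spec, labels = c("A", "B")) {
  stopifnot(length(labels) == 2)
  a <- generate_cohort(spec, cohort = labels[1], seed = spec$seed * 2L + 1L)
  b <- generate_cohort(spec, cohort = labels[2], seed = spec$seed * 2L + 2L)
  out <- stats::setNames(list(a, b), labels)
  out$truth <- a$truth[a$truth$kind != "seed", , drop = FALSE]
  out
}

#' Write a count table as per-sample synthetic Kraken2-format reports
#'
#' Emits one standard 6-column report per sample (root/domain/genus/
#' species hierarchy with clade-read totals and human reads under Homo
#' sapiens) so the parser and table builder can be exercised end to end
#' on generated data. Zero-count taxa are omitted per sample, as a real
#' classifier report would.
#'
#' @param table A `taxon_count_table` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named vector of written file paths.
#' @export
write_kraken_reports <- function(table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lin <- table$lineages
  sp <- lin[match(as.integer(rownames(table$counts)), lin$taxid), ,
            drop = FALSE]
  if (anyNA(sp$taxid)) stop("count rows must be keyed by taxid")
  paths <- character(0)
  for (s in colnames(table$counts)) {
    cnt <- table$counts[, s]
    keep <- cnt > 0
    hr <- table$human_reads[[s]]
    lines <- character(0)
    fmt <- function(pct, clade, direct, code, taxid, depth, name) {
      sprintf("%6.2f\t%d\t%d\t%s\t%d\t%s%s", pct, clade, direct, code,
              taxid, strrep("  ", depth), name)
    }
    total <- sum(cnt[keep]) + hr
    lines <- c(lines, fmt(100, as.integer(total), 0L, "R", 1L, 0L, "root"))
    # human branch
    lines <- c(lines, fmt(100 * hr / total, as.integer(hr), 0L, "D", 3L,
                          1L, "Eukaryota"),
               fmt(100 * hr / total, as.integer(hr), as.integer(hr), "S",
                   9606L, 2L, "Homo sapiens"))
    bact <- sum(cnt[keep])
    lines <- c(lines, fmt(100 * bact / total, as.integer(bact), 0L, "D",
                          2L, 1L, "Bacteria"))
    for (g in sort(unique(sp$parent_taxid[keep]))) {
      gi <- lin[match(g, lin$taxid), ]
      in_g <- keep & sp$parent_taxid == g
      gc <- sum(cnt[in_g])
      lines <- c(lines, fmt(100 * gc / total, as.integer(gc), 0L, "G",
                            gi$taxid, 2L, gi$name))
      for (i in which(in_g)) {
        lines <- c(lines, fmt(100 * cnt[i] / total, as.integer(cnt[i]),
                              as.integer(cnt[i]), "S", sp$taxid[i], 3L,
                              sp$name[i]))
      }
    }
    path <- file.path(dir, paste0(s, ".kreport"))
    writeLines(lines, path)
    paths[s] <- path
  }
  paths
}
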