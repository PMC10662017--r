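# Concordant microbe-gene bipartite networks: all-pairs Spearman
# correlation, concordance + extreme-tail edge selection, centralities,
# the random-matrix null, degree-distribution diagnostics, and preranked
# pathway enrichment.

# Column-wise midranks, then Pearson on ranks = Spearman; one matrix
# multiply gives all microbe x gene correlations at once.
.rank_scale <- function(m) {
  r <- apply(m, 1, rank)           # samples x features, midranks
  r <- scale(r)                    # center + unit SD per feature
  r
}

#' All-pairs Spearman correlation of microbes against genes
#'
#' One rho and t-approximation p per (microbe, gene) pair over the shared
#' samples, with average ranks for ties (identical to [spearman_assoc()]
#' pair by pair, computed in bulk).
#'
#' @param micro Real microbes x samples matrix (normalized abundance).
#' @param genes Real genes x samples matrix (expression).
#' @return data.frame `microbe`, `gene`, `rho`, `p` over all pairs.
#' @export
correlate_microbes_genes <- function(micro, genes) {
  shared <- intersect(colnames(micro), colnames(genes))
  if (length(shared) < 4L) stop("need at least 4 shared samples")
  n <- length(shared)
  rm_ <- .rank_scale(micro[, shared, drop = FALSE])
  rg <- .rank_scale(genes[, shared, drop = FALSE])
  rho <- crossprod(rm_, rg) / (n - 1)    # microbes x genes
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  data.frame(microbe = rep(rownames(micro), times = nrow(genes)),
             gene = rep(rownames(genes), each = nrow(micro)),
             rho = as.vector(rho), p = as.vector(p),
             stringsAsFactors = FALSE)
}

#' Pair up discovery and validation correlations
#'
#' @param pairs_a,pairs_b Outputs of [correlate_microbes_genes()] for the
#'   discovery and validation cohorts.
#' @return data.frame `microbe`, `gene`, `rho_a`, `p_a`, `rho_b`, `p_b`,
#'   `concordant` (same non-zero sign in both, neither missing).
#' @export
pair_correlations <- function(pairs_a, pairs_b) {
  m <- merge(pairs_a, pairs_b, by = c("microbe", "gene"),
             suffixes = c("_a", "_b"))
  m$concordant <- !is.na(m$rho_a) & !is.na(m$rho_b) &
    sign(m$rho_a) == sign(m$rho_b) & m$rho_a != 0
  m
}

#' Select extreme concordant correlations as network edges
#'
#' Restricts to direction-concordant pairs, ranks them by the validation
#' cohort's signed rho, and keeps the top and bottom `tail_fraction`
#' (default 2.5% per tail, i.e. the most extreme 5%). Ties at a cutoff are
#' all included.
#'
#' @param pairs Output of [pair_correlations()].
#' @param tail_fraction Fraction kept per tail (must be < 0.5).
#' @param rank_by `"validation"` (default, rho_b) or `"mean"` of the two.
#' @return Edge-list data.frame `microbe`, `gene`, `rho_a`, `rho_b`,
#'   `weight` (the ranking rho).
#' @export
concordant_edge_select <- function(pairs, tail_fraction = 0.025,
                                   rank_by = c("validation", "mean")) {
  if (tail_fraction >= 0.5) stop("tail_fraction must be < 0.5")
  rank_by <- match.arg(rank_by)
  cc <- pairs[pairs$concordant, , drop = FALSE]
  if (nrow(cc) == 0L) {
    return(data.frame(microbe = character(), gene = character(),
                      rho_a = numeric(), rho_b = numeric(),
                      weight = numeric()))
  }
  w <- if (rank_by == "validation") cc$rho_b else (cc$rho_a + cc$rho_b) / 2
  k <- max(1L, floor(nrow(cc) * tail_fraction))
  ws <- sort(w)
  lo_cut <- ws[k]                        # include ties at the cutoff
  hi_cut <- ws[length(ws) - k + 1L]
  keep <- w <= lo_cut | w >= hi_cut
  out <- cc[keep, c("microbe", "gene", "rho_a", "rho_b"), drop = FALSE]
  out$weight <- w[keep]
  rownames(out) <- NULL
  out
}

#' Build the bipartite microbe-gene network
#'
#' Degree is the incident edge count; betweenness and closeness are
#' computed on the unweighted graph (closeness per connected component by
#' default, or globally as harmonic centrality).
#'
#' @param edges Edge list from [concordant_edge_select()].
#' @param closeness Either `"component"` (default) or `"harmonic"`.
#' @return Object of class `microbe_gene_network`: the `igraph` graph and
#'   a `nodes` data.frame (`node`, `type` microbe/gene, `degree`,
#'   `betweenness`, `closeness`).
#' @export
build_network <- function(edges, closeness = c("component", "harmonic")) {
  closeness <- match.arg(closeness)
  if (nrow(edges) == 0L) stop("empty edge list")
  microbes <- unique(edges$microbe)
  genes <- unique(edges$gene)
  g <- igraph::graph_from_data_frame(
    edges[, c("microbe", "gene")], directed = FALSE,
    vertices = data.frame(name = c(microbes, genes),
                          type = rep(c("microbe", "gene"),
                                     c(length(microbes), length(genes)))))
  igraph::E(g)$weight_rho <- edges$weight
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA)
  clo <- if (closeness == "harmonic") {
    igraph::harmonic_centrality(g, weights = NA, normalized = TRUE)
  } else {
    suppressWarnings(igraph::closeness(g, weights = NA, mode = "all"))
  }
  clo[!is.finite(clo)] <- 0
  nodes <- data.frame(node = igraph::V(g)$name,
                      type = igraph::V(g)$type,
                      degree = unname(deg),
                      betweenness = unname(btw),
                      closeness = unname(clo),
                      stringsAsFactors = FALSE)
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "microbe_gene_network")
}

#' @export
print.microbe_gene_network <- function(x, ...) {
  cat("microbe_gene_network:", sum(x$nodes$type == "microbe"), "microbes,",
      sum(x$nodes$type == "gene"), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Random-matrix null for the concordant network
#'
#' Fills two cohorts' microbe and gene matrices with iid standard normal
#' values, runs the identical correlate -> concordance filter -> extreme
#' 5% selection -> degree pipeline, and summarizes the per-microbe degree
#' distribution. Under independence the concordant fraction is ~0.5 and
#' degrees are approximately normal, in contrast to the heavy-tailed
#' degrees of real structured data.
#'
#' @param n_samples,n_microbes,n_genes Matrix dimensions (defaults 100,
#'   100, 1000).
#' @param replicates Number of independent replicates (default 1).
#' @param tail_fraction Per-tail selection fraction (default 0.025).
#' @param seed Integer seed.
#' @return data.frame with one row per replicate: `n_pairs`,
#'   `n_concordant`, `concordant_fraction`, `n_edges`, `degree_mean`,
#'   `degree_sd`, `degree_skewness`, `degree_kurtosis`; the last
#'   replicate's per-microbe degrees are attached as attribute `degrees`.
#' @export
random_network_null <- function(n_samples = 100L, n_microbes = 100L,
                                n_genes = 1000L, replicates = 1L,
                                tail_fraction = 0.025, seed = 1L) {
  stopifnot(n_samples >= 4, n_microbes >= 4, n_genes >= 4)
  set.seed(seed)
  out <- vector("list", replicates)
  degrees <- NULL
  for (r in seq_len(replicates)) {
    mk <- function(nr, prefix) {
      m <- matrix(stats::rnorm(nr * n_samples), nr, n_samples,
                  dimnames = list(paste0(prefix, seq_len(nr)),
                                  paste0("s", seq_len(n_samples))))
      m
    }
    ca <- correlate_microbes_genes(mk(n_microbes, "m"), mk(n_genes, "g"))
    cb <- correlate_microbes_genes(mk(n_microbes, "m"), mk(n_genes, "g"))
    pairs <- pair_correlations(ca, cb)
    edges <- concordant_edge_select(pairs, tail_fraction = tail_fraction)
    deg <- table(factor(edges$microbe, levels = paste0("m", seq_len(n_microbes))))
    degrees <- as.integer(deg)
    out[[r]] <- data.frame(
      n_pairs = nrow(pairs),
      n_concordant = sum(pairs$concordant),
      concordant_fraction = mean(pairs$concordant),
      n_edges = nrow(edges),
      degree_mean = mean(degrees),
      degree_sd = stats::sd(degrees),
      degree_skewness = e1071::skewness(degrees),
      degree_kurtosis = e1071::kurtosis(degrees))
  }
  res <- do.call(rbind, out)
  attr(res, "degrees") <- degrees
  res
}

#' Discrete power-law fit and heavy-tail diagnostic for degrees
#'
#' Maximum-likelihood discrete power-law exponent over degrees >= dmin,
#' with dmin chosen by Kolmogorov-Smirnov minimization (Clauset-style);
#' `heavy_tail` is raised when the excess kurtosis of the positive degrees
#' exceeds 1 and the exponent lies in (1.5, 4) — the regime of scale-free
#' real networks, as opposed to the near-normal degrees of the random
#' null.
#'
#' @param degrees Integer vector of node degrees.
#' @return List `alpha`, `dmin`, `ks`, `excess_kurtosis`, `heavy_tail`
#'   (all-`NA` null fit when fewer than 10 nodes have degree >= 1 or the
#'   degrees are constant).
#' @export
degree_distribution_fit <- function(degrees) {
  d <- degrees[degrees >= 1]
  null_fit <- list(alpha = NA_real_, dmin = NA_integer_, ks = NA_real_,
                   excess_kurtosis = NA_real_, heavy_tail = NA)
  if (length(d) < 10L || length(unique(d)) < 2L) return(null_fit)
  kurt <- e1071::kurtosis(d)                 # e1071 type 3 ~ excess kurtosis
  cands <- sort(unique(d))
  best <- NULL
  for (dmin in cands) {
    tail_d <- d[d >= dmin]
    if (length(tail_d) < 5L) next
    alpha <- 1 + length(tail_d) / sum(log(tail_d / (dmin - 0.5)))
    if (!is.finite(alpha) || alpha <= 1) next
    # fitted discrete CDF by truncated zeta sums
    kmax <- max(tail_d)
    supp <- dmin:kmax
    pk <- supp^(-alpha)
    tail_mass <- sum((seq(kmax + 1, kmax + 10000))^(-alpha))
    pk <- pk / (sum(pk) + tail_mass)
    fit_cdf <- cumsum(pk)
    emp_cdf <- vapply(supp, function(k) mean(tail_d <= k), numeric(1))
    ks <- max(abs(emp_cdf - fit_cdf))
    if (is.null(best) || ks < best$ks)
      best <- list(alpha = alpha, dmin = as.integer(dmin), ks = ks)
  }
  if (is.null(best)) return(null_fit)
  list(alpha = best$alpha, dmin = best$dmin, ks = best$ks,
       excess_kurtosis = kurt,
       heavy_tail = isTRUE(kurt > 1 && best$alpha > 1.5 && best$alpha < 4))
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (set name, description, tab-separated
#'   member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (weight exponent 1
#' on the absolute ranking statistic) with a gene-label permutation
#' p-value and BH correction across sets. Sets with fewer than `min_size`
#' members present in the ranking are skipped with a warning.
#'
#' @param ranked_genes Named numeric vector: gene -> ranking statistic
#'   (e.g. a microbe's correlation with each gene).
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]).
#' @param n_permutations Permutations (default 1000).
#' @param min_size Minimum overlapping set size (default 3).
#' @param seed Integer seed.
#' @return data.frame `set`, `size`, `es`, `nes`, `p`, `q`.
#' @export
preranked_enrichment <- function(ranked_genes, gene_sets,
                                 n_permutations = 1000L, min_size = 3L,
                                 seed = 1L) {
  overlap <- vapply(gene_sets, function(s)
    sum(s %in% names(ranked_genes)), integer(1))
  if (any(overlap < min_size))
    warning(sum(overlap < min_size), " gene set(s) below minimum size ",
            min_size, " skipped")
  keep <- gene_sets[overlap >= min_size]
  if (!length(keep)) stop("no gene set with at least ", min_size,
                          " members present in the ranking")
  set.seed(seed)
  quiet <- utils::capture.output(
    res <- suppressWarnings(
      fgsea::fgseaSimple(pathways = keep, stats = ranked_genes,
                         nperm = n_permutations, minSize = min_size,
                         gseaParam = 1, nproc = 1)),
    type = "output")
  data.frame(set = res$pathway, size = res$size, es = res$ES,
             nes = res$NES, p = res$pval, q = bh_adjust(res$pval),
             stringsAsFactors = FALSE)
}
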