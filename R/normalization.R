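# log-CPM precision weighting (VOOM), supervised removal of technical
# covariates (SNM-style iterative weighted regression), relative abundance,
# rarefaction, and prevalence.

#' Build a [intercept | biological | technical] design matrix
#'
#' Categorical covariates are one-hot coded (treatment contrasts).
#'
#' @param metadata data.frame with a `sample` column.
#' @param samples Sample ids, in column order of the matrix to be fitted.
#' @param bio_vars,adj_vars Metadata column names for biological
#'   (preserved) and technical (removed) covariates.
#' @return List with `design` (samples x p), `bio_cols`, `adj_cols`
#'   (logical masks over columns).
#' @keywords internal
.build_design <- function(metadata, samples, bio_vars, adj_vars) {
  if (length(intersect(bio_vars, adj_vars)))
    stop("bio_vars and adj_vars must be disjoint")
  md <- metadata[match(samples, metadata$sample), , drop = FALSE]
  miss <- setdiff(c(bio_vars, adj_vars), names(md))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  one_hot <- function(vars) {
    # covariates constant over these samples carry no information; drop
    usable <- vars[vapply(vars, function(v)
      length(unique(md[[v]])) > 1, logical(1))]
    if (!length(usable)) return(NULL)
    f <- stats::as.formula(paste("~", paste(usable, collapse = " + ")))
    m <- stats::model.matrix(f, data = md)
    m[, colnames(m) != "(Intercept)", drop = FALSE]
  }
  bio <- one_hot(bio_vars)
  adj <- one_hot(adj_vars)
  design <- cbind(`(Intercept)` = rep(1, length(samples)), bio, adj)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- setdiff(colnames(design),
                       colnames(design)[qrd$pivot[seq_len(qrd$rank)]])
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  nb <- if (is.null(bio)) 0L else ncol(bio)
  na <- if (is.null(adj)) 0L else ncol(adj)
  list(design = design,
       bio_cols = c(FALSE, rep(TRUE, nb), rep(FALSE, na)),
       adj_cols = c(FALSE, rep(FALSE, nb), rep(TRUE, na)))
}

#' Normalized abundance container
#'
#' @param values Real taxa x samples matrix on the log2-CPM scale.
#' @param weights Positive precision-weight matrix of the same shape.
#' @param bio_vars,adj_vars Covariate names preserved / removed.
#' @return Object of class `normalized_abundance`.
#' @export
normalized_abundance <- function(values, weights, bio_vars = character(),
                                 adj_vars = character()) {
  stopifnot(identical(dim(values), dim(weights)), all(weights > 0),
            length(intersect(bio_vars, adj_vars)) == 0)
  structure(list(values = values, weights = weights,
                 bio_vars = bio_vars, adj_vars = adj_vars),
            class = "normalized_abundance")
}

#' @export
print.normalized_abundance <- function(x, ...) {
  cat("normalized_abundance:", nrow(x$values), "taxa x", ncol(x$values),
      "samples (log2-CPM)\n")
  if (length(x$bio_vars)) cat("preserved:", paste(x$bio_vars, collapse = ", "), "\n")
  if (length(x$adj_vars)) cat("removed:", paste(x$adj_vars, collapse = ", "), "\n")
  invisible(x)
}

#' Log-CPM transform with precision weights
#'
#' Computes `log2((count + 0.5) / (library_size + 1) * 1e6)` and
#' per-observation precision weights from the fitted mean-variance trend
#' (LOESS span 0.5 of sqrt residual SD against average log2 count, after a
#' least-squares fit on the supplied design). Weights are the inverse
#' fourth power of the predicted sqrt-SD, clamped at the trend's extremes.
#'
#' @param table A `taxon_count_table` with at least 2 taxa and 2 samples.
#' @param metadata Optional metadata (needed when covariates are named).
#' @param bio_vars,adj_vars Covariate names entering the trend-fitting
#'   design; the adjustment itself happens in [snm_normalize()].
#' @return A [normalized_abundance()] (technical variance not yet removed).
#' @export
voom_transform <- function(table, metadata = NULL, bio_vars = character(),
                           adj_vars = character()) {
  counts <- table$counts
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least 2 taxa and 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  if (length(c(bio_vars, adj_vars))) {
    d <- .build_design(metadata, colnames(counts), bio_vars, adj_vars)
    design <- d$design
  } else {
    design <- matrix(1, ncol(counts), 1, dimnames = list(colnames(counts),
                                                         "(Intercept)"))
  }
  v <- limma::voom(counts, design = design, lib.size = lib, span = 0.5)
  normalized_abundance(v$E, v$weights, bio_vars, adj_vars)
}

# voom-style weight refit on an (already log-scale) value matrix:
# per-taxon weighted LS residual sqrt-SD vs average value, lowess trend,
# per-observation weights = trend(fitted)^(-4), clamped to trend range.
.refit_weights <- function(values, design, weights, span = 0.5) {
  fit <- limma::lmFit(values, design, weights = weights)
  sx <- rowMeans(values)
  sy <- sqrt(fit$sigma)
  ok <- is.finite(sx) & is.finite(sy)
  l <- stats::lowess(sx[ok], sy[ok], f = span)
  fitted_vals <- fit$coefficients %*% t(design)
  f <- stats::approx(l$x, l$y, xout = fitted_vals, rule = 2, ties = mean)
  w <- matrix(f$y, nrow(values), ncol(values))
  w[w < 1e-6] <- 1e-6
  w^-4
}

#' Supervised removal of technical covariates
#'
#' Per taxon, a weighted least-squares fit of the log2-CPM values on
#' `[intercept | biological | technical]` one-hot covariates, using the
#' precision weights; the fitted technical component is subtracted, the
#' mean-variance trend refit on the adjusted values, and the cycle repeated
#' until the technical coefficient matrix changes by less than `tol` in
#' max-norm (or `max_iter` iterations). Biological covariates stay in the
#' model so their variance is preserved, not absorbed.
#'
#' @param norm A [normalized_abundance()] from [voom_transform()].
#' @param metadata data.frame with a `sample` column and all covariates.
#' @param bio_vars Covariates whose effects are preserved (e.g. cancer
#'   type).
#' @param adj_vars Technical covariates whose variance is removed (e.g.
#'   sequencing center, preservation method).
#' @param tol Convergence tolerance on the adjustment coefficients
#'   (default 1e-6, max-norm).
#' @param max_iter Iteration cap (default 50).
#' @return A [normalized_abundance()] with the technical component removed
#'   and weights refit.
#' @export
snm_normalize <- function(norm, metadata, bio_vars = norm$bio_vars,
                          adj_vars = norm$adj_vars, tol = 1e-6,
                          max_iter = 50L) {
  if (!length(adj_vars)) return(norm)  # nothing to remove
  samples <- colnames(norm$values)
  d <- .build_design(metadata, samples, bio_vars, adj_vars)
  design <- d$design
  values <- norm$values
  weights <- norm$weights
  b_adj_prev <- NULL
  adjusted <- values
  for (it in seq_len(max_iter)) {
    fit <- limma::lmFit(values, design, weights = weights)
    b_adj <- fit$coefficients[, d$adj_cols, drop = FALSE]
    adjusted <- values - b_adj %*% t(design[, d$adj_cols, drop = FALSE])
    if (!is.null(b_adj_prev) &&
        max(abs(b_adj - b_adj_prev)) < tol) break
    b_adj_prev <- b_adj
    weights <- .refit_weights(adjusted, design[, !d$adj_cols, drop = FALSE],
                              weights)
  }
  normalized_abundance(adjusted, weights, bio_vars, adj_vars)
}

#' Relative abundance
#'
#' Per-sample proportions of taxon counts; optionally the human read count
#' enters the denominator as an extra "Homo sapiens" row so microbial and
#' human portions are on one scale.
#'
#' @param table A `taxon_count_table`.
#' @param include_human Include human reads as a row (default FALSE).
#' @return Real matrix whose columns each sum to 1.
#' @export
relative_abundance <- function(table, include_human = FALSE) {
  m <- table$counts
  if (include_human) {
    m <- rbind(m, `Homo sapiens` = table$human_reads)
  }
  tot <- colSums(m)
  if (any(tot <= 0))
    stop("zero column total for sample(s): ",
         paste(colnames(m)[tot <= 0], collapse = ", "))
  sweep(m, 2, tot, "/")
}

#' Rarefy a count table
#'
#' Subsamples each sample's reads uniformly without replacement down to a
#' common depth (single draw, recorded seed). With `depth = "min"` the
#' lowest library size is used and no sample is dropped; with an explicit
#' depth, samples below it are dropped with a warning.
#'
#' @param table A `taxon_count_table`.
#' @param depth Integer target depth or `"min"`.
#' @param seed Integer seed making the draw reproducible.
#' @return A `taxon_count_table` whose column sums all equal `depth`, with
#'   attributes `rarefaction_depth` and `rarefaction_seed`.
#' @export
rarefy <- function(table, depth = "min", seed = 1L) {
  lib <- colSums(table$counts)
  if (identical(depth, "min")) {
    depth <- min(lib)
  }
  depth <- as.integer(depth)
  if (depth <= 0) stop("rarefaction depth must be > 0")
  keep <- lib >= depth
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(colnames(table$counts)[!keep], collapse = ", "))
  }
  counts <- table$counts[, keep, drop = FALSE]
  # draw in canonical row order so the subsample does not depend on how
  # the caller happened to order taxa
  ord <- order(rownames(counts))
  set.seed(seed)
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic
  # for non-count data); our inputs are genuine counts, so muffle it
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(counts[ord, , drop = FALSE]), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  rar <- rar[match(rownames(counts), rownames(rar)), , drop = FALSE]
  out <- taxon_count_table(rar, table$lineages, table$human_reads[keep])
  attr(out, "rarefaction_depth") <- depth
  attr(out, "rarefaction_seed") <- as.integer(seed)
  out
}

#' Presence/absence prevalence table
#'
#' A taxon is "present" in a sample when any reads support it (count >= 1)
#' in the rarefied, decontaminated table.
#'
#' @param table A rarefied `taxon_count_table` (see [rarefy()]).
#' @return Object of class `prevalence_table`: `presence` (logical taxa x
#'   samples), `rarefaction_depth`, `seed`.
#' @export
prevalence <- function(table) {
  depth <- attr(table, "rarefaction_depth")
  if (is.null(depth)) {
    warning("input table carries no rarefaction attributes; ",
            "prevalence should be computed from rarefied counts")
    depth <- NA_integer_
  }
  structure(list(presence = table$counts >= 1,
                 rarefaction_depth = depth,
                 seed = attr(table, "rarefaction_seed")),
            class = "prevalence_table")
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat("prevalence_table:", nrow(x$presence), "taxa x", ncol(x$presence),
      "samples; rarefaction depth", x$rarefaction_depth, "\n")
  invisible(x)
}
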