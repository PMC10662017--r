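# Survival and clinical-covariate association of taxa, BH correction, and
# the two-cohort concordance intersection.

#' Cox proportional-hazards test of microbe presence
#'
#' One-covariate Cox partial-likelihood fit (Efron ties) of overall
#' survival on a presence/absence indicator; significance by the
#' likelihood-ratio test against the null model (chi-square, 1 df).
#' Degenerate inputs (one-sided presence, no events) and non-converged
#' fits return a null result rather than raising.
#'
#' @param presence Logical (or 0/1) vector, one entry per sample.
#' @param time Days to death or last follow-up (>= 0).
#' @param event Death indicator (TRUE/1 = death observed).
#' @return List with `log_hr`, `p`, `n`, `n_events`, `converged`.
#' @export
cox_presence <- function(presence, time, event) {
  ok <- !is.na(presence) & !is.na(time) & !is.na(event)
  presence <- as.logical(presence[ok])
  time <- time[ok]
  event <- as.logical(event[ok])
  null_res <- list(log_hr = NA_real_, p = NA_real_, n = length(time),
                   n_events = sum(event), converged = FALSE)
  if (length(time) == 0 || all(presence) || !any(presence) || !any(event))
    return(null_res)
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ presence,
                      ties = "efron"),
      warning = function(w) {
        if (grepl("infinite|converge|beta may be", conditionMessage(w)))
          invokeRestart("muffleWarning") else invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(null_res)
  beta <- unname(fit$coefficients[1])
  # monotone likelihood walks the coefficient to +/-inf; flag, don't throw
  if (!is.finite(beta) || abs(beta) > 15) {
    null_res$converged <- FALSE
    return(null_res)
  }
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  list(log_hr = beta,
       p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       n = length(time), n_events = sum(event), converged = TRUE)
}

#' Multi-threshold survival scan over abundance cutoffs
#'
#' Dichotomizes a taxon's abundance at each quantile of a grid and runs
#' [cox_presence()] on each split, showing whether a survival association
#' is robust to the stratification threshold.
#'
#' @param abundance Real abundance vector per sample.
#' @param time,event Survival outcome as in [cox_presence()].
#' @param quantile_grid Quantiles at which to cut (default 0.1..0.9).
#' @return data.frame with one row per quantile: `quantile`, `threshold`,
#'   `log_hr`, `p` (NA where a side of the split is empty or the abundance
#'   is degenerate).
#' @export
multi_threshold_survival <- function(abundance, time, event,
                                     quantile_grid = seq(0.1, 0.9, by = 0.1)) {
  out <- data.frame(quantile = quantile_grid,
                    threshold = NA_real_,
                    log_hr = NA_real_, p = NA_real_)
  if (length(unique(abundance[!is.na(abundance)])) < 2L) return(out)
  for (i in seq_along(quantile_grid)) {
    thr <- stats::quantile(abundance, quantile_grid[i], na.rm = TRUE,
                           names = FALSE)
    out$threshold[i] <- thr
    grp <- abundance > thr
    if (all(grp, na.rm = TRUE) || !any(grp, na.rm = TRUE)) next
    r <- cox_presence(grp, time, event)
    out$log_hr[i] <- r$log_hr
    out$p[i] <- r$p
  }
  out
}

#' Spearman rank correlation with a clinical covariate
#'
#' Average (mid-) ranks for ties; two-sided p from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom. Missing
#' pairs are deleted pairwise.
#'
#' @param abundance Taxon abundance per sample.
#' @param covariate Covariate values per sample.
#' @return List with `rho`, `p`, `n` (`rho = NA` if fewer than 4 complete
#'   pairs or a constant vector).
#' @export
spearman_assoc <- function(abundance, covariate) {
  ok <- !is.na(abundance) & !is.na(covariate)
  x <- abundance[ok]
  y <- covariate[ok]
  n <- length(x)
  if (n < 4L || length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

#' Hypoxia expression score
#'
#' Median-split metagene score: per sample, each signature gene present in
#' the matrix contributes +1 when its expression exceeds the cohort median
#' for that gene and -1 otherwise (ties at the median count as -1).
#'
#' @param expression Genes x samples real matrix with gene rownames.
#' @param signature Character vector of signature gene names.
#' @return Named integer vector of per-sample scores in
#'   `[-k, k]` for k genes found.
#' @export
hypoxia_score <- function(expression, signature) {
  found <- intersect(signature, rownames(expression))
  if (!length(found)) stop("no signature genes found in expression matrix")
  if (length(found) < length(signature))
    warning(length(signature) - length(found),
            " signature gene(s) absent from the expression matrix")
  sub <- expression[found, , drop = FALSE]
  med <- apply(sub, 1, stats::median)
  sgn <- ifelse(sub > med, 1L, -1L)
  colSums(sgn)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate control; `NA` p-values pass through
#' untouched and do not count toward the family size.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs allowed).
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Taxon-survival association table for one cohort
#'
#' Runs [cox_presence()] for every taxon within each cancer-type stratum
#' and in a pooled `"all"` stratum, then BH-adjusts within each stratum
#' (the narrowest defensible family: one cohort, one stratum, one
#' covariate, one rank level).
#'
#' @param prev A [prevalence()] table.
#' @param metadata data.frame with `sample`, `os_days`, `os_event`, and
#'   `cancer_type` columns.
#' @param cohort Cohort label recorded in the output.
#' @param rank_level Rank label recorded in the output.
#' @param strata `"per_cancer"`, `"all"`, or `"both"` (default).
#' @return data.frame of class `association_result`: taxon, rank_level,
#'   stratum, covariate, estimate (log HR), p, q, direction, cohort.
#' @export
survival_associations <- function(prev, metadata, cohort = "cohort",
                                  rank_level = "species",
                                  strata = c("both", "per_cancer", "all")) {
  strata <- match.arg(strata)
  samples <- colnames(prev$presence)
  md <- metadata[match(samples, metadata$sample), , drop = FALSE]
  groups <- list()
  if (strata %in% c("both", "per_cancer"))
    groups <- split(seq_along(samples), md$cancer_type)
  if (strata %in% c("both", "all"))
    groups[["all"]] <- seq_along(samples)
  res <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    rows <- lapply(rownames(prev$presence), function(tx) {
      r <- cox_presence(prev$presence[tx, idx], md$os_days[idx],
                        md$os_event[idx])
      data.frame(taxon = tx, rank_level = rank_level, stratum = g,
                 covariate = "survival", estimate = r$log_hr, p = r$p,
                 stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    block$q <- bh_adjust(block$p)
    res[[g]] <- block
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$direction <- sign(out$estimate)
  out$cohort <- cohort
  class(out) <- c("association_result", class(out))
  out
}

#' Taxon-covariate Spearman association table for one cohort
#'
#' Correlates each taxon's abundance with each clinical covariate (age,
#' BMI, hypoxia score, immune fractions, ...) within cancer strata and/or
#' pooled, BH-adjusting within each (stratum, covariate) family.
#'
#' @param abundance Real taxa x samples matrix (relative or normalized).
#' @param covariates data.frame with `sample` plus one column per
#'   covariate to test.
#' @param metadata data.frame with `sample` and `cancer_type`.
#' @param cohort,rank_level Labels recorded in the output.
#' @param strata As in [survival_associations()].
#' @return `association_result` data.frame (estimate = Spearman rho).
#' @export
covariate_associations <- function(abundance, covariates, metadata,
                                   cohort = "cohort", rank_level = "species",
                                   strata = c("both", "per_cancer", "all")) {
  strata <- match.arg(strata)
  samples <- colnames(abundance)
  md <- metadata[match(samples, metadata$sample), , drop = FALSE]
  cv <- covariates[match(samples, covariates$sample), , drop = FALSE]
  cov_names <- setdiff(names(cv), "sample")
  groups <- list()
  if (strata %in% c("both", "per_cancer"))
    groups <- split(seq_along(samples), md$cancer_type)
  if (strata %in% c("both", "all"))
    groups[["all"]] <- seq_along(samples)
  res <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (cn in cov_names) {
      rows <- lapply(rownames(abundance), function(tx) {
        r <- spearman_assoc(abundance[tx, idx], cv[[cn]][idx])
        data.frame(taxon = tx, rank_level = rank_level, stratum = g,
                   covariate = cn, estimate = r$rho, p = r$p,
                   stringsAsFactors = FALSE)
      })
      block <- do.call(rbind, rows)
      block$q <- bh_adjust(block$p)
      res[[paste(g, cn)]] <- block
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$direction <- sign(out$estimate)
  out$cohort <- cohort
  class(out) <- c("association_result", class(out))
  out
}

#' Two-cohort concordance intersection
#'
#' Keeps associations that are significant in both cohorts (q below
#' `alpha`, or raw p with `use = "p"`) with the same direction of effect —
#' the discovery/validation rule that suppresses false discoveries far
#' below either cohort's own FDR.
#'
#' @param results_a,results_b `association_result` tables keyed by
#'   (taxon, rank_level, stratum, covariate); unmatched keys are ignored.
#' @param alpha Significance cutoff (default 0.05).
#' @param use `"q"` (default, BH-adjusted) or `"p"` (raw).
#' @return data.frame of concordant keys with both estimates and both
#'   q-values (`estimate_a`, `estimate_b`, `q_a`, `q_b`, `direction`).
#' @export
concordance_intersect <- function(results_a, results_b, alpha = 0.05,
                                  use = c("q", "p")) {
  use <- match.arg(use)
  key_cols <- c("taxon", "rank_level", "stratum", "covariate")
  m <- merge(as.data.frame(results_a), as.data.frame(results_b),
             by = key_cols, suffixes = c("_a", "_b"))
  sig_a <- m[[paste0(use, "_a")]]
  sig_b <- m[[paste0(use, "_b")]]
  keep <- !is.na(sig_a) & !is.na(sig_b) & sig_a < alpha & sig_b < alpha &
    !is.na(m$direction_a) & !is.na(m$direction_b) &
    m$direction_a == m$direction_b & m$direction_a != 0
  out <- m[keep, c(key_cols, "estimate_a", "estimate_b", "q_a", "q_b",
                   "direction_a"), drop = FALSE]
  names(out)[names(out) == "direction_a"] <- "direction"
  rownames(out) <- NULL
  out
}
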