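# Survival and covariate association, BH correction, concordance.

test_that("cox presence fit matches the brute-force partial likelihood", {
  # n = 12, distinct interleaved times: presence group tends to die
  # earlier but the groups overlap, so the MLE is finite
  time <- c(10, 25, 35, 60, 110, 150, 30, 40, 100, 120, 180, 200)
  event <- rep(TRUE, 12)
  presence <- c(rep(TRUE, 6), rep(FALSE, 6))
  r <- cox_presence(presence, time, event)
  o <- oracle_cox(presence, time, event)
  expect_lt(abs(r$log_hr - o$log_hr), 1e-4)
  expect_lt(abs(r$p - o$p), 1e-4)
  expect_gt(r$log_hr, 0)
  # a censored variant still matches (distinct times, Breslow = Efron)
  event2 <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
              FALSE, TRUE, TRUE)
  r2 <- cox_presence(presence, time, event2)
  o2 <- oracle_cox(presence, time, event2)
  expect_lt(abs(r2$log_hr - o2$log_hr), 1e-4)
  expect_lt(abs(r2$p - o2$p), 1e-4)
})

test_that("cox presence keeps its type-I error under permutation", {
  set.seed(41)
  n <- 100
  time <- rexp(n, 0.01)
  event <- time < quantile(time, 0.6)
  hits <- 0
  for (i in 1:200) {
    pres <- sample(c(TRUE, FALSE), n, replace = TRUE)
    r <- cox_presence(pres, time, event)
    if (!is.na(r$p) && r$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.08)
})

test_that("degenerate survival inputs give null results, not errors", {
  time <- c(5, 10, 15, 20); event <- c(TRUE, TRUE, FALSE, TRUE)
  expect_false(cox_presence(rep(TRUE, 4), time, event)$converged)
  expect_false(cox_presence(rep(FALSE, 4), time, event)$converged)
  expect_false(cox_presence(c(TRUE, TRUE, FALSE, FALSE), time,
                            rep(FALSE, 4))$converged)
  # complete separation: all deaths in one group, tiny n
  r <- cox_presence(c(TRUE, TRUE, FALSE, FALSE), c(1, 2, 100, 200),
                    c(TRUE, TRUE, FALSE, FALSE))
  expect_true(is.na(r$p) || is.finite(r$log_hr))
})

test_that("multi-threshold scan spans the grid and finds the changepoint", {
  set.seed(52)
  n <- 200
  abund <- runif(n)
  hi <- abund > 0.7   # planted effect above the 0.7 quantile
  time <- rexp(n, 0.01 * exp(1.5 * hi))
  event <- time < 150
  time <- pmin(time, 150)
  res <- multi_threshold_survival(abund, time, event)
  expect_equal(nrow(res), 9L)
  expect_equal(res$quantile, seq(0.1, 0.9, 0.1))
  best <- res$quantile[which.min(res$p)]
  expect_gte(best, 0.5)   # sharpest separation near the planted cut
  expect_true(all(is.finite(res$p)))
  # constant abundance: all rows null
  res0 <- multi_threshold_survival(rep(1, n), time, event)
  expect_true(all(is.na(res0$p)))
  expect_equal(nrow(res0), 9L)
})

test_that("spearman association handles monotone, reversed, tied data", {
  expect_equal(spearman_assoc(1:3 * 1.0, c(10, 20, 30))$rho, NA_real_)
  r <- spearman_assoc(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(r$rho, 1)
  expect_equal(spearman_assoc(c(1, 2, 3, 4), c(40, 30, 20, 10))$rho, -1)
  x <- c(1, 2, 2, 3); y <- c(3, 1, 4, 5)
  r2 <- spearman_assoc(x, y)
  expect_equal(r2$rho, oracle_spearman(x, y), tolerance = 1e-12)
  # missing values removed pairwise
  r3 <- spearman_assoc(c(x, NA), c(y, 1))
  expect_equal(r3$n, 4L)
  expect_true(is.na(spearman_assoc(rep(2, 6), 1:6)$rho))
})

test_that("hypoxia score follows the median-split rule", {
  expr <- rbind(VEGFA = c(5, 1, 2, 9), LDHA = c(7, 2, 3, 8),
                ENO1 = c(6, 1, 2, 9))
  colnames(expr) <- paste0("s", 1:4)
  sc <- hypoxia_score(expr, c("VEGFA", "LDHA", "ENO1"))
  expect_equal(unname(sc["s4"]), 3L)     # above all medians
  expect_equal(unname(sc["s2"]), -3L)
  # a value exactly at the median contributes -1 (strict '>')
  e2 <- rbind(G = c(1, 2, 2, 3))
  colnames(e2) <- paste0("s", 1:4)
  expect_equal(unname(hypoxia_score(e2, "G")), c(-1L, -1L, -1L, 1L))
  expect_warning(hypoxia_score(expr, c("VEGFA", "NOPE")), "absent")
  expect_error(hypoxia_score(expr, "NOPE"), "no signature genes")
  # random expression: cohort mean score near 0
  set.seed(61)
  big <- matrix(rnorm(10 * 500), 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:500)))
  sc2 <- hypoxia_score(big, paste0("g", 1:10))
  expect_lt(abs(mean(sc2)), 3 * sd(sc2) / sqrt(500))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(71)
  for (i in 1:5) {
    p <- runif(20)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # NAs pass through without shrinking the family of observed p-values
  p <- c(0.01, NA, 0.5)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(c(0.01, 0.5)))
})

test_that("concordance keeps only doubly significant same-sign results", {
  mk <- function(q, est) data.frame(taxon = "t1", rank_level = "species",
                                    stratum = "all", covariate = "survival",
                                    estimate = est, p = q / 2, q = q,
                                    direction = sign(est), cohort = "x")
  hit <- concordance_intersect(mk(0.01, 1), mk(0.04, 0.5))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$direction, 1)
  expect_equal(nrow(concordance_intersect(mk(0.01, 1), mk(0.04, -0.5))), 0L)
  expect_equal(nrow(concordance_intersect(mk(0.01, 1), mk(0.20, 0.5))), 0L)
  # raw-p mode
  expect_equal(nrow(concordance_intersect(mk(0.08, 1), mk(0.08, 2),
                                          use = "p")), 1L)
})

test_that("survival association tables stratify and correct per family", {
  spec <- fixture_spec(n_samples = 80L, n_taxa = 30L, n_genes = 5L,
                       n_contaminants = 0L, seed = 19L)
  ch <- generate_cohort(spec)
  prev <- prevalence(rarefy(ch$table, "min", seed = 1))
  rownames(prev$presence) <- taxon_names(ch$table)
  res <- survival_associations(prev, ch$metadata, cohort = "A")
  expect_s3_class(res, "association_result")
  expect_true(all(c("all", unique(ch$metadata$cancer_type)) %in%
                    res$stratum))
  # q is a BH within-stratum correction of p
  blk <- res[res$stratum == "all", ]
  expect_equal(blk$q, bh_adjust(blk$p))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  expect_equal(res$direction, sign(res$estimate))
})
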