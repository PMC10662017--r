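# log-CPM precision weighting, supervised covariate removal, relative
# abundance, rarefaction, and prevalence.

test_that("log-CPM offset formula gives the closed-form value", {
  counts <- matrix(c(0, 999999, 10, 999990), 2, 2,
                   dimnames = list(c("101", "102"), c("a", "b")))
  tab <- toy_table(counts)
  nv <- voom_transform(tab)
  # log2((0 + 0.5) / (999999 + 1) * 1e6) = log2(0.5) = -1
  expect_equal(unname(nv$values["101", "a"]), -1, tolerance = 1e-12)
  expect_true(all(is.finite(nv$weights)) && all(nv$weights > 0))
})

test_that("log-CPM is invariant to doubling counts and library sizes", {
  set.seed(5)
  counts <- matrix(rpois(200, 100), 20, 10,
                   dimnames = list(as.character(101:120), NULL))
  v1 <- voom_transform(toy_table(counts))$values
  v2 <- voom_transform(toy_table(counts * 2))$values
  expect_equal(v1, v2, tolerance = 0.01)  # equal up to +0.5/+1 offsets
})

test_that("precision weights increase with mean count on Poisson data", {
  set.seed(6)
  mu <- sort(rlnorm(50, log(50), 1.2))
  counts <- matrix(rpois(50 * 30, rep(mu, 30)), 50, 30,
                   dimnames = list(as.character(seq_len(50) + 100L), NULL))
  nv <- voom_transform(toy_table(counts))
  w <- rowMeans(nv$weights)
  expect_gt(cor(w, mu, method = "spearman"), 0.9)
})

test_that("supervised normalization removes a planted additive shift", {
  # fixture exactly as specified: additive batch shift on the values,
  # half the samples, no biological effect
  set.seed(101)
  n <- 100; p <- 60
  batch <- rep(c(0, 1), each = n / 2)
  values <- matrix(rnorm(p * n, 5, 1), p, n,
                   dimnames = list(paste0("t", 1:p), paste0("s", 1:n)))
  values <- values + 2.0 * matrix(batch, p, n, byrow = TRUE)
  md <- data.frame(sample = colnames(values),
                   batch = factor(batch),
                   cancer_type = sample(c("A", "B"), n, replace = TRUE))
  nv <- normalized_abundance(values, matrix(1, p, n),
                             bio_vars = "cancer_type", adj_vars = "batch")
  sn <- snm_normalize(nv, md)
  delta <- rowMeans(sn$values[, batch == 1]) -
    rowMeans(sn$values[, batch == 0])
  expect_lt(abs(mean(delta)), 0.05)
})

test_that("biological effects survive normalization; empty adj is identity", {
  set.seed(102)
  n <- 120; p <- 40
  md <- data.frame(sample = paste0("s", 1:n),
                   cancer_type = sample(c("LUAD", "COAD"), n, TRUE),
                   batch = sample(c("x", "y"), n, TRUE))
  bio <- as.numeric(md$cancer_type == "LUAD")
  tech <- as.numeric(md$batch == "y")
  planted_bio <- 1.5
  values <- matrix(rnorm(p * n, 4, 0.8), p, n,
                   dimnames = list(paste0("t", 1:p), md$sample)) +
    planted_bio * matrix(bio, p, n, byrow = TRUE) +
    2.0 * matrix(tech, p, n, byrow = TRUE)
  nv <- normalized_abundance(values, matrix(1, p, n),
                             bio_vars = "cancer_type", adj_vars = "batch")
  sn <- snm_normalize(nv, md)
  est <- mean(rowMeans(sn$values[, bio == 1]) -
                rowMeans(sn$values[, bio == 0]))
  expect_lt(abs(est - planted_bio) / planted_bio, 0.05)
  # no adjustment variables: values pass through untouched
  nv2 <- normalized_abundance(values, matrix(1, p, n),
                              bio_vars = "cancer_type",
                              adj_vars = character())
  expect_identical(snm_normalize(nv2, md)$values, values)
})

test_that("confounded designs are rejected with the aliased columns", {
  n <- 20
  md <- data.frame(sample = paste0("s", 1:n),
                   cancer_type = rep(c("A", "B"), each = n / 2),
                   center = rep(c("c1", "c2"), each = n / 2))  # 1:1 alias
  values <- matrix(rnorm(5 * n), 5, n,
                   dimnames = list(paste0("t", 1:5), md$sample))
  nv <- normalized_abundance(values, matrix(1, 5, n),
                             bio_vars = "cancer_type",
                             adj_vars = "center")
  expect_error(snm_normalize(nv, md), "rank deficient")
})

test_that("batch variance vanishes while biology keeps its share", {
  # count-level fixture with planted technical and biological shifts
  spec <- fixture_spec(n_samples = 100L, n_taxa = 80L, n_genes = 5L,
                       n_contaminants = 0L, batch_effect_size = 2.0,
                       bio_effect_size = 1.0, seed = 3L)
  ch <- generate_cohort(spec)
  nv <- voom_transform(ch$table, ch$metadata, bio_vars = "cancer_type",
                       adj_vars = "preservation_method")
  sn <- snm_normalize(nv, ch$metadata)
  r2 <- function(vals, fac) {
    apply(vals, 1, function(y) summary(lm(y ~ fac))$r.squared)
  }
  ffpe <- factor(ch$metadata$preservation_method)
  bio <- factor(ch$metadata$cancer_type)
  batch_taxa <- match(ch$truth$unit[ch$truth$kind == "batch_taxon"],
                      taxon_names(ch$table))
  bio_taxa <- match(ch$truth$unit[ch$truth$kind == "bio_taxon"],
                    taxon_names(ch$table))
  expect_lt(mean(r2(sn$values[batch_taxa, ], ffpe)), 0.01)
  pre_bio <- mean(r2(nv$values[bio_taxa, ], bio))
  post_bio <- mean(r2(sn$values[bio_taxa, ], bio))
  expect_gte(post_bio, 0.8 * pre_bio)
})

test_that("relative abundance normalizes columns with or without human", {
  tab <- toy_table(matrix(c(2, 3), 2, 1,
                          dimnames = list(c("101", "102"), "s1")),
                   human = 95)
  expect_equal(unname(relative_abundance(tab)[, 1]), c(0.4, 0.6))
  ra <- relative_abundance(tab, include_human = TRUE)
  expect_equal(unname(ra[, 1]), c(0.02, 0.03, 0.95))
  set.seed(9)
  big <- toy_table(matrix(rpois(60, 30) + 1, 6, 10,
                          dimnames = list(as.character(101:106), NULL)))
  expect_equal(unname(colSums(relative_abundance(big))), rep(1, 10),
               tolerance = 1e-12)
})

test_that("rarefaction hits the target depth exactly and reproducibly", {
  set.seed(10)
  counts <- matrix(rpois(50, 40), 5, 10,
                   dimnames = list(as.character(101:105), NULL))
  tab <- toy_table(counts)
  depth <- min(colSums(counts))
  r <- rarefy(tab, "min", seed = 4)
  expect_equal(unname(colSums(r$counts)), rep(depth, 10))
  expect_equal(attr(r, "rarefaction_depth"), depth)
  # the sample already at depth is untouched
  at_min <- which.min(colSums(counts))
  expect_equal(r$counts[, at_min], counts[, at_min])
  expect_identical(rarefy(tab, "min", seed = 4)$counts, r$counts)
  expect_error(rarefy(tab, 0), "depth")
  expect_warning(rarefy(tab, depth + 1, seed = 1), "dropping")
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- matrix(c(60, 30, 10), 3, 1, dimnames = list(
    as.character(101:103), "s1"))
  tab <- toy_table(counts)
  depth <- 50
  draws <- sapply(1:500, function(s) rarefy(tab, depth, seed = s)$counts[, 1])
  expected <- depth * counts[, 1] / sum(counts)
  se <- sqrt(depth * (counts[, 1] / 100) * (1 - counts[, 1] / 100) *
               (100 - depth) / 99) / sqrt(500)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se))
})

test_that("prevalence is any-read presence and commutes with reordering", {
  counts <- matrix(c(0, 1, 5, 0), 2, 2,
                   dimnames = list(c("101", "102"), c("a", "b")))
  tab <- toy_table(counts)
  r <- rarefy(tab, 1, seed = 1)
  pv <- prevalence(r)
  expect_type(pv$presence[1, 1], "logical")
  # count 1 -> present; count 0 -> absent (on the rarefied table)
  expect_equal(unname(pv$presence), unname(r$counts >= 1))
  # taxon reordering commutes through rarefy + prevalence
  set.seed(3)
  big <- toy_table(matrix(rpois(40, 20), 4, 10,
                          dimnames = list(as.character(101:104), NULL)))
  perm <- c(3, 1, 4, 2)
  ptab <- toy_table(big$counts[perm, ],
                    taxon_names = taxon_names(big)[perm])
  p1 <- prevalence(rarefy(big, "min", seed = 6))$presence
  p2 <- prevalence(rarefy(ptab, "min", seed = 6))$presence
  expect_equal(p1[rownames(p2), ], p2)
  # warning when prevalence is taken from unrarefied counts
  expect_warning(prevalence(big), "rarefied")
})
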