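# Bipartite microbe-gene networks: correlation, edge selection,
# centralities, the random-matrix null, degree diagnostics, enrichment.

test_that("bulk correlation equals the pairwise statistic", {
  set.seed(81)
  micro <- matrix(rnorm(5 * 20), 5, 20,
                  dimnames = list(paste0("m", 1:5), paste0("s", 1:20)))
  genes <- matrix(rnorm(4 * 20), 4, 20,
                  dimnames = list(paste0("g", 1:4), paste0("s", 1:20)))
  genes[1, ] <- micro[1, ]                       # identical -> rho 1
  res <- correlate_microbes_genes(micro, genes)
  expect_equal(nrow(res), 20L)
  expect_equal(res$rho[res$microbe == "m1" & res$gene == "g1"], 1)
  for (i in c(2, 7, 13)) {
    r <- spearman_assoc(micro[res$microbe[i], ], genes[res$gene[i], ])
    expect_equal(res$rho[i], r$rho, tolerance = 1e-12)
    expect_equal(res$p[i], r$p, tolerance = 1e-10)
  }
  expect_error(correlate_microbes_genes(micro[, 1:3, drop = FALSE],
                                        genes[, 1:3, drop = FALSE]),
               "shared samples")
})

test_that("edge selection keeps the extreme tails of concordant pairs", {
  set.seed(82)
  n <- 40
  pairs <- data.frame(microbe = paste0("m", 1:n), gene = paste0("g", 1:n),
                      rho_a = runif(n, 0.1, 0.9), p_a = 0.01,
                      rho_b = seq(0.01, 0.9, length.out = n), p_b = 0.01)
  pairs$concordant <- TRUE
  e <- concordant_edge_select(pairs)
  expect_equal(nrow(e), 2L)                      # 1 top + 1 bottom
  expect_setequal(e$weight, range(pairs$rho_b))
  disc <- transform(pairs, concordant = FALSE)
  expect_equal(nrow(concordant_edge_select(disc)), 0L)
  expect_error(concordant_edge_select(pairs, tail_fraction = 0.5), "0.5")
})

test_that("edge selection equals brute-force sort-and-slice", {
  set.seed(83)
  n <- 1000
  pairs <- data.frame(microbe = sample(paste0("m", 1:50), n, TRUE),
                      gene = paste0("g", 1:n),
                      rho_a = runif(n, -1, 1), p_a = 0.5,
                      rho_b = runif(n, -1, 1), p_b = 0.5)
  pairs$concordant <- sign(pairs$rho_a) == sign(pairs$rho_b)
  e <- concordant_edge_select(pairs, tail_fraction = 0.025)
  cc <- pairs[pairs$concordant, ]
  k <- floor(nrow(cc) * 0.025)
  srt <- cc[order(cc$rho_b), ]
  oracle <- rbind(head(srt, k), tail(srt, k))
  expect_setequal(paste(e$microbe, e$gene),
                  paste(oracle$microbe, oracle$gene))
})

test_that("centralities match hand values and path enumeration", {
  star <- data.frame(microbe = "m1", gene = paste0("g", 1:5),
                     rho_a = 0.5, rho_b = 0.5, weight = 0.5)
  net <- build_network(star)
  expect_equal(net$nodes$degree[net$nodes$node == "m1"], 5)
  expect_true(all(net$nodes$degree[net$nodes$type == "gene"] == 1))
  # degree bookkeeping: microbe side = gene side = edge count
  expect_equal(sum(net$nodes$degree[net$nodes$type == "microbe"]),
               nrow(star))
  expect_equal(sum(net$nodes$degree[net$nodes$type == "gene"]),
               nrow(star))
  # path m1 - g1 - m2: the middle gene carries the one shortest path
  path <- data.frame(microbe = c("m1", "m2"), gene = "g1",
                     rho_a = 0.5, rho_b = 0.5, weight = 0.5)
  np <- build_network(path)
  expect_equal(np$nodes$betweenness[np$nodes$node == "g1"], 1)
  # larger toy graph against exhaustive enumeration
  edges <- data.frame(microbe = c("m1", "m1", "m2", "m2", "m3"),
                      gene = c("g1", "g2", "g2", "g3", "g3"),
                      rho_a = 0.5, rho_b = 0.5, weight = 0.5)
  nb <- build_network(edges)
  ob <- oracle_betweenness(as.matrix(edges[, c("microbe", "gene")]))
  for (v in nb$nodes$node) {
    expect_equal(nb$nodes$betweenness[nb$nodes$node == v],
                 unname(ob[v]), tolerance = 1e-12)
  }
  # disconnected components: harmonic closeness stays finite
  two <- data.frame(microbe = c("m1", "m2"), gene = c("g1", "g2"),
                    rho_a = 0.5, rho_b = 0.5, weight = 0.5)
  nh <- build_network(two, closeness = "harmonic")
  expect_true(all(is.finite(nh$nodes$closeness)))
})

test_that("random-matrix null gives ~50% concordance and normal degrees", {
  rn <- random_network_null(n_samples = 50, n_microbes = 40, n_genes = 200,
                            replicates = 3, seed = 91)
  # concordance of two independent sign draws is a fair coin
  se <- sqrt(0.25 / (40 * 200))
  expect_true(all(abs(rn$concordant_fraction - 0.5) < 4 * se))
  expect_true(all(rn$n_edges >= 2 * floor(rn$n_concordant * 0.025)))
  expect_true(all(rn$n_edges <= 0.06 * rn$n_concordant))
  rn2 <- random_network_null(n_samples = 50, n_microbes = 40,
                             n_genes = 200, seed = 91)
  strip <- function(x) { attr(x, "degrees") <- NULL; x[1, ] }
  expect_identical(strip(rn2), strip(rn))         # seeded determinism
})

test_that("power-law degrees are recovered; binomial degrees are not", {
  set.seed(92)
  # discrete power law alpha = 2.5 via weighted sampling on 1..5000
  supp <- 1:5000
  w <- supp^-2.5
  d <- sample(supp, 500, replace = TRUE, prob = w / sum(w))
  f <- degree_distribution_fit(d)
  expect_lt(abs(f$alpha - 2.5), 0.3)
  expect_true(f$heavy_tail)
  b <- rbinom(500, 100, 0.3)
  fb <- degree_distribution_fit(b)
  expect_false(fb$heavy_tail)
  expect_true(is.na(degree_distribution_fit(rep(3, 50))$alpha))
})

test_that("a planted hub microbe dominates degree centrality", {
  spec <- fixture_spec(n_samples = 60L, n_taxa = 50L, n_genes = 400L,
                       n_contaminants = 0L,
                       planted_hub = list(n_genes = 80, rho = 0.5),
                       seed = 23L)
  pair <- generate_cohort_pair(spec)
  logcpm <- function(m) log2(sweep(m + 0.5, 2, colSums(m) + 1, "/") * 1e6)
  pa <- correlate_microbes_genes(logcpm(named_counts(pair$A$table)),
                                 logcpm(pair$A$expression))
  pb <- correlate_microbes_genes(logcpm(named_counts(pair$B$table)),
                                 logcpm(pair$B$expression))
  edges <- concordant_edge_select(pair_correlations(pa, pb))
  net <- build_network(edges)
  mn <- net$nodes[net$nodes$type == "microbe", ]
  hub <- pair$truth$unit[pair$truth$kind == "hub_microbe"]
  expect_equal(mn$node[which.max(mn$degree)], hub)
  deg <- stats::setNames(rep(0L, 50), paste0("taxon_", 1:50))
  deg[mn$node] <- mn$degree
  expect_true(degree_distribution_fit(as.integer(deg))$heavy_tail)
})

test_that("preranked enrichment finds a planted extreme set", {
  set.seed(93)
  stats <- stats::setNames(sort(rnorm(100), decreasing = TRUE),
                           paste0("g", 1:100))
  sets <- list(planted = names(stats)[1:10],
               background = sample(names(stats), 12))
  res <- preranked_enrichment(stats, sets, n_permutations = 1000, seed = 3)
  pl <- res[res$set == "planted", ]
  expect_gt(pl$es, 0)
  expect_lte(pl$p, 0.01)
  expect_true(all(res$q >= res$p))
  w <- testthat::capture_warnings(
    preranked_enrichment(stats, c(sets, list(tiny = "g1")), seed = 3))
  expect_match(w, "below minimum size", all = FALSE)
  expect_error(suppressWarnings(preranked_enrichment(stats,
                                                     list(tiny = "g1"))),
               "no gene set")
})

test_that("random gene sets give well-spread enrichment p-values", {
  set.seed(94)
  stats <- stats::setNames(rnorm(200), paste0("g", 1:200))
  ps <- sapply(1:30, function(i) {
    sets <- list(s = sample(names(stats), 15))
    preranked_enrichment(stats, sets, n_permutations = 200,
                         seed = i)$p
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_gt(length(unique(round(ps, 3))), 10)
})
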