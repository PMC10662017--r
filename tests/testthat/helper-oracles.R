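# Small fixtures and brute-force oracles kept independent of the package
# implementation paths they check.

toy_table <- function(counts, taxon_names = NULL, human = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- as.character(seq_len(nrow(counts)) + 100L)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(taxon_names)) taxon_names <- paste0("tax_", rownames(counts))
  if (is.null(human)) human <- rep(1e6, ncol(counts))
  lin <- data.frame(taxid = as.integer(rownames(counts)),
                    name = taxon_names, rank = "species",
                    parent_taxid = NA_integer_)
  taxon_count_table(counts, lin,
                    stats::setNames(human, colnames(counts)))
}

# Brute-force permutation oracle for the frequency contaminant test,
# written independently: residual sums via explicit lm fits.
oracle_frequency_p <- function(abundance, concentration, n_perm = 10000,
                               seed = 99) {
  ok <- abundance > 0 & concentration > 0
  y <- log(abundance[ok]); x <- log(concentration[ok])
  rss <- function(yy, slope, xx) {
    a <- mean(yy - slope * xx)           # LS intercept at fixed slope
    sum((yy - slope * xx - a)^2)
  }
  lam <- function(xx) {
    s1 <- rss(y, -1, xx); s0 <- rss(y, 0, xx)
    s1 / (s1 + s0)
  }
  obs <- lam(x)
  set.seed(seed)
  hits <- 0
  for (i in seq_len(n_perm)) {
    if (lam(sample(x)) <= obs) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# 1-parameter Cox partial likelihood (Breslow form; oracle cases use
# distinct event times so Breslow = Efron) maximized by golden-section.
oracle_cox <- function(presence, time, event) {
  x <- as.numeric(presence)
  pll <- function(beta) {
    s <- 0
    for (i in which(event)) {
      at_risk <- time >= time[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[at_risk])))
    }
    s
  }
  opt <- stats::optimize(pll, interval = c(-10, 10), maximum = TRUE,
                         tol = 1e-9)
  lrt <- 2 * (opt$objective - pll(0))
  list(log_hr = opt$maximum,
       p = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

# Hand step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  prev <- Inf
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- min(val, 1)
    prev <- val
  }
  q
}

# Spearman rho as Pearson on midranks (direct formula).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive shortest-path betweenness on a tiny undirected graph given
# as an edge list of node-name pairs.
oracle_betweenness <- function(edges) {
  nodes <- unique(c(edges[, 1], edges[, 2]))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges[i, 1], edges[i, 2]] <- TRUE
    adj[edges[i, 2], edges[i, 1]] <- TRUE
  }
  # all shortest paths between a pair by DFS over BFS-leveled graph
  all_paths <- function(s, t) {
    dist <- rep(Inf, n); names(dist) <- nodes
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in nodes[adj[u, ]]) {
        if (dist[v] > dist[u] + 1) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (u == t) { paths[[length(paths) + 1]] <<- path; return() }
      for (v in nodes[adj[u, ]]) {
        if (dist[v] == dist[u] + 1 && dist[v] <= dist[t]) walk(c(path, v))
      }
    }
    walk(s)
    paths
  }
  btw <- stats::setNames(rep(0, n), nodes)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ps <- all_paths(nodes[i], nodes[j])
    if (!length(ps)) next
    for (p in ps) {
      inner <- setdiff(p, c(nodes[i], nodes[j]))
      for (u in inner) btw[u] <- btw[u] + 1 / length(ps)
    }
  }
  btw
}
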