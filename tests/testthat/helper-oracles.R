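# Independent brute-force oracles. These deliberately avoid igraph and the
# package's own code paths: Floyd-Warshall over an adjacency matrix, explicit
# double loops for the proximity measures, midranks computed by counting.

# all-pairs shortest paths by Floyd-Warshall; nodes = symbols, edges = 2-col df
oracleFloydWarshall <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]
    b <- edges[i, 2]
    if (a != b) d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# closest-distance proximity: mean over h of min_d dist(h, d); h with no
# reachable d dropped from numerator and divisor
oracleClosestProximity <- function(dm, H, D) {
  vals <- c()
  for (h in H) {
    best <- Inf
    for (d in D) if (dm[h, d] < best) best <- dm[h, d]
    if (is.finite(best)) vals <- c(vals, best)
  }
  if (length(vals) == 0) stop("no reachable source")
  as.numeric(sum(vals) / length(vals))
}

# weighted all-pairs proximity with unreachable pairs excluded from both sums
oracleWeightedProximity <- function(dm, H, D, wH, wD) {
  num <- 0
  den <- 0
  for (h in H) {
    for (d in D) {
      if (is.finite(dm[h, d])) {
        num <- num + dm[h, d] * wH[h] * wD[d]
        den <- den + wH[h] * wD[d]
      }
    }
  }
  if (den == 0) stop("no reachable pair")
  as.numeric(num / den)
}

# midranks by counting (no call to rank())
oracleMidranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

# Spearman as Pearson on midranks
oracleSpearman <- function(x, y) {
  rx <- oracleMidranks(x)
  ry <- oracleMidranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Erdos-Renyi-ish random connected-ish test graph as an edge data frame
randomEdgeTable <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  # guarantee at least a spanning path so most pairs are reachable
  spine <- cbind(nodes[-n], nodes[-1])
  ed <- unique(rbind(pairs[keep, , drop = FALSE], spine))
  data.frame(a = ed[, 1], b = ed[, 2], stringsAsFactors = FALSE)
}
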