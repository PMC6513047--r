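# Shared fixtures: micro-scale phantom configurations keep per-test runtime
# small; geometry-sensitive checks use the desk scale (256 x 512 x 24).

microConfig <- function(...) {
  args <- list(nRows = 128L, nCols = 256L, nSlices = 12L)
  args[names(list(...))] <- list(...)
  do.call(phantomConfig, args)
}

# a tiny but structurally complete network: full 7-layer topology, few filters
tinyNetConfig <- function(poolingMode = "literal")
  networkConfig(filterWidths = c(4L, 8L, 8L, 8L, 16L, 16L, 16L),
                inputShape = c(48L, 64L), poolingMode = poolingMode)

tinyImage <- function(seed = 1, d = c(48, 64)) {
  withr::with_seed(seed, matrix(runif(prod(d)), d[1], d[2]))
}

# independent flood-fill labeling oracle built on igraph connectivity
floodFillOracle <- function(bw) {
  idx <- which(bw)
  if (length(idx) == 0) return(matrix(0L, nrow(bw), ncol(bw)))
  H <- nrow(bw)
  rr <- (idx - 1) %% H + 1
  cc <- (idx - 1) %/% H + 1
  edges <- integer(0)
  pos <- matrix(0L, nrow(bw), ncol(bw))
  pos[idx] <- seq_along(idx)
  for (k in seq_along(idx)) {
    for (dc in -1:1) for (dr in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- rr[k] + dr; c2 <- cc[k] + dc
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= ncol(bw) &&
          bw[r2, c2] && pos[r2, c2] > k)
        edges <- c(edges, k, pos[r2, c2])
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab <- matrix(0L, nrow(bw), ncol(bw))
  lab[idx] <- comp
  lab
}

# brute-force Otsu: try every histogram cut, maximise between-class variance
otsuOracle <- function(v, nBins = 256L) {
  v <- as.numeric(v)
  edges <- seq(min(v), max(v), length.out = nBins + 1)
  idx <- pmin(nBins, findInterval(v, edges, rightmost.closed = TRUE))
  counts <- tabulate(idx, nBins)
  centers <- (edges[-1] + edges[-(nBins + 1)]) / 2
  best <- -Inf; bestCut <- NA
  for (cut in 1:(nBins - 1)) {
    n0 <- sum(counts[1:cut]); n1 <- sum(counts[(cut + 1):nBins])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:cut] * centers[1:cut]) / n0
    m1 <- sum(counts[(cut + 1):nBins] * centers[(cut + 1):nBins]) / n1
    v_b <- n0 * n1 * (m0 - m1)^2
    if (v_b > best) { best <- v_b; bestCut <- cut }
  }
  edges[bestCut + 1]
}

# transitive-closure region grouping oracle: O(n^2) pairwise union-find
groupRegionsOracle <- function(flagged, gapT) {
  n <- length(flagged)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(flagged[i] - flagged[j]) <= gapT) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  lapply(unique(roots), function(r) sort(flagged[roots == r]))
}
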