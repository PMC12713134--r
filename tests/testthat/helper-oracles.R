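# Independent brute-force oracles used to validate the network metric and
# FDR implementations. These deliberately take different algorithmic routes
# than the package (Floyd-Warshall instead of Dijkstra, explicit simple-path
# enumeration instead of sigma products, p.adjust instead of a hand-rolled
# step-up).

makeNet <- function(incoming, outgoing, weight = 1, nodes = NULL) {
  ed <- data.frame(incoming = as.integer(incoming),
                   outgoing = as.integer(outgoing),
                   weight = as.numeric(weight))
  if (is.null(nodes)) nodes <- sort(unique(c(ed$incoming, ed$outgoing)))
  new("BehaviorNetwork", edges = ed, nodes = as.integer(nodes),
      multigraph = FALSE)
}

# Random weighted digraph. Weights are powers of two so that inverse-mode
# path lengths are exact in binary floating point (no spurious near-ties).
randomDigraph <- function(n, p = 0.4) {
  pairs <- expand.grid(from = seq_len(n) - 1L, to = seq_len(n) - 1L)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  ed <- pairs[keep, , drop = FALSE]
  w <- sample(c(1, 2, 4, 8), nrow(ed), replace = TRUE)
  makeNet(ed$from, ed$to, w, nodes = seq_len(n) - 1L)
}

edgeLengthsOracle <- function(weight, mode) {
  switch(mode, raw = weight, inverse = 1 / weight,
         unweighted = rep(1, length(weight)))
}

# Floyd-Warshall all-pairs shortest distances with shortest-path counts.
fwOracle <- function(net, mode = "raw") {
  nodes <- nodeIds(net)
  n <- length(nodes)
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(d) <- 0
  diag(sigma) <- 1
  ed <- edgeTable(net)
  if (nrow(ed)) {
    len <- edgeLengthsOracle(ed$weight, mode)
    for (k in seq_len(nrow(ed))) {
      i <- match(ed$incoming[k], nodes); j <- match(ed$outgoing[k], nodes)
      if (len[k] < d[i, j]) { d[i, j] <- len[k]; sigma[i, j] <- 1 }
      else if (len[k] == d[i, j]) sigma[i, j] <- sigma[i, j] + 1
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == k || !is.finite(d[i, k])) next
      for (j in seq_len(n)) {
        if (j == k || j == i || !is.finite(d[k, j])) next
        alt <- d[i, k] + d[k, j]
        if (alt < d[i, j] - 1e-9) {
          d[i, j] <- alt
          sigma[i, j] <- sigma[i, k] * sigma[k, j]
        } else if (abs(alt - d[i, j]) <= 1e-9) {
          sigma[i, j] <- sigma[i, j] + sigma[i, k] * sigma[k, j]
        }
      }
    }
  }
  sigma[!is.finite(d)] <- 0
  dimnames(d) <- dimnames(sigma) <- list(nodes, nodes)
  list(nodes = nodes, dist = d, sigma = sigma)
}

fwWiener <- function(net, mode = "raw") {
  d <- fwOracle(net, mode)$dist
  diag(d) <- 0
  sum(d[is.finite(d)])
}

fwVitality <- function(net, node, mode = "raw") {
  nodes <- nodeIds(net)
  ed <- edgeTable(net)
  keep <- ed$incoming != node & ed$outgoing != node
  sub <- new("BehaviorNetwork", edges = ed[keep, , drop = FALSE],
             nodes = setdiff(nodes, node), multigraph = FALSE)
  dG <- fwOracle(net, mode)$dist
  dH <- fwOracle(sub, mode)$dist
  others <- match(setdiff(nodes, node), nodes)
  if (any(is.finite(dG[others, others]) & !is.finite(dH)))
    return(-Inf)
  fwWiener(net, mode) - fwWiener(sub, mode)
}

# Betweenness from the Floyd-Warshall sigma matrices (combinatorial route,
# independent of the package's Dijkstra accumulation).
fwBetweenness <- function(net, mode = "raw") {
  o <- fwOracle(net, mode)
  n <- length(o$nodes)
  cb <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v) next
      if (!is.finite(o$dist[s, t])) next
      if (is.finite(o$dist[s, v]) && is.finite(o$dist[v, t]) &&
          abs(o$dist[s, v] + o$dist[v, t] - o$dist[s, t]) <= 1e-9)
        acc <- acc + o$sigma[s, v] * o$sigma[v, t] / o$sigma[s, t]
    }
    cb[v] <- acc
  }
  names(cb) <- o$nodes
  cb
}

# Path-enumeration betweenness: enumerate every simple path, keep those of
# minimal length per ordered pair. Only viable for tiny graphs.
enumBetweenness <- function(net, mode = "raw") {
  nodes <- nodeIds(net)
  n <- length(nodes)
  ed <- edgeTable(net)
  len <- if (nrow(ed)) edgeLengthsOracle(ed$weight, mode) else numeric(0)
  adj <- lapply(seq_len(n), function(i) {
    k <- which(ed$incoming == nodes[i])
    list(to = match(ed$outgoing[k], nodes), len = len[k])
  })
  paths <- function(s, t) {
    found <- list()
    recurse <- function(v, visited, dist, path) {
      if (v == t) {
        found[[length(found) + 1L]] <<- list(dist = dist, path = path)
        return()
      }
      a <- adj[[v]]
      for (k in seq_along(a$to)) {
        u <- a$to[k]
        if (u %in% visited) next
        recurse(u, c(visited, u), dist + a$len[k], c(path, u))
      }
    }
    recurse(s, s, 0, s)
    found
  }
  cb <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    ps <- paths(s, t)
    if (!length(ps)) next
    dmin <- min(vapply(ps, `[[`, numeric(1), "dist"))
    sp <- ps[vapply(ps, function(x) abs(x$dist - dmin) <= 1e-9, logical(1))]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(sp, function(x) v %in% x$path, logical(1)))
      cb[v] <- cb[v] + through / length(sp)
    }
  }
  names(cb) <- nodes
  cb
}

# Reference two-stage BKY step-up built on stats::p.adjust threshold
# comparisons (rejection decisions only).
refBkyReject <- function(p, q = 0.05) {
  m <- length(p)
  qp <- q / (1 + q)
  r1 <- sum(p.adjust(p, "BH") <= qp)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  p.adjust(p, "BH") <= qp * m / m0
}

randomValidSequence <- function(Tn, n) {
  e <- integer(Tn)
  e[1] <- sample.int(n, 1L) - 1L
  for (t in 2:Tn) {
    repeat {
      x <- sample.int(n, 1L) - 1L
      if (x != e[t - 1L]) break
    }
    e[t] <- x
  }
  e
}
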