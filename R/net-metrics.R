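#' @include AllClasses.R transitions.R
NULL

## Collapse a (possibly multigraph) network to one weighted edge per ordered
## node pair. Replication preserves total weight, so this is the inverse of
## replicateEdges for metric purposes.
collapseEdges <- function(net) {
  ed <- edgeTable(net)
  if (nrow(ed) == 0L) return(ed)
  key <- paste(ed$incoming, ed$outgoing)
  w <- tapply(ed$weight, key, sum)
  first <- !duplicated(key)
  out <- data.frame(incoming = ed$incoming[first],
                    outgoing = ed$outgoing[first],
                    weight = as.numeric(w[key[first]]))
  out[order(out$incoming, out$outgoing), , drop = FALSE]
}

edgeLengths <- function(weights, weightMode) {
  len <- switch(weightMode,
    raw = weights,
    inverse = 1 / weights,
    unweighted = rep(1, length(weights)),
    stop("weightMode must be one of 'raw', 'inverse', 'unweighted'"))
  if (any(!is.finite(len)) || any(len <= 0))
    stop("nonpositive or non-finite edge length after weight transform")
  len
}

#' All-pairs shortest-path distances and path counts
#'
#' Runs Dijkstra's algorithm from every source on the collapsed weighted
#' digraph, tracking the number of distinct shortest paths per ordered pair.
#' The weight mode fixes how transition frequencies enter path length:
#' `raw` treats the frequency itself as the edge length (the convention of
#' the graph library the network measures are defined in), `inverse` uses
#' 1/frequency so that frequent transitions are short, and `unweighted`
#' ignores weights.
#'
#' @param net a [BehaviorNetwork-class].
#' @param weightMode one of "raw", "inverse", "unweighted".
#' @return List with `nodes` (integer ids), `dist` (n x n matrix, Inf for
#'   unreachable ordered pairs, 0 on the diagonal) and `sigma` (matrix of
#'   shortest-path counts; 0 for unreachable pairs).
#' @export
allPairsDistances <- function(net, weightMode = c("raw", "inverse",
                                                  "unweighted")) {
  weightMode <- match.arg(weightMode)
  nodes <- nodeIds(net)
  n <- length(nodes)
  ed <- collapseEdges(net)
  len <- if (nrow(ed)) edgeLengths(ed$weight, weightMode) else numeric(0)
  from <- match(ed$incoming, nodes)
  to <- match(ed$outgoing, nodes)
  ## adjacency lists
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(to = integer(0), len = numeric(0))
  for (k in seq_along(from)) {
    adj[[from[k]]]$to <- c(adj[[from[k]]]$to, to[k])
    adj[[from[k]]]$len <- c(adj[[from[k]]]$len, len[k])
  }
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  tol <- 1e-9
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sg <- rep(0, n); sg[s] <- 1
    done <- rep(FALSE, n)
    repeat {
      d_open <- replace(d, done, Inf)
      u <- which.min(d_open)
      if (!is.finite(d_open[u])) break
      done[u] <- TRUE
      nb <- adj[[u]]
      for (k in seq_along(nb$to)) {
        v <- nb$to[k]
        alt <- d[u] + nb$len[k]
        eps <- tol * max(1, abs(alt))
        if (alt < d[v] - eps) {
          d[v] <- alt
          sg[v] <- sg[u]
        } else if (is.finite(d[v]) && abs(alt - d[v]) <= eps) {
          sg[v] <- sg[v] + sg[u]
        }
      }
      if (all(done | !is.finite(d))) break
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
    sigma[s, !is.finite(d)] <- 0
  }
  list(nodes = nodes, dist = dist, sigma = sigma)
}

#' Wiener index of a behavior network
#'
#' Sum of shortest-path distances over all ordered reachable node pairs.
#'
#' @inheritParams allPairsDistances
#' @param oracle optional precomputed result of [allPairsDistances()].
#' @return Numeric W_G.
#' @export
wienerIndex <- function(net, weightMode = "raw", oracle = NULL) {
  if (is.null(oracle)) oracle <- allPairsDistances(net, weightMode)
  d <- oracle$dist
  diag(d) <- 0
  sum(d[is.finite(d)])
}

dropNode <- function(net, node) {
  ed <- edgeTable(net)
  keep <- ed$incoming != node & ed$outgoing != node
  new("BehaviorNetwork", edges = ed[keep, , drop = FALSE],
      nodes = setdiff(nodeIds(net), node), multigraph = net@multigraph)
}

#' Closeness vitality of a node
#'
#' The change in the Wiener index when the node is removed:
#' W(G) - W(G \ v). A node whose removal disconnects pairs that were
#' previously connected makes the residual sum of distances blow up; such
#' removals are reported as `-Inf` so distributions keep one entry per node.
#'
#' @inheritParams allPairsDistances
#' @param node node id.
#' @param oracle optional precomputed [allPairsDistances()] of `net`.
#' @return Numeric vitality, or `-Inf` for a disconnecting removal.
#' @export
closenessVitality <- function(net, node, weightMode = "raw", oracle = NULL) {
  if (!node %in% nodeIds(net)) stop("unknown node: ", node)
  oracleG <- if (is.null(oracle)) allPairsDistances(net, weightMode)
             else oracle
  sub <- dropNode(net, node)
  oracleH <- allPairsDistances(sub, weightMode)
  keep <- match(oracleH$nodes, oracleG$nodes)
  wasFinite <- is.finite(oracleG$dist[keep, keep, drop = FALSE])
  nowFinite <- is.finite(oracleH$dist)
  if (any(wasFinite & !nowFinite)) return(-Inf)
  wienerIndex(net, weightMode, oracle = oracleG) -
    wienerIndex(sub, weightMode, oracle = oracleH)
}

#' Node strength (weighted edge count)
#'
#' Total weight of edges incident to a node in the chosen direction. On a
#' replicated multigraph this equals the count of parallel unit edges, so
#' the two edge-count conventions agree numerically.
#'
#' @param net a [BehaviorNetwork-class].
#' @param node node id; or NULL for all nodes.
#' @param direction one of "total", "in", "out".
#' @return Named numeric vector (or scalar for a single node).
#' @export
strength <- function(net, node = NULL, direction = c("total", "in", "out")) {
  direction <- match.arg(direction)
  nodes <- nodeIds(net)
  ed <- edgeTable(net)
  outw <- vapply(nodes, function(v) sum(ed$weight[ed$incoming == v]),
                 numeric(1))
  inw <- vapply(nodes, function(v) sum(ed$weight[ed$outgoing == v]),
                numeric(1))
  s <- switch(direction, total = outw + inw, `in` = inw, out = outw)
  names(s) <- nodes
  if (is.null(node)) return(s)
  if (!node %in% nodes) stop("unknown node: ", node)
  unname(s[as.character(node)])
}

## total unweighted degree (count of distinct directed incident edges)
totalDegree <- function(net) {
  nodes <- nodeIds(net)
  ed <- collapseEdges(net)
  k <- vapply(nodes, function(v)
    sum(ed$incoming == v) + sum(ed$outgoing == v), numeric(1))
  names(k) <- nodes
  k
}

#' Average neighbor degree of a node
#'
#' For node i with strength s_i > 0 and neighborhood N_i (union of
#' predecessors and successors): (1/s_i) * sum over j in N_i of w_ij * k_j,
#' where w_ij is the summed weight of all edges between i and j in either
#' direction and k_j is j's total unweighted degree. Nodes with zero
#' strength have no defined value and return NA.
#'
#' @param net a [BehaviorNetwork-class].
#' @param node node id, or NULL for all nodes.
#' @return Named numeric vector (or scalar).
#' @export
averageNeighborDegree <- function(net, node = NULL) {
  nodes <- nodeIds(net)
  ed <- collapseEdges(net)
  s <- strength(net, direction = "total")
  k <- totalDegree(net)
  val <- vapply(nodes, function(i) {
    inc <- ed$incoming == i | ed$outgoing == i
    if (!any(inc) || s[as.character(i)] == 0) return(NA_real_)
    sub <- ed[inc, , drop = FALSE]
    j <- ifelse(sub$incoming == i, sub$outgoing, sub$incoming)
    wij <- tapply(sub$weight, j, sum)
    sum(wij * k[names(wij)]) / s[as.character(i)]
  }, numeric(1))
  names(val) <- nodes
  if (is.null(node)) return(val)
  if (!node %in% nodes) stop("unknown node: ", node)
  unname(val[as.character(node)])
}

#' Average degree connectivity
#'
#' Groups nodes by total unweighted degree k and averages their
#' [averageNeighborDegree()] values; isolated nodes (degree 0) are
#' excluded. Lower values across the degree range indicate a more dispersed,
#' less connected network.
#'
#' @param net a [BehaviorNetwork-class].
#' @return data.frame with columns `degree` and `value`, one row per
#'   observed degree.
#' @export
averageDegreeConnectivity <- function(net) {
  if (length(nodeIds(net)) == 0L) stop("empty network")
  k <- totalDegree(net)
  annd <- averageNeighborDegree(net)
  keep <- k > 0 & !is.na(annd)
  if (!any(keep))
    return(data.frame(degree = numeric(0), value = numeric(0)))
  agg <- tapply(annd[keep], k[keep], mean)
  data.frame(degree = as.numeric(names(agg)), value = as.numeric(agg),
             row.names = NULL)
}

#' Betweenness centrality
#'
#' For each node v, the sum over ordered pairs (s, t) with s != t, s != v,
#' t != v of the fraction of shortest s-t paths that pass through v;
#' unreachable pairs contribute 0. Unnormalized by default; with
#' `normalized = TRUE` values are divided by (n-1)(n-2).
#'
#' @inheritParams allPairsDistances
#' @param normalized logical.
#' @return Named numeric vector over all nodes.
#' @export
betweennessCentrality <- function(net, weightMode = "raw",
                                  normalized = FALSE) {
  oracle <- allPairsDistances(net, weightMode)
  d <- oracle$dist; sigma <- oracle$sigma
  n <- length(oracle$nodes)
  cb <- numeric(n)
  if (n >= 3L) {
    tol <- 1e-9
    for (v in seq_len(n)) {
      through <- outer(d[, v], d[v, ], "+")
      ok <- is.finite(d) & abs(through - d) <= tol * pmax(1, abs(d))
      cnt <- outer(sigma[, v], sigma[v, ])
      frac <- ifelse(ok & sigma > 0, cnt / sigma, 0)
      frac[v, ] <- 0; frac[, v] <- 0; diag(frac) <- 0
      cb[v] <- sum(frac)
    }
  }
  if (normalized && n > 2L) cb <- cb / ((n - 1) * (n - 2))
  names(cb) <- oracle$nodes
  cb
}

#' Closeness centrality (incoming paths)
#'
#' Reciprocal of the average shortest incoming path length to the node,
#' computed over the r nodes able to reach it and scaled by (r-1)/(n-1) so
#' that values on partially reachable digraphs remain comparable; on a
#' strongly connected graph this reduces to (n-1)/sum of incoming
#' distances. A node nothing reaches has closeness 0.
#'
#' @inheritParams allPairsDistances
#' @param node node id, or NULL for all nodes.
#' @return Named numeric vector (or scalar).
#' @export
closenessCentrality <- function(net, node = NULL, weightMode = "raw") {
  oracle <- allPairsDistances(net, weightMode)
  n <- length(oracle$nodes)
  val <- vapply(seq_len(n), function(u) {
    din <- oracle$dist[, u]
    reach <- is.finite(din)
    r <- sum(reach)  # includes u itself (d(u,u) = 0)
    if (r <= 1L || n == 1L) return(0)
    tot <- sum(din[reach])
    ((r - 1) / tot) * ((r - 1) / (n - 1))
  }, numeric(1))
  names(val) <- oracle$nodes
  if (is.null(node)) return(val)
  if (!node %in% oracle$nodes) stop("unknown node: ", node)
  unname(val[as.character(node)])
}

#' First-quartile and robust-max summary of a distribution
#'
#' The first quartile uses linear interpolation; the robust max is the mean
#' of the three largest values (undefined, NA, for fewer than 3 values).
#'
#' @param values numeric vector.
#' @return List with `first_quartile` and `robust_max`.
#' @examples
#' summarizeDistribution(c(1, 2, 3, 4, 5)) # Q1 = 2, robust max = 4
#' @export
summarizeDistribution <- function(values) {
  if (length(values) == 0L) stop("empty sample")
  q1 <- unname(stats::quantile(values, 0.25, type = 7))
  rmax <- if (length(values) >= 3L)
    mean(sort(values, decreasing = TRUE)[1:3]) else NA_real_
  list(first_quartile = q1, robust_max = rmax)
}

#' Node-level metric table for one network
#'
#' Computes all six network measures per node: strength (weighted edge
#' count), average neighbor degree, closeness vitality, betweenness
#' centrality and closeness centrality, plus the network's average degree
#' connectivity table.
#'
#' @inheritParams allPairsDistances
#' @return List with `nodes` (data.frame: node, strength,
#'   avg_neighbor_degree, closeness_vitality, betweenness, closeness) and
#'   `degree_connectivity` (data.frame: degree, value).
#' @export
nodeMetrics <- function(net, weightMode = "raw") {
  nodes <- nodeIds(net)
  oracle <- allPairsDistances(net, weightMode)
  vit <- vapply(nodes, function(v)
    closenessVitality(net, v, weightMode, oracle = oracle), numeric(1))
  tab <- data.frame(
    node = nodes,
    strength = as.numeric(strength(net)),
    avg_neighbor_degree = as.numeric(averageNeighborDegree(net)),
    closeness_vitality = vit,
    betweenness = as.numeric(betweennessCentrality(net, weightMode)),
    closeness = as.numeric(closenessCentrality(net, weightMode = weightMode)),
    row.names = NULL
  )
  list(nodes = tab, degree_connectivity = averageDegreeConnectivity(net))
}
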