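#' @include AllClasses.R
NULL

#' Count syllable-to-syllable transitions
#'
#' Builds the per-animal non-normalized transition matrix: cell (a, b) holds
#' the number of times syllable a was immediately followed by syllable b.
#' When `includedIds` is given, emissions outside the set are removed before
#' pairing; by default consecutive survivors become adjacent (so a
#' transition can bridge a dropped syllable), or with `breakAtGaps = TRUE`
#' the sequence is split at every dropped emission and pairs are only counted
#' within fragments.
#'
#' @param seq a [SyllableSequence-class] or integer vector (T >= 2).
#' @param includedIds optional integer set of syllables to retain.
#' @param breakAtGaps logical; see above.
#' @return A [TransitionMatrix-class] over the retained ids (the sorted
#'   included set if given, otherwise the sorted observed ids).
#' @examples
#' transitionCounts(countTransitions(c(2, 4, 2, 4)))
#' @export
countTransitions <- function(seq, includedIds = NULL, breakAtGaps = FALSE) {
  e <- if (is(seq, "SyllableSequence")) emissions(seq) else as.integer(seq)
  if (length(e) < 2L) stop("need at least 2 emissions (T >= 2)")
  if (is.null(includedIds)) {
    ids <- sort(unique(e))
    segs <- list(e)
  } else {
    includedIds <- sort(unique(as.integer(includedIds)))
    ids <- includedIds
    keep <- e %in% includedIds
    if (breakAtGaps) {
      grp <- cumsum(!keep)
      segs <- split(e[keep], grp[keep])
    } else {
      segs <- list(e[keep])
    }
  }
  n <- length(ids)
  counts <- matrix(0, n, n, dimnames = list(as.character(ids),
                                            as.character(ids)))
  for (s in segs) {
    if (length(s) < 2L) next
    from <- match(s[-length(s)], ids)
    to <- match(s[-1L], ids)
    tab <- table(factor(from, levels = seq_len(n)),
                 factor(to, levels = seq_len(n)))
    counts <- counts + unclass(tab)
  }
  dimnames(counts) <- list(as.character(ids), as.character(ids))
  new("TransitionMatrix", counts = counts)
}

#' Select the syllables explaining a usage coverage fraction
#'
#' Sorts syllables by descending usage (ties broken by ascending id) and
#' returns the smallest prefix whose cumulative usage fraction reaches
#' `coverage`. With the conventional 0.99 this mirrors restricting analysis
#' to the syllables that explain 99% of behavioral variance.
#'
#' @param usage named numeric vector of per-syllable usage counts (names =
#'   syllable ids), or an unnamed vector indexed by id 0..n-1.
#' @param coverage fraction in (0, 1]; default 0.99.
#' @return Sorted integer vector of included syllable ids.
#' @examples
#' syllableInclusion(c(`0` = 98, `1` = 1, `2` = 1), coverage = 0.99)
#' @export
syllableInclusion <- function(usage, coverage = 0.99) {
  if (length(usage) == 0L) stop("empty usage vector")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  ids <- if (is.null(names(usage))) seq_along(usage) - 1L
         else as.integer(names(usage))
  pos <- usage > 0
  ids <- ids[pos]; usage <- usage[pos]
  ord <- order(-usage, ids)
  cumfrac <- cumsum(usage[ord]) / sum(usage)
  k <- which(cumfrac >= coverage - 1e-12)[1L]
  sort(ids[ord][seq_len(k)])
}

#' Build a directed weighted network from a transition matrix
#'
#' One directed edge per nonzero cell, weighted by the transition count.
#' Nodes are the syllables with at least one incident transition;
#' `keepIsolated = TRUE` retains all matrix ids as nodes.
#'
#' @param m a [TransitionMatrix-class].
#' @param keepIsolated logical; keep ids without any transitions as isolated
#'   nodes.
#' @return A [BehaviorNetwork-class].
#' @export
buildNetwork <- function(m, keepIsolated = FALSE) {
  stopifnot(is(m, "TransitionMatrix"))
  cm <- transitionCounts(m)
  ids <- syllableIds(m)
  nz <- which(cm > 0, arr.ind = TRUE)
  edges <- data.frame(incoming = ids[nz[, 1L]], outgoing = ids[nz[, 2L]],
                      weight = cm[nz])
  edges <- edges[order(edges$incoming, edges$outgoing), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (keepIsolated) ids
           else sort(unique(c(edges$incoming, edges$outgoing)))
  new("BehaviorNetwork", edges = edges, nodes = as.integer(nodes),
      multigraph = FALSE)
}

#' Replicate weighted edges into parallel unit-weight edges
#'
#' An edge of weight w becomes w parallel edges of weight 1 (e.g. incoming 2
#' -> outgoing 4 with weight 20 becomes 20 unit edges). Total weight, and
#' hence every node's strength, is preserved.
#'
#' @param net a [BehaviorNetwork-class] with integer weights.
#' @return The multigraph [BehaviorNetwork-class].
#' @export
replicateEdges <- function(net) {
  stopifnot(is(net, "BehaviorNetwork"))
  ed <- edgeTable(net)
  if (any(ed$weight != round(ed$weight)))
    stop("edge replication requires integer weights")
  idx <- rep(seq_len(nrow(ed)), times = ed$weight)
  out <- data.frame(incoming = ed$incoming[idx], outgoing = ed$outgoing[idx],
                    weight = rep(1, length(idx)))
  new("BehaviorNetwork", edges = out, nodes = nodeIds(net),
      multigraph = TRUE)
}

#' Partition nodes into shared and group-specific sets
#'
#' A node is specific to a group when it appears in at least one of that
#' group's networks and in none of any other group's; all other observed
#' nodes are shared.
#'
#' @param netsByGroup named list: group -> list of
#'   [BehaviorNetwork-class] objects.
#' @return List with `shared` (integer ids) and `specific` (named list of
#'   integer id vectors, one per group).
#' @export
nodePartition <- function(netsByGroup) {
  if (length(netsByGroup) < 2L) stop("need at least 2 groups")
  if (any(!vapply(netsByGroup, length, integer(1))))
    stop("every group needs at least one network")
  groupNodes <- lapply(netsByGroup, function(nets)
    sort(unique(unlist(lapply(nets, nodeIds)))))
  allNodes <- sort(unique(unlist(groupNodes)))
  specific <- lapply(names(groupNodes), function(g) {
    others <- unique(unlist(groupNodes[names(groupNodes) != g]))
    sort(setdiff(groupNodes[[g]], others))
  })
  names(specific) <- names(groupNodes)
  list(shared = setdiff(allNodes, unlist(specific)), specific = specific)
}
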