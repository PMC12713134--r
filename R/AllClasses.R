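#' @import methods
NULL

#' SyllableSequence: one animal-session's syllable emissions
#'
#' Ordered integer syllable labels for a single animal and recording session,
#' together with its group and timepoint annotation. Motion-sequencing
#' syllables change at segment boundaries, so a valid sequence never contains
#' an immediate self-repeat (\code{S[t] != S[t+1]}).
#'
#' @slot animalId character scalar identifying the animal-session.
#' @slot group character scalar, experimental group (e.g. "naive",
#'   "epileptic").
#' @slot timepoint character scalar (e.g. "1.5w", "12w", "20w").
#' @slot emissions integer vector of 0-based syllable ids, in emission order.
#'
#' @seealso [syllableSequence()], [classifyTriplets()], [countTransitions()]
#' @exportClass SyllableSequence
setClass("SyllableSequence",
  representation(
    animalId = "character",
    group = "character",
    timepoint = "character",
    emissions = "integer"
  ),
  prototype(animalId = NA_character_, group = NA_character_,
            timepoint = NA_character_, emissions = integer(0))
)

setValidity("SyllableSequence", function(object) {
  e <- object@emissions
  msgs <- character(0)
  if (length(object@animalId) != 1L)
    msgs <- c(msgs, "animalId must be a single string")
  if (length(e) < 1L)
    msgs <- c(msgs, "sequence length < 1")
  if (anyNA(e))
    msgs <- c(msgs, "emissions contain NA")
  else {
    if (any(e < 0L))
      msgs <- c(msgs, "syllable ids must be >= 0")
    if (length(e) > 1L && any(e[-1L] == e[-length(e)]))
      msgs <- c(msgs, "immediate self-repeat: S[t] == S[t+1] is not allowed")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SyllableSequence
#'
#' @param emissions integer vector of 0-based syllable ids; no immediate
#'   self-repeats allowed.
#' @param animalId,group,timepoint annotation strings.
#' @return A [SyllableSequence-class] object.
#' @examples
#' syllableSequence(c(5L, 6L, 9L), animalId = "m1")
#' @export
syllableSequence <- function(emissions, animalId = "animal",
                             group = NA_character_,
                             timepoint = NA_character_) {
  if (is.numeric(emissions) && !is.integer(emissions)) {
    if (any(emissions != floor(emissions), na.rm = TRUE))
      stop("syllable ids must be integers")
    emissions <- as.integer(emissions)
  }
  new("SyllableSequence", animalId = as.character(animalId),
      group = as.character(group), timepoint = as.character(timepoint),
      emissions = emissions)
}

#' TransitionMatrix: syllable-to-syllable transition counts
#'
#' Square matrix of nonnegative transition counts. Rows index the incoming
#' syllable (the syllable at time t), columns the outgoing syllable (time
#' t+1); dimnames carry the syllable ids. Matrices are per-animal and
#' non-normalized: the grand total equals T - 1 for a length-T sequence with
#' no exclusions.
#'
#' @slot counts numeric matrix, square, nonnegative, with identical row and
#'   column dimnames (syllable ids as characters).
#' @seealso [countTransitions()], [buildNetwork()], [matrixToLong()]
#' @exportClass TransitionMatrix
setClass("TransitionMatrix", representation(counts = "matrix"))

setValidity("TransitionMatrix", function(object) {
  m <- object@counts
  msgs <- character(0)
  if (nrow(m) != ncol(m))
    msgs <- c(msgs, "counts must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "counts must carry syllable ids as dimnames")
  else if (!identical(rownames(m), colnames(m)))
    msgs <- c(msgs, "row and column syllable ids must match")
  if (any(m < 0))
    msgs <- c(msgs, "counts must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TransitionMatrix
#'
#' @param counts square nonnegative matrix; dimnames are syllable ids. If
#'   dimnames are missing, `syllableIds` must be given.
#' @param syllableIds optional integer vector of ids labelling rows/columns.
#' @return A [TransitionMatrix-class] object.
#' @export
transitionMatrix <- function(counts, syllableIds = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(syllableIds))
    dimnames(counts) <- list(as.character(syllableIds),
                             as.character(syllableIds))
  new("TransitionMatrix", counts = counts)
}

#' BehaviorNetwork: directed weighted syllable transition network
#'
#' Nodes are syllables; a directed edge incoming -> outgoing carries the
#' transition frequency as weight. In the replicated (multigraph)
#' representation an edge of weight w is expanded into w parallel unit-weight
#' edges; node-level strength is identical in either representation.
#'
#' @slot edges data.frame with integer columns `incoming`, `outgoing` and
#'   numeric `weight` (>= 1 per row).
#' @slot nodes integer vector of node (syllable) ids, including any
#'   explicitly retained isolated nodes.
#' @slot multigraph logical; TRUE after [replicateEdges()].
#' @seealso [buildNetwork()], [nodeMetrics()], [exportNetwork()]
#' @exportClass BehaviorNetwork
setClass("BehaviorNetwork",
  representation(edges = "data.frame", nodes = "integer",
                 multigraph = "logical"),
  prototype(edges = data.frame(incoming = integer(0), outgoing = integer(0),
                               weight = numeric(0)),
            nodes = integer(0), multigraph = FALSE)
)

setValidity("BehaviorNetwork", function(object) {
  ed <- object@edges
  msgs <- character(0)
  if (!all(c("incoming", "outgoing", "weight") %in% names(ed)))
    msgs <- c(msgs, "edges must have columns incoming, outgoing, weight")
  else {
    if (nrow(ed) && any(ed$weight < 1))
      msgs <- c(msgs, "edge weights must be >= 1")
    if (!all(c(ed$incoming, ed$outgoing) %in% object@nodes))
      msgs <- c(msgs, "edge endpoints must be listed in nodes")
  }
  if (length(msgs)) msgs else TRUE
})

#' AlternationProfile: triplet alternation structure of one sequence
#'
#' Binary indicators over all sliding three-syllable windows (1 =
#' non-repetitive, first and third syllables differ; 0 = repetitive), plus
#' the maximal run lengths of each value. Runs of 0s are perseveration bouts.
#'
#' @slot animalId,group,timepoint annotation copied from the source sequence.
#' @slot indicators integer vector b of length T - 2.
#' @slot repetitiveRuns integer lengths of maximal 0-runs, in order.
#' @slot nonrepetitiveRuns integer lengths of maximal 1-runs, in order.
#' @seealso [alternationProfile()], [nonrepetitiveFraction()]
#' @exportClass AlternationProfile
setClass("AlternationProfile",
  representation(animalId = "character", group = "character",
                 timepoint = "character", indicators = "integer",
                 repetitiveRuns = "integer", nonrepetitiveRuns = "integer")
)

setValidity("AlternationProfile", function(object) {
  b <- object@indicators
  msgs <- character(0)
  if (!all(b %in% c(0L, 1L)))
    msgs <- c(msgs, "indicators must be binary")
  if (sum(object@repetitiveRuns) + sum(object@nonrepetitiveRuns) != length(b))
    msgs <- c(msgs, "run lengths must partition the indicator sequence")
  if (length(msgs)) msgs else TRUE
})

#' CohortConfig: parameters of the synthetic cohort generator
#'
#' Describes a two-group, multi-timepoint cohort of synthetic syllable
#' sequences emulating motion-sequencing output. The generative model for one
#' sequence: the first two emissions are drawn from the group vocabulary
#' without immediate repeat; thereafter, with probability `returnBias` the
#' animal returns to the syllable two steps back (an A-B-A repetitive
#' alternation), otherwise it draws from the base distribution over the group
#' vocabulary excluding the previous syllable, with racing syllables' base
#' mass multiplied by the racing boost and renormalized.
#'
#' Group/timepoint structure: the case group has exclusive access to
#' `groupSpecificIds`; at chronic timepoints (all but the first) it receives
#' the elevated `returnBias` and `racingBoost`; at the final timepoint its
#' sequence length is shortened by `lengthFactor` (sedentary effect). The
#' control group uses `controlBias` throughout, no boost, full length.
#'
#' @slot nSyllables vocabulary size n; ids are 0..n-1.
#' @slot seqLength emissions per animal-session T.
#' @slot nAnimalsPerGroup animals per group per timepoint.
#' @slot returnBias probability of the return-to-S[t-2] branch for the case
#'   group at chronic timepoints, in [0, 1].
#' @slot controlBias same probability for the control group (and the case
#'   group at the first timepoint).
#' @slot groupSpecificIds syllable ids emitted only by the case group.
#' @slot racingIds syllable ids flagged as racing.
#' @slot racingBoost multiplier (>= 0) on racing ids' base mass for the case
#'   group at chronic timepoints.
#' @slot racingBaseWeight resting relative base mass of racing ids when
#'   `baseWeights` is empty (non-racing ids have mass 1). Racing is rare in
#'   unaffected animals, so the default is below 1; configs without racing
#'   ids keep an exactly uniform base.
#' @slot lengthFactor multiplier in (0, 1] on T for the case group at the
#'   final timepoint.
#' @slot baseWeights optional numeric vector of length n of relative base
#'   emission weights; empty means uniform.
#' @slot groups character(2): control group name, case group name.
#' @slot timepoints character vector of timepoint labels, in temporal order.
#' @slot seed master integer seed; per-animal seeds are derived from it.
#' @seealso [cohortConfig()], [simulateSequence()], [simulateCohort()]
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    nSyllables = "integer", seqLength = "integer",
    nAnimalsPerGroup = "integer", returnBias = "numeric",
    controlBias = "numeric", groupSpecificIds = "integer",
    racingIds = "integer", racingBoost = "numeric",
    racingBaseWeight = "numeric",
    lengthFactor = "numeric", baseWeights = "numeric",
    groups = "character", timepoints = "character", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character(0)
  n <- object@nSyllables
  if (n < 2L) msgs <- c(msgs, "nSyllables must be >= 2")
  for (nm in c("returnBias", "controlBias")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msgs <- c(msgs, paste(nm, "must be in [0, 1]"))
  }
  if (length(object@groupSpecificIds) &&
      (any(object@groupSpecificIds < 0L) ||
       any(object@groupSpecificIds >= n)))
    msgs <- c(msgs, "groupSpecificIds must lie in [0, nSyllables)")
  if (length(object@racingIds) &&
      (any(object@racingIds < 0L) || any(object@racingIds >= n)))
    msgs <- c(msgs, "racingIds must lie in [0, nSyllables)")
  if (object@racingBoost < 0) msgs <- c(msgs, "racingBoost must be >= 0")
  if (object@racingBaseWeight <= 0)
    msgs <- c(msgs, "racingBaseWeight must be > 0")
  if (object@lengthFactor <= 0 || object@lengthFactor > 1)
    msgs <- c(msgs, "lengthFactor must be in (0, 1]")
  if (floor(object@lengthFactor * object@seqLength) < 3)
    msgs <- c(msgs, "lengthFactor * seqLength must be >= 3")
  if (length(object@baseWeights) &&
      length(object@baseWeights) != n)
    msgs <- c(msgs, "baseWeights must have length nSyllables")
  if (length(object@baseWeights) && any(object@baseWeights < 0))
    msgs <- c(msgs, "baseWeights must be nonnegative")
  if (length(object@groups) != 2L || anyDuplicated(object@groups))
    msgs <- c(msgs, "groups must name two distinct groups (control, case)")
  if (length(object@timepoints) < 1L)
    msgs <- c(msgs, "at least one timepoint required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortConfig
#'
#' Defaults mirror a chronic-epilepsy motion-sequencing cohort: a 37-syllable
#' vocabulary of which 7 ids (30..36) are case-specific, racing flags on the
#' specific ids plus two shared ids, ~1500 emissions per 20-min session, 15
#' animals per group, and three timepoints.
#'
#' @param nSyllables,seqLength,nAnimalsPerGroup,returnBias,controlBias
#'   see [CohortConfig-class].
#' @param groupSpecificIds,racingIds,racingBoost,racingBaseWeight see
#'   [CohortConfig-class].
#' @param lengthFactor,baseWeights,groups,timepoints,seed see
#'   [CohortConfig-class].
#' @return A validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(nSyllables = 11, seqLength = 500, returnBias = 0.3)
#' @export
cohortConfig <- function(nSyllables = 37, seqLength = 1500,
                         nAnimalsPerGroup = 15,
                         returnBias = 0.35, controlBias = 0.05,
                         groupSpecificIds = 30:36,
                         racingIds = 28:36,
                         racingBoost = 5, racingBaseWeight = 0.3,
                         lengthFactor = 0.6,
                         baseWeights = numeric(0),
                         groups = c("naive", "epileptic"),
                         timepoints = c("1.5w", "12w", "20w"),
                         seed = 1L) {
  groupSpecificIds <- as.integer(groupSpecificIds)
  racingIds <- as.integer(racingIds)
  groupSpecificIds <- groupSpecificIds[groupSpecificIds < nSyllables]
  racingIds <- racingIds[racingIds < nSyllables]
  new("CohortConfig",
      nSyllables = as.integer(nSyllables),
      seqLength = as.integer(seqLength),
      nAnimalsPerGroup = as.integer(nAnimalsPerGroup),
      returnBias = as.numeric(returnBias),
      controlBias = as.numeric(controlBias),
      groupSpecificIds = groupSpecificIds,
      racingIds = racingIds,
      racingBoost = as.numeric(racingBoost),
      racingBaseWeight = as.numeric(racingBaseWeight),
      lengthFactor = as.numeric(lengthFactor),
      baseWeights = as.numeric(baseWeights),
      groups = as.character(groups),
      timepoints = as.character(timepoints),
      seed = as.integer(seed))
}
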