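#' @include AllClasses.R
NULL

#' Normalized per-animal syllable usage
#'
#' Occurrence count of each syllable divided by the total number of
#' emissions, so usage fractions sum to 1 for every animal.
#'
#' @param seq a [SyllableSequence-class] or integer vector (T >= 1).
#' @return Named numeric vector: syllable id -> usage fraction.
#' @export
usageFromSequence <- function(seq) {
  e <- if (is(seq, "SyllableSequence")) emissions(seq) else as.integer(seq)
  if (length(e) == 0L) stop("empty sequence")
  tab <- table(e)
  u <- as.numeric(tab) / length(e)
  names(u) <- names(tab)
  u
}

#' Binarize racing-syllable usage at a threshold
#'
#' For each racing-flagged syllable, 1 when the animal's normalized usage
#' strictly exceeds the threshold, else 0. The default 0.025 corresponds to
#' setting the threshold at the highest normalized racing usage observed in
#' aged control animals, which by construction makes all control entries 0
#' under strict exceedance.
#'
#' @param usage named usage vector from [usageFromSequence()].
#' @param labels a label map data.frame (see [readLabelMap()]) with columns
#'   `syllable_id`, `behavior_name`, `is_racing`.
#' @param threshold usage fraction; default 0.025.
#' @return Named integer vector (0/1) over all racing syllable ids.
#' @export
binarizeRacing <- function(usage, labels, threshold = 0.025) {
  if (threshold < 0) stop("threshold must be >= 0")
  rids <- sort(labels$syllable_id[labels$is_racing])
  if (length(rids) == 0L) {
    warning("label map flags no racing syllables")
    return(setNames(integer(0), character(0)))
  }
  u <- usage[as.character(rids)]
  u[is.na(u)] <- 0
  out <- as.integer(u > threshold)
  names(out) <- as.character(rids)
  out
}

#' Cohort-level binarized racing heatmap matrix
#'
#' @param cohort list of [SyllableSequence-class] objects.
#' @param labels label map data.frame.
#' @param threshold see [binarizeRacing()].
#' @return Integer matrix, racing syllables (rows) x animals (columns).
#' @export
racingHeatmap <- function(cohort, labels, threshold = 0.025) {
  cols <- lapply(cohort, function(s)
    binarizeRacing(usageFromSequence(s), labels, threshold))
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(cohort, animalId, character(1))
  m
}

#' Total racing and non-racing usage of an animal
#'
#' The two totals are complementary: they sum to 1.
#'
#' @param usage named usage vector.
#' @param labels label map data.frame.
#' @return Numeric fraction in [0, 1].
#' @export
racingUsageTotal <- function(usage, labels) {
  rids <- labels$syllable_id[labels$is_racing]
  sum(usage[names(usage) %in% as.character(rids)])
}

#' @rdname racingUsageTotal
#' @export
nonracingUsageTotal <- function(usage, labels) {
  rids <- labels$syllable_id[labels$is_racing]
  sum(usage[!names(usage) %in% as.character(rids)])
}

#' Behavior-name multiplicity table for a node list
#'
#' Counts how often each behavior name occurs among the given syllable ids
#' (the numbers that size words in a word cloud of the node list). Ids
#' absent from the label map count under "unlabeled".
#'
#' @param nodes integer syllable ids (repeats allowed).
#' @param labels label map data.frame.
#' @return Named integer vector: behavior name -> count.
#' @export
behaviorWordCounts <- function(nodes, labels) {
  if (length(nodes) == 0L) return(setNames(integer(0), character(0)))
  nm <- labels$behavior_name[match(nodes, labels$syllable_id)]
  nm[is.na(nm)] <- "unlabeled"
  tab <- table(nm)
  setNames(as.integer(tab), names(tab))
}
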