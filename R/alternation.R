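#' @include AllClasses.R
NULL

#' Classify sliding three-syllable windows as repetitive or not
#'
#' For every overlapping triplet (S[t], S[t+1], S[t+2]) the indicator b[t] is
#' 1 when the first and third syllables differ (a non-repetitive
#' alternation, e.g. 5,6,9) and 0 when they are identical (a repetitive
#' A-B-A alternation, e.g. 12,1,12).
#'
#' @param seq a [SyllableSequence-class] or an integer vector of syllable
#'   ids with at least 3 emissions.
#' @return Integer vector b of length T - 2.
#' @examples
#' classifyTriplets(c(5, 6, 9))   # 1
#' classifyTriplets(c(12, 1, 12)) # 0
#' @export
classifyTriplets <- function(seq) {
  e <- if (is(seq, "SyllableSequence")) emissions(seq) else as.integer(seq)
  Tn <- length(e)
  if (Tn < 3L)
    stop("alternation analysis needs at least 3 emissions (T >= 3)")
  as.integer(e[seq_len(Tn - 2L)] != e[3:Tn])
}

#' Fraction of non-repetitive alternations
#'
#' f = mean of the binary indicator sequence; 1 - f is the fraction of
#' repetitive (perseverative) windows.
#'
#' @param b binary indicator vector from [classifyTriplets()].
#' @return Numeric in [0, 1].
#' @export
nonrepetitiveFraction <- function(b) {
  if (length(b) == 0L) stop("empty indicator sequence")
  if (!all(b %in% c(0L, 1L))) stop("indicators must be binary")
  mean(b)
}

#' Run lengths of repetitive and non-repetitive bouts
#'
#' A run is a maximal contiguous block of constant value in the indicator
#' sequence. Runs of 0s are perseveration bouts (consecutive repetitive
#' alternations); runs of 1s are stretches of flexible behavior. Order is
#' preserved within each list.
#'
#' @param b binary indicator vector.
#' @return List with integer vectors `repetitive` (0-runs) and
#'   `nonrepetitive` (1-runs).
#' @examples
#' runLengths(c(1, 1, 0, 0, 0, 1))
#' @export
runLengths <- function(b) {
  if (length(b) == 0L) stop("empty indicator sequence")
  if (!all(b %in% c(0L, 1L))) stop("indicators must be binary")
  r <- rle(as.integer(b))
  list(repetitive = as.integer(r$lengths[r$values == 0L]),
       nonrepetitive = as.integer(r$lengths[r$values == 1L]))
}

#' Full alternation profile of a sequence
#'
#' @param seq a [SyllableSequence-class] (T >= 3).
#' @return An [AlternationProfile-class].
#' @export
alternationProfile <- function(seq) {
  stopifnot(is(seq, "SyllableSequence"))
  b <- classifyTriplets(seq)
  rl <- runLengths(b)
  new("AlternationProfile", animalId = animalId(seq),
      group = groupLabel(seq), timepoint = timepointLabel(seq),
      indicators = b, repetitiveRuns = rl$repetitive,
      nonrepetitiveRuns = rl$nonrepetitive)
}

#' @rdname nonrepetitiveFraction
#' @param x an [AlternationProfile-class].
#' @export
profileFraction <- function(x) {
  stopifnot(is(x, "AlternationProfile"))
  nonrepetitiveFraction(indicators(x))
}

#' Empirical cumulative frequency distribution in percent
#'
#' Transforms a sample into its empirical cumulative distribution using
#' relative frequency (percentage): for each distinct observed value v,
#' the percent of observations <= v.
#'
#' @param values nonempty numeric vector.
#' @return data.frame with columns `value` (sorted distinct values) and
#'   `cum_percent` (nondecreasing, ending at 100).
#' @examples
#' cumulativeDistribution(c(1, 1, 2))
#' @export
cumulativeDistribution <- function(values) {
  if (length(values) == 0L) stop("empty sample")
  v <- sort(unique(values))
  data.frame(value = v,
             cum_percent = 100 * stats::ecdf(values)(v))
}

#' Average several cumulative distributions on their union grid
#'
#' Each per-animal step CDF is evaluated (right-continuous) on the union of
#' all observed values; the average curve is the pointwise mean. Averaging a
#' set of identical CDFs returns the same CDF.
#'
#' @param cdfs list of data.frames as returned by
#'   [cumulativeDistribution()].
#' @return data.frame with `value` (union grid) and `cum_percent` (mean).
#' @export
averageDistributions <- function(cdfs) {
  if (length(cdfs) == 0L) stop("no distributions to average")
  grid <- sort(unique(unlist(lapply(cdfs, `[[`, "value"))))
  evalStep <- function(d) {
    ## right-continuous step interpolation; 0 before the first value
    idx <- findInterval(grid, d$value)
    c(0, d$cum_percent)[idx + 1L]
  }
  mat <- vapply(cdfs, evalStep, numeric(length(grid)))
  data.frame(value = grid,
             cum_percent = rowMeans(as.matrix(mat)))
}

#' Tabulate alternation profiles for a cohort
#'
#' @param cohort list of [SyllableSequence-class] objects.
#' @return List with `profiles` (data.frame: animal_id, group, timepoint, T,
#'   f, percent_repetitive) and `runs` (long data.frame: animal_id, group,
#'   timepoint, run_type, length).
#' @export
cohortAlternation <- function(cohort) {
  profs <- lapply(cohort, alternationProfile)
  tab <- data.frame(
    animal_id = vapply(profs, animalId, character(1)),
    group = vapply(profs, groupLabel, character(1)),
    timepoint = vapply(profs, timepointLabel, character(1)),
    T = vapply(cohort, seqLength, integer(1)),
    f = vapply(profs, profileFraction, numeric(1)),
    row.names = NULL
  )
  tab$percent_repetitive <- 100 * (1 - tab$f)
  oneType <- function(p, type, lens) {
    if (length(lens) == 0L) return(NULL)
    data.frame(animal_id = animalId(p), group = groupLabel(p),
               timepoint = timepointLabel(p), run_type = type,
               length = lens)
  }
  runs <- do.call(rbind, unlist(lapply(profs, function(p) {
    list(oneType(p, "repetitive", repetitiveRuns(p)),
         oneType(p, "nonrepetitive", nonrepetitiveRuns(p)))
  }), recursive = FALSE))
  rownames(runs) <- NULL
  list(profiles = tab, runs = runs)
}
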