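#' @include AllClasses.R
NULL

## Evaluate expr under a private RNG stream, restoring global state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Deterministic 31-bit string hash (polynomial rolling hash) used to derive
## independent per-animal seeds from the master seed.
stableHash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Derive the per-animal seed from a cohort's master seed
#'
#' Seeds are `(seed + hash(group|timepoint|index)) mod (2^31 - 1)`, so
#' animals are reproducible individually and mutually independent.
#'
#' @param seed master integer seed.
#' @param group,timepoint,index identity of the animal slot.
#' @return An integer seed below 2^31.
#' @export
animalSeed <- function(seed, group, timepoint, index) {
  as.integer((as.numeric(seed) +
              stableHash(paste(group, timepoint, index, sep = "|"))) %%
             2147483647)
}

## Resolve the group/timepoint-dependent generator parameters.
resolveParams <- function(config, group, timepoint) {
  if (!group %in% config@groups)
    stop("unknown group: ", group)
  if (!timepoint %in% config@timepoints)
    stop("unknown timepoint: ", timepoint)
  isCase <- group == config@groups[2]
  chronic <- match(timepoint, config@timepoints) > 1L
  last <- timepoint == config@timepoints[length(config@timepoints)]
  vocab <- 0:(config@nSyllables - 1L)
  if (!isCase && length(config@groupSpecificIds))
    vocab <- setdiff(vocab, config@groupSpecificIds)
  list(
    vocab = vocab,
    rho = if (isCase && chronic) config@returnBias else config@controlBias,
    boost = if (isCase && chronic) config@racingBoost else 1,
    len = if (isCase && last)
            as.integer(floor(config@lengthFactor * config@seqLength))
          else config@seqLength
  )
}

#' Simulate one synthetic syllable sequence
#'
#' Generates a sequence under the cohort's generative model (see
#' [CohortConfig-class]): emissions 1 and 2 are drawn from the group
#' vocabulary without immediate repeat; for t >= 3, with probability rho the
#' syllable two steps back is re-emitted (producing a repetitive A-B-A
#' alternation), otherwise a fresh draw is taken from the base distribution
#' over the vocabulary excluding the previous syllable (racing ids' mass
#' multiplied by the racing boost, then renormalized). The same seed always
#' yields the identical sequence; global RNG state is left untouched.
#'
#' @param config a [CohortConfig-class].
#' @param group group name (one of `config@groups`); determines the
#'   vocabulary, return bias, racing boost and effective length together
#'   with `timepoint`.
#' @param seed integer seed for this sequence.
#' @param timepoint timepoint label; defaults to the final timepoint.
#' @param animalId id stored on the result.
#' @return A [SyllableSequence-class].
#' @examples
#' cfg <- cohortConfig(nSyllables = 11, seqLength = 100, returnBias = 0,
#'                     controlBias = 0, racingIds = integer(0),
#'                     groupSpecificIds = integer(0))
#' simulateSequence(cfg, "epileptic", seed = 7)
#' @export
simulateSequence <- function(config, group, seed,
                             timepoint = config@timepoints[length(config@timepoints)],
                             animalId = paste0(group, "_", seed)) {
  validObject(config)
  p <- resolveParams(config, group, timepoint)
  nv <- length(p$vocab)
  if (nv < 2L)
    stop("group vocabulary has fewer than 2 syllables; no valid non-repeating draw")
  racing <- p$vocab %in% config@racingIds
  base <- if (length(config@baseWeights)) config@baseWeights[p$vocab + 1L]
          else ifelse(racing, config@racingBaseWeight, 1)
  w <- base * ifelse(racing, p$boost, 1)
  if (sum(w) <= 0)
    stop("base weights sum to zero after boosting")
  Tn <- p$len
  emis <- withSeed(seed, {
    out <- integer(Tn)
    u <- stats::runif(Tn)
    pos1 <- sample.int(nv, 1L, prob = w)
    out[1L] <- p$vocab[pos1]
    prev <- pos1
    for (t in 2:Tn) {
      if (t >= 3L && u[t] < p$rho && out[t - 2L] != out[t - 1L]) {
        out[t] <- out[t - 2L]
        prev <- match(out[t], p$vocab)
      } else {
        w2 <- w
        w2[prev] <- 0
        pos <- sample.int(nv, 1L, prob = w2)
        out[t] <- p$vocab[pos]
        prev <- pos
      }
    }
    out
  })
  syllableSequence(emis, animalId = animalId, group = group,
                   timepoint = timepoint)
}

#' Simulate a full synthetic cohort
#'
#' Generates `nAnimalsPerGroup` sequences per group per timepoint. Per-animal
#' seeds are derived deterministically from the master seed via
#' [animalSeed()], so the identical config always reproduces the identical
#' cohort while animals remain independent. The case group receives the
#' elevated return bias and racing boost at chronic timepoints, exclusive
#' access to the group-specific syllables, and shortened sequences at the
#' final timepoint.
#'
#' @param config a [CohortConfig-class].
#' @return A list of [SyllableSequence-class] objects, one per animal-session.
#' @examples
#' cfg <- cohortConfig(nSyllables = 11, seqLength = 60, nAnimalsPerGroup = 2,
#'                     timepoints = "12w")
#' length(simulateCohort(cfg))
#' @export
simulateCohort <- function(config) {
  validObject(config)
  out <- list()
  for (tp in config@timepoints) {
    for (g in config@groups) {
      for (i in seq_len(config@nAnimalsPerGroup)) {
        aid <- sprintf("%s_%s_%02d", g, tp, i)
        sd <- animalSeed(config@seed, g, tp, i)
        out[[aid]] <- simulateSequence(config, g, seed = sd, timepoint = tp,
                                       animalId = aid)
      }
    }
  }
  out
}

#' Tabulate a cohort as a manifest data.frame
#'
#' @param cohort list of [SyllableSequence-class] objects.
#' @return data.frame with animal_id, group, timepoint and sequence length.
#' @export
cohortManifest <- function(cohort) {
  data.frame(
    animal_id = vapply(cohort, animalId, character(1)),
    group = vapply(cohort, groupLabel, character(1)),
    timepoint = vapply(cohort, timepointLabel, character(1)),
    T = vapply(cohort, seqLength, integer(1)),
    row.names = NULL
  )
}
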