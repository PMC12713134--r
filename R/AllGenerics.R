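#' @include AllClasses.R
NULL

#' Accessors for syllograph classes
#'
#' `emissions()` returns the integer syllable vector of a sequence;
#' `seqLength()` its length T. `animalId()`, `groupLabel()` and
#' `timepointLabel()` return the annotation of a sequence or profile.
#' `transitionCounts()` returns the count matrix of a
#' [TransitionMatrix-class] and `syllableIds()` its integer ids.
#' `edgeTable()` and `nodeIds()` return the edge data.frame and node id
#' vector of a [BehaviorNetwork-class]; `isMultigraph()` reports whether
#' edges have been replicated to unit weight. `indicators()`,
#' `repetitiveRuns()` and `nonrepetitiveRuns()` access an
#' [AlternationProfile-class].
#'
#' @param x an object of the documented class.
#' @return The slot value (see above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("emissions", function(x) standardGeneric("emissions"))
#' @rdname accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' @rdname accessors
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("timepointLabel", function(x) standardGeneric("timepointLabel"))
#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))
#' @rdname accessors
#' @export
setGeneric("syllableIds", function(x) standardGeneric("syllableIds"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("isMultigraph", function(x) standardGeneric("isMultigraph"))
#' @rdname accessors
#' @export
setGeneric("indicators", function(x) standardGeneric("indicators"))
#' @rdname accessors
#' @export
setGeneric("repetitiveRuns", function(x) standardGeneric("repetitiveRuns"))
#' @rdname accessors
#' @export
setGeneric("nonrepetitiveRuns",
           function(x) standardGeneric("nonrepetitiveRuns"))

#' @rdname accessors
setMethod("emissions", "SyllableSequence", function(x) x@emissions)
#' @rdname accessors
setMethod("seqLength", "SyllableSequence", function(x) length(x@emissions))
#' @rdname accessors
setMethod("animalId", "SyllableSequence", function(x) x@animalId)
#' @rdname accessors
setMethod("groupLabel", "SyllableSequence", function(x) x@group)
#' @rdname accessors
setMethod("timepointLabel", "SyllableSequence", function(x) x@timepoint)

#' @rdname accessors
setMethod("transitionCounts", "TransitionMatrix", function(x) x@counts)
#' @rdname accessors
setMethod("syllableIds", "TransitionMatrix",
          function(x) as.integer(rownames(x@counts)))

#' @rdname accessors
setMethod("edgeTable", "BehaviorNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("nodeIds", "BehaviorNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("isMultigraph", "BehaviorNetwork", function(x) x@multigraph)

#' @rdname accessors
setMethod("animalId", "AlternationProfile", function(x) x@animalId)
#' @rdname accessors
setMethod("groupLabel", "AlternationProfile", function(x) x@group)
#' @rdname accessors
setMethod("timepointLabel", "AlternationProfile", function(x) x@timepoint)
#' @rdname accessors
setMethod("indicators", "AlternationProfile", function(x) x@indicators)
#' @rdname accessors
setMethod("repetitiveRuns", "AlternationProfile", function(x) x@repetitiveRuns)
#' @rdname accessors
setMethod("nonrepetitiveRuns", "AlternationProfile",
          function(x) x@nonrepetitiveRuns)

setMethod("show", "SyllableSequence", function(object) {
  cat(sprintf("SyllableSequence '%s' (group=%s, timepoint=%s): T=%d, %d distinct syllables\n",
              object@animalId, object@group, object@timepoint,
              length(object@emissions),
              length(unique(object@emissions))))
  head_n <- min(10L, length(object@emissions))
  cat("  head:", paste(object@emissions[seq_len(head_n)], collapse = " "),
      if (length(object@emissions) > head_n) "..." else "", "\n")
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d syllables, %g transitions\n",
              nrow(object@counts), sum(object@counts)))
})

setMethod("show", "BehaviorNetwork", function(object) {
  cat(sprintf("BehaviorNetwork: %d nodes, %d edges%s, total weight %g\n",
              length(object@nodes), nrow(object@edges),
              if (object@multigraph) " (replicated multigraph)" else "",
              sum(object@edges$weight)))
})

setMethod("show", "AlternationProfile", function(object) {
  b <- object@indicators
  cat(sprintf("AlternationProfile '%s' (group=%s, timepoint=%s)\n",
              object@animalId, object@group, object@timepoint))
  cat(sprintf("  windows: %d, non-repetitive fraction f = %.4f\n",
              length(b), mean(b)))
  cat(sprintf("  perseveration bouts (0-runs): %d, longest %s\n",
              length(object@repetitiveRuns),
              if (length(object@repetitiveRuns))
                max(object@repetitiveRuns) else "-"))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: n=%d syllables, T=%d, %d animals/group\n",
              object@nSyllables, object@seqLength, object@nAnimalsPerGroup))
  cat(sprintf("  groups: %s (control) vs %s (case); timepoints: %s\n",
              object@groups[1], object@groups[2],
              paste(object@timepoints, collapse = ", ")))
  cat(sprintf("  return bias: %.2f (case, chronic) / %.2f (control); racing boost %.1f; length factor %.2f; seed %d\n",
              object@returnBias, object@controlBias, object@racingBoost,
              object@lengthFactor, object@seed))
})
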