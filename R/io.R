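#' @include AllClasses.R transitions.R
NULL

## All on-disk formats are UTF-8 comma-delimited CSV with a mandatory header
## row; syllable ids are 0-based integers everywhere, behavior names live
## only in the label map.

#' Read and write syllable sequence CSVs
#'
#' A sequence file has one row per emission with columns `frame_index` and
#' `syllable_id` (a bare `syllable_id` column is also accepted on read).
#' Write-then-read is an identity on the emissions.
#'
#' @param path file path.
#' @param animalId,group,timepoint annotation attached on read.
#' @return [SyllableSequence-class] for the reader.
#' @export
readSequence <- function(path, animalId = basename(path),
                         group = NA_character_, timepoint = NA_character_) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!"syllable_id" %in% names(df))
    stop("sequence file must have a 'syllable_id' column: ", path)
  raw <- df$syllable_id
  if (length(raw) == 0L) stop("sequence length < 1: ", path)
  bad <- grep("^-?[0-9]+$", raw, invert = TRUE)
  if (length(bad))
    stop(sprintf("non-integer syllable id '%s' at row %d of %s",
                 raw[bad[1L]], bad[1L], path))
  syllableSequence(as.integer(raw), animalId = animalId, group = group,
                   timepoint = timepoint)
}

#' @rdname readSequence
#' @param seq a [SyllableSequence-class].
#' @export
writeSequence <- function(seq, path) {
  stopifnot(is(seq, "SyllableSequence"))
  utils::write.csv(
    data.frame(frame_index = seq_along(emissions(seq)) - 1L,
               syllable_id = emissions(seq)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write wide-format transition matrices
#'
#' The wide format has incoming syllable ids along the side and outgoing
#' syllable ids along the top; the corner cell is an empty header. Counts
#' round-trip exactly.
#'
#' @param path file path.
#' @return [TransitionMatrix-class] for the reader.
#' @export
readWideMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("wide transition matrix must be square: ", path)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column syllable labels must match: ", path)
  storage <- suppressWarnings(as.numeric(m))
  if (anyNA(storage))
    stop("non-numeric cells in transition matrix: ", path)
  m <- matrix(storage, nrow(m), ncol(m), dimnames = dimnames(m))
  if (any(m < 0)) stop("counts must be nonnegative: ", path)
  new("TransitionMatrix", counts = m)
}

#' @rdname readWideMatrix
#' @param m a [TransitionMatrix-class].
#' @export
writeWideMatrix <- function(m, path) {
  stopifnot(is(m, "TransitionMatrix"))
  cm <- transitionCounts(m)
  ## written by hand so the corner header cell stays empty
  lines <- c(paste0(",", paste(colnames(cm), collapse = ",")),
             vapply(seq_len(nrow(cm)), function(i)
               paste0(rownames(cm)[i], ",",
                      paste(cm[i, ], collapse = ",")), character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Convert between wide matrices and long transition records
#'
#' The long format has one row per observed (incoming, outgoing) pair with
#' its transition frequency; zero-frequency pairs are omitted. Given the
#' syllable id universe the two representations are mutually lossless.
#'
#' @param m a [TransitionMatrix-class].
#' @return data.frame with columns `incoming`, `outgoing`, `frequency`.
#' @export
matrixToLong <- function(m) {
  stopifnot(is(m, "TransitionMatrix"))
  cm <- transitionCounts(m)
  ids <- syllableIds(m)
  nz <- which(cm > 0, arr.ind = TRUE)
  out <- data.frame(incoming = ids[nz[, 1L]], outgoing = ids[nz[, 2L]],
                    frequency = cm[nz])
  out <- out[order(out$incoming, out$outgoing), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname matrixToLong
#' @param records long-format data.frame (incoming, outgoing, frequency).
#' @param syllableIds integer id universe for the reconstructed matrix.
#' @export
longToMatrix <- function(records, syllableIds) {
  ids <- sort(unique(as.integer(syllableIds)))
  n <- length(ids)
  cm <- matrix(0, n, n, dimnames = list(as.character(ids),
                                        as.character(ids)))
  if (nrow(records)) {
    ri <- match(records$incoming, ids)
    ci <- match(records$outgoing, ids)
    if (anyNA(ri) || anyNA(ci))
      stop("record references an id outside the given universe")
    cm[cbind(ri, ci)] <- records$frequency
  }
  new("TransitionMatrix", counts = cm)
}

#' @rdname matrixToLong
#' @param path file path.
#' @export
writeLongMatrix <- function(m, path) {
  utils::write.csv(matrixToLong(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname matrixToLong
#' @export
readLongMatrix <- function(path, syllableIds = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("incoming", "outgoing", "frequency") %in% names(df)))
    stop("long matrix file needs columns incoming, outgoing, frequency")
  if (is.null(syllableIds))
    syllableIds <- sort(unique(c(df$incoming, df$outgoing)))
  longToMatrix(df, syllableIds)
}

#' Read and write syllable label maps
#'
#' Columns: `syllable_id` (unique integer), `behavior_name`, `is_racing`
#' (logical). Ids referenced elsewhere but missing from the map resolve to
#' behavior "unlabeled" with `is_racing = FALSE` via [resolveLabels()].
#'
#' @param path file path.
#' @return data.frame label map.
#' @export
readLabelMap <- function(path) {
  df <- utils::read.csv(path)
  need <- c("syllable_id", "behavior_name", "is_racing")
  if (!all(need %in% names(df)))
    stop("label map needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$syllable_id)) stop("duplicate syllable_id in label map")
  df$syllable_id <- as.integer(df$syllable_id)
  df$is_racing <- as.logical(df$is_racing)
  df[need]
}

#' @rdname readLabelMap
#' @param labels label map data.frame.
#' @export
writeLabelMap <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readLabelMap
#' @param ids integer ids to resolve.
#' @param labels label map data.frame.
#' @return data.frame with one row per id: syllable_id, behavior_name,
#'   is_racing (missing ids become "unlabeled", not racing).
#' @export
resolveLabels <- function(ids, labels) {
  i <- match(ids, labels$syllable_id)
  data.frame(
    syllable_id = as.integer(ids),
    behavior_name = ifelse(is.na(i), "unlabeled", labels$behavior_name[i]),
    is_racing = ifelse(is.na(i), FALSE, labels$is_racing[i])
  )
}

#' Export a behavior network to disk
#'
#' `graphml` writes GraphML (node ids, behavior names when a label map is
#' supplied, edge weights); `edge-table` writes a delimited file with
#' columns source, target, weight, directly importable into Cytoscape.
#'
#' @param net a [BehaviorNetwork-class].
#' @param path output file.
#' @param format "graphml" or "edge-table".
#' @param labels optional label map for behavior names.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "edge-table"),
                          labels = NULL) {
  format <- match.arg(format)
  ed <- edgeTable(net)
  if (format == "edge-table") {
    utils::write.csv(
      data.frame(source = ed$incoming, target = ed$outgoing,
                 weight = ed$weight),
      path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  nodes <- data.frame(name = as.character(nodeIds(net)))
  if (!is.null(labels))
    nodes$behavior <- resolveLabels(nodeIds(net), labels)$behavior_name
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$incoming),
               to = as.character(ed$outgoing), weight = ed$weight),
    directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a GraphML network written by [exportNetwork()]
#'
#' @param path GraphML file.
#' @return A [BehaviorNetwork-class].
#' @export
importNetwork <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  vs <- igraph::as_data_frame(g, what = "vertices")
  edges <- data.frame(incoming = as.integer(ed$from),
                      outgoing = as.integer(ed$to),
                      weight = as.numeric(ed$weight))
  edges <- edges[order(edges$incoming, edges$outgoing), , drop = FALSE]
  rownames(edges) <- NULL
  new("BehaviorNetwork", edges = edges,
      nodes = sort(as.integer(vs$name)), multigraph = FALSE)
}

#' Write a cohort to per-animal CSVs plus a manifest
#'
#' @param cohort list of [SyllableSequence-class] objects.
#' @param dir output directory (created if needed).
#' @param seeds optional named integer vector of per-animal seeds recorded
#'   in the manifest.
#' @return Path of the manifest CSV.
#' @export
writeCohort <- function(cohort, dir, seeds = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    files[i] <- paste0(animalId(cohort[[i]]), ".csv")
    writeSequence(cohort[[i]], file.path(dir, files[i]))
  }
  manifest <- cohortManifest(cohort)
  manifest$file <- files
  if (!is.null(seeds))
    manifest$seed <- unname(seeds[manifest$animal_id])
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifestPath path to a manifest written by [writeCohort()].
#' @return List of [SyllableSequence-class] objects.
#' @export
readCohort <- function(manifestPath) {
  manifest <- utils::read.csv(manifestPath)
  dir <- dirname(manifestPath)
  out <- lapply(seq_len(nrow(manifest)), function(i)
    readSequence(file.path(dir, manifest$file[i]),
                 animalId = manifest$animal_id[i],
                 group = manifest$group[i],
                 timepoint = manifest$timepoint[i]))
  names(out) <- manifest$animal_id
  out
}
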