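#' @include AllClasses.R io.R alternation.R transitions.R net-metrics.R
#' @include racing.R group-stats.R synthetic-cohort.R
NULL

#' Assemble a pipeline configuration
#'
#' @param cohort a [CohortConfig-class] for synthetic input, or NULL when
#'   reading an existing cohort.
#' @param manifest path to a cohort manifest CSV (used when `cohort` is
#'   NULL).
#' @param labels label map data.frame or CSV path; NULL derives an
#'   "unlabeled" map, flagging the cohort config's racing ids when present.
#' @param coverage syllable inclusion coverage (default 0.99).
#' @param racingThreshold binarization threshold (default 0.025).
#' @param weightMode distance convention for the network metrics.
#' @param outputDir directory for all written artifacts.
#' @param seed integer seed overriding the cohort config's.
#' @return A validated plain-list pipeline configuration.
#' @export
pipelineConfig <- function(cohort = NULL, manifest = NULL, labels = NULL,
                           coverage = 0.99, racingThreshold = 0.025,
                           weightMode = "raw", outputDir = tempfile("sgrun"),
                           seed = NULL) {
  if (is.null(cohort) && is.null(manifest))
    stop("either a cohort config or a manifest path is required")
  if (!is.null(cohort)) {
    stopifnot(is(cohort, "CohortConfig"))
    if (!is.null(seed)) cohort@seed <- as.integer(seed)
    validObject(cohort)
  }
  if (is.character(labels)) labels <- readLabelMap(labels)
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  if (racingThreshold < 0) stop("racingThreshold must be >= 0")
  list(cohort = cohort, manifest = manifest, labels = labels,
       coverage = coverage, racingThreshold = racingThreshold,
       weightMode = match.arg(weightMode, c("raw", "inverse", "unweighted")),
       outputDir = outputDir,
       seed = if (!is.null(seed)) as.integer(seed)
              else if (!is.null(cohort)) cohort@seed else NA_integer_)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys matching [cohortConfig()] arguments go under `cohort:`; the
#' remaining top-level keys match [pipelineConfig()] arguments.
#'
#' @param path YAML file.
#' @return A pipeline configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) do.call(cohortConfig, y$cohort) else NULL
  args <- y[setdiff(names(y), "cohort")]
  do.call(pipelineConfig, c(list(cohort = cohort), args))
}

loadCohort <- function(config) {
  if (!is.null(config$manifest)) readCohort(config$manifest)
  else simulateCohort(config$cohort)
}

defaultLabels <- function(config, cohort) {
  if (!is.null(config$labels)) return(config$labels)
  ids <- sort(unique(unlist(lapply(cohort, emissions))))
  racing <- if (!is.null(config$cohort)) config$cohort@racingIds
            else integer(0)
  data.frame(syllable_id = ids,
             behavior_name = ifelse(ids %in% racing, "racing", "unlabeled"),
             is_racing = ids %in% racing)
}

cohortNetworks <- function(cohort, coverage) {
  pooled <- table(unlist(lapply(cohort, emissions)))
  included <- syllableInclusion(
    setNames(as.numeric(pooled), names(pooled)), coverage)
  nets <- lapply(cohort, function(s)
    buildNetwork(countTransitions(s, includedIds = included)))
  list(included = included, nets = nets)
}

writeRunLog <- function(config, command, dir) {
  lines <- c(
    sprintf("command: %s", command),
    sprintf("seed: %s", config$seed),
    sprintf("coverage: %g", config$coverage),
    sprintf("racing_threshold: %g", config$racingThreshold),
    sprintf("weight_mode: %s", config$weightMode),
    sprintf("syllograph_version: %s",
            as.character(utils::packageVersion("syllograph"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  writeLines(lines, file.path(dir, paste0("runlog_", command, ".txt")))
}

#' Run one pipeline command
#'
#' Commands: `simulate` writes the synthetic cohort (per-animal CSVs +
#' manifest); `alternation` writes per-animal alternation profiles and the
#' run-length long table; `networks` writes per-animal long-format
#' transition matrices and GraphML networks over the syllables meeting the
#' coverage criterion; `metrics` writes the six-measure node table and the
#' degree-connectivity table; `racing` writes normalized usage, the
#' binarized racing heatmap, racing totals, and behavior word counts of
#' shared vs group-specific nodes; `stats` writes per-timepoint group
#' comparisons with BKY q-values; `report` runs everything in order. Each
#' command also writes a run log (seed, parameters, package version). On
#' error the command's partial outputs are removed.
#'
#' @param command one of simulate, alternation, networks, metrics, racing,
#'   stats, report.
#' @param config a [pipelineConfig()] list.
#' @return Invisibly, a character vector of written file paths.
#' @export
runPipeline <- function(command = c("report", "simulate", "alternation",
                                    "networks", "metrics", "racing",
                                    "stats"),
                        config) {
  command <- match.arg(command)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  before <- list.files(config$outputDir, recursive = TRUE, full.names = TRUE)
  written <- tryCatch(
    doPipeline(command, config),
    error = function(e) {
      after <- list.files(config$outputDir, recursive = TRUE,
                          full.names = TRUE)
      unlink(setdiff(after, before))
      stop(e)
    })
  writeRunLog(config, command, config$outputDir)
  invisible(written)
}

doPipeline <- function(command, config) {
  out <- config$outputDir
  fp <- function(...) file.path(out, ...)
  if (command == "report") {
    return(unlist(lapply(c("simulate", "alternation", "networks", "metrics",
                           "racing", "stats"),
                         function(cmd) doPipeline(cmd, config))))
  }
  if (command == "simulate") {
    if (is.null(config$cohort))
      stop("simulate requires a cohort config")
    cohort <- simulateCohort(config$cohort)
    cc <- config$cohort
    seeds <- vapply(cohort, function(s) {
      idx <- as.integer(sub(".*_", "", animalId(s)))
      animalSeed(cc@seed, groupLabel(s), timepointLabel(s), idx)
    }, integer(1))
    writeCohort(cohort, fp("cohort"), seeds = seeds)
    return(fp("cohort", "manifest.csv"))
  }
  cohort <- if (!is.null(config$manifest)) readCohort(config$manifest)
            else if (file.exists(fp("cohort", "manifest.csv")))
              readCohort(fp("cohort", "manifest.csv"))
            else simulateCohort(config$cohort)
  labels <- defaultLabels(config, cohort)
  if (command == "alternation") {
    alt <- cohortAlternation(cohort)
    utils::write.csv(alt$profiles, fp("alternation_profiles.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(alt$runs, fp("run_lengths.csv"),
                     row.names = FALSE, quote = FALSE)
    return(fp(c("alternation_profiles.csv", "run_lengths.csv")))
  }
  if (command == "networks") {
    cn <- cohortNetworks(cohort, config$coverage)
    files <- character(0)
    for (aid in names(cn$nets)) {
      m <- countTransitions(cohort[[aid]], includedIds = cn$included)
      f1 <- fp(paste0(aid, "_long.csv"))
      writeLongMatrix(m, f1)
      f2 <- fp(paste0(aid, ".graphml"))
      exportNetwork(cn$nets[[aid]], f2, "graphml", labels = labels)
      files <- c(files, f1, f2)
    }
    return(files)
  }
  if (command == "metrics") {
    cn <- cohortNetworks(cohort, config$coverage)
    manifest <- cohortManifest(cohort)
    nodeTabs <- list(); adcTabs <- list()
    for (i in seq_along(cn$nets)) {
      nm <- nodeMetrics(cn$nets[[i]], config$weightMode)
      nodeTabs[[i]] <- cbind(animal_id = manifest$animal_id[i],
                             group = manifest$group[i],
                             timepoint = manifest$timepoint[i],
                             nm$nodes)
      adcTabs[[i]] <- cbind(animal_id = manifest$animal_id[i],
                            group = manifest$group[i],
                            timepoint = manifest$timepoint[i],
                            nm$degree_connectivity)
    }
    utils::write.csv(do.call(rbind, nodeTabs), fp("node_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(do.call(rbind, adcTabs), fp("degree_connectivity.csv"),
                     row.names = FALSE, quote = FALSE)
    return(fp(c("node_metrics.csv", "degree_connectivity.csv")))
  }
  if (command == "racing") {
    usages <- lapply(cohort, usageFromSequence)
    allIds <- sort(unique(unlist(lapply(cohort, emissions))))
    usageMat <- vapply(usages, function(u) {
      v <- setNames(numeric(length(allIds)), as.character(allIds))
      v[names(u)] <- u
      v
    }, numeric(length(allIds)))
    usageDf <- data.frame(syllable_id = allIds, usageMat,
                          check.names = FALSE)
    utils::write.csv(usageDf, fp("usage.csv"), row.names = FALSE,
                     quote = FALSE)
    hm <- racingHeatmap(cohort, labels, config$racingThreshold)
    utils::write.csv(data.frame(syllable_id = rownames(hm), hm,
                                check.names = FALSE),
                     fp("racing_heatmap.csv"), row.names = FALSE,
                     quote = FALSE)
    manifest <- cohortManifest(cohort)
    totals <- data.frame(
      manifest[c("animal_id", "group", "timepoint")],
      racing_total = vapply(usages, racingUsageTotal, numeric(1),
                            labels = labels),
      nonracing_total = vapply(usages, nonracingUsageTotal, numeric(1),
                               labels = labels))
    utils::write.csv(totals, fp("racing_totals.csv"), row.names = FALSE,
                     quote = FALSE)
    cn <- cohortNetworks(cohort, config$coverage)
    groups <- unique(manifest$group)
    netsByGroup <- lapply(setNames(groups, groups), function(g)
      cn$nets[manifest$group == g])
    part <- nodePartition(netsByGroup)
    wc <- list()
    wcTab <- function(ids, setName) {
      cnts <- behaviorWordCounts(ids, labels)
      if (!length(cnts)) return(NULL)
      data.frame(node_set = setName, behavior = names(cnts),
                 count = as.integer(cnts))
    }
    wc[["shared"]] <- wcTab(part$shared, "shared")
    for (g in names(part$specific))
      wc[[g]] <- wcTab(part$specific[[g]], paste0(g, "_specific"))
    utils::write.csv(do.call(rbind, wc), fp("word_counts.csv"),
                     row.names = FALSE, quote = FALSE)
    return(fp(c("usage.csv", "racing_heatmap.csv", "racing_totals.csv",
                "word_counts.csv")))
  }
  if (command == "stats") {
    alt <- cohortAlternation(cohort)
    manifest <- cohortManifest(cohort)
    groups <- unique(manifest$group)
    if (length(groups) != 2L)
      stop("stats requires exactly two groups")
    comps <- list()
    for (tp in unique(manifest$timepoint)) {
      pr <- alt$profiles[alt$profiles$timepoint == tp, ]
      a <- pr$percent_repetitive[pr$group == groups[1]]
      b <- pr$percent_repetitive[pr$group == groups[2]]
      comps[[paste0(tp, ":percent_repetitive:mw")]] <-
        c(mannWhitney(a, b), list(tp = tp))
      rr <- alt$runs[alt$runs$timepoint == tp &
                     alt$runs$run_type == "repetitive", ]
      comps[[paste0(tp, ":repetitive_runs:ks")]] <-
        c(ksTwoSample(rr$length[rr$group == groups[1]],
                      rr$length[rr$group == groups[2]]), list(tp = tp))
      nr <- alt$runs[alt$runs$timepoint == tp &
                     alt$runs$run_type == "nonrepetitive", ]
      comps[[paste0(tp, ":nonrepetitive_runs:ks")]] <-
        c(ksTwoSample(nr$length[nr$group == groups[1]],
                      nr$length[nr$group == groups[2]]), list(tp = tp))
    }
    p <- vapply(comps, `[[`, numeric(1), "p_value")
    fdr <- bkyFdr(p)
    res <- data.frame(
      comparison = names(comps),
      test = vapply(comps, `[[`, character(1), "test_name"),
      statistic = vapply(comps, `[[`, numeric(1), "statistic"),
      p = p, q = fdr$q_values, reject = fdr$reject,
      n1 = vapply(comps, `[[`, numeric(1), "n1"),
      n2 = vapply(comps, `[[`, numeric(1), "n2"),
      row.names = NULL)
    utils::write.csv(res, fp("group_stats.csv"), row.names = FALSE,
                     quote = FALSE)
    return(fp("group_stats.csv"))
  }
  stop("unknown command: ", command)
}
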