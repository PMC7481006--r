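#' @include AllClasses.R
NULL

#' Per-group summary of a cohort metric
#'
#' Median, Q1 and Q3 (type-7 linear-interpolation quantiles, the convention
#' stated in the report header) and n per group; missing values are
#' excluded from n. An empty group is an error naming the group.
#'
#' @param table a cohort data.frame, one row per cell/pair/recording.
#' @param metric metric column name.
#' @param group group column name (default `"group"`).
#' @return data.frame with columns `group`, `median`, `q1`, `q3`, `n`.
#' @export
summarizeCohort <- function(table, metric, group = "group") {
  stopifnot(is.data.frame(table), metric %in% names(table),
            group %in% names(table))
  groups <- unique(table[[group]])
  res <- lapply(groups, function(g) {
    v <- table[[metric]][table[[group]] == g]
    v <- v[!is.na(v)]
    if (!length(v))
      stop(sprintf("group '%s' has no non-missing values for metric '%s'",
                   g, metric), call. = FALSE)
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, median = qs[2], q1 = qs[1], q3 = qs[3],
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Normality-gated two-group comparison
#'
#' Assesses normality of each group with the Shapiro-Wilk test; when both
#' groups are compatible with normality (p > `alphaNormality`) the groups
#' are compared with a two-tailed unpaired Student's t test, otherwise with
#' a two-tailed Mann-Whitney U test. The branch taken is reported.
#'
#' @param table cohort data.frame.
#' @param metric metric column name.
#' @param group group column name; the column must contain exactly two
#'   groups, each with at least 3 non-missing values.
#' @param alphaNormality significance level of the normality gate.
#' @return A [GroupComparison-class].
#' @export
compareGroups <- function(table, metric, group = "group",
                          alphaNormality = 0.05) {
  stopifnot(is.data.frame(table), metric %in% names(table))
  groups <- unique(table[[group]])
  if (length(groups) != 2)
    stop("exactly two groups are required", call. = FALSE)
  vals <- lapply(groups, function(g) {
    v <- table[[metric]][table[[group]] == g]
    v[!is.na(v)]
  })
  ns <- lengths(vals)
  if (any(ns < 3))
    stop(sprintf("group '%s' has fewer than 3 values for metric '%s'",
                 groups[which.min(ns)], metric), call. = FALSE)
  shapiroP <- vapply(vals, function(v) {
    if (length(unique(v)) < 3) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (all(shapiroP > alphaNormality)) {
    test <- "t_test"
    p <- stats::t.test(vals[[1]], vals[[2]], var.equal = TRUE,
                       alternative = "two.sided")$p.value
  } else {
    test <- "mann_whitney"
    p <- suppressWarnings(
      stats::wilcox.test(vals[[1]], vals[[2]],
                         alternative = "two.sided")$p.value)
  }
  new("GroupComparison", metric = metric, groups = as.character(groups),
      summary = summarizeCohort(table, metric, group), test = test,
      pValue = p, shapiroP = shapiroP)
}

#' Demo cohort configuration
#'
#' A packaged two-group in vivo cohort contrasting a euploid-like and a
#' trisomic-like condition: overall firing rates of about 0.81 vs 0.42 Hz
#' (UP-state rates 1.45 vs 0.72 Hz, DOWN-state rates 0.17 vs 0.12 Hz) and
#' stronger low-gamma (20-40 Hz) spike-field coupling in the trisomic-like
#' group (von Mises kappa 0.2 vs 0.5). The kappa contrast is sized so the
#' group difference is detectable at 12 cells per group given the per-cell
#' PPC sampling noise of ~250-spike trains, while keeping PPC magnitudes
#' inside the range such recordings report (up to ~0.05). Recordings are
#' 600 s so that most cells clear the 250-spike PPC reliability threshold;
#' the juxtacellular channel is simulated at 5 kHz.
#'
#' @param nPerGroup recordings per group.
#' @param duration recording duration (s).
#' @param seed integer seed; recording seeds are derived deterministically.
#' @return A pipeline config list for [runPipeline()].
#' @export
demoCohortConfig <- function(nPerGroup = 12, duration = 600, seed = 1) {
  mk <- function(g, i) {
    base <- list(group = g, id = sprintf("%s_%02d", g, i))
    kappa <- if (g == "Eu-like") 0.2 else 0.5
    up <- if (g == "Eu-like") 1.45 else 0.72
    down <- if (g == "Eu-like") 0.17 else 0.12
    base$simConfig <- inVivoSimConfig(
      duration = duration, juxtaRate = 5000,
      spikeRateUp = up, spikeRateDown = down,
      couplingBand = c(20, 40), kappa = kappa,
      seed = (seed * 1000L + (if (g == "Eu-like") 0L else 500L) + i) %% .Machine$integer.max)
    base
  }
  recordings <- c(lapply(seq_len(nPerGroup), function(i) mk("Eu-like", i)),
                  lapply(seq_len(nPerGroup), function(i) mk("Ts-like", i)))
  list(recordings = recordings,
       metrics = c("spikingRate", "stlfpP2P", "ppcLow", "ppcHigh",
                   "ppc_10_20", "ppc_20_40", "ppc_40_60", "ppc_60_80",
                   "ppc_80_100"),
       bands = list(c(10, 20), c(20, 40), c(40, 60), c(60, 80),
                    c(80, 100)),
       computeStLFP = TRUE, computeStates = FALSE, seed = seed)
}

.analyzeRecording <- function(lfp, juxta, bands, computeStLFP = TRUE,
                              computeStates = FALSE) {
  spikes <- detectSpikesJuxta(juxta)
  lfpA <- lowpass(if (samplingRate(lfp) > 1000) decimateTo(lfp, 1000) else lfp,
                  100)
  row <- list(spikingRate = firingRate(spikes))
  ppcTab <- bandPPC(lfpA, spikes, bands = bands)
  for (i in seq_len(nrow(ppcTab)))
    row[[sprintf("ppc_%g_%g", ppcTab$fLo[i], ppcTab$fHi[i])]] <- ppcTab$ppc[i]
  lowBands <- ppcTab$fLo >= 10 & ppcTab$fHi <= 60
  highBands <- ppcTab$fLo >= 60 & ppcTab$fHi <= 100
  row$ppcLow <- mean(ppcTab$ppc[lowBands])
  row$ppcHigh <- mean(ppcTab$ppc[highBands])
  row$nSpikes <- nSpikes(spikes)
  row$ppcReliable <- all(ppcTab$reliable)
  stlfp <- NULL
  if (computeStLFP && nSpikes(spikes) > 0) {
    stlfp <- spikeTriggeredLFP(lfpA, spikes)
    row$stlfpP2P <- stlfp@peakToPeak
  } else row$stlfpP2P <- NA_real_
  states <- NULL
  if (computeStates) {
    states <- detectStates(stateEvidence(lfpA))
    ss <- stateStats(states$segmentation, spikes)
    row$upRate <- ss$spikeRateHz[ss$label == "UP"]
    row$downRate <- ss$spikeRateHz[ss$label == "DOWN"]
  }
  list(row = row, spikes = spikes, stlfp = stlfp, states = states)
}

#' Run a cohort analysis pipeline
#'
#' Executes simulate (for recordings given as simulation configs) or load
#' (for recordings given as trace file paths), then analyze (spike
#' detection, firing rate, band-wise PPC, optionally spike-triggered LFP
#' and state segmentation), then summarize and compare every configured
#' metric across the two groups. Per-recording failures are recorded and
#' the pipeline continues. With `outDir` set, writes `cohort.tsv`,
#' `comparisons.json`, per-recording segmentation interval files and
#' `run.log`.
#'
#' @param config a pipeline config: `recordings` (list of entries with
#'   `id`, `group`, and either `simConfig` or `lfpPath`/`juxtaPath`),
#'   `metrics`, `bands`, `computeStLFP`, `computeStates`, `seed`. See
#'   [demoCohortConfig()].
#' @param outDir optional output directory.
#' @return A list with `cohort` (data.frame), `comparisons` (list of
#'   [GroupComparison-class]), `failures` (named list of error messages)
#'   and `log` (character).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (!length(config$recordings))
    stop("config lists no recordings", call. = FALSE)
  bands <- config$bands
  if (is.null(bands))
    bands <- list(c(4, 10), c(10, 20), c(20, 40), c(40, 60), c(60, 80),
                  c(80, 100))
  log <- c(sprintf("ephyskit pipeline, %d recordings, seed %s",
                   length(config$recordings),
                   deparse(config$seed)),
           "quantiles: type 7 (linear interpolation)",
           "multiple-testing correction: none (per-metric reporting)")
  rows <- list(); failures <- list(); segs <- list()
  for (rec in config$recordings) {
    res <- tryCatch({
      if (!is.null(rec$simConfig)) {
        sim <- simulateInVivo(rec$simConfig)
        lfp <- sim$lfp; juxta <- sim$juxta
      } else {
        lfp <- readTrace(rec$lfpPath)
        juxta <- readTrace(rec$juxtaPath)
      }
      .analyzeRecording(lfp, juxta, bands,
                        computeStLFP = isTRUE(config$computeStLFP),
                        computeStates = isTRUE(config$computeStates))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[rec$id]] <- conditionMessage(res)
      log <- c(log, sprintf("FAIL %s: %s", rec$id, conditionMessage(res)))
      next
    }
    row <- c(list(id = rec$id, group = rec$group), res$row)
    rows[[rec$id]] <- as.data.frame(row, stringsAsFactors = FALSE)
    if (!is.null(res$states)) segs[[rec$id]] <- res$states$segmentation
    log <- c(log, sprintf("ok %s (%s): %d spikes", rec$id, rec$group,
                          res$row$nSpikes))
  }
  if (!length(rows))
    stop("every recording failed; see failures", call. = FALSE)
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  metrics <- config$metrics
  if (is.null(metrics)) metrics <- "spikingRate"
  comparisons <- list()
  for (m in metrics) {
    cmp <- tryCatch(compareGroups(cohort, m), error = function(e) e)
    if (inherits(cmp, "error")) {
      log <- c(log, sprintf("comparison %s failed: %s", m,
                            conditionMessage(cmp)))
    } else {
      comparisons[[m]] <- cmp
      log <- c(log, sprintf("comparison %s: %s p=%.5g", m, cmp@test,
                            cmp@pValue))
    }
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(cohort, file.path(outDir, "cohort.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cmpJson <- lapply(comparisons, function(cmp)
      list(metric = cmp@metric, test = cmp@test, pValue = cmp@pValue,
           groups = cmp@groups, summary = cmp@summary,
           shapiroP = cmp@shapiroP))
    jsonlite::write_json(cmpJson, file.path(outDir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA)
    if (length(segs)) {
      dir.create(file.path(outDir, "segmentation"), showWarnings = FALSE)
      for (id in names(segs))
        writeSegmentation(segs[[id]],
                          file.path(outDir, "segmentation",
                                    paste0(id, ".bed")))
    }
    writeLines(log, file.path(outDir, "run.log"))
  }
  list(cohort = cohort, comparisons = comparisons, failures = failures,
       log = log)
}
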