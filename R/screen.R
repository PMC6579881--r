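## Antibody-screen summary statistics: blank-thresholded percent positive,
## per-(subset, antibody) medians, fixation gain/loss classification, and
## the standardized-residual differential-marker test.

#' Blank-well positivity threshold
#'
#' The 99th percentile (linear-interpolation convention) of all events in
#' the blank control well; events above it are called positive.
#'
#' @param blankValues arcsinh readout intensities of the blank well.
#' @return a number (arcsinh units).
#' @examples
#' blankThreshold(1:100)  # 99.01
#' @export
blankThreshold <- function(blankValues) {
  if (length(blankValues) == 0) {
    stop_validation("blank well has no events")
  }
  stats::quantile(blankValues, 0.99, names = FALSE, type = 7)
}

#' Percent of events above a threshold
#'
#' @param values numeric intensities.
#' @param threshold positivity cutoff (strictly-greater convention).
#' @return percentage in [0, 100]; an empty input returns 0 with a warning.
#' @export
percentPositive <- function(values, threshold) {
  if (length(values) == 0) {
    warning("no events: percent positive reported as 0")
    return(0)
  }
  100 * mean(values > threshold)
}

#' Summarize an antibody screen
#'
#' For each (donor, treatment), a single blank threshold is taken from the
#' blank well's readout values; every (profiling subset, antibody) cell of
#' the screen then gets its median readout intensity, percent positive and
#' event count. Cells with no events are emitted with `n = 0` and `NA`
#' statistics.
#'
#' @param eventTable data.frame with one row per labeled event: columns
#'   `donor`, `treatment`, `well_id`, `antibody`, `profiling_subset`,
#'   `readout` (arcsinh readout-channel intensity).
#' @param blankWellId well id of the blank (no-primary-antibody) control.
#' @return list with `summary` (long data.frame: `donor`, `treatment`,
#'   `profiling_subset`, `antibody`, `median`, `pct_positive`, `n`) and
#'   `thresholds` (data.frame: `donor`, `treatment`, `threshold`).
#' @export
summarizeScreen <- function(eventTable, blankWellId) {
  need <- c("donor", "treatment", "well_id", "antibody",
            "profiling_subset", "readout")
  if (!all(need %in% names(eventTable))) {
    stop_validation("eventTable must have columns ",
                    paste(need, collapse = ", "))
  }
  conds <- unique(eventTable[, c("donor", "treatment")])
  conds <- conds[order(conds$donor, conds$treatment), , drop = FALSE]
  rows <- list()
  thr_rows <- list()
  for (i in seq_len(nrow(conds))) {
    d <- conds$donor[i]; tr <- conds$treatment[i]
    sel <- eventTable$donor == d & eventTable$treatment == tr
    blank <- eventTable$readout[sel & eventTable$well_id == blankWellId]
    if (length(blank) == 0) {
      stop_validation("blank well '", blankWellId,
                      "' has no events for donor ", d, ", treatment ", tr)
    }
    thr <- blankThreshold(blank)
    thr_rows[[i]] <- data.frame(donor = d, treatment = tr, threshold = thr,
                                stringsAsFactors = FALSE)
    et <- eventTable[sel, , drop = FALSE]
    grid <- expand.grid(
      profiling_subset = sort(unique(et$profiling_subset)),
      antibody = sort(unique(et$antibody)),
      stringsAsFactors = FALSE
    )
    key_ev <- paste(et$profiling_subset, et$antibody, sep = "\r")
    key_gd <- paste(grid$profiling_subset, grid$antibody, sep = "\r")
    split_vals <- split(et$readout, factor(key_ev, levels = key_gd))
    grid$median <- vapply(split_vals, function(v) {
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1))
    grid$pct_positive <- vapply(split_vals, function(v) {
      if (length(v)) percentPositive(v, thr) else NA_real_
    }, numeric(1))
    grid$n <- as.integer(lengths(split_vals))
    grid$donor <- d
    grid$treatment <- tr
    rows[[i]] <- grid[, c("donor", "treatment", "profiling_subset",
                          "antibody", "median", "pct_positive", "n")]
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       thresholds = do.call(rbind, c(thr_rows, make.row.names = FALSE)))
}

## Median arcsinh intensity back to the raw ion-count scale. The arcsinh
## transform is monotone, so the raw median is cofactor * sinh(arcsinh
## median); fold changes are taken on this scale, as ratios of transformed
## values compress real intensity shifts.
raw_median <- function(m, cofactor = 5) cofactor * sinh(m)

#' Classify antibodies by fixation-induced intensity shift
#'
#' For each (subset, antibody), the log10 ratio of the fixed to the fresh
#' median intensity (ratios are taken on the raw ion-count scale by
#' inverting the arcsinh transform). An antibody counts as expressed when
#' its percent positive reaches `expressionFloor` in at least one subset of
#' either condition; its summary ratio is the median log10 ratio over those
#' expressing subsets, and it is classified `gain` when the summary ratio
#' is at least `log10(foldThreshold)`, `loss` when at most the negative of
#' that, else `unchanged`.
#'
#' @param summaryFresh,summaryFixed data.frames with columns
#'   `profiling_subset`, `antibody`, `median`, `pct_positive` (rows beyond
#'   one per cell are aggregated by median / max respectively).
#' @param foldThreshold fold change treated as a significant shift
#'   (default 2).
#' @param expressionFloor percent-positive floor for an antibody to count
#'   as expressed in a subset (default 5).
#' @param cofactor arcsinh cofactor used to invert the transform.
#' @return list with `bySubset` (data.frame: `profiling_subset`,
#'   `antibody`, `log10_ratio`), `byAntibody` (data.frame: `antibody`,
#'   `summary_ratio`, `class`) and `expressed` (character vector of
#'   expressed antibodies).
#' @export
fixationClassify <- function(summaryFresh, summaryFixed, foldThreshold = 2,
                             expressionFloor = 5, cofactor = 5) {
  agg <- function(df) {
    med <- stats::aggregate(median ~ profiling_subset + antibody, df,
                            stats::median, na.action = stats::na.omit)
    pp <- stats::aggregate(pct_positive ~ profiling_subset + antibody, df,
                           max, na.action = stats::na.omit)
    merge(med, pp, by = c("profiling_subset", "antibody"))
  }
  fr <- agg(summaryFresh)
  fx <- agg(summaryFixed)
  common_ab <- intersect(unique(fr$antibody), unique(fx$antibody))
  dropped <- setdiff(union(unique(fr$antibody), unique(fx$antibody)),
                     common_ab)
  if (length(dropped)) {
    warning("antibodies absent from one condition skipped: ",
            paste(dropped, collapse = ", "))
  }
  m <- merge(fr, fx, by = c("profiling_subset", "antibody"),
             suffixes = c("_fresh", "_fixed"))
  m <- m[m$antibody %in% common_ab, , drop = FALSE]
  m$expressing <- pmax(m$pct_positive_fresh, m$pct_positive_fixed,
                       na.rm = TRUE) >= expressionFloor
  rf <- raw_median(m$median_fresh, cofactor)
  rx <- raw_median(m$median_fixed, cofactor)
  m$log10_ratio <- ifelse(rf > 0 & rx > 0, log10(rx / rf), NA_real_)

  expressed <- sort(unique(m$antibody[m$expressing]))
  cut <- log10(foldThreshold)
  by_ab <- do.call(rbind, lapply(expressed, function(ab) {
    r <- m$log10_ratio[m$antibody == ab & m$expressing]
    sr <- stats::median(r, na.rm = TRUE)
    cls <- if (is.na(sr)) "unchanged"
           else if (sr >= cut) "gain"
           else if (sr <= -cut) "loss"
           else "unchanged"
    data.frame(antibody = ab, summary_ratio = sr, class = cls,
               stringsAsFactors = FALSE)
  }))
  list(
    bySubset = m[, c("profiling_subset", "antibody", "log10_ratio")],
    byAntibody = by_ab %||% data.frame(antibody = character(0),
                                       summary_ratio = numeric(0),
                                       class = character(0)),
    expressed = expressed
  )
}

#' Differential markers between two subsets by standardized residuals
#'
#' Per donor, percent positive in subset A is regressed on percent positive
#' in subset B across antibodies (ordinary least squares with intercept);
#' residuals are standardized by their own standard deviation. An antibody
#' is flagged when its absolute standardized residual exceeds
#' `residualCutoff` in every donor and the residual sign agrees across
#' donors (sign conflicts are dropped with a warning).
#'
#' @param ppPos,ppNeg numeric matrices, antibodies x donors, of percent
#'   positive in the two subsets; identical dimnames.
#' @param residualCutoff absolute standardized-residual cutoff (default 2).
#' @return list with `residuals` (antibody x donor standardized residuals),
#'   `flagged` (data.frame: `antibody`, `direction`).
#' @export
differentialMarkers <- function(ppPos, ppNeg, residualCutoff = 2) {
  ppPos <- as.matrix(ppPos); ppNeg <- as.matrix(ppNeg)
  if (!identical(dim(ppPos), dim(ppNeg)) ||
      !identical(rownames(ppPos), rownames(ppNeg))) {
    stop_validation("ppPos and ppNeg must share antibodies and donors")
  }
  if (ncol(ppPos) < 2) {
    stop_validation("need at least 2 donors for a consensus")
  }
  if (nrow(ppPos) < 10) {
    stop_validation("need at least 10 antibodies per donor")
  }
  sr <- matrix(NA_real_, nrow(ppPos), ncol(ppPos), dimnames = dimnames(ppPos))
  for (j in seq_len(ncol(ppPos))) {
    fit <- stats::lm(ppPos[, j] ~ ppNeg[, j])
    res <- stats::residuals(fit)
    s <- stats::sd(res)
    ## a numerically perfect fit leaves only floating-point noise; treat
    ## it as zero residuals rather than standardizing the noise
    degenerate <- s <= 1e-8 * max(1, stats::sd(ppPos[, j]))
    sr[, j] <- if (degenerate) 0 else res / s
  }
  hits <- rowSums(abs(sr) > residualCutoff) == ncol(sr)
  flagged <- rownames(sr)[hits]
  consistent <- vapply(flagged, function(ab) {
    length(unique(sign(sr[ab, ]))) == 1
  }, logical(1))
  if (any(!consistent)) {
    warning("direction inconsistent across donors, dropped: ",
            paste(flagged[!consistent], collapse = ", "))
  }
  flagged <- flagged[consistent]
  list(
    residuals = sr,
    flagged = data.frame(
      antibody = flagged,
      direction = if (length(flagged))
        ifelse(sr[flagged, 1] > 0, "positive", "negative")
      else character(0),
      stringsAsFactors = FALSE
    )
  )
}
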