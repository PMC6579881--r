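#' One-vs-rest confusion counts
#'
#' Sets `target` as the positive class and everything else as negative,
#' with `truth` as the reference.
#'
#' @param truth,pred per-event class labels, equal length.
#' @param target the class treated as positive.
#' @return named list `TP`, `FP`, `TN`, `FN` (their sum is the number of
#'   compared events).
#' @export
confusionCounts <- function(truth, pred, target) {
  if (length(truth) != length(pred)) {
    stop_validation("truth and pred must have equal length")
  }
  t_pos <- truth == target
  p_pos <- pred == target
  list(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
       TN = sum(!t_pos & !p_pos), FN = sum(t_pos & !p_pos))
}

#' Relevance metrics for one-vs-rest classification
#'
#' `precision` is TP/(TP+FP): the frequency of correctly classified target
#' events out of all events classified as target. `recall` is TP/(TP+FN).
#' `f1Score` is the harmonic mean of precision and recall. `mcc` is the
#' Matthews correlation coefficient, (TP*TN - FP*FN) over the root of the
#' four marginal products; it equals the Pearson correlation of the two
#' binary indicator vectors. Zero denominators return 0 (with a warning for
#' precision/recall; for MCC, 0 by convention).
#'
#' @param counts a list from [confusionCounts()].
#' @param p,r precision and recall values for `f1Score`.
#' @return a number in [0, 1] (MCC in [-1, 1]).
#' @examples
#' f1Score(0.996, 0.914)  # 0.953
#' @export
precision <- function(counts) {
  den <- counts$TP + counts$FP
  if (den == 0) {
    warning("precision undefined (no predicted positives); returning 0")
    return(0)
  }
  counts$TP / den
}

#' @rdname precision
#' @export
recall <- function(counts) {
  den <- counts$TP + counts$FN
  if (den == 0) {
    warning("recall undefined (no true positives); returning 0")
    return(0)
  }
  counts$TP / den
}

#' @rdname precision
#' @export
f1Score <- function(p, r) {
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' @rdname precision
#' @export
mcc <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Average Overlap Frequency of two staining modalities
#'
#' Quantifies how much a marker's negative and positive modalities overlap.
#' A normal distribution is fitted (mean, sd) to each modality; the AOF is
#' the mean of two tail frequencies: the fraction of negative events above
#' the 5th percentile of the positive-fitted normal, and the fraction of
#' positive events below the 95th percentile of the negative-fitted normal.
#' It is 0 for completely separated modalities and approaches 0.95 (the
#' formula's intrinsic ceiling, \eqn{\Phi(1.645)}) when the modalities are
#' identical. A zero-sd modality is treated as a point mass (its tail
#' percentile equals its mean).
#'
#' @param neg,pos numeric values of the negative and positive modality;
#'   both must be non-empty.
#' @return a number in [0, 1].
#' @export
aof <- function(neg, pos) {
  if (length(neg) == 0 || length(pos) == 0) {
    stop_validation("both modalities must be non-empty")
  }
  q_of <- function(v, p) {
    m <- mean(v)
    s <- if (length(v) > 1) stats::sd(v) else 0
    if (s == 0) m else stats::qnorm(p, mean = m, sd = s)
  }
  lo_pos <- q_of(pos, 0.05)   # 5th percentile of positive-fitted normal
  hi_neg <- q_of(neg, 0.95)   # 95th percentile of negative-fitted normal
  val <- 0.5 * (mean(neg > lo_pos) + mean(pos < hi_neg))
  min(max(val, 0), 1)
}

#' Split marker values into negative and positive modalities
#'
#' @param values numeric marker intensities.
#' @param method `"two_means"` (2-cluster 1-d split with the boundary at
#'   the midpoint of the cluster centers), `"fixed_threshold"` (user
#'   cutoff) or `"labeled"` (caller supplies the per-event modality).
#' @param threshold cutoff for `fixed_threshold`.
#' @param labels logical per-event vector for `labeled` (`TRUE` =
#'   positive).
#' @return list with `neg` and `pos` value vectors and the `boundary` used
#'   (NA for `labeled`).
#' @export
splitModalities <- function(values,
                            method = c("two_means", "fixed_threshold",
                                       "labeled"),
                            threshold = NULL, labels = NULL) {
  method <- match.arg(method)
  if (method == "labeled") {
    if (is.null(labels) || length(labels) != length(values)) {
      stop_validation("labeled split needs one logical label per value")
    }
    return(list(neg = values[!labels], pos = values[labels],
                boundary = NA_real_))
  }
  if (method == "fixed_threshold") {
    if (is.null(threshold)) stop_validation("fixed_threshold needs a cutoff")
    return(list(neg = values[values <= threshold],
                pos = values[values > threshold], boundary = threshold))
  }
  ## two_means
  if (length(values) < 2) stop_validation("two_means needs at least 2 values")
  if (length(unique(values)) < 2) {
    stop_validation("values are constant: no modality structure")
  }
  centers <- sort(unique(stats::quantile(values, c(0.1, 0.9),
                                         names = FALSE)))
  if (length(centers) < 2) centers <- range(values)
  km <- stats::kmeans(values, centers = matrix(centers, ncol = 1))
  boundary <- mean(range(km$centers))
  list(neg = values[values <= boundary], pos = values[values > boundary],
       boundary = boundary)
}

#' Scaled-squared AOF across samples
#'
#' Per marker row of an AOF matrix, values are z-scored against the row
#' (mean, sd), negative z floored at 0, then squared. A constant row (sd 0)
#' scales to 0. `aofQuality` sums the scaled matrix per sample (column);
#' high values flag samples whose staining quality is unusually poor for
#' one or more markers.
#'
#' @param aofMat marker x sample numeric matrix of AOF values.
#' @return matrix of the same shape (`scaledAof`), or a per-sample numeric
#'   vector (`aofQuality`).
#' @export
scaledAof <- function(aofMat) {
  aofMat <- as.matrix(aofMat)
  if (ncol(aofMat) < 2) {
    warning("fewer than 2 samples: Scaled^2 AOF set to 0")
    out <- aofMat * 0
    return(out)
  }
  t(apply(aofMat, 1, function(row) {
    s <- stats::sd(row)
    if (s == 0) return(row * 0)
    pmax((row - mean(row)) / s, 0)^2
  }))
}

#' @rdname scaledAof
#' @param scaled a matrix from [scaledAof()].
#' @export
aofQuality <- function(scaled) {
  colSums(as.matrix(scaled))
}

#' Build an AofReport from per-(marker, sample) value lists
#'
#' @param values nested list: `values[[marker]][[sample]]` is the numeric
#'   vector of that marker's intensities in that sample.
#' @param method,threshold,labels passed to [splitModalities()]; `labels`
#'   may be a parallel nested list for `method = "labeled"`.
#' @return an [AofReport-class] object.
#' @export
buildAofReport <- function(values, method = "two_means", threshold = NULL,
                           labels = NULL) {
  markers <- names(values)
  samples <- names(values[[1]])
  a <- matrix(NA_real_, length(markers), length(samples),
              dimnames = list(markers, samples))
  meta <- list()
  for (m in markers) {
    for (s in samples) {
      sp <- splitModalities(values[[m]][[s]], method = method,
                            threshold = threshold,
                            labels = if (is.null(labels)) NULL else
                              labels[[m]][[s]])
      a[m, s] <- aof(sp$neg, sp$pos)
      meta[[paste(m, s, sep = "|")]] <- list(boundary = sp$boundary,
                                             nNeg = length(sp$neg),
                                             nPos = length(sp$pos))
    }
  }
  sc <- suppressWarnings(scaledAof(a))
  new("AofReport", aof = a, scaled = sc, quality = aofQuality(sc),
      modality = meta)
}

#' @rdname AofReport-class
#' @export
setMethod("aofMatrix", "AofReport", function(x) x@aof)

#' @rdname AofReport-class
#' @export
setMethod("sampleQuality", "AofReport", function(x) x@quality)

setMethod("show", "AofReport", function(object) {
  cat("AofReport:", nrow(object@aof), "markers x", ncol(object@aof),
      "samples\n")
  cat("Quality^2 AOF per sample:\n")
  print(round(object@quality, 3))
})

#' Acquisition-drift detection by time-quartile AOF
#'
#' Splits the events into four equal-count quartiles of acquisition time,
#' computes the marker's AOF within each, and flags the sample when the
#' last quartile's AOF exceeds the first's by more than `driftThreshold`.
#' A time-dependent rise in background (e.g. an instrument malfunction)
#' shows up as AOF increasing across quartiles; restricting analysis to the
#' first quartile then recovers the undrifted staining quality.
#'
#' @param events a [CytoEvents-class] with acquisition time.
#' @param marker channel to evaluate.
#' @param method,threshold,labels modality split, see [splitModalities()].
#' @param driftThreshold AOF-units increase that triggers the flag
#'   (default 0.1).
#' @return list with `aof` (length-4 vector, first to last quartile),
#'   `flag`, and `drift` (last minus first).
#' @export
quartileDrift <- function(events, marker, method = "two_means",
                          threshold = NULL, labels = NULL,
                          driftThreshold = 0.1) {
  at <- acquisitionTime(events)
  if (is.null(at)) stop_validation("events carry no acquisition time")
  if (!marker %in% channelNames(events)) {
    stop_key("channel not present: ", marker)
  }
  v <- events@exprs[, marker]
  n <- length(v)
  if (n < 4) stop_validation("need at least 4 events for quartile analysis")
  qt <- ceiling(4 * rank(at, ties.method = "first") / n)
  ## the modality boundary is estimated once on all events and applied as
  ## a fixed cutoff per quartile: re-splitting within a quartile would let
  ## a drifting background re-define the modalities and mask the drift
  if (method == "two_means") {
    boundary <- splitModalities(v, method = "two_means")$boundary
    method <- "fixed_threshold"
    threshold <- boundary
  }
  aofs <- vapply(1:4, function(q) {
    idx <- qt == q
    sp <- splitModalities(v[idx], method = method, threshold = threshold,
                          labels = if (is.null(labels)) NULL else labels[idx])
    aof(sp$neg, sp$pos)
  }, numeric(1))
  drift <- aofs[4] - aofs[1]
  list(aof = aofs, flag = drift > driftThreshold, drift = drift)
}
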