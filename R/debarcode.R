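## Assignment of pooled events back to their source samples from their
## k-of-n barcode channel signatures, by either a per-event top-k rule or
## the cluster-then-label route used for subset labeling.

## Rescale each barcode channel to [0, 1] by its 1st-99th percentile window
## (robust to outliers), clamping outside the window. A channel whose own
## window is degenerate -- e.g. a partial batch in which some outer-tier
## channel is never positive, so its window spans only noise -- falls back
## to the window pooled over all barcode channels, which share positive and
## negative levels by design.
rescale_barcode <- function(x, lower = 0.01, upper = 0.99) {
  pooled <- stats::quantile(x, c(lower, upper), names = FALSE, type = 7)
  pooled_spread <- pooled[2] - pooled[1]
  apply(x, 2, function(v) {
    q <- stats::quantile(v, c(lower, upper), names = FALSE, type = 7)
    if ((q[2] - q[1]) < 0.5 * pooled_spread) q <- pooled
    if (q[2] <= q[1]) return(rep(0, length(v)))
    pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  })
}

debarcode_result <- function(assignment, separation, nCodes) {
  new("DebarcodeResult", assignment = as.integer(assignment),
      separation = as.numeric(separation), nCodes = as.integer(nCodes))
}

#' @rdname DebarcodeResult-class
#' @export
setMethod("assignments", "DebarcodeResult", function(x) x@assignment)

#' @rdname DebarcodeResult-class
#' @export
setMethod("perCodeCounts", "DebarcodeResult", function(x) {
  counts <- tabulate(x@assignment + 1L, nbins = x@nCodes)
  stats::setNames(counts, seq_len(x@nCodes) - 1L)
})

setMethod("show", "DebarcodeResult", function(object) {
  n <- length(object@assignment)
  na <- sum(is.na(object@assignment))
  cat("DebarcodeResult:", n, "events,", n - na, "assigned (",
      if (n) round(100 * (n - na) / n, 1) else 0, "% ),",
      object@nCodes, "codes\n")
})

#' Per-event top-k debarcoding
#'
#' Barcode channels are rescaled per channel to [0, 1] by their 1st-99th
#' percentile window; the k brightest channels of each event form its
#' candidate code. The event is assigned if and only if the candidate is a
#' valid scheme code and the separation (rescaled gap between the k-th and
#' (k+1)-th brightest channel) is at least `minSeparation`; otherwise it is
#' UNASSIGNED. The default `minSeparation` of 0.3 rejects ambiguous
#' doublet-like signatures.
#'
#' @param events an arcsinh-scale [CytoEvents-class] object.
#' @param scheme a [BarcodeScheme-class] object.
#' @param minSeparation nonnegative rejection threshold (normalized units).
#' @return a [DebarcodeResult-class] object.
#' @export
debarcodeTopK <- function(events, scheme, minSeparation = 0.3) {
  if (events@scale != "arcsinh") {
    stop_validation("debarcoding expects arcsinh-transformed events")
  }
  miss <- setdiff(scheme@channels, channelNames(events))
  if (length(miss)) stop_key("barcode channel(s) missing: ",
                             paste(miss, collapse = ", "))
  if (minSeparation < 0) stop_validation("minSeparation must be >= 0")
  n <- nEvents(events)
  if (n == 0) return(debarcode_result(integer(0), numeric(0), nCodes(scheme)))

  x <- rescale_barcode(events@exprs[, scheme@channels, drop = FALSE])
  k <- scheme@k
  nch <- length(scheme@channels)

  ord <- t(apply(x, 1, order, decreasing = TRUE))
  sorted <- t(apply(x, 1, sort, decreasing = TRUE))
  separation <- if (k < nch) sorted[, k] - sorted[, k + 1L] else sorted[, k]

  ## candidate code as a logical pattern, matched against the scheme rows
  pattern <- matrix(FALSE, n, nch)
  pattern[cbind(rep(seq_len(n), k), as.vector(ord[, seq_len(k), drop = FALSE]))] <- TRUE
  code_key <- apply(scheme@codes, 1, function(r) paste(as.integer(r), collapse = ""))
  event_key <- apply(pattern, 1, function(r) paste(as.integer(r), collapse = ""))
  cand <- match(event_key, code_key) - 1L

  assignment <- ifelse(!is.na(cand) & separation >= minSeparation,
                       cand, NA_integer_)
  debarcode_result(assignment, separation, nCodes(scheme))
}

#' Cluster-based debarcoding
#'
#' The cluster-then-label route: events are clustered on the barcode
#' channels (SOM + metaclustering), each cluster is signed per channel by
#' the MCC-optimal cutoff, and a cluster is assigned to the code whose
#' k-positive / (n-k)-negative conjunction its sign vector satisfies —
#' the scheme acting as a one-level gating hierarchy. Events in clusters
#' matching no code are UNASSIGNED. When a channel shows no contrast
#' across clusters (a single code present, or a tier channel unused in a
#' partial batch), its clusters are signed against the pooled midrange of
#' all barcode channels, which share positive and negative levels by
#' design. No per-event separation score is produced (reported as 0).
#'
#' @param events an arcsinh-scale [CytoEvents-class] object.
#' @param scheme a [BarcodeScheme-class] object.
#' @param params clustering parameters, see [clusterParams()]. The default
#'   metacluster count is twice the number of codes (capped at `kMax`).
#' @return a [DebarcodeResult-class] object.
#' @export
debarcodeCluster <- function(events, scheme,
                             params = clusterParams(kMax = 30)) {
  if (events@scale != "arcsinh") {
    stop_validation("debarcoding expects arcsinh-transformed events")
  }
  miss <- setdiff(scheme@channels, channelNames(events))
  if (length(miss)) stop_key("barcode channel(s) missing: ",
                             paste(miss, collapse = ", "))
  n <- nEvents(events)
  if (n == 0) return(debarcode_result(integer(0), numeric(0), nCodes(scheme)))
  x <- events@exprs[, scheme@channels, drop = FALSE]
  sub <- cytoEvents(x, scale = "arcsinh")
  model <- fitSOM(sub, scheme@channels, gridRows = params$gridRows,
                  gridCols = params$gridCols, seed = params$seed,
                  epochs = params$epochs)
  ## sign at node granularity (identity metaclustering): agglomerating
  ## nodes first can chain distinct codes together when inter-code
  ## distances tie, and fine clusters cost nothing for code matching
  k <- params$k %||% (model@gridRows * model@gridCols)
  k <- max(1L, min(k, model@gridRows * model@gridCols))
  cl <- assignEvents(metaCluster(model, k), sub)

  mid <- mean(stats::quantile(x, c(0.01, 0.99), names = FALSE, type = 7))
  obs <- sort(unique(cl))
  signs <- matrix("-", length(obs), ncol(x),
                  dimnames = list(obs, scheme@channels))
  for (ch in scheme@channels) {
    th <- mccThreshold(x[, ch], cl)
    if (th$informative) {
      signs[, ch] <- th$signs[as.character(obs)]
    } else {
      meds <- vapply(obs, function(g) {
        stats::median(x[cl == g, ch])
      }, numeric(1))
      signs[, ch] <- ifelse(meds > mid, "+", "-")
    }
  }
  code_key <- apply(scheme@codes, 1, function(r) {
    paste(ifelse(r, "+", "-"), collapse = "")
  })
  cluster_code <- (match(apply(signs, 1, paste, collapse = ""),
                         code_key) - 1L)[match(cl, obs)]
  debarcode_result(cluster_code, rep(0, n), nCodes(scheme))
}

#' Two-tier debarcoding of a pooled batch
#'
#' Resolves the outer (well-within-batch, palladium) tier first, then the
#' inner (donor x treatment, CD45) tier, and maps the (inner, outer) code
#' pair through the batch's expected-code table. An event is assigned iff
#' both tiers resolve AND the pair is expected in this batch; otherwise it
#' is UNASSIGNED (never an error).
#'
#' @param events an arcsinh-scale [CytoEvents-class] object (one pooled
#'   batch).
#' @param manifest an [ExperimentManifest-class] object.
#' @param batchId batch identifier.
#' @param method `"topk"` or `"cluster"`.
#' @param minSeparation passed to [debarcodeTopK()].
#' @param params passed to [debarcodeCluster()].
#' @return data.frame with one row per event: `donor`, `treatment`,
#'   `well_id`, `antibody` (NA when unassigned), plus `inner_code`,
#'   `outer_code` and `separation` diagnostics.
#' @export
twoTierDebarcode <- function(events, manifest, batchId,
                             method = c("topk", "cluster"),
                             minSeparation = 0.3,
                             params = clusterParams(kMax = 30)) {
  method <- match.arg(method)
  expected <- expectedCodes(manifest, batchId)
  run <- function(scheme) {
    if (method == "topk") {
      debarcodeTopK(events, scheme, minSeparation = minSeparation)
    } else {
      debarcodeCluster(events, scheme, params = params)
    }
  }
  outer <- run(manifest@outerScheme)
  inner <- run(manifest@innerScheme)

  key <- paste(assignments(inner), assignments(outer))
  hit <- match(key, paste(expected$inner_code, expected$outer_code))
  out <- data.frame(
    inner_code = assignments(inner),
    outer_code = assignments(outer),
    donor = expected$donor[hit],
    treatment = expected$treatment[hit],
    well_id = expected$well_id[hit],
    antibody = expected$antibody[hit],
    separation = pmin(inner@separation, outer@separation),
    stringsAsFactors = FALSE
  )
  out$assigned <- !is.na(hit)
  out
}

#' Score a debarcoding result against ground truth
#'
#' One-vs-rest precision/recall/F1/MCC per code plus overall accuracy among
#' assigned events.
#'
#' @param truth per-event true code id (or any label vector).
#' @param result a [DebarcodeResult-class] or a vector of predicted labels.
#' @return list with `accuracy` (fraction of assigned events whose
#'   prediction matches truth), `assignedFraction`, and a per-code metric
#'   data.frame.
#' @export
scoreDebarcode <- function(truth, result) {
  pred <- if (is(result, "DebarcodeResult")) assignments(result) else result
  if (length(pred) != length(truth)) {
    stop_validation("truth and prediction must have equal length")
  }
  assigned <- !is.na(pred)
  accuracy <- if (any(assigned)) {
    mean(pred[assigned] == truth[assigned])
  } else {
    NA_real_
  }
  codes <- sort(unique(truth))
  per_code <- do.call(rbind, lapply(codes, function(cc) {
    cts <- confusionCounts(truth, ifelse(is.na(pred), "__none__", pred), cc)
    p <- precision(cts); r <- recall(cts)
    data.frame(code = cc, precision = p, recall = r,
               f1 = f1Score(p, r), mcc = mcc(cts))
  }))
  list(accuracy = accuracy, assignedFraction = mean(assigned),
       perCode = per_code)
}
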