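## Per-subset profiling: every terminal cell subset is clustered separately
## (so clusters never straddle biologically distinct subsets) and the
## resulting profiling subsets are named by the markers that differentiate
## them the most, according to the MCC.

#' Profiling parameters
#'
#' @param minCells minimum events for a subset to be split at all
#'   (default 200).
#' @param theta achievable-MCC threshold above which a marker counts as
#'   heterogeneous (default 0.7).
#' @param kMax cap on profiling clusters per subset (default 8).
#' @param gridRows,gridCols,epochs SOM settings.
#' @export
profilingParams <- function(minCells = 200, theta = 0.7, kMax = 8,
                            gridRows = 8, gridCols = 8, epochs = 10) {
  list(minCells = minCells, theta = theta, kMax = kMax,
       gridRows = gridRows, gridCols = gridCols, epochs = epochs)
}

#' Best achievable binarization MCC of a marker
#'
#' Measures marker heterogeneity within a subset: a one-dimensional
#' Gaussian mixture (1 vs 2 components, chosen by BIC) is fitted to the
#' values; a unimodal fit scores 0, and for a bimodal fit the score is the
#' MCC of the best threshold classifier between the two fitted components
#' (computed in closed form from the component normals and mixing
#' proportions). A cleanly bimodal marker scores near 1; a unimodal or
#' heavily overlapping marker scores near 0, so slicing a continuum never
#' counts as heterogeneity.
#'
#' @param values numeric marker intensities (arcsinh scale).
#' @return a number in [0, 1].
#' @export
achievableMcc <- function(values) {
  if (length(values) < 10 || stats::sd(values) == 0) return(0)
  ## Mclust resolves mclustBIC in the caller's frame; bind it locally
  mclustBIC <- mclust::mclustBIC
  fit <- tryCatch(
    mclust::Mclust(values, G = 1:2, verbose = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$G < 2) return(0)
  p <- fit$parameters$pro
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  o <- order(mu)
  mu <- mu[o]; sg <- sg[o]; p <- p[o]
  if (min(p) < 0.01) return(0)
  grid <- seq(mu[1], mu[2], length.out = 201)
  best <- 0
  for (t in grid) {
    tp <- p[2] * (1 - stats::pnorm(t, mu[2], sg[2]))
    fn <- p[2] - tp
    fp <- p[1] * (1 - stats::pnorm(t, mu[1], sg[1]))
    tn <- p[1] - fp
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den > 0) best <- max(best, (tp * tn - fp * fn) / den)
  }
  min(max(best, 0), 1)
}

#' Choose the number of profiling clusters
#'
#' The heuristic depends on the number of cells in the subset and on marker
#' heterogeneity: 1 cluster when the subset is small
#' (`nEvents < minCells`) or no marker reaches an achievable binarization
#' MCC of `theta`; otherwise 1 plus the number of markers at or above
#' `theta`, capped at `min(kMax, floor(nEvents / minCells))`.
#'
#' @param nEvents number of events in the subset.
#' @param markerMcc numeric vector of per-marker best achievable
#'   binarization MCC.
#' @param params see [profilingParams()].
#' @return an integer >= 1.
#' @export
chooseK <- function(nEvents, markerMcc, params = profilingParams()) {
  if (nEvents < params$minCells) return(1L)
  nhet <- sum(markerMcc >= params$theta)
  if (nhet == 0) return(1L)
  as.integer(max(1L, min(1L + nhet, params$kMax,
                         floor(nEvents / params$minCells))))
}

#' Name profiling clusters by their most-separating markers
#'
#' For each marker, [mccThreshold()] is computed over the clusters; the
#' naming markers are those within 0.05 of the maximum MCC (at most 2).
#' Each cluster is named by those markers with an `hi`/`lo` suffix per its
#' sign. Colliding names are disambiguated by appending the next-best
#' marker; when every marker is uninformative the clusters fall back to
#' `C1..Ck`.
#'
#' @param values numeric matrix (events x markers) for the subset.
#' @param clusters per-event cluster ids.
#' @param minMcc naming floor: markers below this MCC (default 0.2) never
#'   name a cluster, so arbitrary splits fall back to `C1..Ck` instead of
#'   borrowing a meaningless marker name.
#' @return named character vector: cluster id -> auto name.
#' @export
nameClusters <- function(values, clusters, minMcc = 0.2) {
  ids <- sort(unique(clusters))
  fallback <- stats::setNames(paste0("C", seq_along(ids)), ids)
  if (length(ids) < 2) return(fallback)
  markers <- colnames(values)
  th <- lapply(markers, function(m) mccThreshold(values[, m], clusters))
  names(th) <- markers
  mccs <- vapply(th, function(t) t$mcc, numeric(1))
  if (all(!vapply(th, function(t) t$informative, logical(1))) ||
      max(mccs) < minMcc) {
    return(fallback)
  }
  ranked <- markers[order(-mccs, seq_along(markers))]
  sel <- ranked[mccs[ranked] >= max(mccs) - 0.05]
  sel <- utils::head(sel, 2)

  make_names <- function(markerSet) {
    vapply(as.character(ids), function(g) {
      paste(vapply(markerSet, function(m) {
        paste0(m, if (th[[m]]$signs[[g]] == "+") "hi" else "lo")
      }, character(1)), collapse = " ")
    }, character(1))
  }
  nm <- make_names(sel)
  extra <- setdiff(ranked, sel)
  while (anyDuplicated(nm) && length(extra)) {
    sel <- c(sel, extra[1])
    extra <- extra[-1]
    nm <- make_names(sel)
  }
  if (anyDuplicated(nm)) {
    dup <- duplicated(nm) | duplicated(nm, fromLast = TRUE)
    nm[dup] <- paste0(nm[dup], " C", seq_along(ids)[dup])
  }
  stats::setNames(nm, ids)
}

#' Profile one cell subset
#'
#' Each marker's heterogeneity is measured by [achievableMcc()];
#' [chooseK()] turns that profile into a cluster count; a SOM is fitted on
#' the profiling markers, cut at that count, and the clusters are named by
#' [nameClusters()]. A subset below `minCells`, or with no heterogeneous
#' marker, stays a single cluster named after the parent subset.
#'
#' @param subsetEvents arcsinh-scale [CytoEvents-class] of the subset's
#'   events.
#' @param markers profiling markers.
#' @param subsetName parent subset name (used for the k = 1 cluster name).
#' @param params see [profilingParams()].
#' @param seed RNG seed.
#' @return list with `labels` (per-event auto name), `clusters`
#'   (data.frame: `cluster`, `auto_name`, `n`), `markerMcc` (named numeric)
#'   and `k`.
#' @export
profileSubset <- function(subsetEvents, markers, subsetName = "Subset",
                          params = profilingParams(), seed = 1) {
  n <- nEvents(subsetEvents)
  empty <- list(labels = character(0),
                clusters = data.frame(cluster = integer(0),
                                      auto_name = character(0),
                                      n = integer(0)),
                markerMcc = stats::setNames(numeric(length(markers)),
                                            markers),
                k = 0L)
  if (n == 0) return(empty)

  one_cluster <- function(markerMcc) {
    list(labels = rep(subsetName, n),
         clusters = data.frame(cluster = 1L, auto_name = subsetName, n = n),
         markerMcc = markerMcc, k = 1L)
  }
  if (n < params$minCells) {
    return(one_cluster(stats::setNames(rep(NA_real_, length(markers)),
                                       markers)))
  }

  vals <- subsetEvents@exprs[, markers, drop = FALSE]
  markerMcc <- vapply(markers, function(m) achievableMcc(vals[, m]),
                      numeric(1))
  k <- chooseK(n, markerMcc, params)
  if (k == 1L) return(one_cluster(markerMcc))

  model <- fitSOM(subsetEvents, markers, gridRows = params$gridRows,
                  gridCols = params$gridCols, seed = seed,
                  epochs = params$epochs)
  cut <- metaCluster(model, k)
  cl <- assignEvents(cut, subsetEvents)
  nm <- nameClusters(vals, cl)
  labels <- unname(nm[as.character(cl)])
  tab <- table(factor(cl, levels = names(nm)))
  list(labels = labels,
       clusters = data.frame(cluster = as.integer(names(nm)),
                             auto_name = unname(nm),
                             n = as.integer(tab), row.names = NULL),
       markerMcc = markerMcc, k = k)
}

#' Profile every terminal subset of a labeling
#'
#' @param events arcsinh-scale [CytoEvents-class] for all events.
#' @param labeling a [SubsetLabeling-class] (or a per-event label vector).
#' @param markers profiling markers.
#' @param params see [profilingParams()].
#' @param seed base RNG seed; per-subset seeds are derived from it.
#' @return list with `perEvent` (data.frame: `subset`,
#'   `profiling_subset`), `clusters` (data.frame: `subset`, `cluster`,
#'   `auto_name`, `n`, `frequency`) and `markerMcc` (subset x marker
#'   matrix). UNASSIGNED events keep the profiling subset `UNASSIGNED`.
#' @export
profileSubsets <- function(events, labeling, markers,
                           params = profilingParams(), seed = 1) {
  lbl <- if (is(labeling, "SubsetLabeling")) labels(labeling) else labeling
  if (length(lbl) != nEvents(events)) {
    stop_validation("labeling must cover every event")
  }
  subsets <- setdiff(sort(unique(lbl)), UNASSIGNED)
  perEvent <- data.frame(subset = lbl, profiling_subset = lbl,
                         stringsAsFactors = FALSE)
  clusters <- list()
  mccTab <- matrix(NA_real_, length(subsets), length(markers),
                   dimnames = list(subsets, markers))
  for (s in subsets) {
    idx <- which(lbl == s)
    sub <- new("CytoEvents", exprs = events@exprs[idx, , drop = FALSE],
               scale = events@scale, acquisitionTime = numeric(0))
    res <- profileSubset(sub, markers, subsetName = s, params = params,
                         seed = child_seed(seed, s))
    pname <- if (res$k <= 1L) res$labels else paste(s, res$labels)
    perEvent$profiling_subset[idx] <- pname
    if (nrow(res$clusters)) {
      cl <- res$clusters
      cl$subset <- s
      cl$profiling_subset <- if (res$k <= 1L) cl$auto_name else
        paste(s, cl$auto_name)
      cl$frequency <- cl$n / length(idx)
      clusters[[s]] <- cl[, c("subset", "profiling_subset", "cluster",
                              "auto_name", "n", "frequency")]
    }
    mccTab[s, ] <- res$markerMcc
  }
  list(perEvent = perEvent,
       clusters = if (length(clusters)) do.call(rbind, c(clusters,
                                                 make.row.names = FALSE))
                  else NULL,
       markerMcc = mccTab)
}
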