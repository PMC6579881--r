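#' Construct a gating hierarchy
#'
#' @param levels a list of levels, each a list of rules; a rule is a list
#'   with elements `parent`, `child` and `terms`, where `terms` is a list
#'   of `list(marker =, sign =)` entries (`sign` is `"+"` or `"-"`).
#' @param root name of the root label (default `"Cell"`).
#' @return a [GatingHierarchy-class] object.
#' @examples
#' h <- gatingHierarchy(list(list(
#'   list(parent = "Cell", child = "T Cells",
#'        terms = list(list(marker = "CD3", sign = "+"))),
#'   list(parent = "Cell", child = "B Cells",
#'        terms = list(list(marker = "CD19", sign = "+")))
#' )))
#' terminalLabels(h)
#' @export
gatingHierarchy <- function(levels, root = "Cell") {
  rows <- list()
  for (lv in seq_along(levels)) {
    for (rule in levels[[lv]]) {
      tm <- do.call(rbind, lapply(rule$terms, function(t) {
        data.frame(marker = t$marker, sign = t$sign,
                   stringsAsFactors = FALSE)
      }))
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, parent = rule$parent, child = rule$child,
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$terms <- list(tm)
    }
  }
  rules <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = integer(0), parent = character(0),
               child = character(0), terms = I(list()))
  new("GatingHierarchy", root = root, rules = rules)
}

#' Read a gating hierarchy from YAML or JSON
#'
#' Expected structure: `root:` and `levels:`, where `levels` is a list of
#' lists of rules `{parent, child, terms: [{marker, sign}]}`.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a [GatingHierarchy-class] object.
#' @export
readGatingHierarchy <- function(path) {
  obj <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  gatingHierarchy(obj$levels, root = obj$root %||% "Cell")
}

#' Labels of a hierarchy with no outgoing rules
#'
#' @param hierarchy a [GatingHierarchy-class] object.
#' @return character vector of terminal subset names (the root if there are
#'   no rules at all).
#' @export
terminalLabels <- function(hierarchy) {
  r <- hierarchy@rules
  if (nrow(r) == 0) return(hierarchy@root)
  setdiff(unique(r$child), unique(r$parent))
}

#' All markers referenced by a hierarchy's rules
#' @param hierarchy a [GatingHierarchy-class] object.
#' @export
hierarchyMarkers <- function(hierarchy) {
  unique(unlist(lapply(hierarchy@rules$terms, function(t) t$marker)))
}

setMethod("show", "GatingHierarchy", function(object) {
  r <- object@rules
  cat("GatingHierarchy: root '", object@root, "', ", nrow(r), " rules over ",
      length(unique(r$level)), " level(s), ",
      length(terminalLabels(object)), " terminal subsets\n", sep = "")
})

## MCC of two logical vectors, with the zero-denominator -> 0 convention.
binary_mcc <- function(e, p) {
  tp <- sum(e & p); tn <- sum(!e & !p)
  fp <- sum(!e & p); fn <- sum(e & !p)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' MCC-optimal marker cutoff over clusters
#'
#' The greedy threshold search used to turn a clustering into
#' marker-positivity calls. Candidate cutoffs are the midpoints between
#' consecutive sorted cluster medians. For a candidate `t`, events are
#' called positive when their value exceeds `t` and each cluster is signed
#' by whether its median exceeds `t`; the chosen cutoff maximizes the
#' Matthews correlation between the event-level calls and the
#' cluster-propagated calls, with ties broken toward the lowest cutoff.
#'
#' @param values per-event marker intensities (arcsinh scale).
#' @param clusters per-event cluster ids.
#' @return a list with `cutoff` (NA when uninformative), `signs` (named
#'   character vector, `"+"`/`"-"` per cluster), `mcc` (achieved score, 0
#'   when uninformative), and `informative` (logical).
#' @examples
#' mccThreshold(c(0, 0, 10, 10), c("A", "A", "B", "B"))
#' @export
mccThreshold <- function(values, clusters) {
  if (length(values) != length(clusters)) {
    stop_validation("values and clusters must have equal length")
  }
  cl <- as.character(clusters)
  ids <- sort(unique(cl))
  meds <- vapply(ids, function(g) stats::median(values[cl == g]), numeric(1))
  uninformative <- list(
    cutoff = NA_real_,
    signs = stats::setNames(rep("-", length(ids)), ids),
    mcc = 0, informative = FALSE
  )
  if (length(ids) < 2 || length(unique(meds)) < 2) return(uninformative)

  sm <- sort(unique(meds))
  cand <- (sm[-length(sm)] + sm[-1]) / 2
  best <- NULL
  for (t in cand) {               # ascending: first strict max wins ties low
    e <- values > t
    p <- meds[cl] > t
    s <- binary_mcc(e, p)
    if (is.null(best) || s > best$mcc + 1e-12) {
      best <- list(cutoff = t, mcc = s)
    }
  }
  list(
    cutoff = best$cutoff,
    signs = stats::setNames(ifelse(meds > best$cutoff, "+", "-"), ids),
    mcc = best$mcc, informative = TRUE
  )
}

#' Default clustering parameters for hierarchy labeling
#'
#' @param gridRows,gridCols SOM grid per parent group (default 8 x 8).
#' @param k metacluster count; `NULL` means twice the number of child
#'   labels of the group, capped at `kMax`.
#' @param kMax cap on the automatic metacluster count (default 20).
#' @param epochs SOM training epochs.
#' @param seed integer base seed; per-group seeds are derived from it.
#' @export
clusterParams <- function(gridRows = 8, gridCols = 8, k = NULL, kMax = 20,
                          epochs = 10, seed = 1) {
  list(gridRows = gridRows, gridCols = gridCols, k = k, kMax = kMax,
       epochs = epochs, seed = seed)
}

## Label one hierarchy level. Returns updated labels, per-event cluster ids
## for this level, and the threshold audit rows.
#' Apply one level of gating rules to grouped events
#'
#' Each parent group is clustered independently on the union of its rules'
#' markers; per marker, [mccThreshold()] signs every cluster; a cluster is
#' assigned to the child of the unique rule whose conjunction its sign
#' vector satisfies, and to `UNASSIGNED` when no rule matches. A sign
#' vector satisfying several rules is a configuration error: rules within a
#' level must be mutually exclusive.
#'
#' @param events arcsinh-scale [CytoEvents-class] for all events.
#' @param parentLabels current per-event labels.
#' @param levelRules the rules data.frame rows for this level.
#' @param params see [clusterParams()].
#' @param level level number (only used in the threshold audit).
#' @return list with `labels`, `clusters` (integer per event, NA outside
#'   this level's parent groups) and `thresholds` (audit data.frame).
#' @export
labelLevel <- function(events, parentLabels, levelRules,
                       params = clusterParams(), level = 1L) {
  n <- nEvents(events)
  if (length(parentLabels) != n) {
    stop_validation("parentLabels must have one entry per event")
  }
  labels <- parentLabels
  clusters <- rep(NA_integer_, n)
  audit <- list()

  for (parent in unique(levelRules$parent)) {
    pr <- levelRules[levelRules$parent == parent, , drop = FALSE]
    idx <- which(parentLabels == parent)
    if (length(idx) == 0) next
    markers <- unique(unlist(lapply(pr$terms, function(t) t$marker)))
    miss <- setdiff(markers, channelNames(events))
    if (length(miss)) {
      stop_validation("hierarchy markers missing from panel: ",
                      paste(miss, collapse = ", "))
    }
    sub <- new("CytoEvents",
               exprs = events@exprs[idx, , drop = FALSE],
               scale = events@scale, acquisitionTime = numeric(0))
    k <- params$k %||% min(2L * nrow(pr), params$kMax)
    k <- max(1L, min(k, length(idx),
                     params$gridRows * params$gridCols))
    model <- fitSOM(sub, markers,
                    gridRows = params$gridRows, gridCols = params$gridCols,
                    seed = child_seed(params$seed, c(parent, level)),
                    epochs = params$epochs)
    model <- metaCluster(model, k)
    cl <- assignEvents(model, sub)
    clusters[idx] <- cl

    ## sign every observed cluster on every rule marker
    signs <- list()
    for (m in markers) {
      th <- mccThreshold(sub@exprs[, m], cl)
      signs[[m]] <- th$signs
      audit[[length(audit) + 1L]] <- data.frame(
        level = level, parent = parent, marker = m,
        cutoff = th$cutoff, mcc = th$mcc, stringsAsFactors = FALSE
      )
    }

    obs <- sort(unique(cl))
    for (g in obs) {
      gi <- as.character(g)
      hits <- vapply(seq_len(nrow(pr)), function(r) {
        tm <- pr$terms[[r]]
        all(vapply(seq_len(nrow(tm)), function(j) {
          signs[[tm$marker[j]]][[gi]] == tm$sign[j]
        }, logical(1)))
      }, logical(1))
      if (sum(hits) > 1) {
        stop_validation("cluster satisfies multiple rules under parent '",
                        parent, "'; level rules must be mutually exclusive")
      }
      labels[idx[cl == g]] <- if (sum(hits) == 1) {
        pr$child[hits]
      } else {
        UNASSIGNED
      }
    }
  }
  thresholds <- if (length(audit)) do.call(rbind, audit) else
    data.frame(level = integer(0), parent = character(0),
               marker = character(0), cutoff = numeric(0), mcc = numeric(0))
  list(labels = labels, clusters = clusters, thresholds = thresholds)
}

#' Label events against a gating hierarchy
#'
#' Iterates [labelLevel()] over the hierarchy's levels: at each level,
#' every parent group is clustered on that level's rule markers and each
#' cluster is assigned to the child subset whose marker-polarity rule its
#' MCC-derived sign vector satisfies. Events end in a terminal subset or
#' `UNASSIGNED`.
#'
#' @param events an arcsinh-scale [CytoEvents-class] object.
#' @param hierarchy a [GatingHierarchy-class] object.
#' @param params see [clusterParams()].
#' @return a [SubsetLabeling-class] object.
#' @export
labelEvents <- function(events, hierarchy, params = clusterParams()) {
  if (!is(events, "CytoEvents")) stop_validation("events must be CytoEvents")
  if (events@scale != "arcsinh") {
    stop_validation("labeling expects arcsinh-transformed events")
  }
  validObject(hierarchy)
  n <- nEvents(events)
  r <- hierarchy@rules
  nlev <- if (nrow(r)) max(r$level) else 0L
  labels <- rep(hierarchy@root, n)
  levelClusters <- matrix(NA_integer_, nrow = n, ncol = nlev)
  thresholds <- list()
  for (lv in seq_len(nlev)) {
    res <- labelLevel(events, labels, r[r$level == lv, , drop = FALSE],
                      params = params, level = lv)
    labels <- res$labels
    levelClusters[, lv] <- res$clusters
    thresholds[[lv]] <- res$thresholds
  }
  thr <- if (length(thresholds)) do.call(rbind, thresholds) else
    data.frame(level = integer(0), parent = character(0),
               marker = character(0), cutoff = numeric(0), mcc = numeric(0))
  new("SubsetLabeling", labels = labels, levelClusters = levelClusters,
      thresholds = thr)
}

#' @rdname SubsetLabeling-class
#' @param object a [SubsetLabeling-class] object.
#' @param ... unused.
#' @export
setMethod("labels", "SubsetLabeling", function(object, ...) object@labels)

#' @rdname SubsetLabeling-class
#' @export
setMethod("labelCounts", "SubsetLabeling", function(x) {
  table(x@labels)
})

setMethod("show", "SubsetLabeling", function(object) {
  cat("SubsetLabeling:", length(object@labels), "events\n")
  print(table(object@labels))
})
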