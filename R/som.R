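## Self-organizing-map clustering with hierarchical metaclustering, the
## clustering contract behind hierarchy labeling and subset profiling.
##
## Training is batch-mode: every epoch assigns all events to their best
## matching unit and then replaces each node's prototype by the
## neighborhood-weighted mean of the events, with the neighborhood radius
## shrinking across epochs. Batch updates plus a seed-driven initialization
## and internal event shuffle make the fit fully deterministic.

som_grid_dist2 <- function(rows, cols) {
  pos <- cbind(rep(seq_len(rows), times = cols),
               rep(seq_len(cols), each = rows))
  as.matrix(stats::dist(pos))^2
}

## squared Euclidean distances between rows of x and rows of cb
cross_dist2 <- function(x, cb) {
  d2 <- outer(rowSums(x^2), rowSums(cb^2), "+") - 2 * tcrossprod(x, cb)
  d2[d2 < 0] <- 0
  d2
}

nearest_node <- function(x, cb) {
  max.col(-cross_dist2(x, cb), ties.method = "first")
}

#' Train a self-organizing map
#'
#' Fits a rectangular SOM to the requested markers of an arcsinh-scale
#' event matrix. Events are shuffled internally from the seed so the result
#' does not depend on input order; refitting with the same seed reproduces
#' the codebook exactly.
#'
#' @param events an arcsinh-scale [CytoEvents-class] object.
#' @param markers channels to train on (subset of `channelNames(events)`).
#' @param gridRows,gridCols grid dimensions (default 10 x 10).
#' @param seed integer RNG seed governing initialization and shuffling.
#' @param epochs training epochs (default 10).
#' @return a [ClusterModel-class] without metaclusters.
#' @seealso [metaCluster()], [assignEvents()]
#' @export
fitSOM <- function(events, markers, gridRows = 10, gridCols = 10,
                   seed = 1, epochs = 10) {
  if (!is(events, "CytoEvents")) stop_validation("events must be CytoEvents")
  if (length(markers) == 0) stop_validation("marker list must be non-empty")
  miss <- setdiff(markers, channelNames(events))
  if (length(miss)) stop_key("marker(s) not present: ",
                             paste(miss, collapse = ", "))
  if (nEvents(events) < 1) stop_validation("need at least one event")
  x <- events@exprs[, markers, drop = FALSE]
  n <- nrow(x)
  nn <- as.integer(gridRows) * as.integer(gridCols)

  cb <- with_seed(seed, {
    ord <- sample.int(n)
    x <- x[ord, , drop = FALSE]
    ## init: sample events as prototypes (with replacement when n < nodes),
    ## jittered slightly so duplicate events seed distinct nodes
    init_idx <- sample.int(n, nn, replace = n < nn)
    cb <- x[init_idx, , drop = FALSE] +
      matrix(stats::rnorm(nn * ncol(x), sd = 1e-4), nn)

    g2 <- som_grid_dist2(gridRows, gridCols)
    ## initial neighborhood of about a quarter of the grid diameter:
    ## wide enough to order the map, narrow enough that prototypes keep
    ## differentiating on coarse or discrete data
    r0 <- max(1, sqrt(max(g2)) / 4)
    for (e in seq_len(epochs)) {
      ## radius shrinks to ~0.3 so the final epochs are near BMU-only
      ## refinement and prototypes stop blending across cluster boundaries
      r <- (r0 - 0.3) * (1 - (e - 1) / max(1, epochs - 1)) + 0.3
      h <- exp(-g2 / (2 * r^2))          # node x node neighborhood kernel
      bmu <- nearest_node(x, cb)
      cnt <- tabulate(bmu, nbins = nn)
      sums <- matrix(0, nn, ncol(x))
      rs <- rowsum(x, group = bmu)
      sums[as.integer(rownames(rs)), ] <- rs
      wsum <- h %*% sums
      wcnt <- as.numeric(h %*% cnt)
      upd <- wcnt > 1e-12
      cb[upd, ] <- wsum[upd, , drop = FALSE] / wcnt[upd]
    }
    cb
  })
  dimnames(cb) <- list(NULL, markers)
  new("ClusterModel", gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), codebook = cb,
      nodeToMeta = integer(0), markers = as.character(markers),
      seed = as.integer(seed))
}

#' Group SOM nodes into metaclusters
#'
#' Average-linkage agglomerative clustering (Euclidean distance on codebook
#' vectors) cut at `k` groups. Deterministic.
#'
#' @param model a [ClusterModel-class] from [fitSOM()].
#' @param k number of metaclusters, between 1 and the number of nodes.
#' @return the model with `nodeToMeta` filled in.
#' @export
metaCluster <- function(model, k) {
  nn <- nrow(model@codebook)
  if (!is_count(k) || k < 1 || k > nn) {
    stop_validation("k must satisfy 1 <= k <= ", nn)
  }
  k <- as.integer(k)
  n2m <- if (k == 1L) {
    rep(1L, nn)
  } else {
    hc <- stats::hclust(stats::dist(model@codebook), method = "average")
    as.integer(stats::cutree(hc, k = k))
  }
  model@nodeToMeta <- n2m
  model
}

#' Assign events to metaclusters
#'
#' Each event goes to its nearest codebook node (Euclidean; ties to the
#' lowest node index) and inherits that node's metacluster.
#'
#' @param model a metaclustered [ClusterModel-class].
#' @param events an arcsinh-scale [CytoEvents-class] containing the model's
#'   markers.
#' @return integer metacluster id (1..k) per event.
#' @export
assignEvents <- function(model, events) {
  if (length(model@nodeToMeta) == 0) {
    stop_validation("model has no metaclusters; call metaCluster() first")
  }
  miss <- setdiff(model@markers, channelNames(events))
  if (length(miss)) {
    stop_validation("events lack model markers: ", paste(miss, collapse = ", "))
  }
  if (nEvents(events) == 0) return(integer(0))
  x <- events@exprs[, model@markers, drop = FALSE]
  model@nodeToMeta[nearest_node(x, model@codebook)]
}

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel:", object@gridRows, "x", object@gridCols, "SOM on",
      length(object@markers), "markers")
  if (length(object@nodeToMeta)) {
    cat(" |", length(unique(object@nodeToMeta)), "metaclusters")
  }
  cat(" | seed", object@seed, "\n")
})
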