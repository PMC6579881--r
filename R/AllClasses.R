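#' @import methods
NULL

## UNASSIGNED sentinel used for events that cannot be resolved to a barcode
## code or a terminal cell subset.
UNASSIGNED <- "UNASSIGNED"

#' CytoEvents: an events-by-channels intensity matrix
#'
#' The central event-level container: a numeric matrix of ion-count
#' intensities (one row per event, one column per channel) together with a
#' scale tag (`"raw"` for on-disk ion counts, `"arcsinh"` after variance
#' stabilization) and an optional per-event acquisition time in seconds.
#'
#' @slot exprs numeric matrix, events x channels; column names are the
#'   canonical channel identifiers (FCS $PnN short names).
#' @slot scale `"raw"` or `"arcsinh"`.
#' @slot acquisitionTime numeric; either length 0 (absent) or one
#'   non-decreasing, non-negative value per event (seconds).
#'
#' @seealso [cytoEvents()], [asinhTransform()], [readFCS()]
#' @export
setClass("CytoEvents",
  representation(
    exprs = "matrix",
    scale = "character",
    acquisitionTime = "numeric"
  ),
  prototype(
    exprs = matrix(numeric(0), nrow = 0, ncol = 0),
    scale = "raw",
    acquisitionTime = numeric(0)
  )
)

setValidity("CytoEvents", function(object) {
  msg <- character(0)
  ex <- object@exprs
  if (!is.numeric(ex)) msg <- c(msg, "exprs must be a numeric matrix")
  cn <- colnames(ex)
  if (ncol(ex) > 0 && (is.null(cn) || anyNA(cn) || any(cn == ""))) {
    msg <- c(msg, "all channels must be named")
  }
  if (!is.null(cn) && anyDuplicated(cn)) {
    msg <- c(msg, "channel names must be unique")
  }
  if (length(object@scale) != 1 || !object@scale %in% c("raw", "arcsinh")) {
    msg <- c(msg, "scale must be 'raw' or 'arcsinh'")
  }
  at <- object@acquisitionTime
  if (length(at) > 0) {
    if (length(at) != nrow(ex)) {
      msg <- c(msg, "acquisitionTime must have one value per event")
    } else if (anyNA(at) || any(at < 0)) {
      msg <- c(msg, "acquisitionTime must be nonnegative")
    } else if (is.unsorted(at)) {
      msg <- c(msg, "acquisitionTime must be non-decreasing in event order")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PanelDefinition: channel-to-marker mapping with roles
#'
#' Describes the antibody panel: which FCS channel carries which metal and
#' marker, and the analytic role of the channel. Roles `barcode_cd45` and
#' `barcode_pd` mark the two barcoding tiers and are disjoint by
#' construction (a channel has exactly one role).
#'
#' @slot entries data.frame with columns `channel`, `metal`, `marker`,
#'   `role`.
#' @export
setClass("PanelDefinition", representation(entries = "data.frame"))

PANEL_ROLES <- c(
  "barcode_cd45", "barcode_pd", "lineage", "screen_readout",
  "viability", "dna", "other"
)

setValidity("PanelDefinition", function(object) {
  e <- object@entries
  msg <- character(0)
  need <- c("channel", "metal", "marker", "role")
  if (!all(need %in% names(e))) {
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(e$channel)) msg <- c(msg, "channels must be unique")
  if (!all(e$role %in% PANEL_ROLES)) {
    msg <- c(msg, paste("role must be one of", paste(PANEL_ROLES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' BarcodeScheme: a k-of-n combinatorial barcode code book
#'
#' Enumerates all C(n, k) ways of choosing `k` positive channels out of the
#' scheme's `n` barcode channels, in lexicographic order by channel index.
#' Code identifiers are 0-based and stable.
#'
#' @slot channels ordered barcode channel names.
#' @slot k number of positive channels per code.
#' @slot codes logical matrix, codes x channels; `TRUE` marks a positive
#'   channel. Row `i` is code id `i - 1`.
#' @export
setClass("BarcodeScheme",
  representation(channels = "character", k = "integer", codes = "matrix")
)

setValidity("BarcodeScheme", function(object) {
  msg <- character(0)
  n <- length(object@channels)
  if (anyDuplicated(object@channels)) msg <- c(msg, "channels must be unique")
  if (ncol(object@codes) != n) msg <- c(msg, "codes must have one column per channel")
  if (nrow(object@codes) != choose(n, object@k)) {
    msg <- c(msg, "number of codes must equal choose(n, k)")
  }
  if (nrow(object@codes) > 0) {
    if (!all(rowSums(object@codes) == object@k)) {
      msg <- c(msg, "every code must have exactly k positive channels")
    }
    if (anyDuplicated(object@codes)) msg <- c(msg, "codes must be distinct")
  }
  if (length(msg)) msg else TRUE
})

#' ExperimentManifest: wells, batches and the two-tier code assignment
#'
#' Bookkeeping for a plate-format barcoded experiment: every
#' (donor, treatment) pair receives a fixed inner (CD45-tier) code, wells
#' are partitioned into batches in input order, and each well receives the
#' outer (palladium-tier) code of its position within its batch. Excluded
#' wells stay in the batch structure but are flagged.
#'
#' @slot donors,treatments character vectors.
#' @slot wells data.frame with columns `well_id`, `antibody`, `is_control`.
#' @slot batchSize maximum wells per batch.
#' @slot batches named list, batch id -> character vector of well ids.
#' @slot innerScheme,outerScheme [BarcodeScheme-class] objects for the
#'   donor x treatment tier and the well-within-batch tier.
#' @slot exclusions well ids flagged as excluded post hoc.
#' @export
setClass("ExperimentManifest",
  representation(
    donors = "character", treatments = "character", wells = "data.frame",
    batchSize = "integer", batches = "list",
    innerScheme = "BarcodeScheme", outerScheme = "BarcodeScheme",
    exclusions = "character"
  )
)

setValidity("ExperimentManifest", function(object) {
  msg <- character(0)
  w <- object@wells
  if (!all(c("well_id", "antibody", "is_control") %in% names(w))) {
    return("wells must have columns well_id, antibody, is_control")
  }
  inb <- unlist(object@batches, use.names = FALSE)
  if (anyDuplicated(inb)) msg <- c(msg, "a well may appear in only one batch")
  if (!setequal(inb, w$well_id)) {
    msg <- c(msg, "batches must partition exactly the declared wells")
  }
  if (any(lengths(object@batches) > object@batchSize)) {
    msg <- c(msg, "batch sizes must not exceed batchSize")
  }
  if (length(object@donors) * length(object@treatments) >
      nrow(object@innerScheme@codes)) {
    msg <- c(msg, "donor x treatment pairs exceed inner scheme capacity")
  }
  if (object@batchSize > nrow(object@outerScheme@codes)) {
    msg <- c(msg, "batchSize exceeds outer scheme capacity")
  }
  if (!all(object@exclusions %in% w$well_id)) {
    msg <- c(msg, "exclusions must reference declared wells")
  }
  if (length(msg)) msg else TRUE
})

#' GatingHierarchy: a leveled tree of marker-polarity gating rules
#'
#' Encodes knowledge-based gating as a tree: each rule says that cells of a
#' parent subset whose clusters satisfy a conjunction of marker polarities
#' (e.g. CD3+ CD19-) belong to a child subset. Rules are grouped into
#' levels; a rule's parent must be produced at an earlier level (the root at
#' level 0 is implicit). Labels without outgoing rules are terminal subsets.
#'
#' @slot root name of the root label (all events start here).
#' @slot rules data.frame with columns `level` (integer, >= 1), `parent`,
#'   `child`, and a list-column `terms` of data.frames with columns
#'   `marker`, `sign` (`"+"` or `"-"`).
#' @export
setClass("GatingHierarchy",
  representation(root = "character", rules = "data.frame")
)

setValidity("GatingHierarchy", function(object) {
  r <- object@rules
  msg <- character(0)
  need <- c("level", "parent", "child", "terms")
  if (!all(need %in% names(r))) {
    return(paste("rules must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(r) > 0) {
    if (anyDuplicated(r$child)) {
      msg <- c(msg, "label graph must be a tree: duplicate child labels")
    }
    if (object@root %in% r$child) msg <- c(msg, "root cannot be a child")
    lv <- sort(unique(r$level))
    if (!identical(lv, seq_along(lv))) {
      msg <- c(msg, "levels must be 1, 2, ... with no gaps (each non-empty)")
    }
    produced_before <- function(lab, level) {
      lab == object@root || any(r$child == lab & r$level < level)
    }
    ok <- mapply(produced_before, r$parent, r$level)
    if (!all(ok)) {
      msg <- c(msg, "every rule's parent must be produced at an earlier level")
    }
    for (tm in r$terms) {
      if (!is.data.frame(tm) || !all(c("marker", "sign") %in% names(tm)) ||
          !all(tm$sign %in% c("+", "-"))) {
        msg <- c(msg, "each terms entry must be a data.frame(marker, sign %in% +/-)")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClusterModel: a trained self-organizing map with optional metaclusters
#'
#' @slot gridRows,gridCols SOM grid dimensions.
#' @slot codebook (gridRows*gridCols) x n_markers matrix of node prototype
#'   vectors (row i is node i, grid filled column-major by row index).
#' @slot nodeToMeta integer metacluster id (1..k) per node; length 0 until
#'   [metaCluster()] has been applied.
#' @slot markers marker (channel) names the map was trained on.
#' @slot seed RNG seed that governed initialization and event shuffling.
#' @export
setClass("ClusterModel",
  representation(
    gridRows = "integer", gridCols = "integer", codebook = "matrix",
    nodeToMeta = "integer", markers = "character", seed = "integer"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character(0)
  nn <- object@gridRows * object@gridCols
  if (nrow(object@codebook) != nn) {
    msg <- c(msg, "codebook must have gridRows*gridCols rows")
  }
  if (ncol(object@codebook) != length(object@markers)) {
    msg <- c(msg, "codebook must have one column per marker")
  }
  if (any(!is.finite(object@codebook))) {
    msg <- c(msg, "codebook must be finite-valued")
  }
  if (length(object@nodeToMeta) > 0 && length(object@nodeToMeta) != nn) {
    msg <- c(msg, "nodeToMeta must map every node")
  }
  if (length(msg)) msg else TRUE
})

#' DebarcodeResult: per-event barcode assignments
#'
#' @slot assignment integer code id (0-based) per event; `NA` means
#'   UNASSIGNED.
#' @slot separation per-event nonnegative separation score (normalized gap
#'   between the k-th and (k+1)-th brightest barcode channel).
#' @slot nCodes number of codes in the scheme the result refers to.
#' @export
setClass("DebarcodeResult",
  representation(
    assignment = "integer", separation = "numeric", nCodes = "integer"
  )
)

setValidity("DebarcodeResult", function(object) {
  msg <- character(0)
  if (length(object@separation) != length(object@assignment)) {
    msg <- c(msg, "separation must have one value per event")
  }
  if (length(object@separation) && any(object@separation < 0, na.rm = TRUE)) {
    msg <- c(msg, "separation must be nonnegative")
  }
  a <- object@assignment
  if (any(!is.na(a) & (a < 0L | a >= object@nCodes))) {
    msg <- c(msg, "assignments must be valid code ids or NA")
  }
  if (length(msg)) msg else TRUE
})

#' SubsetLabeling: per-event subset labels from hierarchy labeling
#'
#' @slot labels final per-event label: a terminal subset name or
#'   `"UNASSIGNED"`.
#' @slot levelClusters integer matrix, events x levels, the metacluster id
#'   each event fell into at each level (NA once the event left the active
#'   set).
#' @slot thresholds data.frame `level`, `parent`, `marker`, `cutoff`, `mcc`
#'   recording every MCC-optimal cutoff chosen during labeling.
#' @export
setClass("SubsetLabeling",
  representation(
    labels = "character", levelClusters = "matrix", thresholds = "data.frame"
  )
)

setValidity("SubsetLabeling", function(object) {
  msg <- character(0)
  if (nrow(object@levelClusters) != length(object@labels)) {
    msg <- c(msg, "levelClusters must have one row per event")
  }
  if (anyNA(object@labels)) msg <- c(msg, "every event must carry a label")
  if (length(msg)) msg else TRUE
})

#' AofReport: staining-quality matrices for a set of samples
#'
#' @slot aof marker x sample matrix of Average Overlap Frequency values in
#'   [0, 1].
#' @slot scaled marker x sample matrix of Scaled^2 AOF values (>= 0).
#' @slot quality per-sample Quality^2 AOF (column sums of `scaled`).
#' @slot modality list of per (marker, sample) modality-split metadata.
#' @export
setClass("AofReport",
  representation(
    aof = "matrix", scaled = "matrix", quality = "numeric", modality = "list"
  )
)

setValidity("AofReport", function(object) {
  msg <- character(0)
  a <- object@aof
  if (length(a) && (min(a, na.rm = TRUE) < 0 || max(a, na.rm = TRUE) > 1)) {
    msg <- c(msg, "AOF values must lie in [0, 1]")
  }
  if (!identical(dim(object@aof), dim(object@scaled))) {
    msg <- c(msg, "aof and scaled must have identical shape")
  }
  if (length(object@scaled) && min(object@scaled, na.rm = TRUE) < 0) {
    msg <- c(msg, "scaled values must be nonnegative")
  }
  if (length(object@quality) != ncol(a)) {
    msg <- c(msg, "quality must have one value per sample")
  }
  if (length(msg)) msg else TRUE
})
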