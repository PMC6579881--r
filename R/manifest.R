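#' Build a k-of-n combinatorial barcode scheme
#'
#' Enumerates every way of choosing `k` positive channels from `channels`,
#' in lexicographic order by channel index, so that code ids are stable and
#' reproducible. A two-out-of-four CD45 scheme yields 6 codes; a
#' two-out-of-five palladium scheme yields 10.
#'
#' @param channels ordered barcode channel names.
#' @param k number of positive channels per code, `1 <= k <= length(channels)`.
#' @return a [BarcodeScheme-class] object.
#' @examples
#' nCodes(makeScheme(paste0("Pd", 1:5), 2))  # 10
#' @export
makeScheme <- function(channels, k) {
  channels <- as.character(channels)
  n <- length(channels)
  if (!is_count(k) || k < 1 || k > n) {
    stop_validation("k must satisfy 1 <= k <= ", n)
  }
  k <- as.integer(k)
  combos <- utils::combn(n, k)   # columns in lexicographic order
  codes <- matrix(FALSE, nrow = ncol(combos), ncol = n,
                  dimnames = list(NULL, channels))
  for (i in seq_len(ncol(combos))) codes[i, combos[, i]] <- TRUE
  new("BarcodeScheme", channels = channels, k = k, codes = codes)
}

#' @rdname BarcodeScheme-class
#' @export
setMethod("nCodes", "BarcodeScheme", function(x) nrow(x@codes))

#' @rdname BarcodeScheme-class
#' @param codeId 0-based code identifier.
#' @export
setMethod("codeChannels", "BarcodeScheme", function(x, codeId) {
  if (!is_count(codeId) || codeId >= nrow(x@codes)) {
    stop_key("codeId out of range: ", codeId)
  }
  x@channels[x@codes[codeId + 1L, ]]
})

setMethod("show", "BarcodeScheme", function(object) {
  cat("BarcodeScheme:", object@k, "of", length(object@channels),
      "->", nrow(object@codes), "codes\n")
  cat("channels:", paste(object@channels, collapse = ", "), "\n")
})

#' Build the experiment manifest for a two-tier barcoded screen
#'
#' Encodes the plate-format design: every (donor, treatment) pair is
#' barcoded with a fixed inner-tier code (assigned by lexicographic pairing
#' order), wells are partitioned into batches of at most `batchSize` in
#' input order, and each well receives the outer-tier code of its position
#' within its batch. Excluded wells are flagged but retained in the batch
#' structure, mirroring post-hoc exclusion of failed wells.
#'
#' @param donors,treatments character vectors of donor and treatment names.
#' @param wells data.frame with columns `well_id`, `antibody`,
#'   `is_control`, in plate order.
#' @param batchSize wells per batch (last batch may be smaller).
#' @param innerScheme [BarcodeScheme-class] for the donor x treatment tier.
#' @param outerScheme [BarcodeScheme-class] for the well-within-batch tier.
#' @param exclusions character vector of well ids to flag as excluded.
#' @return an [ExperimentManifest-class] object.
#' @examples
#' wells <- data.frame(well_id = sprintf("W%03d", 1:20),
#'                     antibody = sprintf("Ab%03d", 1:20),
#'                     is_control = FALSE)
#' m <- buildManifest(c("D1", "D2", "D3"), c("fresh", "fixed"), wells, 10,
#'                    makeScheme(paste0("CD45_", 1:4), 2),
#'                    makeScheme(paste0("Pd", 1:5), 2))
#' nBatches(m)
#' @export
buildManifest <- function(donors, treatments, wells, batchSize,
                          innerScheme, outerScheme,
                          exclusions = character(0)) {
  donors <- as.character(donors)
  treatments <- as.character(treatments)
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  if (!is_count(batchSize) || batchSize < 1) {
    stop_validation("batchSize must be a positive integer")
  }
  if (length(donors) * length(treatments) > nCodes(innerScheme)) {
    stop_validation("donor x treatment pairs (",
                    length(donors) * length(treatments),
                    ") exceed inner scheme capacity (", nCodes(innerScheme), ")")
  }
  if (batchSize > nCodes(outerScheme)) {
    stop_validation("batchSize (", batchSize,
                    ") exceeds outer scheme capacity (", nCodes(outerScheme), ")")
  }
  nb <- ceiling(nrow(wells) / batchSize)
  batches <- lapply(seq_len(nb), function(b) {
    idx <- ((b - 1L) * batchSize + 1L):min(b * batchSize, nrow(wells))
    wells$well_id[idx]
  })
  names(batches) <- sprintf("batch_%02d", seq_len(nb))
  new("ExperimentManifest",
      donors = donors, treatments = treatments, wells = wells,
      batchSize = as.integer(batchSize), batches = batches,
      innerScheme = innerScheme, outerScheme = outerScheme,
      exclusions = as.character(exclusions))
}

#' @rdname ExperimentManifest-class
#' @param x an [ExperimentManifest-class] object.
#' @export
nBatches <- function(x) length(x@batches)

#' @rdname ExperimentManifest-class
#' @export
batchIds <- function(x) names(x@batches)

#' Sample-unit accounting for a manifest
#'
#' A sample unit is one (donor, treatment, well) combination. `nSampleUnits`
#' counts all of them; `nRetainedUnits` counts those whose well is not
#' flagged as excluded.
#'
#' @param x an [ExperimentManifest-class] object.
#' @return an integer count.
#' @export
nSampleUnits <- function(x) {
  length(x@donors) * length(x@treatments) * nrow(x@wells)
}

#' @rdname nSampleUnits
#' @export
nRetainedUnits <- function(x) {
  kept <- sum(!x@wells$well_id %in% x@exclusions)
  length(x@donors) * length(x@treatments) * kept
}

## Fixed inner-code assignment: donors x treatments in lexicographic pairing
## order (donor index varies slowest).
inner_code_table <- function(manifest) {
  grid <- expand.grid(treatment = manifest@treatments,
                      donor = manifest@donors,
                      stringsAsFactors = FALSE)[, c("donor", "treatment")]
  grid$inner_code <- seq_len(nrow(grid)) - 1L
  grid
}

#' Expected (inner, outer) code combinations for a batch
#'
#' For each well of the batch and each (donor, treatment) pair, the code
#' pair an event from that sample unit must carry. A full batch of the
#' plate-screen design (6 inner codes x 10 wells) yields 60 combinations.
#'
#' @param manifest an [ExperimentManifest-class] object.
#' @param batchId a batch id from [batchIds()].
#' @return data.frame with columns `inner_code`, `outer_code`, `donor`,
#'   `treatment`, `well_id`, `antibody`, `excluded`.
#' @export
expectedCodes <- function(manifest, batchId) {
  if (!batchId %in% names(manifest@batches)) {
    stop_key("unknown batch: ", batchId)
  }
  wls <- manifest@batches[[batchId]]
  inner <- inner_code_table(manifest)
  out <- do.call(rbind, lapply(seq_along(wls), function(pos) {
    data.frame(
      inner_code = inner$inner_code,
      outer_code = pos - 1L,
      donor = inner$donor,
      treatment = inner$treatment,
      well_id = wls[pos],
      stringsAsFactors = FALSE
    )
  }))
  out$antibody <- manifest@wells$antibody[match(out$well_id,
                                                manifest@wells$well_id)]
  out$excluded <- out$well_id %in% manifest@exclusions
  rownames(out) <- NULL
  out
}

setMethod("show", "ExperimentManifest", function(object) {
  cat("ExperimentManifest:", length(object@donors), "donors x",
      length(object@treatments), "treatments x", nrow(object@wells),
      "wells\n")
  cat(nBatches(object), "batches (size <=", object@batchSize, "),",
      nSampleUnits(object), "sample units,",
      nRetainedUnits(object), "retained\n")
  cat("inner: ", object@innerScheme@k, "-of-",
      length(object@innerScheme@channels),
      "; outer: ", object@outerScheme@k, "-of-",
      length(object@outerScheme@channels), "\n", sep = "")
})

#' Serialize / restore a manifest as JSON
#'
#' @param manifest an [ExperimentManifest-class] object.
#' @param path output (input) JSON path.
#' @return `path` invisibly (`readManifest` returns the manifest).
#' @export
writeManifest <- function(manifest, path) {
  obj <- list(
    donors = manifest@donors, treatments = manifest@treatments,
    wells = manifest@wells, batch_size = manifest@batchSize,
    inner = list(channels = manifest@innerScheme@channels,
                 k = manifest@innerScheme@k),
    outer = list(channels = manifest@outerScheme@channels,
                 k = manifest@outerScheme@k),
    exclusions = manifest@exclusions
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  buildManifest(
    donors = obj$donors, treatments = obj$treatments,
    wells = as.data.frame(obj$wells), batchSize = obj$batch_size,
    innerScheme = makeScheme(obj$inner$channels, obj$inner$k),
    outerScheme = makeScheme(obj$outer$channels, obj$outer$k),
    exclusions = as.character(obj$exclusions %||% character(0))
  )
}
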