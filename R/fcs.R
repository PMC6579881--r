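#' Construct a CytoEvents object
#'
#' @param exprs numeric events x channels matrix with unique column names.
#' @param scale `"raw"` (ion counts) or `"arcsinh"` (transformed).
#' @param acquisitionTime optional per-event acquisition time in seconds,
#'   non-decreasing in event order.
#' @return a [CytoEvents-class] object.
#' @examples
#' ev <- cytoEvents(matrix(rpois(20, 50), 10, 2,
#'   dimnames = list(NULL, c("CD3", "CD19"))))
#' nEvents(ev)
#' @export
cytoEvents <- function(exprs, scale = c("raw", "arcsinh"),
                       acquisitionTime = numeric(0)) {
  scale <- match.arg(scale)
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  new("CytoEvents", exprs = exprs, scale = scale,
      acquisitionTime = as.numeric(acquisitionTime))
}

#' @rdname CytoEvents-class
#' @export
setMethod("nEvents", "CytoEvents", function(x) nrow(x@exprs))

#' @rdname CytoEvents-class
#' @export
setMethod("channelNames", "CytoEvents", function(x) colnames(x@exprs))

#' @rdname CytoEvents-class
#' @export
setMethod("intensities", "CytoEvents", function(x) x@exprs)

#' @rdname CytoEvents-class
#' @export
setMethod("intensityScale", "CytoEvents", function(x) x@scale)

#' @rdname CytoEvents-class
#' @export
setMethod("acquisitionTime", "CytoEvents", function(x) {
  if (length(x@acquisitionTime)) x@acquisitionTime else NULL
})

setMethod("show", "CytoEvents", function(object) {
  cat("CytoEvents:", nrow(object@exprs), "events x",
      ncol(object@exprs), "channels |", object@scale, "scale")
  if (length(object@acquisitionTime)) cat(" | acquisition time present")
  cat("\n")
  if (ncol(object@exprs)) {
    cat("channels:", paste(utils::head(colnames(object@exprs), 8),
                           collapse = ", "))
    if (ncol(object@exprs) > 8) cat(", ...")
    cat("\n")
  }
})

#' Subset the channels of a CytoEvents object
#'
#' @param x a [CytoEvents-class] object.
#' @param channels channel names to keep (order respected).
#' @return a CytoEvents with only the requested channels.
#' @export
selectChannels <- function(x, channels) {
  miss <- setdiff(channels, channelNames(x))
  if (length(miss)) {
    stop_key("channel(s) not present: ", paste(miss, collapse = ", "))
  }
  new("CytoEvents", exprs = x@exprs[, channels, drop = FALSE],
      scale = x@scale, acquisitionTime = x@acquisitionTime)
}

#' Apply the arcsinh variance-stabilizing transform
#'
#' Each intensity `x` becomes `asinh(x / cofactor)`. The transform is applied
#' uniformly to every channel, including barcode and DNA channels; downstream
#' operations select the channels they need explicitly. The conventional
#' mass-cytometry cofactor is 5.
#'
#' @param events a raw-scale [CytoEvents-class] object.
#' @param cofactor positive scaling constant (default 5).
#' @return a CytoEvents on the arcsinh scale.
#' @examples
#' ev <- cytoEvents(matrix(c(0, 5), 2, 1, dimnames = list(NULL, "CD3")))
#' intensities(asinhTransform(ev))   # 0 and asinh(1) = 0.8814
#' @export
asinhTransform <- function(events, cofactor = 5) {
  if (!is(events, "CytoEvents")) stop_validation("events must be CytoEvents")
  if (events@scale != "raw") {
    stop_validation("events are already transformed (scale = '",
                    events@scale, "')")
  }
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    stop_validation("cofactor must be a positive number")
  }
  new("CytoEvents", exprs = asinh(events@exprs / cofactor),
      scale = "arcsinh", acquisitionTime = events@acquisitionTime)
}

#' Single-channel spillover compensation
#'
#' Subtracts a fixed fraction of a source channel from a target channel,
#' the standard correction for isolated spillover such as oxide formation
#' (e.g. compensating a 162Dy readout by 1.9% of the 146Nd CD8 channel).
#' Negative results are retained, not clamped: clamping would bias medians
#' used downstream.
#'
#' @param events a raw-scale [CytoEvents-class] object.
#' @param target channel to correct.
#' @param source channel whose signal spills into `target`.
#' @param fraction spillover fraction in [0, 1).
#' @return a CytoEvents with the corrected target column.
#' @export
compensateChannel <- function(events, target, source, fraction) {
  if (!is(events, "CytoEvents")) stop_validation("events must be CytoEvents")
  if (events@scale != "raw") {
    stop_validation("compensation operates on raw ion counts")
  }
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction >= 1) {
    stop_validation("fraction must lie in [0, 1)")
  }
  if (identical(target, source)) {
    stop_validation("target and source must differ")
  }
  for (ch in c(target, source)) {
    if (!ch %in% channelNames(events)) stop_key("channel not present: ", ch)
  }
  ex <- events@exprs
  ex[, target] <- ex[, target] - fraction * ex[, source]
  new("CytoEvents", exprs = ex, scale = "raw",
      acquisitionTime = events@acquisitionTime)
}

#' Construct a PanelDefinition
#'
#' @param entries data.frame with columns `channel`, `metal`, `marker`,
#'   `role`; roles are one of `barcode_cd45`, `barcode_pd`, `lineage`,
#'   `screen_readout`, `viability`, `dna`, `other`.
#' @return a [PanelDefinition-class] object.
#' @export
panelDefinition <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  new("PanelDefinition", entries = entries)
}

#' Read a panel definition from CSV
#'
#' @param path CSV file with columns `channel`, `metal`, `marker`, `role`.
#' @return a [PanelDefinition-class] object.
#' @export
readPanel <- function(path) {
  panelDefinition(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Channels of a panel playing a given role
#'
#' @param panel a [PanelDefinition-class] object.
#' @param role one of the panel roles.
#' @return character vector of channel names.
#' @export
panelChannels <- function(panel, role) {
  if (!role %in% PANEL_ROLES) stop_validation("unknown role: ", role)
  panel@entries$channel[panel@entries$role == role]
}

setMethod("show", "PanelDefinition", function(object) {
  cat("PanelDefinition:", nrow(object@entries), "channels\n")
  print(table(object@entries$role))
})

## ---------------------------------------------------------------------------
## FCS 3.0/3.1 binary input/output.
##
## A single-dataset reader/writer: list-mode data, numeric types F (float32)
## and D (float64), little- or big-endian byte order, $PnN short names as
## canonical channel ids. Written files are FCS 3.1, DATATYPE F, fixed
## keyword order, so a rerun produces byte-identical output.
## ---------------------------------------------------------------------------

FCS_DELIM <- "/"

fcs_text_blob <- function(kw) {
  paste0(FCS_DELIM,
         paste0(names(kw), FCS_DELIM, unlist(kw), FCS_DELIM, collapse = ""))
}

#' Write events to an FCS 3.1 file
#'
#' Raw-scale events only: FCS files store ion counts, and transformed values
#' are an analysis product, not data. If acquisition time is present it is
#' written as a trailing `Time` channel. Metadata policy is fixed, so writing
#' the same object twice yields byte-identical files.
#'
#' @param events a raw-scale, nonnegative [CytoEvents-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readFCS()]
#' @export
writeFCS <- function(events, path) {
  if (!is(events, "CytoEvents")) stop_validation("events must be CytoEvents")
  if (events@scale != "raw") {
    stop_validation("only raw-scale events are written to FCS")
  }
  ex <- events@exprs
  if (length(ex) && min(ex) < 0) {
    stop_validation("raw ion counts must be nonnegative")
  }
  if (length(events@acquisitionTime)) {
    if ("Time" %in% colnames(ex)) {
      stop_validation("events already contain a 'Time' channel")
    }
    ex <- cbind(ex, Time = events@acquisitionTime)
  }
  npar <- ncol(ex)
  ntot <- nrow(ex)
  if (npar == 0) stop_validation("cannot write an FCS file with no channels")

  kw <- list(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "0", "$ENDDATA" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(npar), "$TOT" = as.character(ntot)
  )
  rng <- vapply(seq_len(npar), function(j) {
    m <- if (ntot) max(ex[, j]) else 0
    as.character(max(1024, ceiling(m) + 1))
  }, character(1))
  for (j in seq_len(npar)) {
    kw[[sprintf("$P%dN", j)]] <- colnames(ex)[j]
    kw[[sprintf("$P%dB", j)]] <- "32"
    kw[[sprintf("$P%dE", j)]] <- "0,0"
    kw[[sprintf("$P%dR", j)]] <- rng[j]
  }

  header_len <- 58L  # "FCS3.1    " + 6 x 8-char offsets
  data_len <- 4L * npar * ntot
  ## offsets depend on the text length which depends on the offsets; iterate
  ## until the digit widths stabilize
  text_start <- header_len
  repeat {
    blob <- fcs_text_blob(kw)
    text_end <- text_start + nchar(blob, type = "bytes") - 1L
    data_start <- text_end + 1L
    data_end <- if (data_len > 0) data_start + data_len - 1L else 0L
    kw2 <- kw
    kw2[["$BEGINDATA"]] <- as.character(if (data_len > 0) data_start else 0L)
    kw2[["$ENDDATA"]] <- as.character(data_end)
    blob2 <- fcs_text_blob(kw2)
    if (nchar(blob2, type = "bytes") == nchar(blob, type = "bytes")) {
      kw <- kw2
      blob <- blob2
      break
    }
    kw <- kw2
  }

  con <- file(path, "wb")
  on.exit(close(con))
  off <- function(x) formatC(x, width = 8, flag = " ")
  writeChar("FCS3.1    ", con, eos = NULL)
  writeChar(paste0(off(text_start), off(text_end),
                   off(if (data_len > 0) data_start else 0L),
                   off(data_end), off(0L), off(0L)),
            con, eos = NULL)
  writeChar(blob, con, eos = NULL)
  if (data_len > 0) {
    writeBin(as.numeric(t(ex)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

parse_fcs_text <- function(raw_text) {
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1, 1)
  body <- substring(txt, 2)
  ## values containing an escaped (doubled) delimiter are not produced by
  ## this package; split naively and treat empty fields as escapes
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(as.list(trimws(vals)), trimws(keys))
}

#' Read an FCS 3.0/3.1 file
#'
#' Supports single-dataset list-mode files with numeric data type `F`
#' (float32) or `D` (float64) and either byte order. `$PnN` short names
#' become the channel names; a channel named `Time` is lifted into the
#' `acquisitionTime` slot. Event order is preserved.
#'
#' @param path path to an FCS file.
#' @return a raw-scale [CytoEvents-class] object.
#' @export
readFCS <- function(path) {
  if (!file.exists(path)) stop_format("file does not exist: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 58) stop_format("not an FCS file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 6, useBytes = TRUE)
  if (!magic %in% c("FCS3.0", "FCS3.1")) {
    stop_format("unsupported FCS version marker: '", magic, "'")
  }
  readChar(con, 4, useBytes = TRUE)  # padding
  offs <- suppressWarnings(as.integer(sapply(1:6, function(i)
    trimws(readChar(con, 8, useBytes = TRUE)))))
  if (anyNA(offs[1:2])) stop_format("unreadable FCS header offsets")
  text_start <- offs[1]; text_end <- offs[2]
  if (text_end <= text_start || text_end >= sz) {
    stop_format("truncated FCS file: TEXT segment out of range")
  }
  seek(con, text_start)
  kw <- parse_fcs_text(readBin(con, "raw", text_end - text_start + 1L))

  need <- c("$PAR", "$TOT", "$DATATYPE", "$BYTEORD", "$MODE")
  if (!all(need %in% names(kw))) {
    stop_format("missing required FCS keywords: ",
                paste(setdiff(need, names(kw)), collapse = ", "))
  }
  if (kw[["$MODE"]] != "L") stop_format("only list-mode FCS is supported")
  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  if (!dtype %in% c("F", "D")) {
    stop_format("unsupported $DATATYPE '", dtype, "' (need F or D)")
  }
  endian <- switch(kw[["$BYTEORD"]],
    "1,2,3,4" = "little", "4,3,2,1" = "big",
    stop_format("unsupported $BYTEORD ", kw[["$BYTEORD"]]))
  word <- if (dtype == "F") 4L else 8L

  chans <- vapply(seq_len(npar), function(j) {
    v <- kw[[sprintf("$P%dN", j)]]
    if (is.null(v)) stop_format("missing $P", j, "N keyword")
    v
  }, character(1))
  if (anyDuplicated(chans)) {
    stop_validation("duplicate channel names in FCS file: ",
                    paste(chans[duplicated(chans)], collapse = ", "))
  }

  data_start <- offs[3]
  if (is.na(data_start) || data_start == 0L) {
    data_start <- as.integer(kw[["$BEGINDATA"]] %||% NA)
  }
  n_values <- npar * ntot
  ex <- matrix(numeric(0), nrow = 0, ncol = npar)
  if (n_values > 0) {
    if (is.na(data_start) || data_start + n_values * word - 1 > sz) {
      stop_format("truncated FCS file: DATA segment out of range")
    }
    seek(con, data_start)
    vals <- readBin(con, "numeric", n = n_values, size = word,
                    endian = endian)
    if (length(vals) != n_values) stop_format("truncated FCS DATA segment")
    ex <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  }
  colnames(ex) <- chans

  at <- numeric(0)
  if ("Time" %in% chans && ntot > 0) {
    tv <- ex[, "Time"]
    if (!is.unsorted(tv) && all(tv >= 0)) {
      at <- tv
      ex <- ex[, setdiff(chans, "Time"), drop = FALSE]
    }
  } else if ("Time" %in% chans) {
    ex <- ex[, setdiff(chans, "Time"), drop = FALSE]
  }
  cytoEvents(ex, scale = "raw", acquisitionTime = at)
}
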