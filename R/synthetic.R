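## Seeded synthetic barcoded mass-cytometry experiments with ground-truth
## sidecars. Marker modalities are Gaussian on the arcsinh scale (how
## separations are specified throughout the analysis) and mapped to raw ion
## counts through the inverse transform, truncated at zero; each sample
## unit draws from its own (seed, donor, treatment, well) stream so any
## unit is reproducible in isolation.

#' Build a simulation configuration
#'
#' @param donors named list: donor -> named numeric vector of subset
#'   frequencies (summing to 1).
#' @param subsets named list: subset -> named list of marker specs, each a
#'   list with `mean`, `sd` (arcsinh units) and optionally `hiFraction`,
#'   `hiMean` for a bimodal marker.
#' @param barcode list with `positive`, `negative` (arcsinh levels) and
#'   `noiseSd` (>= 0).
#' @param screen `NULL`, or list with `readoutChannel` and `antibodies`, a
#'   named list: antibody -> list(`posLevel`, `negLevel`, `sd`,
#'   `fractions` = named per-subset positive fraction).
#' @param drift `NULL`, or list with `marker`, `slope` (arcsinh units per
#'   second added to background events) and `ref` (arcsinh cutoff below
#'   which an event counts as background).
#' @param fixation named list: antibody -> multiplicative factor applied to
#'   raw readout intensities under the fixed treatment; a factor may itself
#'   be a named per-subset vector.
#' @param fixedTreatment treatment name that triggers fixation factors.
#' @param nEvents events per sample unit.
#' @param cofactor arcsinh cofactor used for the raw mapping.
#' @param acquisitionWindow synthetic acquisition duration per batch
#'   (seconds).
#' @param seed master seed; per-unit streams derive from it.
#' @return a validated `simulationConfig` list.
#' @export
simulationConfig <- function(donors, subsets, barcode,
                             screen = NULL, drift = NULL,
                             fixation = list(), fixedTreatment = "fixed",
                             nEvents = 1000, cofactor = 5,
                             acquisitionWindow = 1800, seed = 1) {
  cfg <- list(donors = donors, subsets = subsets, barcode = barcode,
              screen = screen, drift = drift, fixation = fixation,
              fixedTreatment = fixedTreatment, nEvents = nEvents,
              cofactor = cofactor, acquisitionWindow = acquisitionWindow,
              seed = as.integer(seed))
  for (d in names(donors)) {
    f <- donors[[d]]
    if (abs(sum(f) - 1) > 1e-9) {
      stop_validation("subset frequencies for donor ", d, " must sum to 1")
    }
    if (any(f < 0)) stop_validation("frequencies must be nonnegative")
    if (!all(names(f) %in% names(subsets))) {
      stop_validation("donor ", d, " references unknown subsets")
    }
  }
  for (s in names(subsets)) {
    for (m in names(subsets[[s]])) {
      sp <- subsets[[s]][[m]]
      if (is.null(sp$mean) || is.null(sp$sd) || sp$sd <= 0) {
        stop_validation("subset ", s, ", marker ", m,
                        ": needs mean and sd > 0")
      }
      hf <- sp$hiFraction %||% 0
      if (hf < 0 || hf > 1) {
        stop_validation("hiFraction must lie in [0, 1]")
      }
    }
  }
  if (is.null(barcode$positive) || is.null(barcode$negative) ||
      (barcode$noiseSd %||% -1) < 0) {
    stop_validation("barcode spec needs positive, negative and noiseSd >= 0")
  }
  class(cfg) <- "simulationConfig"
  cfg
}

## rnorm that tolerates sd = 0 (returns the mean)
rnorm0 <- function(n, mean, sd) {
  if (sd == 0) rep(mean, n) else stats::rnorm(n, mean, sd)
}

to_raw <- function(x, cofactor) pmax(cofactor * sinh(x), 0)

sim_markers <- function(cfg, subset_draw) {
  subsets <- cfg$subsets
  markers <- unique(unlist(lapply(subsets, names)))
  n <- length(subset_draw)
  out <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  for (s in unique(subset_draw)) {
    idx <- which(subset_draw == s)
    for (m in markers) {
      sp <- subsets[[s]][[m]]
      if (is.null(sp)) sp <- list(mean = 0, sd = 0.1)
      hf <- sp$hiFraction %||% 0
      v <- rnorm0(length(idx), sp$mean, sp$sd)
      if (hf > 0) {
        hi <- stats::runif(length(idx)) < hf
        v[hi] <- rnorm0(sum(hi), sp$hiMean, sp$sd)
      }
      out[idx, m] <- v
    }
  }
  out
}

#' Simulate one sample unit
#'
#' Draws per-event subsets from the donor's frequency vector, marker values
#' from the subset modality specs, and (when a screen spec and antibody are
#' given) the screen readout channel. Values are generated on the arcsinh
#' scale and returned as raw ion counts; fixation factors multiply the raw
#' readout when `treatment` equals the config's fixed treatment.
#'
#' @param config a [simulationConfig()].
#' @param donor,treatment,well identifiers of the unit.
#' @param antibody antibody in this well (`NULL` for none).
#' @param nEvents events to draw (default from config).
#' @param streamSeed RNG seed for this unit; by default derived from the
#'   config seed and the unit identifiers.
#' @return list with `events` (raw-scale [CytoEvents-class]) and `sidecar`
#'   (data.frame: `subset`, `readout_positive`).
#' @export
simulateSampleUnit <- function(config, donor, treatment, well,
                               antibody = NULL, nEvents = NULL,
                               streamSeed = NULL) {
  if (!inherits(config, "simulationConfig")) {
    stop_validation("config must come from simulationConfig()")
  }
  n <- nEvents %||% config$nEvents
  seed <- streamSeed %||%
    child_seed(config$seed, c(donor, treatment, well))
  freqs <- config$donors[[donor]]
  if (is.null(freqs)) stop_key("unknown donor: ", donor)

  with_seed(seed, {
    subset_draw <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    x <- sim_markers(config, subset_draw)
    readout_pos <- rep(NA, n)
    if (!is.null(config$screen) && !is.null(antibody)) {
      ab <- config$screen$antibodies[[antibody]]
      if (is.null(ab)) stop_key("unknown antibody: ", antibody)
      fr <- if (length(ab$fractions)) ab$fractions[subset_draw] else
        rep(0, n)
      fr[is.na(fr)] <- 0
      ## co-varying positivity: events high in a linked marker (e.g. a
      ## CD161-like channel) get their own positive fraction
      if (!is.null(ab$coMarker) && ab$coMarker %in% colnames(x)) {
        hi <- x[, ab$coMarker] > (ab$coRef %||% 1.8)
        fr[hi] <- ab$coHiFraction %||% fr[hi]
      }
      readout_pos <- stats::runif(n) < fr
      ro <- ifelse(readout_pos,
                   rnorm0(n, ab$posLevel, ab$sd),
                   rnorm0(n, ab$negLevel, ab$sd))
      x <- cbind(x, ro)
      colnames(x)[ncol(x)] <- config$screen$readoutChannel
    }
    raw <- to_raw(x, config$cofactor)
    if (!is.null(antibody) && treatment == config$fixedTreatment &&
        !is.null(config$fixation[[antibody]])) {
      fac <- config$fixation[[antibody]]
      f_ev <- if (length(fac) > 1 || !is.null(names(fac))) {
        fv <- unlist(fac)[subset_draw]
        fv[is.na(fv)] <- 1
        fv
      } else {
        rep(as.numeric(fac), n)
      }
      rc <- config$screen$readoutChannel
      raw[, rc] <- raw[, rc] * f_ev
    }
    list(
      events = cytoEvents(raw, scale = "raw"),
      sidecar = data.frame(subset = subset_draw,
                           readout_positive = readout_pos,
                           stringsAsFactors = FALSE)
    )
  })
}

#' Simulate one pooled, barcoded batch
#'
#' Concatenates all sample units of the batch with their inner and outer
#' barcode channel patterns (positive/negative arcsinh levels plus noise),
#' shuffles events from the seed, assigns acquisition times uniformly over
#' the acquisition window, and applies the drift spec (if any) to the
#' target marker's background events.
#'
#' @param config a [simulationConfig()].
#' @param manifest an [ExperimentManifest-class] object.
#' @param batchId batch to simulate.
#' @param nEventsPerUnit override of events per sample unit.
#' @return list with `events` (raw-scale [CytoEvents-class] with
#'   acquisition time) and `sidecar` (per-event data.frame: `donor`,
#'   `treatment`, `well_id`, `antibody`, `subset`, `inner_code`,
#'   `outer_code`, `readout_positive`).
#' @export
simulateBatch <- function(config, manifest, batchId, nEventsPerUnit = NULL) {
  expected <- expectedCodes(manifest, batchId)
  inner_ch <- manifest@innerScheme@channels
  outer_ch <- manifest@outerScheme@channels
  bc <- config$barcode
  n_unit <- nEventsPerUnit %||% config$nEvents

  blocks <- vector("list", nrow(expected))
  sidecars <- vector("list", nrow(expected))
  for (i in seq_len(nrow(expected))) {
    e <- expected[i, ]
    unit <- simulateSampleUnit(config, e$donor, e$treatment, e$well_id,
                               antibody = e$antibody, nEvents = n_unit)
    n <- nEvents(unit$events)
    bseed <- child_seed(config$seed,
                        c("bc", batchId, e$donor, e$treatment, e$well_id))
    bc_arc <- with_seed(bseed, {
      pat_in <- manifest@innerScheme@codes[e$inner_code + 1L, ]
      pat_out <- manifest@outerScheme@codes[e$outer_code + 1L, ]
      pat <- c(pat_in, pat_out)
      lvl <- ifelse(pat, bc$positive, bc$negative)
      m <- matrix(rnorm0(n * length(pat), 0, bc$noiseSd),
                  n, length(pat), byrow = TRUE)
      m <- sweep(m, 2, lvl, "+")
      colnames(m) <- c(inner_ch, outer_ch)
      m
    })
    blocks[[i]] <- cbind(intensities(unit$events),
                         to_raw(bc_arc, config$cofactor))
    sc <- unit$sidecar
    sc$donor <- e$donor; sc$treatment <- e$treatment
    sc$well_id <- e$well_id; sc$antibody <- e$antibody
    sc$inner_code <- e$inner_code; sc$outer_code <- e$outer_code
    sidecars[[i]] <- sc
  }
  ex <- do.call(rbind, blocks)
  sidecar <- do.call(rbind, c(sidecars, make.row.names = FALSE))

  with_seed(child_seed(config$seed, c("pool", batchId)), {
    ord <- sample.int(nrow(ex))
    ex <- ex[ord, , drop = FALSE]
    sidecar <- sidecar[ord, , drop = FALSE]
    at <- sort(stats::runif(nrow(ex), 0, config$acquisitionWindow))
    if (!is.null(config$drift)) {
      dm <- config$drift$marker
      if (dm %in% colnames(ex)) {
        arc <- asinh(ex[, dm] / config$cofactor)
        bg <- arc < config$drift$ref
        arc[bg] <- arc[bg] + config$drift$slope * at[bg]
        ex[, dm] <- to_raw(arc, config$cofactor)
      }
    }
    rownames(sidecar) <- NULL
    list(events = cytoEvents(ex, scale = "raw", acquisitionTime = at),
         sidecar = sidecar)
  })
}

#' Write a full synthetic experiment to disk
#'
#' One FCS file and one sidecar CSV per batch, plus a provenance JSON
#' recording the seed and a hash of the configuration. Byte-identical
#' across reruns with the same configuration.
#'
#' @param config a [simulationConfig()].
#' @param manifest an [ExperimentManifest-class] object.
#' @param outDir output directory (created if needed).
#' @param nEventsPerUnit override of events per sample unit.
#' @return invisibly, a data.frame of the files written per batch.
#' @export
writeExperiment <- function(config, manifest, outDir, nEventsPerUnit = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- lapply(batchIds(manifest), function(b) {
    sim <- simulateBatch(config, manifest, b,
                         nEventsPerUnit = nEventsPerUnit)
    fcs <- file.path(outDir, paste0(b, ".fcs"))
    csv <- file.path(outDir, paste0(b, "_sidecar.csv"))
    writeFCS(sim$events, fcs)
    utils::write.csv(sim$sidecar, csv, row.names = FALSE)
    data.frame(batch = b, fcs = fcs, sidecar = csv,
               stringsAsFactors = FALSE)
  })
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  prov <- list(seed = config$seed,
               config_hash = child_seed(0L, as.character(cfg_json)),
               n_batches = nBatches(manifest))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(do.call(rbind, c(files, make.row.names = FALSE)))
}

#' Default synthetic study conditions
#'
#' A compact emulation of a three-donor, two-treatment plate screen: four
#' immune-like subsets (CD4 and CD8 T cells, B cells, NK cells) over six
#' lineage markers with a 2 arcsinh-unit separation between negative and
#' positive modalities (sd 0.3), a bimodal CD161-like marker on CD8 T
#' cells (30% high fraction), CD45- and palladium-tier barcodes at a 1.0
#' arcsinh-unit gap with noise sd 0.15, and an anti-PE screen readout. The
#' screen carries a blank control, `nAntibodies` antibodies with seeded
#' per-subset positive fractions, one MAIT-like antibody whose positivity
#' co-varies with the CD161 channel, one fixation-gain antibody (factor
#' 2.5) and one fixation-loss antibody (factor 0.3).
#'
#' @param seed master seed.
#' @param nEvents events per sample unit.
#' @param screen include the screen readout spec (default TRUE).
#' @param nAntibodies number of non-blank screen antibodies (default 12).
#' @return a [simulationConfig()].
#' @export
defaultSimulationConfig <- function(seed = 1, nEvents = 1000,
                                    screen = TRUE, nAntibodies = 12) {
  lo <- 0.8; hi <- 2.8
  mk <- function(...) {
    v <- c(...)
    lapply(stats::setNames(as.list(v), names(v)),
           function(m) list(mean = m, sd = 0.3))
  }
  subsets <- list(
    "CD4 T Cells" = mk(CD3 = hi, CD19 = lo, CD56 = lo, CD4 = hi,
                       CD8 = lo, CD161 = lo),
    "CD8 T Cells" = c(mk(CD3 = hi, CD19 = lo, CD56 = lo, CD4 = lo,
                         CD8 = hi),
                      list(CD161 = list(mean = lo, sd = 0.3,
                                        hiFraction = 0.3, hiMean = hi))),
    "B Cells" = mk(CD3 = lo, CD19 = hi, CD56 = lo, CD4 = lo,
                   CD8 = lo, CD161 = lo),
    "NK Cells" = mk(CD3 = lo, CD19 = lo, CD56 = hi, CD4 = lo,
                    CD8 = lo, CD161 = lo)
  )
  donors <- list(
    D1 = c("CD4 T Cells" = 0.35, "CD8 T Cells" = 0.25,
           "B Cells" = 0.25, "NK Cells" = 0.15),
    D2 = c("CD4 T Cells" = 0.30, "CD8 T Cells" = 0.30,
           "B Cells" = 0.20, "NK Cells" = 0.20),
    D3 = c("CD4 T Cells" = 0.35, "CD8 T Cells" = 0.25,
           "B Cells" = 0.28, "NK Cells" = 0.12)
  )
  scr <- NULL
  fixation <- list()
  if (screen) {
    subset_names <- names(subsets)
    abs <- list(
      Blank = list(posLevel = 2.8, negLevel = 0.8, sd = 0.3,
                   fractions = c())
    )
    ## seeded per-subset positive fractions for the generic antibodies
    fracs <- with_seed(child_seed(seed, "screen-fractions"), {
      matrix(round(stats::runif(nAntibodies * length(subset_names),
                                0.05, 0.9), 2),
             nAntibodies, length(subset_names),
             dimnames = list(NULL, subset_names))
    })
    for (i in seq_len(nAntibodies)) {
      abs[[sprintf("Ab%02d", i)]] <- list(
        posLevel = 2.8, negLevel = 0.8, sd = 0.3,
        fractions = fracs[i, ]
      )
    }
    ## MAIT-like antibody: positive mostly in CD161-high events
    abs[["Ab_MAIT"]] <- list(
      posLevel = 2.8, negLevel = 0.8, sd = 0.3,
      fractions = stats::setNames(rep(0.05, length(subset_names)),
                                  subset_names),
      coMarker = "CD161", coRef = 1.8, coHiFraction = 0.9
    )
    scr <- list(readoutChannel = "PE", antibodies = abs)
    fixation <- list(Ab01 = 2.5, Ab02 = 0.3)
  }
  simulationConfig(
    donors = donors, subsets = subsets,
    barcode = list(positive = 1.5, negative = 0.5, noiseSd = 0.15),
    screen = scr, fixation = fixation, nEvents = nEvents, seed = seed
  )
}

#' Default gating hierarchy matching the synthetic study conditions
#'
#' Level 1 identifies T cells (CD3+ CD19-), B cells (CD19+ CD3-) and NK
#' cells (CD3- CD19- CD56+); level 2 splits T cells into CD4+ CD8- and
#' CD8+ CD4-.
#'
#' @return a [GatingHierarchy-class] object.
#' @export
defaultHierarchy <- function() {
  t1 <- function(m, s) list(marker = m, sign = s)
  gatingHierarchy(list(
    list(
      list(parent = "Cell", child = "T Cells",
           terms = list(t1("CD3", "+"), t1("CD19", "-"))),
      list(parent = "Cell", child = "B Cells",
           terms = list(t1("CD19", "+"), t1("CD3", "-"))),
      list(parent = "Cell", child = "NK Cells",
           terms = list(t1("CD3", "-"), t1("CD19", "-"), t1("CD56", "+")))
    ),
    list(
      list(parent = "T Cells", child = "CD4 T Cells",
           terms = list(t1("CD4", "+"), t1("CD8", "-"))),
      list(parent = "T Cells", child = "CD8 T Cells",
           terms = list(t1("CD8", "+"), t1("CD4", "-")))
    )
  ), root = "Cell")
}

#' Default two-tier schemes and a small manifest for the synthetic screen
#'
#' A 2-of-4 CD45-tier scheme and a 2-of-5 palladium-tier scheme over a
#' configurable number of antibody wells in batches of 10, mirroring the
#' plate-screen design (a full batch carries 6 x 10 = 60 code
#' combinations).
#'
#' @param config a [simulationConfig()] whose screen antibodies become the
#'   wells (one well per antibody, the blank first); or `NULL` with
#'   explicit `antibodies`.
#' @param donors,treatments unit dimensions.
#' @param antibodies explicit antibody-per-well vector overriding the
#'   config's antibody names.
#' @return an [ExperimentManifest-class] object.
#' @export
defaultManifest <- function(config = defaultSimulationConfig(),
                            donors = c("D1", "D2", "D3"),
                            treatments = c("fresh", "fixed"),
                            antibodies = NULL) {
  if (is.null(antibodies)) {
    nm <- names(config$screen$antibodies)
    antibodies <- c(intersect("Blank", nm), setdiff(nm, "Blank"))
  }
  wells <- data.frame(
    well_id = sprintf("W%03d", seq_along(antibodies)),
    antibody = antibodies,
    is_control = antibodies == "Blank",
    stringsAsFactors = FALSE
  )
  buildManifest(
    donors = donors, treatments = treatments, wells = wells,
    batchSize = 10,
    innerScheme = makeScheme(paste0("CD45_", 1:4), 2),
    outerScheme = makeScheme(paste0("Pd", 1:5), 2)
  )
}
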