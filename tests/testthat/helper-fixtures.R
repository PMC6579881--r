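## Shared fixtures, built in code at test time.

## small raw-scale event matrix with named channels
make_events <- function(n = 100, channels = c("CD3", "CD19"), seed = 1,
                        lambda = 50) {
  set.seed(seed)
  m <- matrix(stats::rpois(n * length(channels), lambda), n,
              dimnames = list(NULL, channels))
  cytoEvents(m)
}

## two well-separated Gaussian blobs on two markers (arcsinh scale)
make_blobs <- function(n_per = 200, sep = 6, sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- rbind(
    cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
    cbind(rnorm(n_per, sep, sd), rnorm(n_per, sep, sd))
  )
  colnames(x) <- c("m1", "m2")
  list(events = cytoEvents(x, scale = "arcsinh"),
       truth = rep(1:2, each = n_per))
}

## mixture config with adjustable separation between subset modalities,
## mirroring the default study conditions but without the screen
separation_config <- function(sep = 2, seed = 1, nEvents = 1000) {
  lo <- 0.8
  hi <- lo + sep
  mk <- function(...) {
    v <- c(...)
    lapply(stats::setNames(as.list(v), names(v)),
           function(m) list(mean = m, sd = 0.3))
  }
  simulationConfig(
    donors = list(D1 = c("CD4 T Cells" = 0.3, "CD8 T Cells" = 0.25,
                         "B Cells" = 0.25, "NK Cells" = 0.2)),
    subsets = list(
      "CD4 T Cells" = mk(CD3 = hi, CD19 = lo, CD56 = lo, CD4 = hi,
                         CD8 = lo),
      "CD8 T Cells" = mk(CD3 = hi, CD19 = lo, CD56 = lo, CD4 = lo,
                         CD8 = hi),
      "B Cells" = mk(CD3 = lo, CD19 = hi, CD56 = lo, CD4 = lo, CD8 = lo),
      "NK Cells" = mk(CD3 = lo, CD19 = lo, CD56 = hi, CD4 = lo, CD8 = lo)
    ),
    barcode = list(positive = 1.5, negative = 0.5, noiseSd = 0.15),
    nEvents = nEvents, seed = seed
  )
}

## per-subset recovery MCC of a labeling against sidecar truth
subset_mccs <- function(truth, pred) {
  vapply(unique(truth), function(s) {
    mcc(confusionCounts(truth, pred, s))
  }, numeric(1))
}
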