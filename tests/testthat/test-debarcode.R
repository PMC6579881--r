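## noiseless barcoded events for a scheme: one block per requested code
noiseless_events <- function(scheme, codes, n_per = 20, pos = 1.5,
                             neg = 0.5) {
  x <- do.call(rbind, lapply(codes, function(cid) {
    pat <- scheme@codes[cid + 1L, ]
    matrix(rep(ifelse(pat, pos, neg), n_per), n_per, byrow = TRUE)
  }))
  colnames(x) <- scheme@channels
  list(events = cytoEvents(x, scale = "arcsinh"),
       truth = rep(codes, each = n_per))
}

test_that("noiseless codes are recovered perfectly by both methods", {
  scheme <- makeScheme(paste0("BC", 1:4), 2)
  fx <- noiseless_events(scheme, 0:5)
  topk <- debarcodeTopK(fx$events, scheme)
  expect_identical(assignments(topk), as.integer(fx$truth))
  expect_identical(sum(is.na(assignments(topk))), 0L)
  clus <- debarcodeCluster(fx$events, scheme,
                           params = clusterParams(seed = 1, kMax = 12))
  expect_identical(assignments(clus), assignments(topk))
  ## counts bookkeeping
  expect_identical(unname(perCodeCounts(topk)), rep(20L, 6))
})

test_that("an omitted code receives no spurious events", {
  scheme <- makeScheme(paste0("BC", 1:4), 2)
  fx <- noiseless_events(scheme, c(0:2, 4:5))  # code 3 absent
  clus <- debarcodeCluster(fx$events, scheme,
                           params = clusterParams(seed = 2, kMax = 12))
  expect_identical(unname(perCodeCounts(clus))[4], 0L)
  expect_identical(assignments(clus), as.integer(fx$truth))
  ## single-code input all lands on that code
  one <- noiseless_events(scheme, 2)
  expect_identical(unique(assignments(
    debarcodeCluster(one$events, scheme,
                     params = clusterParams(seed = 3, kMax = 12)))), 2L)
})

test_that("ambiguous signatures are rejected, monotonically in the cutoff", {
  scheme <- makeScheme(paste0("BC", 1:4), 2)
  fx <- noiseless_events(scheme, 0:5)
  ## an event with three near-equal bright channels is unassigned
  amb_m <- rbind(c(1.5, 1.5, 1.45, 0.5),
                 matrix(rep(c(1.5, 1.5, 0.5, 0.5), 30), 30, byrow = TRUE))
  colnames(amb_m) <- scheme@channels
  amb <- cytoEvents(amb_m, scale = "arcsinh")
  res <- debarcodeTopK(amb, scheme, minSeparation = 0.3)
  expect_true(is.na(assignments(res)[1]))
  ## raising the cutoff never assigns more events
  set.seed(31)
  noisy <- cytoEvents(intensities(fx$events) +
                        matrix(rnorm(length(intensities(fx$events)),
                                     0, 0.25), nrow = nEvents(fx$events)),
                      scale = "arcsinh")
  n_assigned <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(ms) {
    sum(!is.na(assignments(debarcodeTopK(noisy, scheme,
                                         minSeparation = ms))))
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("two-tier debarcoding resolves a noisy 60-code batch", {
  cfg <- defaultSimulationConfig(seed = 42, nEvents = 100, screen = FALSE)
  man <- defaultManifest(cfg, antibodies = sprintf("Ab%02d", 1:10))
  sim <- simulateBatch(cfg, man, "batch_01")
  expect_identical(nEvents(sim$events), 6000L)
  asg <- twoTierDebarcode(asinhTransform(sim$events), man, "batch_01")
  truth <- paste(sim$sidecar$donor, sim$sidecar$treatment,
                 sim$sidecar$well_id)
  pred <- paste(asg$donor, asg$treatment, asg$well_id)
  ## all 60 expected combinations are populated
  expect_identical(length(unique(pred[asg$assigned])), 60L)
  ## >= 99% of assigned events match the sidecar at gap 1.0, noise sd 0.15
  expect_gte(mean(pred[asg$assigned] == truth[asg$assigned]), 0.99)
  ## per-code precision >= 0.98
  key_truth <- paste(sim$sidecar$inner_code, sim$sidecar$outer_code)
  key_pred <- ifelse(asg$assigned,
                     paste(asg$inner_code, asg$outer_code), "none")
  per_code <- vapply(unique(key_truth), function(k) {
    cts <- confusionCounts(key_truth, key_pred, k)
    precision(cts)
  }, numeric(1))
  expect_true(all(per_code >= 0.98))
  ## valid outer but unexpected pair stays unassigned, not an error
  asg2 <- asg[!is.na(asg$inner_code) & !is.na(asg$outer_code), ]
  expect_true(all(asg2$assigned | is.na(asg2$well_id)))
})

test_that("zero barcode noise gives exact two-tier recovery", {
  cfg <- defaultSimulationConfig(seed = 9, nEvents = 50, screen = FALSE)
  cfg$barcode$noiseSd <- 0
  man <- defaultManifest(cfg, antibodies = sprintf("Ab%02d", 1:10))
  sim <- simulateBatch(cfg, man, "batch_01")
  asg <- twoTierDebarcode(asinhTransform(sim$events), man, "batch_01")
  expect_true(all(asg$assigned))
  expect_identical(paste(asg$donor, asg$treatment, asg$well_id),
                   paste(sim$sidecar$donor, sim$sidecar$treatment,
                         sim$sidecar$well_id))
})

test_that("missing barcode channels raise key errors", {
  scheme <- makeScheme(paste0("BC", 1:4), 2)
  ev <- cytoEvents(matrix(1, 5, 2, dimnames = list(NULL, c("BC1", "BC2"))),
                   scale = "arcsinh")
  expect_error(debarcodeTopK(ev, scheme), class = "cytoscreen_key_error")
  expect_error(debarcodeCluster(ev, scheme),
               class = "cytoscreen_key_error")
})
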