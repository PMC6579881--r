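## Independent oracle for the MCC cutoff search: enumerate every candidate
## midpoint and score it with plain confusion arithmetic.
brute_mcc_threshold <- function(values, clusters) {
  meds <- tapply(values, clusters, median)
  sm <- sort(unique(meds))
  cand <- (sm[-length(sm)] + sm[-1]) / 2
  scores <- vapply(cand, function(t) {
    e <- values > t
    p <- unname(meds[as.character(clusters)] > t)
    tp <- sum(e & p); tn <- sum(!e & !p)
    fp <- sum(!e & p); fn <- sum(e & !p)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }, numeric(1))
  list(cand = cand, scores = scores,
       best = unname(cand[which.max(scores)]), mcc = max(scores))
}

test_that("the MCC cutoff search agrees with brute-force enumeration", {
  ## perfect two-cluster split
  th <- mccThreshold(c(0, 0, 10, 10), c("A", "A", "B", "B"))
  expect_equal(th$cutoff, 5)
  expect_identical(th$signs, c(A = "-", B = "+"))
  expect_equal(th$mcc, 1)
  ## three clusters with a strictly better upper cutoff: the low cluster
  ## pair overlaps heavily, so splitting between them misclassifies events
  set.seed(41)
  v <- c(rnorm(100, 0, 0.6), rnorm(100, 1, 0.6), rnorm(100, 10, 0.1))
  cl <- rep(c("a", "b", "c"), each = 100)
  oracle <- brute_mcc_threshold(v, cl)
  th <- mccThreshold(v, cl)
  expect_equal(th$cutoff, oracle$best)
  expect_equal(th$mcc, oracle$mcc, tolerance = 1e-12)
  expect_identical(unname(th$signs), c("-", "-", "+"))
  ## seeded well-separated trio: ties resolve to the lowest cutoff
  set.seed(42)
  v2 <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1), rnorm(50, 10, 0.1))
  cl2 <- rep(c("a", "b", "c"), each = 50)
  or2 <- brute_mcc_threshold(v2, cl2)
  th2 <- mccThreshold(v2, cl2)
  expect_equal(th2$mcc, max(or2$scores), tolerance = 1e-12)
  expect_equal(th2$cutoff,
               min(or2$cand[or2$scores >= max(or2$scores) - 1e-12]))
})

test_that("uninformative markers are flagged, not scored", {
  th1 <- mccThreshold(rnorm(20), rep("only", 20))
  expect_false(th1$informative)
  expect_identical(th1$mcc, 0)
  expect_identical(unname(th1$signs), "-")
  th2 <- mccThreshold(rep(3, 40), rep(c("a", "b"), 20))
  expect_false(th2$informative)
  expect_error(mccThreshold(1:3, 1:2), "equal length")
})

test_that("one gating level recovers a two-subset mixture", {
  set.seed(7)
  n <- 1000
  truth <- sample(c("T Cells", "B Cells"), n, replace = TRUE)
  x <- cbind(
    CD3 = rnorm(n, ifelse(truth == "T Cells", 2.8, 0.8), 0.3),
    CD19 = rnorm(n, ifelse(truth == "B Cells", 2.8, 0.8), 0.3)
  )
  ev <- cytoEvents(x, scale = "arcsinh")
  rules <- gatingHierarchy(list(list(
    list(parent = "Cell", child = "T Cells",
         terms = list(list(marker = "CD3", sign = "+"),
                      list(marker = "CD19", sign = "-"))),
    list(parent = "Cell", child = "B Cells",
         terms = list(list(marker = "CD19", sign = "+"),
                      list(marker = "CD3", sign = "-")))
  )))@rules
  res <- labelLevel(ev, rep("Cell", n), rules,
                    params = clusterParams(seed = 5))
  for (s in c("T Cells", "B Cells")) {
    expect_gte(mcc(confusionCounts(truth, res$labels, s)), 0.95)
  }
  expect_true(all(c("CD3", "CD19") %in% res$thresholds$marker))
})

test_that("a two-level hierarchy recovers four subsets end to end", {
  cfg <- separation_config(sep = 2, seed = 11, nEvents = 4000)
  u <- simulateSampleUnit(cfg, "D1", "fresh", "W001")
  tr <- asinhTransform(u$events)
  lab <- labelEvents(tr, defaultHierarchy(), clusterParams(seed = 2))
  ## partition property
  expect_identical(length(labels(lab)), nEvents(tr))
  expect_identical(sum(labelCounts(lab)), as.integer(nEvents(tr)))
  scores <- subset_mccs(u$sidecar$subset, labels(lab))
  expect_true(all(scores >= 0.9))
  ## agreement with direct threshold gating at the generator midpoints
  x <- intensities(tr)
  manual <- rep("UNASSIGNED", nrow(x))
  tcell <- x[, "CD3"] > 1.8 & x[, "CD19"] <= 1.8
  manual[tcell & x[, "CD4"] > 1.8 & x[, "CD8"] <= 1.8] <- "CD4 T Cells"
  manual[tcell & x[, "CD8"] > 1.8 & x[, "CD4"] <= 1.8] <- "CD8 T Cells"
  manual[x[, "CD19"] > 1.8 & x[, "CD3"] <= 1.8] <- "B Cells"
  manual[x[, "CD3"] <= 1.8 & x[, "CD19"] <= 1.8 &
           x[, "CD56"] > 1.8] <- "NK Cells"
  gate_scores <- subset_mccs(manual, labels(lab))
  expect_true(all(gate_scores[names(gate_scores) != "UNASSIGNED"] >= 0.9))
})

test_that("recovery degrades monotonically as separation shrinks", {
  seps <- c(3, 2, 1, 0.5)
  worst <- vapply(seps, function(s) {
    cfg <- separation_config(sep = s, seed = 23, nEvents = 2000)
    u <- simulateSampleUnit(cfg, "D1", "fresh", "W001")
    lab <- labelEvents(asinhTransform(u$events), defaultHierarchy(),
                       clusterParams(seed = 4))
    min(subset_mccs(u$sidecar$subset, labels(lab)))
  }, numeric(1))
  ## non-increasing up to simulation jitter
  expect_true(all(diff(worst) <= 0.02))
  expect_gte(worst[1], 0.95)
  expect_lt(worst[4], worst[1])
})

test_that("degenerate hierarchies and inputs behave as documented", {
  ev <- make_blobs(seed = 5)$events
  root_only <- gatingHierarchy(list(), root = "Cell")
  lab <- labelEvents(ev, root_only)
  expect_identical(unique(labels(lab)), "Cell")
  empty <- cytoEvents(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("m1", "m2"))),
                      scale = "arcsinh")
  expect_identical(length(labels(labelEvents(empty, defaultHierarchy()))),
                   0L)
  ## all-identical events: one effective cluster, one outcome for all
  same <- cytoEvents(matrix(1, 50, 2, dimnames = list(NULL, c("m1", "m2"))),
                     scale = "arcsinh")
  h <- gatingHierarchy(list(list(
    list(parent = "Cell", child = "hi",
         terms = list(list(marker = "m1", sign = "+")))
  )))
  lab_same <- labelEvents(same, h, clusterParams(seed = 1))
  expect_identical(length(unique(labels(lab_same))), 1L)
  expect_true(unique(labels(lab_same)) %in% c("hi", "UNASSIGNED"))
})

test_that("hierarchy validity catches malformed rule sets", {
  expect_error(gatingHierarchy(list(list(
    list(parent = "Ghost", child = "X",
         terms = list(list(marker = "m1", sign = "+")))
  ))), "earlier level")
  expect_error(gatingHierarchy(list(list(
    list(parent = "Cell", child = "X",
         terms = list(list(marker = "m1", sign = "?")))
  ))), "terms")
})
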