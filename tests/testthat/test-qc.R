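test_that("confusion counts follow the one-vs-rest convention", {
  truth <- c(rep("t", 6), rep("o", 4))
  pred <- truth
  pred[c(1, 2)] <- "o"   # two targets flipped away
  pred[7] <- "t"         # one other flipped in
  cts <- confusionCounts(truth, pred, "t")
  expect_identical(cts, list(TP = 4L, FP = 1L, TN = 3L, FN = 2L))
  expect_identical(sum(unlist(cts)), 10L)
  same <- confusionCounts(truth, truth, "t")
  expect_identical(same$FP + same$FN, 0L)
  flip <- confusionCounts(c(TRUE, FALSE), c(FALSE, TRUE), TRUE)
  expect_identical(flip$TP + flip$TN, 0L)
  expect_error(confusionCounts(1:3, 1:2, 1), "equal length")
})

test_that("relevance metrics match direct formula arithmetic", {
  cts <- list(TP = 8, FP = 2, TN = 85, FN = 5)
  expect_equal(precision(cts), 0.8)
  expect_equal(recall(cts), 0.6154, tolerance = 1e-4)
  expect_equal(f1Score(precision(cts), recall(cts)), 0.6957,
               tolerance = 1e-4)
  expect_equal(mcc(cts), 670 / sqrt(10 * 13 * 87 * 90), tolerance = 1e-12)
  perfect <- list(TP = 10, FP = 0, TN = 10, FN = 0)
  expect_equal(c(precision(perfect), recall(perfect), mcc(perfect)),
               c(1, 1, 1))
  ## harmonic-mean properties
  expect_lte(f1Score(0.4, 0.9), max(0.4, 0.9))
  expect_equal(f1Score(0.7, 0.7), 0.7)
  ## zero-denominator conventions
  expect_warning(p0 <- precision(list(TP = 0, FP = 0, TN = 5, FN = 5)))
  expect_identical(p0, 0)
  expect_identical(mcc(list(TP = 0, FP = 0, TN = 10, FN = 0)), 0)
})

test_that("MCC equals the Pearson correlation of indicator vectors", {
  ## brute force over all 2x2 tables with n <= 8 and both classes present
  for (n in 2:8) {
    parts <- expand.grid(TP = 0:n, FP = 0:n, TN = 0:n, FN = 0:n)
    parts <- parts[rowSums(parts) == n, ]
    for (i in seq_len(nrow(parts))) {
      ct <- as.list(parts[i, ])
      e <- c(rep(1, ct$TP), rep(0, ct$FP), rep(0, ct$TN), rep(1, ct$FN))
      p <- c(rep(1, ct$TP), rep(1, ct$FP), rep(0, ct$TN), rep(0, ct$FN))
      if (stats::sd(e) == 0 || stats::sd(p) == 0) next
      expect_equal(mcc(ct), stats::cor(e, p), tolerance = 1e-12)
    }
  }
})

test_that("AOF hits its closed-form anchors", {
  set.seed(3)
  expect_lte(aof(rnorm(10000, 0, 0.1), rnorm(10000, 10, 0.1)), 0.001)
  set.seed(3)
  ## identical normal modalities: each term is Phi(1.645) = 0.95
  expect_equal(aof(rnorm(100000), rnorm(100000)), stats::pnorm(1.645),
               tolerance = 0.01)
  expect_error(aof(numeric(0), rnorm(5)), "non-empty")
  ## zero-sd modality treated as a point mass
  expect_equal(aof(rep(0, 100), rep(10, 100)), 0)
  ## coincident point masses: strict tail inequalities give 0 by the
  ## documented zero-sd convention
  expect_equal(aof(rep(1, 100), rep(1, 100)), 0)
})

test_that("AOF decreases monotonically with modality separation", {
  seps <- c(0.5, 1, 1.5, 2, 3)
  vals <- vapply(seps, function(s) {
    set.seed(17)
    aof(rnorm(20000, 0, 0.5), rnorm(20000, s, 0.5))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("modality splitting honors each method's contract", {
  set.seed(8)
  v <- c(rnorm(3000, 0.8, 0.3), rnorm(1500, 2.8, 0.3))
  sp <- splitModalities(v, "two_means")
  expect_equal(sp$boundary, 1.8, tolerance = 0.1 * 1.8)
  expect_identical(length(sp$neg) + length(sp$pos), length(v))
  fx <- splitModalities(c(-1, 1, -1, 1), "fixed_threshold", threshold = 0)
  expect_identical(fx$neg, c(-1, -1))
  expect_identical(fx$pos, c(1, 1))
  lb <- splitModalities(1:4, "labeled",
                        labels = c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(lb$pos, c(1L, 3L))
  expect_identical(lb$neg, c(2L, 4L))
  expect_error(splitModalities(rep(2, 10), "two_means"), "constant")
})

test_that("Scaled^2 and Quality^2 match a hand-computed oracle", {
  a <- matrix(c(0.1, 0.2, 0.1,
                0.1, 0.2, 0.3,
                0.4, 0.2, 0.2), 3, 3, byrow = FALSE,
              dimnames = list(paste0("m", 1:3), paste0("s", 1:3)))
  ## rows: m1 = (.1,.1,.4), m2 = (.2,.2,.2), m3 = (.1,.3,.2)
  sc <- scaledAof(a)
  ## m1: mean .2, sd sqrt(.03); z = (-.577, -.577, 1.155) -> (0,0,1.333)
  expect_equal(unname(sc[1, ]), c(0, 0, 4 / 3), tolerance = 1e-6)
  ## m2 constant -> all zero by the sd-0 convention
  expect_equal(unname(sc[2, ]), c(0, 0, 0))
  ## m3: mean .2, sd .1; z = (-1, 1, 0) -> (0, 1, 0)
  expect_equal(unname(sc[3, ]), c(0, 1, 0), tolerance = 1e-12)
  q <- aofQuality(sc)
  expect_equal(unname(q), c(0, 1, 4 / 3), tolerance = 1e-6)
  expect_identical(unname(which.max(q)), 3L)
  ## an entry exactly one sd above its row mean scales to 1
  z <- scaledAof(rbind(c(0, 0.1, 0.2)))   # mean .1, sd .1, z = (-1, 0, 1)
  expect_equal(unname(z[1, ]), c(0, 0, 1), tolerance = 1e-12)
  expect_warning(scaledAof(matrix(0.5, 2, 1)), "fewer than 2")
})

test_that("Quality^2 is additive over disjoint marker sets", {
  set.seed(5)
  a <- matrix(runif(40, 0, 0.6), 8, 5)
  q_all <- aofQuality(scaledAof(a))
  q_split <- aofQuality(scaledAof(a[1:3, ])) +
    aofQuality(scaledAof(a[4:8, ]))
  expect_equal(q_all, q_split, tolerance = 1e-12)
})

test_that("time-quartile AOF flags injected drift and not the null", {
  build <- function(slope) {
    set.seed(5)
    n <- 8000
    at <- sort(runif(n, 0, 1800))
    pos <- runif(n) < 0.4
    x <- ifelse(pos, rnorm(n, 2.8, 0.3), rnorm(n, 0.8, 0.3))
    bg <- !pos
    x[bg] <- x[bg] + slope * at[bg]
    list(events = cytoEvents(matrix(x, ncol = 1,
                                    dimnames = list(NULL, "CD27")),
                             scale = "arcsinh", acquisitionTime = at),
         pos = pos)
  }
  ## modalities identified by the expected-positive labels, so a rising
  ## background cannot re-define them
  d <- build(8e-4)
  drifted <- quartileDrift(d$events, "CD27", method = "labeled",
                           labels = d$pos)
  expect_true(drifted$flag)
  expect_true(all(diff(drifted$aof) > 0))
  n0 <- build(0)
  null <- quartileDrift(n0$events, "CD27", method = "labeled",
                        labels = n0$pos)
  expect_false(null$flag)
  ## restricting to the first quartile recovers the undrifted quality
  expect_lt(abs(drifted$aof[1] - null$aof[1]), 0.02)
  no_time <- cytoEvents(matrix(rnorm(100), ncol = 1,
                               dimnames = list(NULL, "CD27")),
                        scale = "arcsinh")
  expect_error(quartileDrift(no_time, "CD27"), "acquisition time")
})

test_that("AOF reports assemble matrices, metadata and quality", {
  set.seed(6)
  vals <- lapply(stats::setNames(nm = c("CD3", "CD19")), function(m) {
    lapply(stats::setNames(nm = c("s1", "s2", "s3")), function(s) {
      shift <- if (s == "s3" && m == "CD3") 1.5 else 0
      c(rnorm(2000, 0.8 + shift, 0.3), rnorm(1000, 2.8, 0.3))
    })
  })
  rep <- buildAofReport(vals)
  expect_identical(dim(aofMatrix(rep)), c(2L, 3L))
  expect_true(all(aofMatrix(rep) >= 0 & aofMatrix(rep) <= 1))
  ## the degraded (marker, sample) drives the worst quality score
  expect_identical(unname(which.max(sampleQuality(rep))), 3L)
})
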