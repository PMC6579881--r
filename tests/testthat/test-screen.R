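test_that("the blank threshold is the interpolated 99th percentile", {
  expect_equal(blankThreshold(1:100), 99.01)
  expect_equal(blankThreshold(rep(2.5, 50)), 2.5)
  set.seed(1)
  v <- rnorm(1000)
  expect_identical(blankThreshold(v), blankThreshold(sample(v)))
  expect_error(blankThreshold(numeric(0)), "no events")
})

test_that("percent positive counts strict exceedances", {
  expect_equal(percentPositive(c(rep(0, 190), rep(10, 10)), 5), 5)
  expect_equal(percentPositive(c(1, 2, 3), 5), 0)
  ## a blank scored against its own threshold sits at ~1%
  set.seed(2)
  blank <- rnorm(10000)
  expect_equal(percentPositive(blank, blankThreshold(blank)), 1,
               tolerance = 0.05)
  expect_warning(p <- percentPositive(numeric(0), 1))
  expect_identical(p, 0)
  ## monotone non-increasing in the threshold
  v <- rnorm(500)
  pp <- vapply(c(-2, -1, 0, 1, 2), function(t) percentPositive(v, t),
               numeric(1))
  expect_true(all(diff(pp) <= 0))
})

## build a labeled+profiled event table straight from generator draws
screen_event_table <- function(seed = 13, nEvents = 3000,
                               treatment = "fresh") {
  cfg <- defaultSimulationConfig(seed = seed, nEvents = nEvents,
                                 nAntibodies = 4)
  man <- defaultManifest(cfg)
  rows <- list()
  for (d in names(cfg$donors)) {
    for (i in seq_len(nrow(man@wells))) {
      w <- man@wells[i, ]
      u <- simulateSampleUnit(cfg, d, treatment, w$well_id,
                              antibody = w$antibody)
      tr <- asinhTransform(u$events)
      rows[[paste(d, w$well_id)]] <- data.frame(
        donor = d, treatment = treatment, well_id = w$well_id,
        antibody = w$antibody, profiling_subset = u$sidecar$subset,
        readout = intensities(tr)[, "PE"],
        truth_positive = u$sidecar$readout_positive
      )
    }
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)), cfg = cfg)
}

test_that("screen summaries recover generator positive fractions", {
  fx <- screen_event_table(seed = 13)
  res <- summarizeScreen(fx$table, "W001")
  expect_identical(nrow(res$thresholds), 3L)  # one per (donor, treatment)
  smry <- res$summary
  ## oracle: the generator sidecar records which events were planted
  ## positive; the blank threshold sits at the negative distribution's
  ## 99th percentile by construction, so the expected percent positive is
  ## the planted rate plus a 1% base rate on the negatives
  truth_pp <- stats::aggregate(
    truth_positive ~ donor + antibody + profiling_subset, fx$table,
    function(z) 100 * mean(z)
  )
  m <- merge(smry, truth_pp,
             by = c("donor", "antibody", "profiling_subset"))
  expect_gt(nrow(m), 40)
  expected <- m$truth_positive + (100 - m$truth_positive) * 0.01
  expect_true(all(abs(m$pct_positive - expected) <= 2))
  ## empty cells are emitted with n = 0 and NA statistics
  et0 <- fx$table
  et0 <- et0[!(et0$profiling_subset == "NK Cells" &
                 et0$antibody == "Ab01"), ]
  res0 <- summarizeScreen(et0, "W001")
  row0 <- res0$summary[res0$summary$profiling_subset == "NK Cells" &
                         res0$summary$antibody == "Ab01", ]
  expect_true(all(row0$n == 0))
  expect_true(all(is.na(row0$median)))
  ## determinism
  res2 <- summarizeScreen(fx$table, "W001")
  expect_identical(res$summary, res2$summary)
  expect_error(summarizeScreen(fx$table, "W999"), "blank well")
})

## synthetic per-(subset, antibody) summary grids for fixation tests
fix_grid <- function(medians, pct = 50) {
  data.frame(
    profiling_subset = rep(names(medians[[1]]), times = length(medians)),
    antibody = rep(names(medians), each = length(medians[[1]])),
    median = unlist(medians, use.names = FALSE),
    pct_positive = pct
  )
}

test_that("fixation classification applies the 2-fold rule", {
  subsets <- c("A", "B", "C")
  base <- list(
    AbU = stats::setNames(c(2.0, 2.2, 1.9), subsets),
    AbG = stats::setNames(c(1.5, 1.8, 1.6), subsets),
    AbL = stats::setNames(c(2.4, 2.1, 2.2), subsets),
    AbX = stats::setNames(c(2.3, 2.0, 2.1), subsets)
  )
  fresh <- fix_grid(base)
  shift <- function(m, f) asinh(f * sinh(m))
  fixed_m <- base
  fixed_m$AbG <- shift(base$AbG, 2.5)          # gain across all subsets
  fixed_m$AbL <- shift(base$AbL, 0.2)          # loss across all subsets
  fixed_m$AbX <- stats::setNames(              # loss in subset A only
    c(shift(base$AbX[1], 0.2), base$AbX[2:3]), subsets)
  fixed <- fix_grid(fixed_m)
  rep <- fixationClassify(fresh, fixed)
  cls <- stats::setNames(rep$byAntibody$class, rep$byAntibody$antibody)
  expect_identical(unname(cls["AbU"]), "unchanged")
  expect_identical(unname(cls["AbG"]), "gain")
  expect_identical(unname(cls["AbL"]), "loss")
  ## subset-specific exception: per-subset ratios differ while the
  ## antibody-level class follows the median over expressing subsets
  bs <- rep$bySubset
  rA <- bs$log10_ratio[bs$antibody == "AbX" & bs$profiling_subset == "A"]
  rB <- bs$log10_ratio[bs$antibody == "AbX" & bs$profiling_subset == "B"]
  expect_lt(rA, -log10(2))
  expect_equal(rB, 0, tolerance = 1e-12)
  expect_identical(unname(cls["AbX"]), "unchanged")
  ## identical inputs: everything unchanged with zero ratios
  same <- fixationClassify(fresh, fresh)
  expect_true(all(same$byAntibody$class == "unchanged"))
  expect_true(all(same$bySubset$log10_ratio == 0))
  ## antibody absent from one condition is skipped with a warning
  expect_warning(fixationClassify(fresh[fresh$antibody != "AbU", ], fixed),
                 "skipped")
})

test_that("expression floor controls which antibodies are classified", {
  g <- fix_grid(list(Ab1 = c(A = 2, B = 2)), pct = 3)
  rep <- fixationClassify(g, g, expressionFloor = 5)
  expect_identical(nrow(rep$byAntibody), 0L)
  rep2 <- fixationClassify(g, g, expressionFloor = 2)
  expect_identical(rep2$expressed, "Ab1")
})

test_that("standardized-residual consensus flags the planted antibody", {
  set.seed(23)
  n_ab <- 50
  donors <- paste0("D", 1:3)
  base <- runif(n_ab, 5, 80)
  ppNeg <- sapply(donors, function(d) base + rnorm(n_ab, 0, 2))
  ppPos <- sapply(donors, function(d) base + rnorm(n_ab, 0, 2))
  rownames(ppPos) <- rownames(ppNeg) <- sprintf("Ab%02d", 1:n_ab)
  ppPos["Ab07", ] <- ppPos["Ab07", ] + 40
  dm <- differentialMarkers(ppPos, ppNeg)
  expect_identical(dm$flagged$antibody, "Ab07")
  expect_identical(dm$flagged$direction, "positive")
  ## identical grids: no flags
  dm0 <- differentialMarkers(ppNeg, ppNeg)
  expect_identical(nrow(dm0$flagged), 0L)
  ## an offset in a single donor fails the consensus rule
  pp1 <- ppPos
  pp1["Ab07", 2:3] <- pp1["Ab07", 2:3] - 40
  expect_identical(nrow(differentialMarkers(pp1, ppNeg)$flagged), 0L)
})

test_that("the residual test is invariant to order and common shifts", {
  set.seed(29)
  n_ab <- 30
  ppNeg <- matrix(runif(n_ab * 3, 5, 80), n_ab, 3,
                  dimnames = list(sprintf("Ab%02d", 1:n_ab),
                                  paste0("D", 1:3)))
  ppPos <- ppNeg + matrix(rnorm(n_ab * 3, 0, 3), n_ab, 3)
  ppPos["Ab11", ] <- ppPos["Ab11", ] + 45
  dm <- differentialMarkers(ppPos, ppNeg)
  perm <- sample(n_ab)
  dm_p <- differentialMarkers(ppPos[perm, ], ppNeg[perm, ])
  expect_setequal(dm$flagged$antibody, dm_p$flagged$antibody)
  dm_s <- differentialMarkers(ppPos + 7, ppNeg + 7)
  expect_equal(dm_s$residuals, dm$residuals, tolerance = 1e-9)
  expect_error(differentialMarkers(ppPos[, 1, drop = FALSE],
                                   ppNeg[, 1, drop = FALSE]), "2 donors")
  expect_error(differentialMarkers(ppPos[1:5, ], ppNeg[1:5, ]),
               "10 antibodies")
})
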