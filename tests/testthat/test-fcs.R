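test_that("arcsinh transform matches its closed form and is invertible", {
  ev <- cytoEvents(matrix(c(0, 5, 10, 2.5), 2, 2,
                          dimnames = list(NULL, c("a", "b"))))
  tr <- asinhTransform(ev, cofactor = 5)
  expect_equal(unname(intensities(tr)[1, "a"]), 0)
  expect_equal(unname(intensities(tr)[2, "a"]), log(1 + sqrt(2)),
               tolerance = 1e-12)
  expect_identical(intensityScale(tr), "arcsinh")
  ## odd symmetry on a compensated (negative-valued) matrix
  expect_equal(asinh(-5 / 5), -asinh(5 / 5))
  ## sinh-inverse recovers raw values
  back <- 5 * sinh(intensities(tr))
  expect_equal(back, intensities(ev), tolerance = 1e-9)
  expect_error(asinhTransform(tr), "transformed")
  expect_error(asinhTransform(ev, cofactor = 0), "positive")
})

test_that("single-channel compensation is exact, local and linear", {
  ev <- cytoEvents(matrix(c(10, 0, 100, 50, 7, 7), 2, 3,
                          dimnames = list(NULL, c("gdTCR", "CD8", "other"))))
  cp <- compensateChannel(ev, "gdTCR", "CD8", 0.019)
  expect_equal(unname(intensities(cp)[1, "gdTCR"]), 10 - 0.019 * 100)
  expect_equal(intensities(cp)[, "other"], intensities(ev)[, "other"])
  expect_equal(intensities(cp)[, "CD8"], intensities(ev)[, "CD8"])
  ## fraction 0 is the identity; zero source leaves target unchanged
  expect_equal(intensities(compensateChannel(ev, "gdTCR", "CD8", 0)),
               intensities(ev))
  ev0 <- cytoEvents(matrix(c(3, 4, 0, 0), 2, 2,
                           dimnames = list(NULL, c("t", "s"))))
  expect_equal(intensities(compensateChannel(ev0, "t", "s", 0.5))[, "t"],
               c(3, 4))
  ## linearity: corrections from disjoint sources add up
  ev3 <- cytoEvents(matrix(runif(30, 1, 9), 10, 3,
                           dimnames = list(NULL, c("t", "s1", "s2"))))
  seq_comp <- compensateChannel(compensateChannel(ev3, "t", "s1", 0.1),
                                "t", "s2", 0.2)
  manual <- intensities(ev3)[, "t"] - 0.1 * intensities(ev3)[, "s1"] -
    0.2 * intensities(ev3)[, "s2"]
  expect_equal(intensities(seq_comp)[, "t"], manual)
  expect_error(compensateChannel(ev, "gdTCR", "gdTCR", 0.1), "differ")
  expect_error(compensateChannel(ev, "missing", "CD8", 0.1),
               class = "cytoscreen_key_error")
})

test_that("FCS files round-trip and are byte-stable", {
  set.seed(7)
  m <- matrix(abs(rnorm(5000, 200, 80)), 1000, 5,
              dimnames = list(NULL, paste0("Ch", 1:5)))
  ev <- cytoEvents(m)
  p1 <- withr::local_tempfile(fileext = ".fcs")
  p2 <- withr::local_tempfile(fileext = ".fcs")
  writeFCS(ev, p1)
  back <- readFCS(p1)
  expect_identical(dim(intensities(back)), dim(m))
  expect_equal(intensities(back), m, tolerance = 1e-4)
  expect_identical(channelNames(back), colnames(m))
  writeFCS(ev, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("FCS handles empty data, acquisition time, and bad input", {
  p <- withr::local_tempfile(fileext = ".fcs")
  empty <- cytoEvents(matrix(numeric(0), 0, 3,
                             dimnames = list(NULL, c("a", "b", "c"))))
  writeFCS(empty, p)
  back <- readFCS(p)
  expect_identical(nEvents(back), 0L)
  expect_identical(channelNames(back), c("a", "b", "c"))

  ## acquisition time goes out as a Time channel and comes back as a slot
  ev <- cytoEvents(matrix(1:8, 4, 2, dimnames = list(NULL, c("a", "b"))),
                   acquisitionTime = c(0, 1, 2, 3))
  writeFCS(ev, p)
  back <- readFCS(p)
  expect_equal(acquisitionTime(back), c(0, 1, 2, 3))
  expect_identical(channelNames(back), c("a", "b"))

  ## validation and format errors
  expect_error(cytoEvents(matrix(1:4, 2, 2,
                                 dimnames = list(NULL, c("x", "x")))),
               "unique")
  neg <- cytoEvents(matrix(c(-1, 2, 3, 4), 2, 2,
                           dimnames = list(NULL, c("a", "b"))))
  expect_error(writeFCS(neg, p), "nonnegative")
  tr <- asinhTransform(make_events())
  expect_error(writeFCS(tr, p), "raw")
  bad <- withr::local_tempfile()
  writeBin(as.raw(1:20), bad)
  expect_error(readFCS(bad), class = "cytoscreen_format_error")
  expect_error(readFCS(file.path(tempdir(), "no_such.fcs")),
               class = "cytoscreen_format_error")
})

test_that("panel definitions validate roles and look up channels", {
  pan <- panelDefinition(data.frame(
    channel = c("Y89", "Pd102", "Pd104"),
    metal = c("89Y", "102Pd", "104Pd"),
    marker = c("CD45", "BC1", "BC2"),
    role = c("barcode_cd45", "barcode_pd", "barcode_pd")
  ))
  expect_identical(panelChannels(pan, "barcode_pd"), c("Pd102", "Pd104"))
  expect_length(intersect(panelChannels(pan, "barcode_cd45"),
                          panelChannels(pan, "barcode_pd")), 0)
  expect_error(panelDefinition(data.frame(
    channel = c("a", "a"), metal = "m", marker = "x", role = "lineage"
  )), "unique")
  expect_error(panelChannels(pan, "nope"), "unknown role")
})
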