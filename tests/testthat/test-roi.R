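constantMap <- function(vals, units = "1e-6 mm^2/s") {
  v <- as3D(vals)
  new("ParametricMap", values = v, mask = array(TRUE, dim(v)),
      units = units, rss = array(0, dim(v)), flags = array(0L, dim(v)))
}

## direct slot-free constructor helpers for small label grids
as3D <- function(x) { d <- dim(x); if (length(d) == 2) dim(x) <- c(d, 1L); x }

test_that("a constant field summarizes to its value with zero spread", {
  lab <- matrix(0L, 6, 6); lab[2:3, 2:3] <- 1L; lab[5, 2:5] <- 2L
  rois <- ROISet(lab, data.frame(label = 1:2,
                                 compartment = c("cortex", "cortex")))
  s <- summarizeCompartment(constantMap(matrix(5, 6, 6)), rois, "cortex")
  expect_equal(s@mean, 5); expect_equal(s@sd, 0)
  expect_equal(s@nPixels, 8L); expect_equal(s@nROIs, 2L)
})

test_that("pixel pooling weights ROIs by area", {
  lab <- matrix(0L, 5, 8)
  lab[1:2, 1:5] <- 1L   # 10 px at value 4
  lab[4:5, 1:5] <- 2L   # 10 px at value 6
  vals <- matrix(0, 5, 8); vals[lab == 1L] <- 4; vals[lab == 2L] <- 6
  rois <- ROISet(lab, data.frame(label = 1:2,
                                 compartment = c("cortex", "cortex")))
  s <- summarizeCompartment(constantMap(vals), rois, "cortex")
  expect_equal(s@mean, 5)
  expect_equal(s@sd, sd(rep(c(4, 6), each = 10)))
  ## mean-of-ROI-means alternative gives the same here by symmetry
  s2 <- summarizeCompartment(constantMap(vals), rois, "cortex",
                             pooling = "roi")
  expect_equal(s2@mean, 5)
})

test_that("pooled statistics equal a naive loop over labelled pixels", {
  set.seed(21)
  lab <- matrix(sample(0:5, 400, replace = TRUE), 20, 20)
  vals <- matrix(rnorm(400, 2000, 150), 20, 20)
  rois <- ROISet(lab, data.frame(
    label = 1:5,
    compartment = c("cortex", "medulla", "cortex", "medulla", "cortex")))
  s <- summarizeCompartment(constantMap(vals), rois, "cortex")
  ## oracle: loop over every pixel
  acc <- c()
  for (r in 1:20) for (cc in 1:20)
    if (lab[r, cc] %in% c(1, 3, 5)) acc <- c(acc, vals[r, cc])
  expect_equal(s@mean, mean(acc))
  expect_equal(s@sd, sd(acc))
  expect_equal(s@nPixels, length(acc))
})

test_that("the pooled mean ignores how a compartment is cut into ROIs", {
  set.seed(5)
  vals <- matrix(rnorm(100, 1500, 100), 10, 10)
  region <- matrix(FALSE, 10, 10); region[3:8, 3:8] <- TRUE
  lab1 <- matrix(0L, 10, 10); lab1[region] <- 1L
  lab2 <- matrix(0L, 10, 10)
  lab2[region] <- ifelse(col(lab2)[region] <= 5, 1L, 2L)
  s1 <- summarizeCompartment(constantMap(vals),
                             ROISet(lab1, data.frame(label = 1L,
                                                     compartment = "cortex")),
                             "cortex")
  s2 <- summarizeCompartment(constantMap(vals),
                             ROISet(lab2, data.frame(label = 1:2,
                                                     compartment = rep("cortex", 2))),
                             "cortex")
  expect_equal(s1@mean, s2@mean)
  expect_equal(s1@sd, s2@sd)
})

test_that("the delta index is the cortex - medulla difference and antisymmetric", {
  lab <- matrix(0L, 6, 6); lab[2:3, 2:3] <- 1L; lab[4:5, 4:5] <- 2L
  vals <- matrix(0, 6, 6); vals[lab == 1L] <- 1800; vals[lab == 2L] <- 2000
  m <- constantMap(vals)
  rois <- ROISet(lab, data.frame(label = 1:2,
                                 compartment = c("cortex", "medulla")))
  cx <- summarizeCompartment(m, rois, "cortex")
  md <- summarizeCompartment(m, rois, "medulla")
  expect_equal(deltaValue(deltaIndex(cx, md)), -200)
  ## swapping the compartment assignment flips the sign
  roisSwap <- ROISet(lab, data.frame(label = 1:2,
                                     compartment = c("medulla", "cortex")))
  cx2 <- summarizeCompartment(m, roisSwap, "cortex")
  md2 <- summarizeCompartment(m, roisSwap, "medulla")
  expect_equal(deltaValue(deltaIndex(cx2, md2)), 200)
  ## identical compartments give zero
  expect_equal(deltaValue(deltaIndex(cx, {
    md0 <- md; md0@mean <- cx@mean; md0
  })), 0)
})

test_that("unit mismatches and empty compartments are rejected with clear errors", {
  lab <- matrix(0L, 4, 4); lab[2, 2] <- 1L; lab[3, 3] <- 2L
  m <- constantMap(matrix(1, 4, 4))
  rois <- ROISet(lab, data.frame(label = 1:2,
                                 compartment = c("cortex", "medulla")))
  cx <- summarizeCompartment(m, rois, "cortex")
  md <- summarizeCompartment(constantMap(matrix(1, 4, 4), units = "ms"),
                             rois, "medulla")
  expect_error(deltaIndex(cx, md), "units mismatch")
  onlyCortex <- ROISet(lab, data.frame(label = 1:2,
                                       compartment = rep("cortex", 2)))
  expect_error(summarizeCompartment(m, onlyCortex, "medulla"),
               "empty compartment 'medulla'")
})

test_that("invalid pixels are excluded with a warning above 20%", {
  lab <- matrix(0L, 6, 6); lab[2:5, 2:5] <- 1L
  v <- array(3, c(6, 6, 1)); msk <- array(TRUE, c(6, 6, 1))
  msk[2:5, 2:3, 1] <- FALSE                      # half the ROI invalid
  v[!msk] <- NA_real_
  m <- new("ParametricMap", values = v, mask = msk, units = "ms",
           rss = array(0, dim(v)), flags = array(0L, dim(v)))
  rois <- ROISet(lab, data.frame(label = 1L, compartment = "cortex"))
  expect_warning(s <- summarizeCompartment(m, rois, "cortex"), "excluded")
  expect_equal(s@nPixels, 8L)
  expect_equal(s@mean, 3)
})

test_that("the fitted delta on a noiseless phantom equals the generated difference", {
  ph <- makeNoiselessPhantoms()
  fit <- fitADCMap(ph$dwi$series, ph$dwi$labels > 0)
  rois <- genROISet(ph$dwi$labels, seed = 2)
  cx <- summarizeCompartment(fit$adc, rois, "cortex")
  md <- summarizeCompartment(fit$adc, rois, "medulla")
  expect_lt(abs(deltaValue(deltaIndex(cx, md)) - (-200)) / 200, 0.001)
})
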