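# Grey-standard gains, ruler rescaling, quantum catches and the
# RGB-to-cone polynomial mapping.

# A minimal hand-built scene: uniform image with a grey patch and a ruler.
toyScene <- function(grey = c(0.3, 0.24, 0.18), rulerPx = 80, n = 300) {
  img <- array(0.5, c(n, n, 3))
  gm <- matrix(FALSE, n, n); gm[10:29, 10:29] <- TRUE
  for (ch in 1:3) img[, , ch][gm] <- grey[ch]
  rm_ <- matrix(FALSE, n, n)
  rm_[n - 20 + seq_len(5), 10 + seq_len(rulerPx) - 1] <- TRUE
  e <- lapply(1:3, function(k) {
    m <- matrix(FALSE, n, n); m[100 + 10 * k, 150] <- TRUE; m
  })
  excl <- ovicrypt:::dilateMask(e[[1]] | e[[2]] | e[[3]], 5) |
    ovicrypt:::dilateMask(rm_, 5) | ovicrypt:::dilateMask(gm, 5)
  masks <- new("MaskSet", eggMasks = e, rulerMask = rm_, greyMask = gm,
               exclusionMask = excl, shape = as.integer(c(n, n)))
  new("NestScene", image = img, masks = masks, nestId = "toy",
      habitat = "beach", scalePxPerMm = NA_real_,
      calibrationGains = numeric(0), groundTruth = list())
}

test_that("grey calibration applies target/mean gains per channel and is idempotent", {
  sc <- toyScene(grey = c(0.30, 0.24, 0.18))
  cal <- greyCalibrate(sc, greyTarget = 0.2)
  expect_equal(cal@calibrationGains, c(2 / 3, 5 / 6, 10 / 9),
               tolerance = 1e-12)
  for (ch in 1:3)
    expect_equal(mean(sceneImage(cal)[, , ch][greyMask(cal)]), 0.2,
                 tolerance = 1e-12)
  twice <- greyCalibrate(cal, greyTarget = 0.2)
  expect_equal(twice@calibrationGains, c(1, 1, 1), tolerance = 1e-9)
  expect_equal(sceneImage(twice), sceneImage(cal), tolerance = 1e-12)
})

test_that("an already-calibrated image gets unit gains; a dead channel errors", {
  sc <- toyScene(grey = c(0.2, 0.2, 0.2))
  cal <- greyCalibrate(sc)
  expect_equal(cal@calibrationGains, c(1, 1, 1))
  expect_equal(sceneImage(cal), sceneImage(sc))
  dead <- toyScene(grey = c(0.2, 0.2, 0))
  expect_error(greyCalibrate(dead), "saturation-or-underexposure")
})

test_that("ruler-based rescaling reaches the target extent and keeps masks boolean", {
  # ruler of 84 px for 40 mm: 2.1 px/mm, 5% above a 2 px/mm target
  sc <- toyScene(rulerPx = 84)
  out <- rescaleToStandard(sc, rulerLengthMm = 40, targetRes = 2)
  expect_equal(ovicrypt:::maskExtent(rulerMask(out)), 80, tolerance = 2)
  expect_identical(out@scalePxPerMm, 2)
  expect_type(eggMasks(out)[[1]], "logical")
  e <- eggMasks(out)
  expect_false(any(e[[1]] & e[[2]]))
  # exact-scale input passes through untouched
  sc2 <- toyScene(rulerPx = 80)
  out2 <- rescaleToStandard(sc2, rulerLengthMm = 40, targetRes = 2)
  expect_identical(sceneImage(out2), sceneImage(sc2))
  # upscaling requires the explicit override
  sc3 <- toyScene(rulerPx = 76)
  expect_error(rescaleToStandard(sc3, rulerLengthMm = 40, targetRes = 2),
               "allowUpscale")
  ok <- rescaleToStandard(sc3, rulerLengthMm = 40, targetRes = 2,
                          allowUpscale = TRUE)
  expect_equal(ovicrypt:::maskExtent(rulerMask(ok)), 80, tolerance = 2)
})

test_that("quantum catch follows the normalised illuminant-weighted sum", {
  sys <- defaultSystem()
  s <- sys@coneSets$avian$D
  ill <- sys@illuminant
  n <- length(sys@wavelengths)
  expect_equal(quantumCatch(rep(1, n), s, ill), 1)
  expect_equal(quantumCatch(rep(0.2, n), s, ill), 0.2)
  # indicator on a single band: catch is that band's normalised weight
  r <- rep(0, n); r[13] <- 1
  expect_equal(quantumCatch(r, s, ill), s[13] * ill[13] / sum(s * ill))
  # linearity in reflectance scale
  bank <- makeSpectraBank(5, sys, seed = 2)
  expect_equal(quantumCatch(0.37 * bank[3, ], s, ill),
               0.37 * quantumCatch(bank[3, ], s, ill))
  expect_error(quantumCatch(rep(1, 10), s, ill), "spectral-grid")
})

test_that("a cone identical to a camera sensor is mapped with R2 = 1", {
  sys <- defaultSystem()
  g <- sys@cameraSens[, 2]
  sys2 <- sys
  sys2@coneSets$carnivore$L <- g / max(g)
  bank <- makeSpectraBank(120, sys, seed = 3)
  m <- fitRgbToConeMap(bank, sys2)
  expect_equal(unname(m@heldoutR2$carnivore["L"]), 1, tolerance = 1e-10)
})

test_that("the quadratic mapping reaches held-out R2 > 0.99 and beats the linear fit", {
  sys <- defaultSystem()
  bank <- makeSpectraBank(200, sys, seed = 1)
  m2 <- fitRgbToConeMap(bank, sys, degree = 2)
  expect_true(all(unlist(m2@heldoutR2$avian) > 0.99))
  m1 <- fitRgbToConeMap(bank, sys, degree = 1)
  # nested-model property: the quadratic cannot fit the training data worse
  for (cone in names(m1@trainR2$avian))
    expect_lte(m1@trainR2$avian[[cone]], m2@trainR2$avian[[cone]] + 1e-12)
  # mapping consistency on the training bank itself
  expect_true(all(unlist(m2@trainR2) > 0.999))
})

test_that("applyMap yields the expected planes and matches direct integration", {
  sys <- defaultSystem()
  bank <- makeSpectraBank(200, sys, seed = 1)
  model <- fitRgbToConeMap(bank, sys)
  # constant image -> constant planes with the right channel counts
  img <- array(0.4, c(8, 8, 3))
  av <- applyMap(img, model, "avian")
  expect_named(catchPlanes(av), c("D", "L", "M", "S"))
  expect_named(catchPlanes(applyMap(img, model, "carnivore")), c("L", "S"))
  expect_named(catchPlanes(applyMap(img, model, "human")), c("X", "Y", "Z"))
  expect_equal(sd(catchPlanes(av)$D), 0)
  expect_error(applyMap(img, model, "plover"), "lookup error")
  # pixels equal to the camera response of a training spectrum map to
  # catches within 1% of that spectrum's integrated catches
  cam <- ovicrypt:::cameraResponses(bank, sys)
  i <- 17
  px <- array(rep(cam[i, ], each = 1), c(1, 1, 3))
  got <- vapply(catchPlanes(applyMap(px, model, "avian")), function(p)
    p[1, 1], 0)
  want <- vapply(sys@coneSets$avian, function(s)
    quantumCatch(bank[i, ], s, sys@illuminant), 0)
  expect_equal(got, want, tolerance = 0.01)
})

test_that("luminance planes of the three systems agree strongly on scenes", {
  tab <- smallTable()
  expect_gt(cor(tab$avian_lum, tab$carn_lum), 0.9)
  expect_gt(cor(tab$avian_lum, tab$human_L), 0.9)
  expect_gt(cor(tab$carn_lum, tab$human_L), 0.9)
})
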