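# Log-Gabor bank construction, filter energies and the texture PCA.

test_that("the default bank has 48 zero-DC filters with o1 horizontal", {
  bank <- buildBank(c(256, 256))
  expect_length(bank@filters, 48)
  expect_identical(bank@labels[1], "s1o1")
  expect_identical(bank@labels[48], "s6o8")
  expect_true(all(vapply(bank@filters, function(f) f[1, 1], 0) == 0))
  # o1 is mirror-symmetric about its wave-vector (vertical frequency) axis
  f <- bank@filters[[which(bank@labels == "s3o1")]]
  flipped <- f[, c(1, rev(seq_len(ncol(f))[-1]))]
  expect_equal(f, flipped, tolerance = 1e-10)
  expect_error(buildBank(c(64, 64)), "bank-configuration")
})

test_that("a constant image floors every feature at log(eps)", {
  bank <- buildBank(c(256, 256))
  mask <- matrix(FALSE, 256, 256); mask[100:150, 100:150] <- TRUE
  v <- filterEnergies(matrix(0.7, 256, 256), bank, mask)
  expect_equal(as.vector(v), rep(log(1e-8), 48))
})

test_that("contrast scaling shifts every feature by exactly log(k)", {
  bank <- buildBank(c(256, 256))
  set.seed(4)
  img <- matrix(runif(256^2, 0.2, 0.8), 256, 256)
  mask <- matrix(FALSE, 256, 256); mask[60:200, 60:200] <- TRUE
  v1 <- filterEnergies(img, bank, mask)
  v2 <- filterEnergies(img * 2.5, bank, mask)
  expect_equal(as.vector(v2 - v1), rep(log(2.5), 48), tolerance = 1e-8)
})

test_that("a grating peaks in its scale/orientation channel and tracks rotation", {
  bank <- buildBank(c(256, 256))
  img <- 0.5 + 0.4 * sin(2 * pi * row(matrix(0, 256, 256)) / 12)
  mask <- matrix(FALSE, 256, 256); mask[96:160, 96:160] <- TRUE
  v <- filterEnergies(img, bank, mask)
  expect_identical(names(which.max(v)), "s3o1")
  v90 <- filterEnergies(t(img), bank, mask)
  expect_identical(names(which.max(v90)), "s3o5")
})

test_that("regions near the border carry a boundary note", {
  bank <- buildBank(c(256, 256))
  img <- matrix(0.5, 256, 256)
  edge <- matrix(FALSE, 256, 256); edge[1:30, 1:30] <- TRUE
  inner <- matrix(FALSE, 256, 256); inner[100:150, 100:150] <- TRUE
  expect_true(attr(filterEnergies(img, bank, edge), "boundary"))
  expect_false(attr(filterEnergies(img, bank, inner), "boundary"))
})

test_that("correlation-matrix PCA has the right spectrum and orientation", {
  set.seed(9)
  # equicorrelated 3-feature table: eigenvalues {1 + 2 rho, 1 - rho, 1 - rho}
  n <- 20000
  z <- rnorm(n)
  x <- sapply(1:3, function(i) sqrt(0.5) * z + sqrt(0.5) * rnorm(n))
  colnames(x) <- paste0("f", 1:3)
  pca <- fitPca(x)
  expect_equal(sum(pca@eigenvalues), 3, tolerance = 1e-9)
  expect_equal(pca@eigenvalues[1], 2.0, tolerance = 0.05)
  expect_true(all(colSums(pca@loadings) >= -1e-12))
  expect_gte(pca@retainedK, 1)
  # degenerate feature is named
  x2 <- cbind(x, dead = 1)
  expect_error(fitPca(x2), "dead")
})

test_that("projection reproduces the PCA identities", {
  tab <- smallTable()
  tex <- as.matrix(tab[, grep("^s[1-9]o[1-9]$", names(tab))])
  pca <- attr(tab, "pca")
  sc <- projectPca(pca, tex, k = pca@retainedK)
  # scores are uncorrelated with variances equal to the eigenvalues
  cc <- cor(sc)
  expect_true(all(abs(cc[upper.tri(cc)]) < 1e-8))
  expect_equal(unname(apply(sc, 2, var)),
               pca@eigenvalues[seq_len(pca@retainedK)], tolerance = 1e-8)
  # the feature-mean vector projects to the origin
  expect_equal(unname(drop(projectPca(pca, pca@center))),
               rep(0, pca@retainedK), tolerance = 1e-10)
})

test_that("texture features from avian and human luminance planes agree", {
  sc <- smallScenes()[[1]]
  sys <- defaultSystem()
  model <- fitRgbToConeMap(makeSpectraBank(200, sys, seed = 1), sys)
  bank <- buildBank(dim(sceneImage(sc))[1:2])
  masks <- eggMasks(sc)
  fa <- filterEnergies(catchPlanes(applyMap(sc, model, "avian"))$D, bank,
                       masks)
  fh <- filterEnergies(catchPlanes(applyMap(sc, model, "human"))$Y, bank,
                       masks)
  expect_gt(cor(as.numeric(fa), as.numeric(fh)), 0.95)
})

test_that("nearest-neighbour rescaling by 5% changes features by under 2% RMS", {
  sc <- smallScenes()[[2]]
  img <- sceneImage(sc)
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  small <- ovicrypt:::resizeNearest(lum, 1 / 1.05)
  m1 <- eggMasks(sc)[[1]]
  m2 <- ovicrypt:::resizeNearest(m1, 1 / 1.05)
  storage.mode(m2) <- "logical"
  f1 <- filterEnergies(lum, buildBank(dim(lum)), m1)
  f2 <- filterEnergies(small, buildBank(dim(small)), m2)
  rel <- (f2 - f1) / abs(f1)
  expect_lt(sqrt(mean(rel^2)), 0.02)
})
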