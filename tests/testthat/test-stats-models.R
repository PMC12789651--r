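# Mixed models, MANOVA/Pillai and the three-way analysis suite.

test_that("with no group variance the LMM reduces to the two-sample case", {
  set.seed(1)
  d <- data.frame(nest_id = rep(c("a", "b", "c", "d"), each = 5),
                  g = rep(c("x", "y"), each = 10),
                  y = rnorm(20))
  r <- suppressMessages(fitLmm(d, "y", "g"))
  ols <- mean(d$y[d$g == "y"]) - mean(d$y[d$g == "x"])
  expect_equal(r$estimate, ols, tolerance = 1e-6)
  expect_equal(r$df, 18, tolerance = 1)
})

test_that("a constant response is flagged singular with zero effect", {
  d <- data.frame(nest_id = rep(c("a", "b"), each = 10),
                  g = rep(c("x", "y"), 10), y = 1)
  r <- fitLmm(d, "y", "g")
  expect_true(r$singular)
  expect_equal(r$estimate, 0)
})

test_that("the LMM recovers a configured egg-background offset on average", {
  ests <- vapply(1:25, function(s) {
    tab <- simulateMetricTable(nNests = 30, eggOffset = -0.1, seed = s)
    suppressMessages(fitLmm(tab, "response", "object_type"))$estimate
  }, 0)
  expect_equal(mean(ests), -0.1, tolerance = 0.01)
})

test_that("LMM inference is invariant to row order and equivariant to scaling", {
  tab <- simulateMetricTable(nNests = 12, eggOffset = -0.1, seed = 3)
  r1 <- suppressMessages(fitLmm(tab, "response", "object_type"))
  perm <- tab[sample(nrow(tab)), ]
  r2 <- suppressMessages(fitLmm(perm, "response", "object_type"))
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
  tab3 <- tab; tab3$response <- 10 * tab3$response + 2
  r3 <- suppressMessages(fitLmm(tab3, "response", "object_type"))
  expect_equal(r3$estimate, 10 * r1$estimate, tolerance = 1e-5)
  expect_equal(r3$t, r1$t, tolerance = 1e-4)
})

test_that("Satterthwaite df lie between the group and residual bounds", {
  tab <- simulateMetricTable(nNests = 10, eggOffset = -0.05, nestSd = 0.08,
                             seed = 11)
  r <- suppressMessages(fitLmm(tab, "response", "object_type"))
  expect_gt(r$df, 1)
  expect_lt(r$df, nrow(tab))
})

test_that("Pillai reduces to R-squared for one response and matches the matrix oracle", {
  set.seed(2)
  d <- data.frame(g = rep(c("a", "b"), each = 10), y1 = rnorm(20))
  d$y1[d$g == "b"] <- d$y1[d$g == "b"] + 1
  mp <- manovaPillai(d, "y1", "g")
  a <- anova(lm(y1 ~ g, d))
  expect_equal(mp$pillai, a$`Sum Sq`[1] / sum(a$`Sum Sq`), tolerance = 1e-9)
  # two responses, exact separation only on response 1: brute-force SSCP
  toy <- data.frame(g = rep(c("a", "b"), each = 3),
                    y1 = c(1, 2, 3, 7, 8, 9), y2 = c(5, 6, 4, 6, 4, 5))
  mp2 <- manovaPillai(toy, c("y1", "y2"), "g")
  Y <- as.matrix(toy[, c("y1", "y2")])
  fitH <- lm(Y ~ toy$g)
  E <- crossprod(stats::residuals(fitH))
  gm <- colMeans(Y)
  H <- Reduce(`+`, lapply(split(as.data.frame(Y), toy$g), function(grp)
    nrow(grp) * tcrossprod(colMeans(grp) - gm)))
  oracle <- sum(diag(H %*% solve(H + E)))
  expect_equal(mp2$pillai, oracle, tolerance = 1e-9)
  expect_true(mp2$pillai >= 0 && mp2$pillai <= 1)
})

test_that("parametric Pillai p agrees with a permutation oracle on null data", {
  set.seed(6)
  n <- 60
  d <- data.frame(g = rep(c("a", "b"), each = n / 2),
                  y1 = rnorm(n), y2 = rnorm(n))
  obs <- manovaPillai(d, c("y1", "y2"), "g")
  perm <- vapply(1:500, function(i) {
    d2 <- d; d2$g <- sample(d2$g)
    manovaPillai(d2, c("y1", "y2"), "g")$pillai
  }, 0)
  permP <- mean(perm >= obs$pillai)
  expect_equal(permP, obs$p, tolerance = 0.05)
})

test_that("Pillai grows with added group separation", {
  set.seed(8)
  d <- data.frame(g = rep(c("a", "b"), each = 20),
                  y1 = rnorm(40), y2 = rnorm(40))
  p0 <- manovaPillai(d, c("y1", "y2"), "g")$pillai
  d$y1[d$g == "b"] <- d$y1[d$g == "b"] + 2
  p1 <- manovaPillai(d, c("y1", "y2"), "g")$pillai
  d$y2[d$g == "b"] <- d$y2[d$g == "b"] + 2
  p2 <- manovaPillai(d, c("y1", "y2"), "g")$pillai
  expect_lt(p0, p1)
  expect_lt(p1, p2)
})

test_that("the analysis suite returns the 10-metric grid for every split", {
  tab <- midTable()
  res <- suppressWarnings(suppressMessages(runTableSuite(tab)))
  expect_identical(unique(table(res$split, res$stratum)[
    cbind(c("interaction", "habitat_within_type", "habitat_within_type",
            "type_within_habitat", "type_within_habitat"),
          c("all", "egg", "background", "beach", "saltmarsh"))]), 10L)
  expect_setequal(unique(res$metric),
                  c("avian_lum", "avian_rg", "avian_yb", "carn_lum",
                    "carn_yb", "PC1-4 joint", "PC1", "PC2", "PC3", "PC4"))
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
  # eggs do not differ between habitats by construction, backgrounds do:
  # the background habitat contrast must be overwhelmingly stronger
  lumRows <- res[res$split == "habitat_within_type" &
                   res$metric == "avian_lum", ]
  expect_lt(lumRows$p[lumRows$stratum == "background"], 0.01)
})
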