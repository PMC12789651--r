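# Leave-one-nest-out classification, confusion summaries and ROC analysis.

# Fabricated feature table under the 3:27 design: every feature is standard
# noise unless given a shift added to egg rows (optionally with a per-nest
# random component to emulate photograph-level variation).
fakeFeatureTable <- function(nNests = 10, eggShift = c(), nestSd = 0,
                             seed = 1) {
  cols <- c("avian_lum", "avian_rg", "avian_yb", "carn_lum", "carn_yb",
            "human_L", "human_a", "human_b", "PC1", "PC2", "PC3", "PC4")
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nNests), function(i) {
      d <- as.data.frame(matrix(rnorm(30 * length(cols)), 30,
                                dimnames = list(NULL, cols)))
      d <- d + matrix(rnorm(length(cols), 0, nestSd), 30, length(cols),
                      byrow = TRUE)
      ot <- c(rep("egg", 3), rep("background", 27))
      for (f in names(eggShift)) d[[f]] <- d[[f]] + eggShift[[f]] * (ot == "egg")
      cbind(nest_id = sprintf("n%02d", i),
            habitat = if (i %% 2) "beach" else "saltmarsh",
            object_type = ot, sample_index = c(1:3, 1:27), d)
    })
    do.call(rbind, rows)
  })
}

test_that("a separating feature yields perfect held-out classification", {
  tab <- fakeFeatureTable(8, eggShift = c(avian_lum = 12))
  loo <- looCrossValidate(tab, "colour_avian")
  expect_identical(nrow(loo), 240L)
  correct <- ifelse(loo$label == "egg", loo$prob > 0.5, loo$prob < 0.5)
  expect_true(all(correct))
  expect_equal(confusionSummary(loo)$accuracy, 1)
})

test_that("label-independent features give the no-information accuracy", {
  accs <- vapply(1:4, function(s) {
    tab <- fakeFeatureTable(10, seed = s)
    confusionSummary(looCrossValidate(tab, "colour_avian"))$accuracy
  }, 0)
  expect_equal(mean(accs), 0.9, tolerance = 0.03)
})

test_that("every sample is predicted exactly once, by a fit without its nest", {
  tab <- fakeFeatureTable(6, eggShift = c(PC1 = 2))
  loo <- looCrossValidate(tab, "pattern")
  expect_identical(as.integer(table(loo$nest_id)), rep(30L, 6))
  expect_identical(attr(loo, "folds"), 6L)
  # row-shuffled input gives the same predictions nest for nest
  perm <- tab[withr::with_seed(1, sample(nrow(tab))), ]
  loo2 <- looCrossValidate(perm, "pattern")
  o1 <- loo[order(loo$nest_id, loo$label, loo$prob), ]
  o2 <- loo2[order(loo2$nest_id, loo2$label, loo2$prob), ]
  expect_equal(o1$prob, o2$prob, tolerance = 1e-6)
})

test_that("confusion summaries count by hand and test against the NIR", {
  # classify-everything-as-background probabilities
  loo <- makeLoo(c(rep("egg", 3), rep("background", 27)), rep(0.01, 30))
  cs <- confusionSummary(loo)
  expect_equal(cs$accuracy, 0.9)
  expect_equal(cs$sensitivity, 0)
  expect_equal(cs$specificity, 1)
  expect_equal(cs$noInformationRate, 0.9)
  # toy hand-counted case
  loo2 <- makeLoo(c("egg", "egg", rep("background", 8)),
                  c(0.6, 0.4, rep(0.1, 8)))
  cs2 <- confusionSummary(loo2)
  expect_equal(cs2$accuracy, 0.9)
  expect_equal(cs2$sensitivity, 0.5)
  expect_equal(cs2$specificity, 1)
  # a perfect classifier at n = 900 beats the 0.9 NIR decisively
  loo3 <- makeLoo(rep(c("egg", rep("background", 9)), 90),
                  rep(c(0.99, rep(0.01, 9)), 90))
  cs3 <- confusionSummary(loo3)
  expect_equal(cs3$accuracy, 1)
  expect_lt(cs3$p, 0.001)
  expect_error(confusionSummary(makeLoo(rep("egg", 5), rep(0.5, 5))),
               "one class")
})

test_that("the ROC curve is monotone and its AUC equals pair concordance", {
  expect_equal(rocCurve(makeLoo(c("egg", "background", "background"),
                                c(0.7, 0.8, 0.2)))$auc, 0.5)
  expect_equal(rocCurve(makeLoo(c(rep("egg", 5), rep("background", 20)),
                                c(0.9, 0.8, 0.85, 0.95, 0.7,
                                  runif(20, 0, 0.6))))$auc, 1)
  withr::with_seed(7, {
    labels <- sample(c("egg", "background"), 200, replace = TRUE,
                     prob = c(0.3, 0.7))
    probs <- runif(200)
    roc <- rocCurve(makeLoo(labels, probs))
    pe <- probs[labels == "egg"]; pb <- probs[labels == "background"]
    pairs <- outer(pe, pb, function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(roc$auc, mean(pairs), tolerance = 1e-12)
    fpr <- 1 - roc$points$specificity
    o <- order(fpr, roc$points$sensitivity)
    expect_true(all(diff(roc$points$sensitivity[o]) >= -1e-12))
  })
  expect_error(rocCurve(makeLoo(rep("egg", 3), runif(3))), "ROC-undefined")
})

test_that("AUC agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(9, {
    labels <- rep(c("egg", "background"), c(30, 120))
    probs <- c(rnorm(30, 0.55, 0.25), rnorm(120, 0.45, 0.25))
    ours <- rocCurve(makeLoo(labels, probs))$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = probs, levels = c("background", "egg"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("label-permuted probabilities give a chance-level AUC", {
  withr::with_seed(12, {
    labels <- sample(rep(c("egg", "background"), c(120, 1080)))
    probs <- runif(1200)
    expect_gt(rocCurve(makeLoo(labels, probs))$auc, 0.45)
    expect_lt(rocCurve(makeLoo(labels, probs))$auc, 0.55)
  })
})

test_that("colour-only separation in the features is invisible to the pattern classifier", {
  tab <- fakeFeatureTable(10, eggShift = c(avian_lum = 4, avian_yb = 2),
                          nestSd = 0.3, seed = 2)
  colour <- rocCurve(looCrossValidate(tab, "colour_avian"))$auc
  pattern <- rocCurve(looCrossValidate(tab, "pattern"))$auc
  expect_gt(colour, 0.9)
  expect_gt(pattern, 0.35)
  expect_lt(pattern, 0.65)
})

test_that("the discrimination grid covers 7 classifiers x 2 habitats", {
  tab <- fakeFeatureTable(12, eggShift = c(PC1 = 2, PC2 = 1.5), seed = 4)
  res <- runDiscriminationSuite(tab)
  expect_identical(nrow(res$grid), 14L)
  expect_setequal(unique(res$grid$measure),
                  c("Human colour", "Avian colour", "Carnivore colour",
                    "Pattern", "Human both", "Avian both", "Carnivore both"))
  expect_setequal(unique(res$grid$habitat), c("beach", "saltmarsh"))
  expect_true(all(res$grid$accuracy >= 0 & res$grid$accuracy <= 1))
  expect_length(res$roc, 14)
})
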