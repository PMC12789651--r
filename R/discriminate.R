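# Signal-detection discriminability of eggs from backgrounds:
# leave-one-nest-out cross-validated binomial mixed-model classification,
# confusion summaries against the no-information rate, and ROC curves.

.featureSets <- list(
  colour_human = c("human_L", "human_a", "human_b"),
  colour_avian = c("avian_lum", "avian_rg", "avian_yb"),
  colour_carnivore = c("carn_lum", "carn_yb"),
  pattern = c("PC1", "PC2", "PC3", "PC4"),
  both_human = c("human_L", "human_a", "human_b",
                 "PC1", "PC2", "PC3", "PC4"),
  both_avian = c("avian_lum", "avian_rg", "avian_yb",
                 "PC1", "PC2", "PC3", "PC4"),
  both_carnivore = c("carn_lum", "carn_yb", "PC1", "PC2", "PC3", "PC4"))

#' Feature columns of a classifier specification
#' @param featureSet one of \code{"colour_human"}, \code{"colour_avian"},
#'   \code{"colour_carnivore"}, \code{"pattern"}, \code{"both_human"},
#'   \code{"both_avian"}, \code{"both_carnivore"}.
#' @return character vector of feature-table column names.
#' @export
classifierFeatures <- function(featureSet) {
  if (!featureSet %in% names(.featureSets))
    stop("unknown feature set: ", featureSet)
  .featureSets[[featureSet]]
}

# Ridge-stabilised logistic regression (IRLS; penalty on slopes only).
ridgeLogistic <- function(X, y, lambda = 1e-4, maxit = 100) {
  p <- ncol(X)
  D <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- drop(solve(crossprod(X, X * w) + D, crossprod(X, w * z)))
    if (max(abs(new - beta)) < 1e-10) { beta <- new; break }
    beta <- new
  }
  beta
}

#' Leave-one-nest-out cross-validated classification
#'
#' For every nest, a binomial (logistic) mixed model with a per-nest random
#' intercept is fitted on the data of all other nests, and the held-out
#' nest's 30 samples are predicted with the population-level linear
#' predictor (random intercept at its zero mean: the held-out nest is an
#' unseen group). Features are standardised on each training fold. A fold
#' whose mixed fit fails or separates (runaway slopes) is refitted with a
#' ridge-stabilised plain logistic regression (penalty 1e-4 on slopes) and
#' flagged.
#'
#' @param table feature table (needs \code{nest_id}, \code{object_type} and
#'   the spec's feature columns).
#' @param featureSet classifier specification, see
#'   \code{\link{classifierFeatures}}.
#' @param useRandomIntercept set FALSE to force plain (ridge) logistic fits
#'   everywhere; results are then flagged throughout.
#' @return data.frame of class \code{"LOOResult"}: one row per sample with
#'   \code{nest_id}, \code{label} (egg/background), \code{prob} (predicted
#'   probability of egg). Attributes: \code{folds} (nest count),
#'   \code{flagged} (nests refitted with the ridge fallback).
#' @export
looCrossValidate <- function(table, featureSet, useRandomIntercept = TRUE) {
  feats <- classifierFeatures(featureSet)
  miss <- setdiff(feats, names(table))
  if (length(miss)) stop("feature table lacks columns: ",
                         paste(miss, collapse = ", "))
  nests <- sort(unique(table$nest_id))
  if (length(nests) < 5) stop("need at least 5 nests for leave-one-out")
  X <- as.matrix(table[, feats, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite feature values")
  y <- as.integer(table$object_type == "egg")
  out <- vector("list", length(nests))
  flagged <- character(0)
  for (i in seq_along(nests)) {
    hold <- table$nest_id == nests[i]
    ctr <- colMeans(X[!hold, , drop = FALSE])
    scl <- apply(X[!hold, , drop = FALSE], 2, stats::sd)
    scl[scl < 1e-12] <- 1
    Ztr <- sweep(sweep(X[!hold, , drop = FALSE], 2, ctr), 2, scl, "/")
    Zte <- sweep(sweep(X[hold, , drop = FALSE], 2, ctr), 2, scl, "/")
    dtr <- data.frame(y = y[!hold], Ztr, nest_id = table$nest_id[!hold])
    prob <- NULL
    if (useRandomIntercept) {
      f <- stats::as.formula(paste("y ~", paste(colnames(Ztr),
                                                collapse = " + "),
                                   "+ (1 | nest_id)"))
      fit <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::glmer(f, data = dtr, family = stats::binomial, nAGQ = 0L))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        fe <- lme4::fixef(fit)
        if (all(is.finite(fe)) && max(abs(fe[-1])) < 25) {
          prob <- 1 / (1 + exp(-(fe[1] + drop(Zte %*% fe[-1]))))
        }
      }
    }
    if (is.null(prob)) {
      flagged <- c(flagged, nests[i])
      beta <- ridgeLogistic(cbind(1, Ztr), y[!hold])
      prob <- 1 / (1 + exp(-(drop(cbind(1, Zte) %*% beta))))
    }
    out[[i]] <- data.frame(nest_id = nests[i],
                           label = table$object_type[hold],
                           prob = pmin(1 - 1e-9, pmax(1e-9, prob)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "folds") <- length(nests)
  attr(res, "flagged") <- flagged
  attr(res, "featureSet") <- featureSet
  class(res) <- c("LOOResult", "data.frame")
  res
}

#' Confusion summary against the no-information rate
#'
#' Thresholds the cross-validated probabilities at 0.5 and reports
#' accuracy, sensitivity (eggs called eggs), specificity (backgrounds
#' called backgrounds), the no-information rate (majority-class proportion;
#' 0.9 under the 3-eggs-to-27-backgrounds design) and the one-sided exact
#' binomial p value for accuracy exceeding the NIR.
#'
#' @param loo a \code{\link{looCrossValidate}} result.
#' @param threshold probability threshold (0.5).
#' @param nir no-information rate; by default the majority-class proportion
#'   of the evaluated table.
#' @return data.frame: \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{noInformationRate}, \code{p}.
#' @export
confusionSummary <- function(loo, threshold = 0.5, nir = NULL) {
  if (!nrow(loo)) stop("empty LOO result")
  isEgg <- loo$label == "egg"
  if (all(isEgg) || !any(isEgg))
    stop("undefined sensitivity error: only one class present")
  pred <- loo$prob > threshold
  correct <- sum(pred == isEgg)
  n <- nrow(loo)
  if (is.null(nir)) nir <- max(mean(isEgg), 1 - mean(isEgg))
  p <- stats::binom.test(correct, n, p = nir,
                         alternative = "greater")$p.value
  data.frame(accuracy = correct / n,
             sensitivity = mean(pred[isEgg]),
             specificity = mean(!pred[!isEgg]),
             noInformationRate = nir,
             p = p)
}

#' Empirical ROC curve and AUC
#'
#' Sensitivity/specificity over all distinct probability thresholds; the
#' trapezoidal area under the curve equals the Mann-Whitney concordance
#' probability (a random egg outranking a random background sample).
#'
#' @param loo a \code{\link{looCrossValidate}} result (or any data.frame
#'   with \code{label} and \code{prob}).
#' @return list of class \code{"ROCCurve"}: \code{points} (data.frame
#'   threshold, sensitivity, specificity) and \code{auc}.
#' @export
rocCurve <- function(loo) {
  isEgg <- loo$label == "egg"
  if (all(isEgg) || !any(isEgg))
    stop("ROC-undefined error: only one class present")
  cuts <- c(-Inf, sort(unique(loo$prob)))
  sens <- vapply(cuts, function(t) mean(loo$prob[isEgg] > t), 0)
  spec <- vapply(cuts, function(t) mean(loo$prob[!isEgg] <= t), 0)
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  auc <- min(1, max(0, auc))
  structure(list(points = data.frame(threshold = cuts, sensitivity = sens,
                                     specificity = spec),
                 auc = auc),
            class = "ROCCurve")
}

#' Full discrimination grid: 7 classifiers x 2 habitats
#'
#' Runs leave-one-nest-out classification for the seven classifier
#' specifications (human/avian/carnivore colour, pattern, and colour +
#' pattern per system) separately per habitat, and returns the confusion
#' summaries and ROC curves.
#'
#' @param table feature table with both habitats.
#' @param featureSets classifier specs to run (default all seven).
#' @param ... passed to \code{\link{looCrossValidate}}.
#' @return list: \code{grid} (data.frame measure, habitat, accuracy, p,
#'   sensitivity, specificity, auc), \code{roc} (named list of
#'   \code{ROCCurve}), \code{loo} (named list of LOO results).
#' @export
runDiscriminationSuite <- function(table, featureSets = names(.featureSets),
                                   ...) {
  habs <- sort(unique(table$habitat))
  if (length(habs) < 2)
    stop("stratum error: both habitats required")
  labels <- c(colour_human = "Human colour", colour_avian = "Avian colour",
              colour_carnivore = "Carnivore colour", pattern = "Pattern",
              both_human = "Human both", both_avian = "Avian both",
              both_carnivore = "Carnivore both")
  rows <- list(); rocs <- list(); loos <- list()
  for (fs in featureSets) for (hab in habs) {
    d <- table[table$habitat == hab, , drop = FALSE]
    loo <- looCrossValidate(d, fs, ...)
    cs <- confusionSummary(loo)
    roc <- rocCurve(loo)
    key <- paste(fs, hab, sep = ".")
    rocs[[key]] <- roc
    loos[[key]] <- loo
    rows[[key]] <- data.frame(measure = unname(labels[fs]), habitat = hab,
                              accuracy = cs$accuracy, p = cs$p,
                              sensitivity = cs$sensitivity,
                              specificity = cs$specificity, auc = roc$auc,
                              stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  list(grid = grid, roc = rocs, loo = loos)
}
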