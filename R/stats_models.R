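# Mean-difference inference: linear mixed models with a per-photograph
# (nest) random intercept and Satterthwaite t-tests, plus MANOVA with
# Pillai's trace for the joint texture principal components.

#' Linear mixed model with nest random intercept
#'
#' REML fit of \code{response ~ fixed + (1 | group)} with Satterthwaite
#' degrees of freedom for the fixed-effect t-tests. With
#' \code{standardize = TRUE} the response is z-scored over the analysed
#' rows first, so a two-level factor's coefficient is the difference in
#' standardised means (negative: lower value for the first level's
#' complement, e.g. egg below background).
#'
#' A constant response (or otherwise singular fit) is returned with the
#' random-effect variance pinned at zero and flagged \code{singular}; the
#' t-test then degenerates to the fixed-effects-only test.
#'
#' @param table data.frame of samples.
#' @param response response column name.
#' @param fixed right-hand-side formula text, e.g. \code{"object_type"} or
#'   \code{"object_type * habitat"}.
#' @param group grouping column for the random intercept.
#' @param standardize z-score the response before fitting.
#' @return data.frame, one row per fixed-effect term (intercept excluded):
#'   \code{term}, \code{estimate}, \code{se}, \code{t}, \code{df} (
#'   Satterthwaite), \code{p}, variance components \code{varGroup},
#'   \code{varResidual}, and \code{singular}.
#' @export
fitLmm <- function(table, response, fixed, group = "nest_id",
                   standardize = FALSE) {
  y <- table[[response]]
  if (!all(is.finite(y))) stop("response contains non-finite values")
  if (length(unique(table[[group]])) < 2)
    stop("need at least 2 groups for a random intercept")
  dat <- table
  if (stats::sd(y) < 1e-12) {
    # constant response: no information; report zero effects, flag singular
    tt <- attr(stats::terms(stats::reformulate(fixed)), "term.labels")
    return(data.frame(term = tt, estimate = 0, se = NA_real_, t = NA_real_,
                      df = NA_real_, p = NA_real_, varGroup = 0,
                      varResidual = 0, singular = TRUE))
  }
  if (standardize) dat[[response]] <- as.numeric(scale(y))
  f <- stats::as.formula(paste0("`", response, "` ~ ", fixed,
                                " + (1 | ", group, ")"))
  fit <- suppressMessages(lmerTest::lmer(f, data = dat, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  cf <- stats::coef(summary(fit, ddf = "Satterthwaite"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  keep <- rownames(cf) != "(Intercept)"
  data.frame(term = rownames(cf)[keep],
             estimate = cf[keep, "Estimate"],
             se = cf[keep, "Std. Error"],
             t = cf[keep, "t value"],
             df = cf[keep, "df"],
             p = cf[keep, "Pr(>|t|)"],
             varGroup = vc$vcov[vc$grp == group][1],
             varResidual = vc$vcov[vc$grp == "Residual"][1],
             singular = singular,
             row.names = NULL)
}

#' MANOVA with Pillai's trace
#'
#' Multivariate analysis of variance over joint responses (the texture
#' principal components), reporting Pillai's trace — the multivariate
#' effect size analogous to R-squared, trace(H (H + E)^-1) — with its
#' standard approximate F transformation and p value. Two modes: raw
#' per-sample rows, or nest means (one multivariate observation per nest),
#' selected to match the structure of the question being asked.
#'
#' @param table data.frame.
#' @param responses character vector of response columns (e.g. PC1-PC4).
#' @param predictor right-hand-side formula text (a factor or interaction).
#' @param level \code{"sample"} (raw rows) or \code{"nest"} (nest means).
#' @param term which term's row to report (default: last, i.e. the
#'   highest-order term of \code{predictor}).
#' @param group nest column used for \code{level = "nest"} aggregation.
#' @return data.frame: \code{term}, \code{pillai}, \code{approxF},
#'   \code{dfNum}, \code{dfDen}, \code{p}.
#' @export
manovaPillai <- function(table, responses, predictor,
                         level = c("sample", "nest"), term = NULL,
                         group = "nest_id") {
  level <- match.arg(level)
  dat <- table
  if (level == "nest") {
    vars <- all.vars(stats::reformulate(predictor))
    agg <- stats::aggregate(dat[responses],
                            by = dat[unique(c(group, vars))], FUN = mean)
    dat <- agg
  }
  if (length(responses) == 1) {
    # univariate reduction: Pillai is the ANOVA R-squared
    f <- stats::as.formula(paste0(responses, " ~ ", predictor))
    a <- stats::anova(stats::lm(f, data = dat))
    rows <- rownames(a)[rownames(a) != "Residuals"]
    if (is.null(term)) term <- rows[length(rows)]
    ss <- a[term, "Sum Sq"]
    return(data.frame(term = term,
                      pillai = ss / (ss + a["Residuals", "Sum Sq"]),
                      approxF = a[term, "F value"],
                      dfNum = a[term, "Df"],
                      dfDen = a["Residuals", "Df"],
                      p = a[term, "Pr(>F)"]))
  }
  f <- stats::as.formula(paste0(
    "cbind(", paste(responses, collapse = ", "), ") ~ ", predictor))
  m <- stats::manova(f, data = dat)
  s <- summary(m, test = "Pillai")$stats
  rows <- rownames(s)[rownames(s) != "Residuals"]
  if (is.null(term)) term <- rows[length(rows)]
  st <- s[term, ]
  data.frame(term = term, pillai = unname(st["Pillai"]),
             approxF = unname(st["approx F"]),
             dfNum = unname(st["num Df"]), dfDen = unname(st["den Df"]),
             p = unname(st["Pr(>F)"]))
}

.colourMetrics <- c("avian_lum", "avian_rg", "avian_yb", "carn_lum",
                    "carn_yb")
.pcMetrics <- c("PC1", "PC2", "PC3", "PC4")

# One 10-metric result block: LMMs per metric + joint MANOVA over the PCs.
metricBlock <- function(dat, fixed, termName, manovaLevel, standardize) {
  lmmRows <- lapply(c(.colourMetrics, .pcMetrics), function(mcol) {
    r <- fitLmm(dat, mcol, fixed, standardize = standardize)
    sel <- r[r$term == termName, , drop = FALSE]
    r <- if (nrow(sel)) sel else r[nrow(r), , drop = FALSE]
    data.frame(metric = mcol, effect = r$estimate, statistic = abs(r$t),
               df = format(round(r$df)), p = r$p, stringsAsFactors = FALSE)
  })
  mv <- manovaPillai(dat, .pcMetrics, fixed, level = manovaLevel)
  mvRow <- data.frame(metric = "PC1-4 joint", effect = mv$pillai,
                      statistic = mv$approxF,
                      df = paste(mv$dfNum, round(mv$dfDen), sep = ", "),
                      p = mv$p, stringsAsFactors = FALSE)
  out <- do.call(rbind, c(lmmRows[1:5], list(mvRow), lmmRows[6:9]))
  rownames(out) <- NULL
  out
}

#' Run the three mean-difference analysis splits
#'
#' Reproduces the standard result grid over 10 metrics (5 colour metrics:
#' avian luminance/RG/YB, carnivore luminance/YB; texture PC1-PC4 jointly by
#' MANOVA and individually by LMM) for three complementary splits of the
#' egg/background x beach/saltmarsh design:
#' \enumerate{
#'   \item \code{interaction}: object type x location interaction on all
#'     data (sample-level MANOVA);
#'   \item \code{habitat_within_type}: beach vs salt marsh separately for
#'     eggs and for backgrounds (nest-level MANOVA: one mean per nest);
#'   \item \code{type_within_habitat}: egg vs background separately per
#'     habitat, with standardised effect sizes (difference in standardised
#'     means; negative = egg below background).
#' }
#'
#' @param table a feature table from \code{\link{buildFeatureTable}} with
#'   both habitats and both object types.
#' @return data.frame with columns \code{split}, \code{stratum},
#'   \code{metric}, \code{effect}, \code{statistic}, \code{df}, \code{p}.
#' @export
runTableSuite <- function(table) {
  need <- c("object_type", "habitat", .colourMetrics, .pcMetrics)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("feature table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (length(unique(table$habitat)) < 2 ||
      length(unique(table$object_type)) < 2)
    stop("stratum error: both habitats and both object types required")
  table$object_type <- factor(table$object_type,
                              levels = c("background", "egg"))
  table$habitat <- factor(table$habitat, levels = c("beach", "saltmarsh"))
  out <- list()
  b <- metricBlock(table, "object_type * habitat",
                   "object_typeegg:habitatsaltmarsh", "sample",
                   standardize = FALSE)
  out[[1]] <- cbind(split = "interaction", stratum = "all", b)
  for (ot in c("egg", "background")) {
    d <- table[table$object_type == ot, , drop = FALSE]
    b <- metricBlock(d, "habitat", "habitatsaltmarsh", "nest",
                     standardize = FALSE)
    out[[length(out) + 1]] <- cbind(split = "habitat_within_type",
                                    stratum = ot, b)
  }
  for (hab in c("beach", "saltmarsh")) {
    d <- table[table$habitat == hab, , drop = FALSE]
    b <- metricBlock(d, "object_type", "object_typeegg", "sample",
                     standardize = TRUE)
    out[[length(out) + 1]] <- cbind(split = "type_within_habitat",
                                    stratum = hab, b)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a feature-style metric table (no images)
#'
#' Direct numerical generator of a 30-rows-per-nest response table under
#' the study design (3 eggs + 27 background samples per nest, two
#' habitats), used to check parameter recovery and test calibration of the
#' mixed-model machinery against known truth. The response is
#' \deqn{y = \mu + \delta_{egg} 1[egg] + \beta_{bg} 1[bg, marsh] +
#'       \beta_{egg} 1[egg, marsh] + u_{nest} + \epsilon}
#' with \code{u ~ N(0, nestSd^2)} and \code{eps ~ N(0, residSd^2)}.
#'
#' @param nNests total nests (split evenly between habitats by default).
#' @param nBeach optional explicit beach count.
#' @param eggOffset egg-minus-background mean difference.
#' @param bgHabitatEffect,eggHabitatEffect salt-marsh shifts for background
#'   and egg samples.
#' @param nestSd,residSd photograph-level and residual standard deviations.
#' @param mu grand mean.
#' @param seed integer seed.
#' @return data.frame with \code{nest_id}, \code{habitat},
#'   \code{object_type}, \code{response}.
#' @export
simulateMetricTable <- function(nNests = 30, nBeach = NULL, eggOffset = -0.1,
                                bgHabitatEffect = 0, eggHabitatEffect = 0,
                                nestSd = 0.05, residSd = 0.05, mu = 0.5,
                                seed = 1) {
  if (is.null(nBeach)) nBeach <- floor(nNests / 2)
  withSeed(seed, {
    rows <- lapply(seq_len(nNests), function(i) {
      hab <- if (i <= nBeach) "beach" else "saltmarsh"
      u <- rnorm(1, 0, nestSd)
      ot <- c(rep("egg", 3), rep("background", 27))
      marsh <- hab == "saltmarsh"
      mean_ <- mu + eggOffset * (ot == "egg") +
        bgHabitatEffect * (ot == "background") * marsh +
        eggHabitatEffect * (ot == "egg") * marsh
      data.frame(nest_id = sprintf("n%03d", i), habitat = hab,
                 object_type = ot,
                 response = mean_ + u + rnorm(30, 0, residSd),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
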