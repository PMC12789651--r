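# Randomised egg-shaped background sampling and assembly of the
# 30-row-per-scene feature table (3 eggs + 27 background samples per nest).

#' Plan egg-shaped background samples for a scene
#'
#' One egg is chosen uniformly at random as the template; its mask is then
#' translated (orientation preserved, no rotation) to n positions drawn
#' uniformly over the valid-offset set by rejection sampling from the
#' bounding rectangle. A placement is valid when the translated mask lies
#' fully inside the image and does not touch the exclusion mask (eggs, nest
#' scrape margin, ruler, chart). Samples may overlap each other: with 27
#' egg-areas on a bounded scene mutual exclusion can be infeasible, and only
#' exclusion-zone avoidance is required.
#'
#' @param scene a \code{\linkS4class{NestScene}}.
#' @param n number of background samples (27 by default).
#' @param seed integer seed; same seed, same plan.
#' @param budget total rejection-draw budget before an infeasibility error.
#' @return list of class \code{"SamplePlan"}: \code{sceneId},
#'   \code{templateEggIndex} (1-3), \code{placements} (n x 2 matrix of
#'   top-left (row, col) positions of the translated template bounding box),
#'   \code{seed}.
#' @export
planBackgroundSamples <- function(scene, n = 27, seed = 1, budget = 1e5) {
  ms <- maskSet(scene)
  excl <- ms@exclusionMask
  sh <- ms@shape
  withSeed(seed, {
    tpl <- sample.int(3L, 1L)
    m <- ms@eggMasks[[tpl]]
    rs <- range(row(m)[m]); cs <- range(col(m)[m])
    h <- rs[2] - rs[1] + 1L; w <- cs[2] - cs[1] + 1L
    sub <- m[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE]
    relR <- row(sub)[sub] - 1L; relC <- col(sub)[sub] - 1L
    area <- length(relR)
    if (n > 0 && sum(!excl) < n * area)
      stop("infeasible-scene error: background area (", sum(!excl),
           " px) cannot hold ", n, " egg-shaped samples of ", area, " px")
    placements <- matrix(NA_integer_, n, 2,
                         dimnames = list(NULL, c("row", "col")))
    got <- 0L; tries <- 0L
    while (got < n) {
      if (tries >= budget)
        stop("infeasible-scene error: rejection budget (", budget,
             " draws) exhausted after ", got, " of ", n, " placements")
      tries <- tries + 1L
      r0 <- sample.int(sh[1] - h + 1L, 1L)
      c0 <- sample.int(sh[2] - w + 1L, 1L)
      if (any(excl[cbind(r0 + relR, c0 + relC)])) next
      got <- got + 1L
      placements[got, ] <- c(r0, c0)
    }
    structure(list(sceneId = nestId(scene), templateEggIndex = tpl,
                   placements = placements, seed = seed),
              class = "SamplePlan")
  })
}

# Materialise a plan's k-th sample as a logical mask.
sampleMask <- function(scene, plan, k) {
  ms <- maskSet(scene)
  m <- ms@eggMasks[[plan$templateEggIndex]]
  rs <- range(row(m)[m]); cs <- range(col(m)[m])
  sub <- m[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE]
  out <- matrix(FALSE, ms@shape[1], ms@shape[2])
  r0 <- plan$placements[k, 1]; c0 <- plan$placements[k, 2]
  out[r0 + seq_len(nrow(sub)) - 1L, c0 + seq_len(ncol(sub)) - 1L] <- sub
  out
}

# All 30 region masks of a scene in table order: eggs 1-3 then samples 1-27.
sceneRegionMasks <- function(scene, plan) {
  c(eggMasks(scene),
    lapply(seq_len(nrow(plan$placements)), function(k)
      sampleMask(scene, plan, k)))
}

#' Colour + texture feature rows for one scene
#'
#' Computes the three cone-catch images (avian, carnivore, human/XYZ), the
#' shared texture features from the avian double-cone luminance plane, and
#' returns the scene's 30 rows (3 egg + n background) of colour and texture
#' features.
#'
#' @param scene a calibrated \code{\linkS4class{NestScene}}.
#' @param model a \code{\linkS4class{MappingModel}}.
#' @param bank a \code{\linkS4class{GaborBank}} matching the scene shape.
#' @param plan a \code{\link{planBackgroundSamples}} plan for this scene.
#' @return data.frame of 3 + n rows.
#' @export
sceneFeatures <- function(scene, model, bank, plan) {
  masks <- sceneRegionMasks(scene, plan)
  nBg <- nrow(plan$placements)
  avian <- applyMap(scene, model, "avian")
  carn <- applyMap(scene, model, "carnivore")
  human <- applyMap(scene, model, "human")
  colourRows <- do.call(rbind, lapply(masks, function(m) {
    a <- regionColour(avian, m)
    cv <- regionColour(carn, m)
    h <- regionColour(human, m)
    data.frame(avian_lum = a$luminance, avian_rg = a$rg, avian_yb = a$yb,
               carn_lum = cv$luminance, carn_yb = cv$yb,
               human_L = h$L, human_a = h$a, human_b = h$b)
  }))
  tex <- filterEnergies(avian@planes$D, bank, masks)
  data.frame(
    nest_id = nestId(scene), habitat = habitat(scene),
    object_type = c(rep("egg", 3), rep("background", nBg)),
    sample_index = c(1:3, seq_len(nBg)),
    colourRows, as.data.frame(tex),
    boundary = attr(tex, "boundary"),
    stringsAsFactors = FALSE)
}

#' Build the pooled feature table for a set of scenes
#'
#' Runs background-sample planning and feature extraction for every scene,
#' pools the rows (30 per scene), fits one correlation-matrix PCA on the
#' pooled 48 texture features across all scenes and both habitats, and
#' appends PC scores (at least PC1-PC4; more if more components have
#' eigenvalue > 1). The fitted \code{\linkS4class{TexturePCA}},
#' \code{\linkS4class{MappingModel}} and per-scene plans are attached as
#' attributes \code{"pca"}, \code{"model"} and \code{"plans"}.
#'
#' @param scenes list of calibrated \code{\linkS4class{NestScene}}s.
#' @param system a \code{\linkS4class{SpectralSystem}}.
#' @param model optional prefitted \code{\linkS4class{MappingModel}};
#'   fitted from a default synthetic spectra bank when NULL.
#' @param seed integer seed driving per-scene sample plans (scene-level
#'   child seeds derive from it and the nest id, so results do not depend on
#'   processing order).
#' @param nBackground background samples per scene (27).
#' @param bankArgs extra arguments for \code{\link{buildBank}}.
#' @return data.frame with 30 rows per scene.
#' @export
buildFeatureTable <- function(scenes, system = spectralSystem(),
                              model = NULL, seed = 1, nBackground = 27,
                              bankArgs = list()) {
  if (!length(scenes)) stop("no scenes supplied")
  if (is.null(model))
    model <- fitRgbToConeMap(makeSpectraBank(200, system, seed = 1), system)
  banks <- list()
  plans <- list()
  rows <- lapply(scenes, function(sc) {
    key <- paste(dim(sc@image)[1:2], collapse = "x")
    if (is.null(banks[[key]]))
      banks[[key]] <<- do.call(buildBank,
                               c(list(shape = dim(sc@image)[1:2]), bankArgs))
    plan <- planBackgroundSamples(sc, n = nBackground,
                                  seed = childSeed(seed, nestId(sc)))
    plans[[nestId(sc)]] <<- plan
    sceneFeatures(sc, model, banks[[key]], plan)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  texCols <- grep("^s[1-9]o[1-9]$", names(tab), value = TRUE)
  pca <- fitPca(as.matrix(tab[, texCols]))
  k <- min(max(pca@retainedK, 4L), length(texCols))
  scores <- projectPca(pca, as.matrix(tab[, texCols]), k = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  tab <- cbind(tab, as.data.frame(scores))
  attr(tab, "pca") <- pca
  attr(tab, "model") <- model
  attr(tab, "plans") <- plans
  tab
}
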