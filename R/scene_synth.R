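# Synthetic nest-scene generator.
#
# Emulates the statistical structure of calibrated nest photographs from two
# coastal habitats: fine-grained, lighter, yellower sandy beach versus
# darker, higher-contrast, coarser salt marsh with pebble-scale objects;
# three maculated ellipsoidal eggs per scene (dark spots and wispy lines on
# a lighter ground, on average darker than the beach background); and the
# grey-patch / ruler fiducials. All ground truth is recorded on the scene.

#' Habitat background parameters
#'
#' Returns the generating parameters for one habitat class. Defaults encode
#' the study conditions: the salt marsh background is darker, has higher
#' luminance variance (contrast), is coarser-grained with more and larger
#' pebbles, and is slightly more reddish-brown than the beach.
#'
#' Physical quantities are specified in mm and converted to pixels at
#' \code{pxPerMm}, so the same habitat statistics can be generated at any
#' working resolution (12 px/mm is the native analysis scale).
#'
#' @param habitat \code{"beach"} or \code{"saltmarsh"}.
#' @param pxPerMm working resolution in pixels per mm.
#' @param ... overrides for any returned field.
#' @return a list with class \code{"HabitatParams"}: \code{habitat},
#'   \code{baseLuminance}, \code{luminanceSd}, \code{grainScalePx},
#'   \code{pebbleDensity} (pebbles per 1e4 px^2),
#'   \code{pebbleRadiusPxRange}, \code{hueRgb}, \code{hueJitterSd}
#'   (log-normal between-nest colour variation applied by
#'   \code{\link{generateDataset}}), \code{pxPerMm}.
#' @export
habitatParams <- function(habitat = c("beach", "saltmarsh"), pxPerMm = 12, ...) {
  habitat <- match.arg(habitat)
  p <- if (habitat == "beach") {
    list(
      habitat = "beach",
      hueRgb = c(0.66, 0.58, 0.40),
      luminanceSd = 0.05,
      grainScalePx = max(2, 0.5 * pxPerMm),      # fine sand, ~0.5 mm grain
      pebbleDensity = 1.8 / pxPerMm^2,           # sparse shells/stones
      pebbleRadiusPxRange = c(1.2, 3.5) * pxPerMm,
      hueJitterSd = 0.12,                        # between-nest colour spread
      pxPerMm = pxPerMm
    )
  } else {
    list(
      habitat = "saltmarsh",
      hueRgb = c(0.42, 0.34, 0.26),
      luminanceSd = 0.09,
      grainScalePx = max(2, 1.6 * pxPerMm),      # coarser mud/shingle
      pebbleDensity = 12 / pxPerMm^2,
      pebbleRadiusPxRange = c(1.5, 6.0) * pxPerMm,
      hueJitterSd = 0.20,                        # marsh backgrounds vary more
      pxPerMm = pxPerMm
    )
  }
  p$baseLuminance <- mean(p$hueRgb)
  p[names(list(...))] <- list(...)
  if (p$baseLuminance - 3 * p$luminanceSd < 0 ||
      p$baseLuminance + 3 * p$luminanceSd > 1)
    stop("baseLuminance +/- 3 sd must lie within [0, 1]", call. = FALSE)
  if (p$pebbleRadiusPxRange[1] <= 0 ||
      p$pebbleRadiusPxRange[1] > p$pebbleRadiusPxRange[2])
    stop("pebble radius range must be positive with min <= max", call. = FALSE)
  structure(p, class = "HabitatParams")
}

#' Egg rendering parameters
#'
#' Defaults describe an egg ca. 33 x 22 mm (within the species' 30-36 mm
#' length range), a brownish ground colour darker than the beach background,
#' and dark maculation (small spots and wispy lines). Spot statistics are
#' free conventions: no quantitative maculation measurements exist for these
#' eggs.
#'
#' @param pxPerMm working resolution in pixels per mm.
#' @param ... overrides for any returned field.
#' @return list of class \code{"EggParams"}: \code{axesPx} (semi-major,
#'   semi-minor), \code{groundRgb}, \code{maculationRgb},
#'   \code{spotDensity} (spots per 1e3 px^2), \code{spotRadiusPxRange},
#'   \code{wispCount}, \code{orientationDeg}, \code{clutchJitterSd}
#'   (log-normal between-nest clutch lightness variation applied by
#'   \code{\link{generateDataset}}), \code{pxPerMm}.
#' @export
eggParams <- function(pxPerMm = 12, ...) {
  p <- list(
    axesPx = c(16.5, 11) * pxPerMm,
    # egg colour sits between the two habitat means (slightly closer to the
    # salt marsh), darker on average than the beach background
    groundRgb = c(0.58, 0.48, 0.37),
    maculationRgb = c(0.18, 0.14, 0.10),
    spotDensity = 100 / pxPerMm^2,               # ~0.1 spots per mm^2
    spotRadiusPxRange = c(0.3, 1.1) * pxPerMm,
    wispCount = 6L,
    orientationDeg = 0,
    clutchJitterSd = 0.08,                       # between-nest egg lightness
    pxPerMm = pxPerMm
  )
  p[names(list(...))] <- list(...)
  if (mean(p$maculationRgb) >= mean(p$groundRgb))
    stop("maculation must be darker than the egg ground colour", call. = FALSE)
  if (p$spotRadiusPxRange[2] >= p$axesPx[2])
    stop("spot radii must be smaller than the egg's semi-minor axis",
         call. = FALSE)
  structure(p, class = "EggParams")
}

#' Generate a habitat background raster
#'
#' Band-limited Gaussian luminance noise (spectrally shaped around
#' \code{grainScalePx}) modulating the mean habitat colour, plus explicit
#' pebble ellipses with independent luminance offsets. The two components
#' give independent control over overall contrast and grain.
#'
#' @param params a \code{\link{habitatParams}} list.
#' @param shape integer (rows, cols); at least 256 x 256.
#' @param seed integer seed; the output is a pure function of
#'   \code{(params, shape, seed)}.
#' @return rows x cols x 3 linear-RGB array in [0, 1].
#' @export
generateBackground <- function(params, shape, seed) {
  if (any(shape < 256))
    stop("scene shape must be at least 256 x 256 to hold the fiducials",
         call. = FALSE)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  withSeed(seed, {
    base <- params$baseLuminance
    hue <- params$hueRgb * base / mean(params$hueRgb)
    f <- matrix(1, nr, nc)
    if (params$luminanceSd > 0) {
      n <- bandNoise(nr, nc, params$grainScalePx)
      f <- 1 + n * params$luminanceSd / base
    }
    nPeb <- qpois(runif(1), params$pebbleDensity * nr * nc / 1e4)
    if (nPeb > 0) {
      rr <- runif(nPeb, 1, nr); cc <- runif(nPeb, 1, nc)
      rad <- runif(nPeb, params$pebbleRadiusPxRange[1],
                   params$pebbleRadiusPxRange[2])
      asp <- runif(nPeb, 0.55, 1)
      ang <- runif(nPeb, 0, 180)
      off <- rnorm(nPeb, 0, 2.5 * params$luminanceSd / max(base, 1e-6))
      for (i in seq_len(nPeb)) {
        m <- ellipseMask(nr, nc, rr[i], cc[i], rad[i], rad[i] * asp[i], ang[i])
        f[m] <- f[m] * (1 + off[i])
      }
    }
    img <- array(0, c(nr, nc, 3))
    for (ch in 1:3) img[, , ch] <- clip01(hue[ch] * f)
    img
  })
}

# Band-limited unit-variance noise with characteristic wavelength `grain` px.
bandNoise <- function(nr, nc, grain) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  fr <- fftFreq(nr); fc <- fftFreq(nc)
  r <- sqrt(outer(fr^2, fc^2, "+"))
  f0 <- 1 / max(grain, 2)
  H <- exp(-(log(pmax(r, 1e-9) / f0))^2 / (2 * log(2)^2))
  H[1, 1] <- 0
  n <- Re(fft(fft(w) * H, inverse = TRUE)) / (nr * nc)
  n / stats::sd(n)
}

#' Render a single maculated egg
#'
#' Draws a filled ellipse of the ground colour at the requested orientation,
#' then stamps dark spots (count drawn by quantile inversion so the
#' maculated fraction is monotone in \code{spotDensity} at a fixed seed) and
#' wispy lines rendered as persistent random-walk polylines 1-2 px wide.
#'
#' @param params an \code{\link{eggParams}} list.
#' @param seed integer seed.
#' @return list with \code{patch} (h x w x 3 array, zero outside the egg)
#'   and \code{mask} (logical h x w filled ellipse).
#' @export
renderEgg <- function(params, seed) {
  a <- params$axesPx[1]; b <- params$axesPx[2]
  th <- params$orientationDeg * pi / 180
  # bounding half-sizes of the rotated ellipse
  hc <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  hr <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  nr <- 2L * as.integer(ceiling(hr)) + 3L
  nc <- 2L * as.integer(ceiling(hc)) + 3L
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  mask <- ellipseMask(nr, nc, cr, cc, a, b, params$orientationDeg)
  patch <- array(0, c(nr, nc, 3))
  for (ch in 1:3) patch[, , ch][mask] <- params$groundRgb[ch]
  withSeed(seed, {
    idx <- which(mask)
    area <- length(idx)
    nSpots <- qpois(runif(1), params$spotDensity * area / 1e3)
    mac <- matrix(FALSE, nr, nc)
    if (nSpots > 0) {
      pick <- idx[ceiling(runif(nSpots) * area)]
      rad <- runif(nSpots, params$spotRadiusPxRange[1],
                   params$spotRadiusPxRange[2])
      pr <- (pick - 1) %% nr + 1
      pc <- (pick - 1) %/% nr + 1
      for (i in seq_len(nSpots))
        mac <- mac | ellipseMask(nr, nc, pr[i], pc[i], rad[i], rad[i])
    }
    for (w in seq_len(params$wispCount)) {
      start <- idx[ceiling(runif(1) * area)]
      r <- (start - 1) %% nr + 1
      c <- (start - 1) %/% nr + 1
      ang <- runif(1, 0, 2 * pi)
      len <- max(6, round(0.8 * b))
      wide <- runif(1) < 0.5  # width 1 or 2 px
      for (s in seq_len(len)) {
        ang <- ang + rnorm(1, 0, 0.35)
        r <- r + sin(ang); c <- c + cos(ang)
        ri <- round(r); ci <- round(c)
        if (ri < 1 || ri > nr || ci < 1 || ci > nc || !mask[ri, ci]) break
        mac[ri, ci] <- TRUE
        if (wide && ri < nr) mac[ri + 1, ci] <- TRUE
      }
    }
    mac <- mac & mask
    for (ch in 1:3) patch[, , ch][mac] <- params$maculationRgb[ch]
    list(patch = patch, mask = mask, maculation = mac)
  })
}

#' Compose a full synthetic nest scene
#'
#' Places the grey calibration patch (known reflectance, default 0.20) and a
#' 40 mm ruler segment in fixed corners, renders three non-overlapping eggs
#' near the scene centre on the supplied background, and assembles the
#' colour-keyed \code{\linkS4class{MaskSet}} with all ground truth recorded.
#'
#' @param background rows x cols x 3 linear-RGB array (see
#'   \code{\link{generateBackground}}).
#' @param eggs list of 3 \code{\link{eggParams}}.
#' @param nestId,habitatLabel scene metadata.
#' @param seed integer seed for placement, orientations and egg rendering.
#' @param pxPerMm resolution the scene is generated at.
#' @param greyReflectance grey-patch target reflectance (all channels).
#' @param eggOffset optional configured egg-minus-background offset: a
#'   scalar luminance offset or length-3 per-channel offset. Egg pixels are
#'   shifted so the difference of means (egg pixels vs background pixels)
#'   equals the configured value before any clipping.
#' @param sensorNoiseSd optional Gaussian sensor noise sd added to every
#'   channel (default 0: clean reflectance image).
#' @param maxTries placement retries per egg before a composition error.
#' @return a \code{\linkS4class{NestScene}}.
#' @export
composeScene <- function(background, eggs, nestId, habitatLabel, seed,
                         pxPerMm = 12, greyReflectance = 0.2,
                         eggOffset = NULL, sensorNoiseSd = 0,
                         maxTries = 200L) {
  nr <- dim(background)[1]; nc <- dim(background)[2]
  img <- background
  margin <- max(4L, round(0.5 * pxPerMm))

  # grey patch: fixed top-left corner
  side <- max(8L, round(12 * pxPerMm))
  gm <- matrix(FALSE, nr, nc)
  gm[margin + seq_len(side), margin + seq_len(side)] <- TRUE
  for (ch in 1:3) img[, , ch][gm] <- greyReflectance

  # ruler segment: fixed bottom-left corner, horizontal
  rlen <- round(40 * pxPerMm); rwid <- max(3L, round(2.5 * pxPerMm))
  if (margin + rlen > nc || 2 * margin + side + rwid > nr)
    stop("sized-input error: scene too small to hold the fiducials",
         call. = FALSE)
  rm_ <- matrix(FALSE, nr, nc)
  rm_[nr - margin - rwid + seq_len(rwid), margin + seq_len(rlen)] <- TRUE
  light <- (col(matrix(0, rwid, rlen)) %/% max(1, round(5 * pxPerMm))) %% 2 == 0
  for (ch in 1:3) img[, , ch][rm_] <- ifelse(light, 0.85, 0.08)

  fidExcl <- dilateMask(gm | rm_, 3)
  placed <- list()
  eggInfo <- list()
  occupied <- fidExcl
  withSeed(childSeed(seed, paste0(nestId, ":compose")), {
    for (k in 1:3) {
      ori <- runif(1, 0, 180)
      ep <- eggs[[k]]; ep$orientationDeg <- ori
      egg <- renderEgg(ep, childSeed(seed, paste0(nestId, ":egg", k)))
      eh <- dim(egg$mask)[1]; ew <- dim(egg$mask)[2]
      ok <- FALSE
      # cluster the clutch near the scene centre, like a nest scrape
      spread <- 0.22 * min(nr, nc)
      for (t in seq_len(maxTries)) {
        r0 <- round(nr / 2 + rnorm(1, 0, spread) - eh / 2)
        c0 <- round(nc / 2 + rnorm(1, 0, spread) - ew / 2)
        if (r0 < 1 || c0 < 1 || r0 + eh - 1 > nr || c0 + ew - 1 > nc) next
        sub <- occupied[r0 + seq_len(eh) - 1, c0 + seq_len(ew) - 1]
        if (any(sub & egg$mask)) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop("composition error: could not place egg ", k,
             " without colliding with ",
             if (k > 1) "another egg or a fiducial" else "a fiducial",
             call. = FALSE)
      full <- matrix(FALSE, nr, nc)
      full[r0 + seq_len(eh) - 1, c0 + seq_len(ew) - 1] <- egg$mask
      occupied <- occupied | dilateMask(full, 2)
      placed[[k]] <- full
      eggInfo[[k]] <- list(topLeft = c(r0, c0), orientationDeg = ori,
                           patch = egg$patch, mask = egg$mask)
    }
  })
  for (k in 1:3) {
    inf <- eggInfo[[k]]
    eh <- dim(inf$mask)[1]; ew <- dim(inf$mask)[2]
    rows <- inf$topLeft[1] + seq_len(eh) - 1
    cols <- inf$topLeft[2] + seq_len(ew) - 1
    for (ch in 1:3) {
      sub <- img[rows, cols, ch]
      sub[inf$mask] <- inf$patch[, , ch][inf$mask]
      img[rows, cols, ch] <- sub
    }
  }

  eggUnion <- placed[[1]] | placed[[2]] | placed[[3]]
  exclusion <- dilateMask(eggUnion, 5) | dilateMask(rm_, 5) | dilateMask(gm, 5)
  bgMask <- !exclusion

  if (!is.null(eggOffset)) {
    bgMean <- vapply(1:3, function(ch) mean(img[, , ch][bgMask]), 0)
    delta <- if (length(eggOffset) == 1) rep(eggOffset, 3) else eggOffset
    eggMean <- vapply(1:3, function(ch) mean(img[, , ch][eggUnion]), 0)
    for (ch in 1:3)
      img[, , ch][eggUnion] <- img[, , ch][eggUnion] +
        (bgMean[ch] + delta[ch] - eggMean[ch])
  }

  if (sensorNoiseSd > 0) {
    img <- img + withSeed(childSeed(seed, paste0(nestId, ":noise")),
                          array(rnorm(length(img), 0, sensorNoiseSd), dim(img)))
  }
  img <- clip01(img)

  masks <- new("MaskSet", eggMasks = placed, rulerMask = rm_, greyMask = gm,
               exclusionMask = exclusion, shape = c(nr, nc))
  new("NestScene",
      image = img, masks = masks, nestId = nestId, habitat = habitatLabel,
      scalePxPerMm = pxPerMm, calibrationGains = numeric(0),
      groundTruth = list(
        seed = seed, pxPerMm = pxPerMm, greyReflectance = greyReflectance,
        eggOffset = eggOffset, sensorNoiseSd = sensorNoiseSd,
        eggs = lapply(eggInfo, function(i) i[c("topLeft", "orientationDeg")]),
        eggParams = eggs))
}

#' Generate a synthetic dataset of nest scenes
#'
#' Produces \code{nBeach + nSaltmarsh} scenes with per-scene seeds derived
#' deterministically from the global seed, under the default habitat and egg
#' parameters (overridable). The study design this emulates had 28 beach and
#' 60 salt-marsh nests.
#'
#' @param nBeach,nSaltmarsh scene counts per habitat (default 28 and 60).
#' @param seed global integer seed.
#' @param pxPerMm working resolution; scene size is chosen automatically so
#'   that the background can hold 27 egg-shaped samples, unless overridden.
#' @param shape optional explicit (rows, cols).
#' @param beach,saltmarsh optional \code{\link{habitatParams}} overrides.
#' @param eggs optional list of 3 \code{\link{eggParams}}.
#' @param ... passed to \code{\link{composeScene}} (e.g. \code{eggOffset},
#'   \code{sensorNoiseSd}).
#' @return list of \code{\linkS4class{NestScene}}.
#' @export
generateDataset <- function(nBeach = 28, nSaltmarsh = 60, seed = 1,
                            pxPerMm = 12, shape = NULL,
                            beach = NULL, saltmarsh = NULL, eggs = NULL, ...) {
  stopifnot(nBeach >= 0, nSaltmarsh >= 0)
  if (nBeach + nSaltmarsh == 0) return(list())
  if (is.null(eggs)) eggs <- replicate(3, eggParams(pxPerMm), simplify = FALSE)
  eggArea <- pi * prod(eggs[[1]]$axesPx)
  if (is.null(shape)) {
    side <- max(256L, as.integer(ceiling(sqrt(27 * eggArea * 1.8))))
    shape <- c(side, side)
  }
  hp <- list(beach = if (is.null(beach)) habitatParams("beach", pxPerMm) else beach,
             saltmarsh = if (is.null(saltmarsh)) habitatParams("saltmarsh", pxPerMm)
                         else saltmarsh)
  labels <- c(rep("beach", nBeach), rep("saltmarsh", nSaltmarsh))
  ids <- c(sprintf("beach%02d", seq_len(nBeach)),
           sprintf("marsh%02d", seq_len(nSaltmarsh)))
  lapply(seq_along(ids), function(i) {
    s <- childSeed(seed, ids[i])
    p <- hp[[labels[i]]]
    sceneEggs <- eggs
    # Between-nest appearance variation: real backgrounds vary from nest to
    # nest (the marsh more than the beach), and clutches vary in lightness;
    # this is what makes egg and background colour distributions overlap
    # across nests rather than separate on a fixed offset.
    withSeed(childSeed(s, "jitter"), {
      if (!is.null(p$hueJitterSd) && p$hueJitterSd > 0) {
        f <- exp(rnorm(1, 0, p$hueJitterSd)) *
          exp(rnorm(3, 0, 0.4 * p$hueJitterSd))
        # keep the +/- 3 sd luminance envelope inside [0, 1]; contrast
        # scales with albedo, so the noise sd is jittered proportionally
        hi <- 0.95 / (p$baseLuminance + 3 * p$luminanceSd)
        f <- pmin(pmax(f, 0.45), hi)
        p$hueRgb <- p$hueRgb * f
        p$luminanceSd <- p$luminanceSd * mean(f)
        p$baseLuminance <- mean(p$hueRgb)
      }
      js <- sceneEggs[[1]]$clutchJitterSd
      if (!is.null(js) && js > 0) {
        g <- min(max(exp(rnorm(1, 0, js)), 0.72), 1.35)
        sceneEggs <- lapply(sceneEggs, function(ep) {
          ep$groundRgb <- clip01(ep$groundRgb * g)
          ep$maculationRgb <- clip01(ep$maculationRgb * g)
          ep
        })
      }
    })
    bg <- generateBackground(p, shape, childSeed(s, "bg"))
    composeScene(bg, sceneEggs, nestId = ids[i], habitatLabel = labels[i],
                 seed = s, pxPerMm = pxPerMm, ...)
  })
}
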