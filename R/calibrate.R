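# Calibration: grey-standard gains, ruler-based rescaling to a common
# resolution, and the spectra-based RGB -> cone-catch polynomial mapping.

# CIE standard illuminant D65, relative spectral power at 10 nm steps,
# 400-700 nm (interpolated to the working grid).
.d65_10nm <- c(
  82.75, 91.49, 93.43, 86.68, 104.86, 117.01, 117.81, 114.86, 115.92,
  108.81, 109.35, 107.80, 104.79, 107.69, 104.41, 104.05, 100.00, 96.33,
  95.79, 88.69, 90.01, 89.60, 87.70, 83.29, 83.70, 80.03, 80.21, 82.28,
  78.28, 69.72, 71.61)

#' Visual-pigment absorbance template (A1 nomogram)
#'
#' Govardovskii-style alpha + beta band template parameterised by the
#' wavelength of maximum absorbance, evaluated on a wavelength grid and
#' normalised to unit peak.
#'
#' @param wl wavelengths in nm.
#' @param lambdaMax peak absorbance wavelength in nm.
#' @return numeric sensitivity curve with unit peak.
#' @export
pigmentTemplate <- function(wl, lambdaMax) {
  x <- lambdaMax / wl
  a <- 0.8795 + 0.0459 * exp(-(lambdaMax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambdaMax
  bb <- -40.5 + 0.195 * lambdaMax
  beta <- 0.26 * exp(-((wl - lmb) / bb)^2)
  s <- alpha + beta
  s / max(s)
}

# Smooth long-pass transmission (oil-droplet / ocular-media approximation).
longPass <- function(wl, cut, slope = 12) 1 / (1 + exp(-(wl - cut) / slope))

#' Build the spectral system: illuminant, camera and cone sensitivities
#'
#' Constructs the wavelength grid (400-700 nm, 5 nm step), a D65 relative
#' irradiance spectrum, Gaussian camera R/G/B sensor sensitivities, and
#' nomogram-based cone sets for three visual systems: an avian
#' violet-sensitive set (double cone D plus L, M, S single cones; the VS
#' cone itself is not modelled), a dichromatic mammalian carnivore (L, S),
#' and a human-like trichromat (L, M, S). Peak wavelengths and oil-droplet
#' cut-offs are conventions and fully configurable; avian cones get a
#' long-pass oil-droplet filter.
#'
#' @param step wavelength step in nm.
#' @param avianLmax,carnivoreLmax,humanLmax named numeric vectors of peak
#'   wavelengths per cone.
#' @param avianCut named long-pass cut-off wavelengths for the avian cones.
#' @param cameraPeaks,cameraSd camera sensor Gaussian peaks and widths (nm).
#' @return a \code{\linkS4class{SpectralSystem}}.
#' @export
spectralSystem <- function(step = 5,
    avianLmax = c(D = 570, L = 605, M = 537, S = 477),
    carnivoreLmax = c(L = 558, S = 430),
    humanLmax = c(L = 566, M = 541, S = 441),
    avianCut = c(D = 440, L = 560, M = 500, S = 440),
    cameraPeaks = c(R = 600, G = 535, B = 450),
    cameraSd = c(R = 50, G = 45, B = 55)) {
  wl <- seq(400, 700, by = step)
  ill <- stats::approx(seq(400, 700, by = 10), .d65_10nm, wl)$y
  cam <- vapply(c("R", "G", "B"), function(ch)
    exp(-(wl - cameraPeaks[[ch]])^2 / (2 * cameraSd[[ch]]^2)), wl * 0)
  cam <- apply(cam, 2, function(s) s / max(s))
  mkSet <- function(lmax, cuts = NULL) {
    out <- lapply(names(lmax), function(cone) {
      s <- pigmentTemplate(wl, lmax[[cone]])
      if (!is.null(cuts) && cone %in% names(cuts))
        s <- s * longPass(wl, cuts[[cone]])
      s / max(s)
    })
    names(out) <- names(lmax)
    out
  }
  new("SpectralSystem", wavelengths = wl, illuminant = ill, cameraSens = cam,
      coneSets = list(avian = mkSet(avianLmax, avianCut),
                      carnivore = mkSet(carnivoreLmax),
                      human = mkSet(humanLmax)))
}

#' Quantum catch of a receptor for a reflectance spectrum
#'
#' Illuminant-weighted integral of reflectance against a sensitivity curve,
#' normalised so a perfect reflector (reflectance identically 1) yields a
#' catch of 1 for every sensitivity/illuminant pair.
#'
#' @param reflectance spectrum in [0, 1] on the system grid (vector or
#'   spectra-by-row matrix).
#' @param sensitivity sensitivity curve on the same grid.
#' @param illuminant relative irradiance on the same grid.
#' @return dimensionless catch (one per spectrum).
#' @export
quantumCatch <- function(reflectance, sensitivity, illuminant) {
  if (is.matrix(reflectance)) {
    if (ncol(reflectance) != length(sensitivity))
      stop("spectral-grid error: reflectance and sensitivity grids differ")
    return(as.numeric(reflectance %*% (sensitivity * illuminant)) /
             sum(sensitivity * illuminant))
  }
  if (length(reflectance) != length(sensitivity) ||
      length(sensitivity) != length(illuminant))
    stop("spectral-grid error: curves must share one wavelength grid")
  sum(reflectance * sensitivity * illuminant) / sum(sensitivity * illuminant)
}

#' Synthetic bank of smooth reflectance spectra
#'
#' Mixtures of 1-3 Gaussian bumps plus a linear ramp over 400-700 nm,
#' clipped to [0, 1]: a low-dimensional smooth family emulating the
#' self-similarity of natural reflectance spectra, used to train and test
#' the RGB-to-cone mapping.
#'
#' @param n number of spectra.
#' @param system a \code{\linkS4class{SpectralSystem}} (for its grid).
#' @param seed integer seed.
#' @return n x length(grid) matrix of reflectances in [0, 1].
#' @export
makeSpectraBank <- function(n = 200, system = spectralSystem(), seed = 1) {
  wl <- system@wavelengths
  withSeed(seed, {
    t(vapply(seq_len(n), function(i) {
      base <- runif(1, 0.05, 0.5)
      ramp <- runif(1, -0.4, 0.6) * (wl - 400) / 300
      s <- base + ramp
      for (g in seq_len(sample(1:3, 1))) {
        s <- s + runif(1, -0.35, 0.6) *
          exp(-(wl - runif(1, 400, 700))^2 / (2 * runif(1, 60, 140)^2))
      }
      clip01(s)
    }, wl * 0))
  })
}

# Polynomial design matrix over camera catches.
polyDesign <- function(rgb, degree = 2) {
  R <- rgb[, 1]; G <- rgb[, 2]; B <- rgb[, 3]
  if (degree == 1) {
    m <- cbind(1, R, G, B)
    colnames(m) <- c("1", "R", "G", "B")
  } else {
    m <- cbind(1, R, G, B, R^2, G^2, B^2, R * G, R * B, G * B)
    colnames(m) <- c("1", "R", "G", "B", "R2", "G2", "B2", "RG", "RB", "GB")
  }
  m
}

#' Fit the RGB-to-cone-catch mapping
#'
#' Computes camera and cone quantum catches for every spectrum in the bank
#' and fits, per cone, a least-squares polynomial (default full 10-term
#' quadratic: intercept, linear, squares and cross-terms) from camera
#' catches to cone catches. A fixed, seeded 75/25 split provides held-out
#' R-squared per cone.
#'
#' @param spectra spectra-by-row matrix (>= 150 recommended).
#' @param system a \code{\linkS4class{SpectralSystem}}.
#' @param degree 1 (linear) or 2 (quadratic).
#' @param splitSeed seed for the 75/25 held-out split.
#' @return a \code{\linkS4class{MappingModel}}.
#' @export
fitRgbToConeMap <- function(spectra, system = spectralSystem(), degree = 2,
                            splitSeed = 1) {
  nterms <- if (degree == 1) 4 else 10
  if (nrow(spectra) <= nterms)
    stop("spectra bank must exceed the number of design terms")
  ill <- system@illuminant
  cam <- vapply(1:3, function(j)
    quantumCatch(spectra, system@cameraSens[, j], ill), numeric(nrow(spectra)))
  X <- polyDesign(cam, degree)
  idxTest <- withSeed(splitSeed,
                      sample(nrow(spectra), max(1, round(nrow(spectra) / 4))))
  tr <- setdiff(seq_len(nrow(spectra)), idxTest)
  coefs <- list(); hr2 <- list(); tr2 <- list()
  for (sysName in names(system@coneSets)) {
    cones <- system@coneSets[[sysName]]
    cf <- matrix(NA_real_, nterms, length(cones),
                 dimnames = list(colnames(X), names(cones)))
    h <- t <- stats::setNames(numeric(length(cones)), names(cones))
    for (cone in names(cones)) {
      y <- quantumCatch(spectra, cones[[cone]], ill)
      fit <- stats::lm.fit(X[tr, , drop = FALSE], y[tr])
      b <- fit$coefficients
      b[is.na(b)] <- 0
      if (qr(X[tr, , drop = FALSE])$rank < nterms)
        stop("collinearity error: rank-deficient design matrix")
      cf[, cone] <- b
      r2 <- function(obs, pred) 1 - sum((obs - pred)^2) /
        sum((obs - mean(obs))^2)
      t[cone] <- r2(y[tr], X[tr, , drop = FALSE] %*% b)
      h[cone] <- r2(y[idxTest], X[idxTest, , drop = FALSE] %*% b)
    }
    coefs[[sysName]] <- cf; hr2[[sysName]] <- h; tr2[[sysName]] <- t
  }
  new("MappingModel", terms = colnames(X), coefficients = coefs,
      heldoutR2 = hr2, trainR2 = tr2, degree = degree)
}

#' Map a calibrated image to per-pixel cone catches
#'
#' Applies the fitted polynomial mapping to every pixel, clipping catches to
#' be non-negative. For the human system the image is converted exactly to
#' CIE XYZ planes via the standard linear-sRGB matrix (no fitted map): its
#' Y plane is the human luminance.
#'
#' @param scene a calibrated \code{\linkS4class{NestScene}} (or bare image
#'   array).
#' @param model a \code{\linkS4class{MappingModel}}.
#' @param systemName \code{"avian"}, \code{"carnivore"} or \code{"human"}.
#' @return a \code{\linkS4class{ConeCatchImage}}.
#' @export
applyMap <- function(scene, model, systemName) {
  img <- if (is(scene, "NestScene")) scene@image else scene
  d <- dim(img)
  if (systemName == "human") {
    xyz <- linearRgbToXyz(cbind(as.numeric(img[, , 1]),
                                as.numeric(img[, , 2]),
                                as.numeric(img[, , 3])))
    planes <- list(X = matrix(xyz[, 1], d[1], d[2]),
                   Y = matrix(xyz[, 2], d[1], d[2]),
                   Z = matrix(xyz[, 3], d[1], d[2]))
    planes <- lapply(planes, function(p) pmax(p, 0))
    return(new("ConeCatchImage", systemName = "human", planes = planes))
  }
  if (!systemName %in% names(model@coefficients))
    stop("lookup error: no fitted mapping for system '", systemName, "'")
  X <- polyDesign(cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
                        as.numeric(img[, , 3])), model@degree)
  cf <- model@coefficients[[systemName]]
  catches <- X %*% cf
  planes <- lapply(seq_len(ncol(cf)), function(j)
    matrix(pmax(catches[, j], 0), d[1], d[2]))
  names(planes) <- colnames(cf)
  new("ConeCatchImage", systemName = systemName, planes = planes)
}

#' Grey-standard calibration
#'
#' Computes one gain per channel, \code{greyTarget / mean(grey pixels)}, and
#' multiplies the whole image by the gains. This simultaneously normalises
#' exposure and white-point balances the image (equalising R, G and B over
#' grey surfaces). Idempotent: applying it twice equals applying it once.
#'
#' @param scene a \code{\linkS4class{NestScene}} with a non-empty grey mask.
#' @param greyTarget known grey-patch reflectance (default 0.20).
#' @return the scene with gains applied and recorded in
#'   \code{calibrationGains}.
#' @export
greyCalibrate <- function(scene, greyTarget = 0.2) {
  gm <- greyMask(scene)
  if (!any(gm)) stop("empty-region error: grey mask selects no pixels")
  means <- vapply(1:3, function(ch) mean(scene@image[, , ch][gm]), 0)
  if (any(means < 1e-6))
    stop("saturation-or-underexposure error: grey patch mean is zero in ",
         "channel ", which(means < 1e-6)[1])
  gains <- greyTarget / means
  img <- scene@image
  for (ch in 1:3) img[, , ch] <- img[, , ch] * gains[ch]
  scene@image <- clip01(img)
  scene@calibrationGains <- gains
  scene
}

# Longer side of a mask's bounding box, in px.
maskExtent <- function(mask) {
  rs <- range(row(mask)[mask]); cs <- range(col(mask)[mask])
  max(rs[2] - rs[1] + 1, cs[2] - cs[1] + 1)
}

#' Rescale a scene to the standard resolution using the ruler
#'
#' The current resolution is inferred as (ruler bounding-box major extent in
#' px) / (ruler length in mm); the image and all masks are resampled to
#' \code{targetRes} px/mm by nearest-neighbour interpolation (preserving the
#' sharp dark-light maculation edges and keeping masks boolean). Normal
#' operation only downscales; upscaling requires \code{allowUpscale}.
#'
#' @param scene a \code{\linkS4class{NestScene}}.
#' @param rulerLengthMm physical length of the masked ruler segment (40 mm).
#' @param targetRes target resolution in px/mm (12 by default).
#' @param allowUpscale permit scale factors > 1.
#' @param tol sanity bound: the implied current resolution must be within
#'   this fraction of the target (default 20\%).
#' @return the rescaled scene with \code{scalePxPerMm = targetRes}.
#' @export
rescaleToStandard <- function(scene, rulerLengthMm = 40, targetRes = 12,
                              allowUpscale = FALSE, tol = 0.2) {
  rm_ <- rulerMask(scene)
  if (!any(rm_)) stop("fiducial error: empty ruler mask")
  ext <- maskExtent(rm_)
  if (ext < 10) stop("fiducial error: degenerate ruler mask (extent < 10 px)")
  curRes <- ext / rulerLengthMm
  if (abs(curRes / targetRes - 1) > tol)
    stop("fiducial error: implied resolution ", signif(curRes, 4),
         " px/mm is outside +/-", 100 * tol, "% of the target")
  scale <- targetRes / curRes
  if (scale > 1 + 1e-9 && !allowUpscale)
    stop("upscaling required (scale ", signif(scale, 4),
         ") but not permitted; set allowUpscale = TRUE")
  if (abs(scale - 1) < 1e-9) {
    scene@scalePxPerMm <- targetRes
    return(scene)
  }
  ms <- maskSet(scene)
  rz <- function(m) {
    out <- resizeNearest(m, scale)
    storage.mode(out) <- "logical"
    out
  }
  eggs <- lapply(ms@eggMasks, rz)
  newMasks <- new("MaskSet", eggMasks = eggs, rulerMask = rz(ms@rulerMask),
                  greyMask = rz(ms@greyMask),
                  exclusionMask = rz(ms@exclusionMask),
                  shape = as.integer(dim(eggs[[1]])))
  scene@image <- resizeNearest(scene@image, scale)
  scene@masks <- newMasks
  scene@scalePxPerMm <- targetRes
  scene
}

# Camera quantum catches for a matrix of spectra (helper for tests and the
# mapping pipeline).
cameraResponses <- function(spectra, system) {
  out <- vapply(1:3, function(j)
    quantumCatch(spectra, system@cameraSens[, j], system@illuminant),
    numeric(nrow(spectra)))
  colnames(out) <- c("R", "G", "B")
  out
}
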