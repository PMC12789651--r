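#' @import methods
NULL

#' Colour-keyed region masks of a nest scene
#'
#' A \code{MaskSet} holds the boolean region layers decoded from (or rendered
#' into) a colour-keyed mask image: one mask per egg (always three, ordered
#' cyan, magenta, yellow), one for a 40 mm ruler segment, one for the
#' 20\%-reflectance grey calibration square, and an exclusion mask covering
#' everything that must not be sampled as background (eggs, nest scrape,
#' ruler, chart).
#'
#' All layers are logical matrices sharing one shape; egg masks are pairwise
#' disjoint; egg, ruler and grey regions are contained in the exclusion mask.
#'
#' @slot eggMasks list of exactly 3 logical matrices.
#' @slot rulerMask,greyMask,exclusionMask logical matrices.
#' @slot shape integer (rows, cols).
#' @export
setClass("MaskSet", representation(
  eggMasks = "list",
  rulerMask = "matrix",
  greyMask = "matrix",
  exclusionMask = "matrix",
  shape = "integer"
))

setValidity("MaskSet", function(object) {
  msg <- character()
  sh <- object@shape
  if (length(sh) != 2) msg <- c(msg, "shape must be (rows, cols)")
  if (length(object@eggMasks) != 3) msg <- c(msg, "exactly 3 egg masks required")
  all_masks <- c(object@eggMasks,
                 list(object@rulerMask, object@greyMask, object@exclusionMask))
  for (m in all_masks) {
    if (!is.logical(m) || !identical(dim(m), sh))
      msg <- c(msg, "all masks must be logical matrices of the shared shape")
  }
  if (!length(msg)) {
    e <- object@eggMasks
    if (any(e[[1]] & e[[2]]) || any(e[[1]] & e[[3]]) || any(e[[2]] & e[[3]]))
      msg <- c(msg, "egg masks must be pairwise disjoint")
    covered <- e[[1]] | e[[2]] | e[[3]] | object@rulerMask | object@greyMask
    if (any(covered & !object@exclusionMask))
      msg <- c(msg, "egg, ruler and grey masks must lie inside the exclusion mask")
  }
  if (length(msg)) msg else TRUE
})

#' A nest scene: calibrated or raw image plus masks and metadata
#'
#' Container for one photographed (or synthesised) nest: a linear-RGB raster
#' in [0, 1], its \code{\linkS4class{MaskSet}}, identifiers, the pixel scale,
#' any grey-standard gains already applied, and (for synthetic scenes) the
#' generating ground truth.
#'
#' @slot image numeric rows x cols x 3 array, linear RGB in [0, 1].
#' @slot masks a \code{\linkS4class{MaskSet}}.
#' @slot nestId character scalar.
#' @slot habitat \code{"beach"} or \code{"saltmarsh"} (or \code{NA}).
#' @slot scalePxPerMm numeric scalar; \code{NA} if unknown.
#' @slot calibrationGains numeric(3) grey-standard gains; \code{numeric(0)}
#'   until \code{\link{greyCalibrate}} has been applied.
#' @slot groundTruth list; generator parameters and seed for synthetic scenes.
#' @export
setClass("NestScene", representation(
  image = "array",
  masks = "MaskSet",
  nestId = "character",
  habitat = "character",
  scalePxPerMm = "numeric",
  calibrationGains = "numeric",
  groundTruth = "list"
))

setValidity("NestScene", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3 || d[3] != 3) msg <- c(msg, "image must be rows x cols x 3")
  else if (!identical(as.integer(d[1:2]), object@masks@shape))
    msg <- c(msg, "image and mask shapes differ")
  if (any(!is.finite(object@image)) ||
      min(object@image) < 0 || max(object@image) > 1)
    msg <- c(msg, "image values must be finite and in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NestScene", function(object) {
  d <- dim(object@image)
  cat("NestScene '", object@nestId, "' (", object@habitat, ")\n", sep = "")
  cat("  image: ", d[1], " x ", d[2], " linear RGB\n", sep = "")
  cat("  scale: ", object@scalePxPerMm, " px/mm; calibrated: ",
      length(object@calibrationGains) == 3, "\n", sep = "")
})

#' Spectral description of illuminant, camera and receptor sets
#'
#' Wavelength grid (400-700 nm), relative illuminant spectrum (D65 by
#' default), camera R/G/B sensor sensitivities and named cone-sensitivity
#' sets (avian VS set D/L/M/S, dichromatic carnivore L/S, human L/M/S), each
#' curve normalised to unit peak. Built by \code{\link{spectralSystem}}.
#'
#' @slot wavelengths numeric grid in nm.
#' @slot illuminant numeric, relative spectral irradiance on the grid.
#' @slot cameraSens numeric matrix (n x 3), columns R, G, B.
#' @slot coneSets named list of named lists of curves on the grid.
#' @export
setClass("SpectralSystem", representation(
  wavelengths = "numeric",
  illuminant = "numeric",
  cameraSens = "matrix",
  coneSets = "list"
))

setValidity("SpectralSystem", function(object) {
  n <- length(object@wavelengths)
  msg <- character()
  if (length(object@illuminant) != n || any(object@illuminant < 0))
    msg <- c(msg, "illuminant must be non-negative on the wavelength grid")
  if (!identical(dim(object@cameraSens), c(n, 3L)) || any(object@cameraSens < 0))
    msg <- c(msg, "cameraSens must be a non-negative n x 3 matrix")
  for (set in object@coneSets) for (curve in set) {
    if (length(curve) != n || any(curve < 0))
      msg <- c(msg, "cone curves must be non-negative and on the grid")
    else if (abs(max(curve) - 1) > 1e-8)
      msg <- c(msg, "cone curves must be normalised to unit peak")
  }
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "SpectralSystem", function(object) {
  cat("SpectralSystem: ", length(object@wavelengths), " wavelengths ",
      min(object@wavelengths), "-", max(object@wavelengths), " nm; systems: ",
      paste(names(object@coneSets), collapse = ", "), "\n", sep = "")
})

#' Polynomial RGB-to-cone-catch mapping
#'
#' Least-squares mapping from camera catches to receptor catches, fitted on a
#' bank of smooth reflectance spectra by \code{\link{fitRgbToConeMap}}. One
#' coefficient matrix per visual system (design terms x cones), with
#' training and held-out R-squared per cone.
#'
#' @slot terms character vector of design-term labels.
#' @slot coefficients named list of (terms x cones) matrices per system.
#' @slot heldoutR2,trainR2 named lists of per-cone R-squared values.
#' @slot degree polynomial degree used (1 or 2).
#' @export
setClass("MappingModel", representation(
  terms = "character",
  coefficients = "list",
  heldoutR2 = "list",
  trainR2 = "list",
  degree = "numeric"
))

setMethod("show", "MappingModel", function(object) {
  cat("MappingModel (degree ", object@degree, "), systems:\n", sep = "")
  for (s in names(object@coefficients)) {
    r2 <- object@heldoutR2[[s]]
    cat("  ", s, ": cones ", paste(colnames(object@coefficients[[s]]),
        collapse = ", "), "; held-out R2 ",
        paste(sprintf("%.4f", r2), collapse = ", "), "\n", sep = "")
  }
})

#' Per-pixel receptor catches for one visual system
#'
#' Named non-negative planes, one per receptor class: avian D/L/M/S,
#' carnivore L/S, human X/Y/Z (the human pathway is represented in CIE XYZ;
#' Y serves as its luminance plane).
#'
#' @slot systemName \code{"avian"}, \code{"carnivore"} or \code{"human"}.
#' @slot planes named list of numeric matrices sharing one shape.
#' @export
setClass("ConeCatchImage", representation(
  systemName = "character",
  planes = "list"
))

setValidity("ConeCatchImage", function(object) {
  msg <- character()
  if (!length(object@planes)) return("planes must be non-empty")
  d <- dim(object@planes[[1]])
  for (p in object@planes) {
    if (!identical(dim(p), d)) msg <- c(msg, "planes must share one shape")
    if (any(p < 0)) msg <- c(msg, "catches must be non-negative")
  }
  if (is.null(names(object@planes))) msg <- c(msg, "planes must be named")
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "ConeCatchImage", function(object) {
  d <- dim(object@planes[[1]])
  cat("ConeCatchImage (", object@systemName, "): planes ",
      paste(names(object@planes), collapse = ", "), "; ",
      d[1], " x ", d[2], "\n", sep = "")
})

#' Log-Gabor filter bank
#'
#' Frequency-domain stack of 6 spatial scales x 8 orientations = 48
#' log-Gabor filters for one image shape, built by \code{\link{buildBank}}.
#' Every filter has zero DC response; orientations are evenly spaced over
#' 180 degrees starting at horizontal (o1), turning anticlockwise.
#'
#' @slot filters list of 48 numeric matrices (frequency-domain gains),
#'   ordered scale-major (s1o1, s1o2, ..., s6o8).
#' @slot wavelengths centre wavelengths in px, one per scale.
#' @slot orientations orientation angles in degrees, one per orientation.
#' @slot shape integer (rows, cols) the bank was built for.
#' @slot labels character(48) feature names (s1o1 ... s6o8).
#' @export
setClass("GaborBank", representation(
  filters = "list",
  wavelengths = "numeric",
  orientations = "numeric",
  shape = "integer",
  labels = "character"
))

setValidity("GaborBank", function(object) {
  msg <- character()
  nf <- length(object@wavelengths) * length(object@orientations)
  if (length(object@filters) != nf)
    msg <- c(msg, "filter count must be scales x orientations")
  for (f in object@filters) {
    if (!identical(as.integer(dim(f)), object@shape))
      msg <- c(msg, "filters must match the declared shape")
    if (abs(f[1, 1]) > 1e-12) msg <- c(msg, "filters must have zero DC gain")
  }
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "GaborBank", function(object) {
  cat("GaborBank: ", length(object@filters), " filters (",
      length(object@wavelengths), " scales x ", length(object@orientations),
      " orientations), wavelengths ",
      paste(signif(object@wavelengths, 3), collapse = ", "), " px, for ",
      object@shape[1], " x ", object@shape[2], " images\n", sep = "")
})

#' Correlation-matrix PCA of the 48 texture features
#'
#' Standardisation constants, loadings and eigenvalues from a PCA on the
#' correlation matrix of the pooled texture feature table, as fitted by
#' \code{\link{fitPca}}. Components with eigenvalue > 1 are retained; each
#' component is oriented so that its loading sum is non-negative.
#'
#' @slot center,scale per-feature mean and sd used for standardisation.
#' @slot loadings full loading matrix (features x features), orthonormal.
#' @slot eigenvalues all eigenvalues, descending; they sum to the feature
#'   count (trace of a correlation matrix).
#' @slot retainedK number of components with eigenvalue > 1.
#' @export
setClass("TexturePCA", representation(
  center = "numeric",
  scale = "numeric",
  loadings = "matrix",
  eigenvalues = "numeric",
  retainedK = "integer"
))

setValidity("TexturePCA", function(object) {
  msg <- character()
  p <- length(object@center)
  if (length(object@scale) != p || !identical(dim(object@loadings), c(p, p)))
    msg <- c(msg, "center/scale/loadings dimensions disagree")
  if (abs(sum(object@eigenvalues) - p) > 1e-6 * p)
    msg <- c(msg, "eigenvalues of a correlation matrix must sum to the feature count")
  if (object@retainedK < 1) msg <- c(msg, "at least one retained component required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TexturePCA", function(object) {
  ev <- object@eigenvalues
  cat("TexturePCA on ", length(ev), " features; retained ", object@retainedK,
      " components (eigenvalue > 1), variance shares ",
      paste(sprintf("%.1f%%", 100 * ev[seq_len(object@retainedK)] / sum(ev)),
            collapse = ", "), "\n", sep = "")
})

# ---- accessors ----

#' Accessors for scene and mask objects
#'
#' @param x a \code{\linkS4class{NestScene}} or \code{\linkS4class{MaskSet}}.
#' @return \code{sceneImage}: the linear-RGB array; \code{maskSet}: the
#'   \code{MaskSet}; \code{eggMasks}: list of 3 logical matrices;
#'   \code{nestId}, \code{habitat}: character scalars.
#' @name scene-accessors
#' @export
sceneImage <- function(x) x@image

#' @rdname scene-accessors
#' @export
maskSet <- function(x) if (is(x, "NestScene")) x@masks else x

#' @rdname scene-accessors
#' @export
eggMasks <- function(x) maskSet(x)@eggMasks

#' @rdname scene-accessors
#' @export
rulerMask <- function(x) maskSet(x)@rulerMask

#' @rdname scene-accessors
#' @export
greyMask <- function(x) maskSet(x)@greyMask

#' @rdname scene-accessors
#' @export
exclusionMask <- function(x) maskSet(x)@exclusionMask

#' @rdname scene-accessors
#' @export
nestId <- function(x) x@nestId

#' @rdname scene-accessors
#' @export
habitat <- function(x) x@habitat

#' @rdname scene-accessors
#' @export
isCalibrated <- function(x) length(x@calibrationGains) == 3

#' @rdname scene-accessors
#' @export
groundTruth <- function(x) x@groundTruth

#' Accessor: catch planes of a ConeCatchImage
#' @param x a \code{\linkS4class{ConeCatchImage}}.
#' @export
catchPlanes <- function(x) x@planes
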