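# Log-Gabor filter-bank texture description of the luminance plane, and
# correlation-matrix PCA over the 48 features.
#
# Bank geometry (conventions, configurable): 6 scales x 8 orientations,
# minimum wavelength 3 px with scale multiplier 2 (3-96 px, i.e. 0.25-8 mm
# at 12 px/mm, spanning maculation to pebble scale); radial bandwidth about
# two octaves (sigmaOnf = 0.55); orientations every 22.5 degrees starting at
# horizontal (o1), anticlockwise. Filtering is done in the frequency domain
# over the whole image; the region mask is applied to the response
# magnitude, not the input, so mask edges cannot contaminate the spectrum.

#' Build a log-Gabor filter bank
#'
#' Frequency-domain filters: a log-Gaussian radial profile centred on each
#' scale's frequency times a Gaussian angular profile around each
#' orientation (single-sided in frequency, so the spatial response is
#' complex and its modulus is the local energy envelope). Every filter has
#' exactly zero DC gain.
#'
#' @param shape integer (rows, cols) of the images the bank will filter.
#' @param nScales,nOrientations bank size (6 x 8 = 48 filters).
#' @param minWavelength finest wavelength in px.
#' @param mult wavelength multiplier between scales.
#' @param sigmaOnf radial bandwidth parameter (sigma of log-frequency
#'   Gaussian as a fraction of centre frequency; 0.55 is about 2 octaves).
#' @param dThetaOnSigma angular spacing / angular sigma ratio.
#' @return a \code{\linkS4class{GaborBank}}.
#' @export
buildBank <- function(shape, nScales = 6, nOrientations = 8,
                      minWavelength = 3, mult = 2, sigmaOnf = 0.55,
                      dThetaOnSigma = 1.5) {
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  wavelengths <- minWavelength * mult^(seq_len(nScales) - 1)
  if (max(wavelengths) * 2 > min(nr, nc))
    stop("bank-configuration error: largest wavelength ", max(wavelengths),
         " px exceeds half the image size")
  fr <- fftFreq(nr); fc <- fftFreq(nc)
  radius <- sqrt(outer(fr^2, fc^2, "+"))
  radius[1, 1] <- 1  # avoid log(0); DC is zeroed explicitly below
  # wave-vector angle; row frequencies point down the image, so the angle of
  # image structure is the wave vector rotated by 90 degrees
  theta <- atan2(outer(fr, fc * 0, "+"), outer(fr * 0, fc, "+"))
  thetaSigma <- pi / nOrientations / dThetaOnSigma
  orientationsDeg <- (seq_len(nOrientations) - 1) * 180 / nOrientations
  filters <- vector("list", nScales * nOrientations)
  labels <- character(nScales * nOrientations)
  i <- 0L
  for (s in seq_len(nScales)) {
    f0 <- 1 / wavelengths[s]
    radial <- exp(-(log(radius / f0))^2 / (2 * log(sigmaOnf)^2))
    radial[1, 1] <- 0
    for (o in seq_len(nOrientations)) {
      # structure at angle phi has wave vector at phi + 90 degrees
      ang <- orientationsDeg[o] * pi / 180 + pi / 2
      ds <- sin(theta) * cos(ang) - cos(theta) * sin(ang)
      dc <- cos(theta) * cos(ang) + sin(theta) * sin(ang)
      dtheta <- abs(atan2(ds, dc))
      spread <- exp(-dtheta^2 / (2 * thetaSigma^2))
      i <- i + 1L
      filters[[i]] <- radial * spread
      labels[i] <- sprintf("s%do%d", s, o)
    }
  }
  new("GaborBank", filters = filters, wavelengths = wavelengths,
      orientations = orientationsDeg, shape = c(nr, nc), labels = labels)
}

#' Filter energies of a region: the 48 texture features
#'
#' For each filter the complex spatial response (quadrature pair) of the
#' whole luminance image is computed by inverse FFT, its modulus averaged
#' over the region mask, and the natural log taken with a floor of 1e-8
#' (simple Gabor energies are non-negative and correlate with mean
#' luminance; logging removes that and admits negative values). A region
#' closer to the image border than half the largest wavelength gets a
#' recorded (non-fatal) boundary note.
#'
#' @param luminance numeric matrix (one plane).
#' @param bank a \code{\linkS4class{GaborBank}} built for this shape.
#' @param mask logical matrix, non-empty; if several regions are needed from
#'   one image pass a list of masks (one FFT pass is shared).
#' @param floorEps log floor.
#' @return named numeric(48) of log mean filter magnitudes (for a list of
#'   masks, a regions x 48 matrix). Attribute \code{boundary} flags regions
#'   near the border.
#' @export
filterEnergies <- function(luminance, bank, mask, floorEps = 1e-8) {
  masks <- if (is.list(mask)) mask else list(mask)
  if (any(!vapply(masks, any, TRUE)))
    stop("empty-region error: mask selects no pixels")
  d <- dim(luminance)
  if (!identical(as.integer(d), bank@shape))
    stop("bank was built for shape ", paste(bank@shape, collapse = " x "),
         ", image is ", paste(d, collapse = " x "))
  half <- max(bank@wavelengths) / 2
  boundary <- vapply(masks, function(m) {
    rs <- range(row(m)[m]); cs <- range(col(m)[m])
    rs[1] <= half || cs[1] <= half || rs[2] > d[1] - half || cs[2] > d[2] - half
  }, TRUE)
  F <- fft(luminance)
  npix <- prod(d)
  out <- matrix(NA_real_, length(masks), length(bank@filters),
                dimnames = list(NULL, bank@labels))
  idx <- lapply(masks, which)
  for (j in seq_along(bank@filters)) {
    resp <- fft(F * bank@filters[[j]], inverse = TRUE) / npix
    mag <- Mod(resp)
    for (k in seq_along(idx))
      out[k, j] <- log(max(mean(mag[idx[[k]]]), floorEps))
  }
  if (!is.list(mask)) {
    v <- out[1, ]
    attr(v, "boundary") <- boundary[1]
    return(v)
  }
  attr(out, "boundary") <- boundary
  out
}

#' PCA of the texture feature table on the correlation matrix
#'
#' Standardises each feature, eigendecomposes the correlation matrix, and
#' retains components with eigenvalue greater than 1 (components explaining
#' more variation than any single original feature). Each component is
#' oriented so the sum of its loadings is non-negative. One PCA is fitted on
#' the pooled egg + background table across habitats; refitting per stratum
#' would break comparability of the scores.
#'
#' @param features N x 48 numeric matrix (N > number of features).
#' @return a \code{\linkS4class{TexturePCA}}.
#' @export
fitPca <- function(features) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (nrow(features) <= p)
    stop("need more observations than features for the PCA")
  sds <- apply(features, 2, stats::sd)
  if (any(sds < 1e-12)) {
    bad <- colnames(features)[which(sds < 1e-12)[1]]
    stop("degenerate-feature error: zero variance in feature ",
         if (is.null(bad)) which(sds < 1e-12)[1] else bad)
  }
  mus <- colMeans(features)
  eg <- eigen(stats::cor(features), symmetric = TRUE)
  load <- eg$vectors
  flip <- colSums(load) < 0
  load[, flip] <- -load[, flip]
  rownames(load) <- colnames(features)
  colnames(load) <- paste0("PC", seq_len(p))
  k <- max(1L, sum(eg$values > 1))
  new("TexturePCA", center = mus, scale = sds, loadings = load,
      eigenvalues = eg$values, retainedK = as.integer(k))
}

#' Project feature vectors onto principal components
#'
#' Standardises with the training constants and multiplies by the loadings.
#'
#' @param pca a \code{\linkS4class{TexturePCA}}.
#' @param vectors length-48 vector or N x 48 matrix.
#' @param k number of components to return (default: the retained count).
#' @return N x k matrix of PC scores.
#' @export
projectPca <- function(pca, vectors, k = pca@retainedK) {
  v <- matrix(vectors, ncol = length(pca@center))
  if (ncol(v) != length(pca@center))
    stop("feature vectors must have length ", length(pca@center))
  z <- sweep(sweep(v, 2, pca@center), 2, pca@scale, "/")
  z %*% pca@loadings[, seq_len(k), drop = FALSE]
}
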