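# Scene I/O: 16-bit images plus colour-keyed mask layers.
#
# Mask palette (8-bit RGB, matched exactly; anti-aliased masks are rejected):
#   cyan #00FFFF, magenta #FF00FF, yellow #FFFF00  -> eggs 1-3 (in that order)
#   green #00FF00 -> 40 mm ruler segment
#   red   #FF0000 -> 20%-reflectance grey square
#   blue  #0000FF -> optional explicit exclusion zone
#   black #000000 -> unkeyed background

.maskPalette <- rbind(
  egg1 = c(0, 255, 255), egg2 = c(255, 0, 255), egg3 = c(255, 255, 0),
  ruler = c(0, 255, 0), grey = c(255, 0, 0), exclusion = c(0, 0, 255),
  background = c(0, 0, 0))

#' Write a nest scene to disk
#'
#' Writes the image as 16-bit TIFF (linear values in [0, 1]), the mask layer
#' as an 8-bit RGB PNG in the fixed colour key (cyan/magenta/yellow eggs,
#' green ruler, red grey-patch, blue exclusion, black elsewhere), and a JSON
#' sidecar with nest id, habitat, pixel scale, seed and ground truth.
#'
#' @param scene a \code{\linkS4class{NestScene}}.
#' @param dir output directory (created if needed).
#' @param name file stem; defaults to the nest id.
#' @return invisibly, the three file paths.
#' @export
writeScene <- function(scene, dir, name = nestId(scene)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgPath <- file.path(dir, paste0(name, ".tif"))
  maskPath <- file.path(dir, paste0(name, "_mask.png"))
  metaPath <- file.path(dir, paste0(name, ".json"))
  tiff::writeTIFF(scene@image, imgPath, bits.per.sample = 16L,
                  compression = "none")
  ms <- maskSet(scene)
  sh <- ms@shape
  maskImg <- array(0, c(sh[1], sh[2], 3))
  layers <- list(exclusion = ms@exclusionMask & !(ms@eggMasks[[1]] |
                   ms@eggMasks[[2]] | ms@eggMasks[[3]] | ms@rulerMask |
                   ms@greyMask),
                 egg1 = ms@eggMasks[[1]], egg2 = ms@eggMasks[[2]],
                 egg3 = ms@eggMasks[[3]], ruler = ms@rulerMask,
                 grey = ms@greyMask)
  for (nm in names(layers))
    for (ch in 1:3)
      maskImg[, , ch][layers[[nm]]] <- .maskPalette[nm, ch] / 255
  png::writePNG(maskImg, maskPath)
  gt <- scene@groundTruth
  gt$eggParams <- NULL  # class attrs do not survive JSON; keep the rest
  jsonlite::write_json(
    list(nest_id = scene@nestId, habitat = scene@habitat,
         scale_px_per_mm = scene@scalePxPerMm, ground_truth = gt),
    metaPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(image = imgPath, mask = maskPath, meta = metaPath))
}

#' Read a nest scene from an image + colour-keyed mask pair
#'
#' Integer image samples are mapped to [0, 1] by division by the format's
#' maximum value (the \pkg{tiff}/\pkg{png} readers do this); the mask image
#' is decoded by exact 8-bit palette match. A missing egg colour, an unknown
#' colour, or mismatched dimensions raise an error. If no explicit (blue)
#' exclusion region is keyed, the exclusion mask defaults to the union of
#' the egg, ruler and grey masks, each dilated by 5 px.
#'
#' @param imagePath 16-bit TIFF or PNG, linear RGB.
#' @param maskPath 8-bit RGB PNG in the fixed palette.
#' @param nestId,habitatLabel metadata (read from a JSON sidecar written by
#'   \code{\link{writeScene}} when present and not supplied).
#' @param scalePxPerMm pixel scale if known (\code{NA} otherwise).
#' @return a \code{\linkS4class{NestScene}}.
#' @export
readScene <- function(imagePath, maskPath, nestId = NULL, habitatLabel = NULL,
                      scalePxPerMm = NA_real_) {
  if (!file.exists(imagePath)) stop("image file not found: ", imagePath)
  if (!file.exists(maskPath)) stop("mask file not found: ", maskPath)
  img <- if (grepl("\\.tiff?$", imagePath, ignore.case = TRUE))
    tiff::readTIFF(imagePath) else png::readPNG(imagePath)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE]
  maskImg <- png::readPNG(maskPath)
  if (length(dim(maskImg)) == 3) maskImg <- maskImg[, , 1:3, drop = FALSE]
  if (!identical(dim(img)[1:2], dim(maskImg)[1:2]))
    stop("malformed-mask error: image and mask dimensions differ")
  masks <- decodeMaskImage(maskImg)

  meta <- sub("(_mask)?\\.[A-Za-z]+$", ".json", maskPath)
  if (file.exists(meta) && (is.null(nestId) || is.null(habitatLabel))) {
    m <- jsonlite::read_json(meta)
    if (is.null(nestId)) nestId <- m$nest_id
    if (is.null(habitatLabel)) habitatLabel <- m$habitat
    if (is.na(scalePxPerMm) && !is.null(m$scale_px_per_mm))
      scalePxPerMm <- m$scale_px_per_mm
  }
  new("NestScene", image = clip01(img), masks = masks,
      nestId = if (is.null(nestId)) "unknown" else nestId,
      habitat = if (is.null(habitatLabel)) NA_character_ else habitatLabel,
      scalePxPerMm = as.numeric(scalePxPerMm),
      calibrationGains = numeric(0), groundTruth = list())
}

# Decode an RGB [0,1] mask raster into a MaskSet by exact palette match.
decodeMaskImage <- function(maskImg) {
  sh <- as.integer(dim(maskImg)[1:2])
  q <- round(maskImg * 255)
  code <- q[, , 1] * 65536 + q[, , 2] * 256 + q[, , 3]
  palCode <- .maskPalette[, 1] * 65536 + .maskPalette[, 2] * 256 +
    .maskPalette[, 3]
  known <- code %in% palCode
  if (!all(known)) {
    bad <- code[which(!known)[1]]
    stop(sprintf(
      "malformed-mask error: unknown mask colour #%06X (anti-aliased mask?)",
      bad))
  }
  layer <- function(nm) matrix(code == palCode[[nm]], sh[1], sh[2])
  eggs <- list(layer("egg1"), layer("egg2"), layer("egg3"))
  missing <- c("cyan", "magenta", "yellow")[!vapply(eggs, any, TRUE)]
  if (length(missing))
    stop("malformed-mask error: missing egg mask colour(s): ",
         paste(missing, collapse = ", "))
  ruler <- layer("ruler"); grey <- layer("grey")
  excl <- layer("exclusion")
  exclusion <- if (any(excl)) {
    excl | eggs[[1]] | eggs[[2]] | eggs[[3]] | ruler | grey
  } else {
    dilateMask(eggs[[1]] | eggs[[2]] | eggs[[3]], 5) |
      dilateMask(ruler, 5) | dilateMask(grey, 5)
  }
  new("MaskSet", eggMasks = eggs, rulerMask = ruler, greyMask = grey,
      exclusionMask = exclusion, shape = sh)
}

#' Extract the pixels of a masked region
#'
#' @param image rows x cols x 3 array (or a matrix for one plane).
#' @param mask logical matrix with at least one TRUE pixel.
#' @return N x 3 matrix (or length-N vector) of the pixels where the mask is
#'   TRUE, in row-major (reading) order.
#' @export
regionPixels <- function(image, mask) {
  if (!any(mask)) stop("empty-region error: mask selects no pixels")
  # row-major (reading) order: sort selected (r, c) by r then c
  rs <- row(mask)[mask]; cs <- col(mask)[mask]
  o <- order(rs, cs)
  if (length(dim(image)) == 2) return(image[mask][o])
  cbind(image[, , 1][mask][o], image[, , 2][mask][o], image[, , 3][mask][o])
}
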