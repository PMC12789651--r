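# Colour metrics per visual system: luminance plus opponent channels.
#
# 'Colour' is summarised by three variables per system: luminance
# (achromatic brightness), a red-green opponent value and a yellow-blue
# opponent value.  Opponent channels use the Michelson-style contrast
# (A - B) / (A + B): intensity-invariant and bounded in [-1, 1].  For the
# human system the CIE L*a*b* space provides the same three axes.

opponent <- function(a, b) {
  s <- a + b
  if (any(s <= 0)) stop("undefined-chromaticity error: zero catch sum")
  (a - b) / s
}

#' Avian opponent channels from cone catches
#'
#' Luminance is the double-cone catch D; red-green is the L vs M contrast;
#' yellow-blue contrasts the mean of L and M against S.
#'
#' @param d,l,m,s non-negative cone catches (scalars or vectors).
#' @return data.frame with columns \code{luminance}, \code{rg}, \code{yb}.
#' @export
avianChannels <- function(d, l, m, s) {
  if (any(c(d, l, m, s) < 0)) stop("catches must be non-negative")
  data.frame(luminance = d,
             rg = opponent(l, m),
             yb = opponent((l + m) / 2, s))
}

#' Carnivore (dichromat) channels from cone catches
#'
#' Luminance is taken as the long-wave catch (the dichromat achromatic
#' signal is dominated by the L mechanism; a documented convention);
#' yellow-blue is the L vs S contrast. No red-green channel exists.
#'
#' @param l,s non-negative cone catches.
#' @return data.frame with columns \code{luminance}, \code{yb}.
#' @export
carnivoreChannels <- function(l, s) {
  if (any(c(l, s) < 0)) stop("catches must be non-negative")
  data.frame(luminance = l, yb = opponent(l, s))
}

# Linear sRGB -> CIE XYZ (D65), IEC 61966-2-1 primaries. Y of linear white
# (1,1,1) is 1.
.rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)

linearRgbToXyz <- function(rgb) {
  rgb <- matrix(rgb, ncol = 3)
  rgb %*% t(.rgb2xyz)
}

#' Linear sRGB to CIE L*a*b*
#'
#' Standard conversion linear sRGB -> XYZ (D65) -> L*a*b*. Out-of-gamut
#' inputs are clipped to [0, 1] first. L = luminance, a = red-green,
#' b = yellow-blue.
#'
#' @param rgb length-3 vector or N x 3 matrix of linear sRGB in [0, 1].
#' @return N x 3 matrix with columns \code{L}, \code{a}, \code{b}.
#' @export
humanLab <- function(rgb) {
  rgb <- clip01(matrix(rgb, ncol = 3))
  xyz <- linearRgbToXyz(rgb)
  xyzToLab(xyz)
}

# CIE XYZ (D65 white) -> L*a*b*.
xyzToLab <- function(xyz) {
  white <- as.numeric(.rgb2xyz %*% c(1, 1, 1))
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1] / white[1])
  fy <- f(xyz[, 2] / white[2])
  fz <- f(xyz[, 3] / white[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Region colour summary for one visual system
#'
#' Pools first, then transforms: cone catches are averaged over the masked
#' region and the opponent (or L*a*b*) transform is applied to the means.
#' This matches spatial pooling preceding opponency when a region is viewed
#' at a distance where its internal pattern is unresolvable.
#'
#' @param catchImage a \code{\linkS4class{ConeCatchImage}}.
#' @param mask logical matrix, non-empty.
#' @return one-row data.frame of the system's colour metrics: avian
#'   \code{luminance}, \code{rg}, \code{yb}; carnivore \code{luminance},
#'   \code{yb}; human \code{L}, \code{a}, \code{b} (plus \code{luminance}
#'   = CIE Y).
#' @export
regionColour <- function(catchImage, mask) {
  if (!any(mask)) stop("empty-region error: mask selects no pixels")
  means <- vapply(catchImage@planes, function(p) mean(p[mask]), 0)
  switch(catchImage@systemName,
    avian = avianChannels(means[["D"]], means[["L"]], means[["M"]],
                          means[["S"]]),
    carnivore = carnivoreChannels(means[["L"]], means[["S"]]),
    human = {
      lab <- xyzToLab(matrix(means[c("X", "Y", "Z")], 1))
      data.frame(luminance = means[["Y"]], L = lab[1, "L"], a = lab[1, "a"],
                 b = lab[1, "b"])
    },
    stop("unknown visual system: ", catchImage@systemName))
}
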