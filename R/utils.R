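# Internal helpers shared across modules.
#
# Coordinate convention (used everywhere): images are numeric matrices or
# row x col x 3 arrays, 0-based pixel (r, c) maps to R index [r + 1, c + 1],
# origin top-left, row-major; rectangles are half-open [r0, r1) x [c0, c1).

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generators are pure in (params, seed).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = env)
      else if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic child seed < 2^31 derived from a parent seed and a label.
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 1) %% 2147483629)
}

# Filled ellipse as a logical matrix over an (nr x nc) grid.
# (cr, cc) centre in 1-based pixel coordinates; a, b semi-axes in px;
# thetaDeg orientation of the major axis, anticlockwise from horizontal.
ellipseMask <- function(nr, nc, cr, cc, a, b, thetaDeg = 0) {
  th <- thetaDeg * pi / 180
  rr <- matrix(seq_len(nr), nr, nc) - cr
  cc2 <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  # image rows grow downwards, so anticlockwise in viewing coordinates
  u <- cc2 * cos(th) - rr * sin(th)
  v <- cc2 * sin(th) + rr * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# Nearest-neighbour index map: for n_out output pixels spanning n_src source
# pixels, the source index of each output pixel centre.
nnIndex <- function(nOut, nSrc) {
  idx <- floor((seq_len(nOut) - 0.5) * nSrc / nOut) + 1L
  pmin.int(nSrc, pmax.int(1L, idx))
}

# Nearest-neighbour resample of a matrix or H x W x 3 array by `scale`.
resizeNearest <- function(x, scale) {
  d <- dim(x)
  nr <- max(1L, as.integer(round(d[1] * scale)))
  nc <- max(1L, as.integer(round(d[2] * scale)))
  ri <- nnIndex(nr, d[1])
  ci <- nnIndex(nc, d[2])
  if (length(d) == 2) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

# FFT frequency coordinates (cycles / pixel) for an axis of length n.
fftFreq <- function(n) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / n
}

# Binary dilation by a disk of radius r (padded FFT convolution).
dilateMask <- function(mask, r) {
  if (r <= 0) return(mask)
  d <- dim(mask)
  k <- 2L * as.integer(ceiling(r)) + 1L
  kern <- ellipseMask(k, k, (k + 1) / 2, (k + 1) / 2, r, r)
  nr <- d[1] + k - 1L
  nc <- d[2] + k - 1L
  A <- matrix(0, nr, nc); A[seq_len(d[1]), seq_len(d[2])] <- mask
  B <- matrix(0, nr, nc); B[seq_len(k), seq_len(k)] <- kern
  conv <- Re(fft(fft(A) * fft(B), inverse = TRUE)) / (nr * nc)
  off <- (k - 1L) / 2L
  out <- conv[off + seq_len(d[1]), off + seq_len(d[2])] > 0.5
  out | mask
}

# Mean of RGB channels: the generator-side working definition of luminance.
channelMean <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopIfNot01 <- function(x, what) {
  if (any(!is.finite(x)) || min(x) < 0 || max(x) > 1)
    stop(what, " must be finite and within [0, 1]", call. = FALSE)
  invisible(x)
}
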