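# Gray-scale gliding-box lacunarity. Box masses are computed with a
# summed-area table, so a full curve on the 32x32 and 64x64 CGR images used
# here is essentially free; the naive per-box double loop lives in the test
# suite as the independent oracle.

.asPixelMatrix <- function(img) {
  if (is(img, "CGRMatrix")) img <- cgrValues(img)
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  img
}

#' Min-max normalize a CGR matrix to a gray-scale image
#'
#' Linear rescale `(v - min) / (max - min)` to `[0, 1]`. A constant non-zero
#' matrix maps to an all-ones image; an all-zero matrix is rejected (no
#' texture to analyze).
#'
#' @param m a [CGRMatrix-class] or numeric matrix with at least one positive
#'   entry
#' @return numeric matrix with values in `[0, 1]`
#' @export
normalizeMatrix <- function(m) {
  px <- .asPixelMatrix(m)
  if (all(px == 0)) stop("all-zero matrix: nothing to normalize", call. = FALSE)
  lo <- min(px)
  hi <- max(px)
  if (hi == lo) return(array(1, dim = dim(px)))
  (px - lo) / (hi - lo)
}

#' Sigmoid preprocessing of a gray image
#'
#' Pixelwise logistic transform `J = 1 / (1 + exp(-k * (I - sigma)))`: a
#' smooth threshold at gray level `sigma` whose steepness grows with `k`,
#' approaching a hard binarization as `k` increases.
#'
#' @param img numeric matrix in `[0, 1]`
#' @param k steepness (> 0); default 7
#' @param sigma midpoint gray level (> 0); default 0.7
#' @return numeric matrix with values in (0, 1)
#' @export
sigmoidPreprocess <- function(img, k = 7, sigma = 0.7) {
  px <- .asPixelMatrix(img)
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("k must be a positive scalar", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a positive scalar", call. = FALSE)
  1 / (1 + exp(-k * (px - sigma)))
}

# box masses via separable shifted-window accumulation: O(b) vectorized adds
# per axis. Unlike a summed-area table this performs the same additions in
# the same order for every placement, so equal boxes get bit-identical
# masses (a constant image yields exact lacunarity 1) and binary images
# stay exact.
.boxMassMatrix <- function(px, b) {
  H <- nrow(px)
  W <- ncol(px)
  nj <- W - b + 1L
  rowSum <- px[, seq_len(nj), drop = FALSE]
  for (dj in seq_len(b - 1L))
    rowSum <- rowSum + px[, seq_len(nj) + dj, drop = FALSE]
  ni <- H - b + 1L
  out <- rowSum[seq_len(ni), , drop = FALSE]
  for (di in seq_len(b - 1L))
    out <- out + rowSum[seq_len(ni) + di, , drop = FALSE]
  out
}

#' Box-mass distribution of a gliding box
#'
#' Moves a `b x b` box one pixel at a time over the image and records the
#' mass (sum of pixel values; the white-pixel count on a binary image) of
#' every fully contained placement — `(H-b+1) * (W-b+1)` boxes in all.
#'
#' @param img numeric matrix
#' @param b box side in pixels, `1 <= b <= min(dim(img))`
#' @return a [BoxMassDistribution-class]
#' @export
boxMassDistribution <- function(img, b) {
  px <- .asPixelMatrix(img)
  b <- as.integer(b)
  if (b < 1L || b > min(dim(px)))
    stop(sprintf("box size %d out of range [1, %d]", b, min(dim(px))),
         call. = FALSE)
  masses <- .boxMassMatrix(px, b)
  new("BoxMassDistribution", boxSize = b,
      masses = as.numeric(t(masses)),   # row-major placement order
      imageDim = dim(px))
}

#' Lacunarity of one box-mass distribution
#'
#' `Lambda(b) = Z2 / Z1^2` where `Zq` is the q-th raw moment of the box mass
#' over the empirical placement distribution. Always >= 1 when the mean mass
#' is positive, with equality iff all box masses are equal.
#'
#' @param dist a [BoxMassDistribution-class]
#' @return numeric lacunarity value
#' @export
lacunarityAt <- function(dist) {
  stopifnot(is(dist, "BoxMassDistribution"))
  m <- dist@masses
  s1 <- sum(m)
  if (s1 <= 0)
    stop("first moment is zero: lacunarity undefined on an empty region",
         call. = FALSE)
  if (max(m) == min(m)) return(1)  # zero variance: exactly 1
  # Z2 / Z1^2 written over sums: integer-valued masses (binary images) give
  # exact rational results
  length(m) * sum(m^2) / s1^2
}

#' Lacunarity curve over a range of box sizes
#'
#' Evaluates gliding-box lacunarity at every integer box size from `bMin`
#' to `bMax`. `bMax = "auto"` uses half the shorter image side: beyond that
#' the number of box placements is too small for a meaningful second moment.
#'
#' @param img numeric matrix (typically the sigmoid-preprocessed CGR image)
#' @param bMin smallest box size (>= 1); default 3
#' @param bMax largest box size, or `"auto"` for `floor(min(dim(img)) / 2)`
#' @param keepDistributions retain the per-b [BoxMassDistribution-class]
#'   objects for diagnostics (default TRUE; set FALSE on large images)
#' @return a [LacunarityCurve-class]
#' @export
lacunarityCurve <- function(img, bMin = 3L, bMax = "auto",
                            keepDistributions = TRUE) {
  px <- .asPixelMatrix(img)
  side <- min(dim(px))
  bMin <- as.integer(bMin)
  if (identical(bMax, "auto")) bMax <- side %/% 2L
  bMax <- as.integer(bMax)
  if (bMin < 1L || bMin >= bMax || bMax > side)
    stop(sprintf("need 1 <= bMin < bMax <= %d (got %d, %d)", side, bMin, bMax),
         call. = FALSE)
  bs <- bMin:bMax
  dists <- lapply(bs, function(b) boxMassDistribution(px, b))
  lambda <- vapply(dists, lacunarityAt, numeric(1))
  new("LacunarityCurve", b = bs, lambda = lambda,
      distributions = if (keepDistributions) dists else list())
}
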