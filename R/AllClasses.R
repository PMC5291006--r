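#' @import methods
NULL

#' NucleotideSequence: a (possibly ambiguous) DNA sequence
#'
#' A finite string over the lowercase 15-letter IUPAC nucleotide alphabet.
#' Plain bases are `a c g t`; degenerate symbols (`r y s w k m b d h v n`)
#' encode heteroplasmic positions, i.e. a mixture of mtDNA molecules carrying
#' different bases at the same nucleotide position.
#'
#' @slot symbols single character string, every letter in the IUPAC alphabet
#' @slot name free-text identifier (FASTA header)
#' @aliases NucleotideSequence-class
#' @exportClass NucleotideSequence
setClass("NucleotideSequence",
  representation(symbols = "character", name = "character"),
  validity = function(object) {
    if (length(object@symbols) != 1L || is.na(object@symbols))
      return("'symbols' must be a single non-NA string")
    if (nchar(object@symbols) < 1L)
      return("sequence must have length >= 1")
    chars <- strsplit(object@symbols, "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% .IUPAC_LETTERS))
    if (length(bad) > 0)
      return(sprintf("illegal symbol '%s' at position %d", chars[bad[1]], bad[1]))
    if (length(object@name) != 1L)
      return("'name' must be a single string")
    TRUE
  }
)

#' CGRMatrix: weighted Chaos Game Representation of a sequence
#'
#' A `2^L x 2^L` matrix whose cell (r, c) holds the total weight of the
#' length-`L` substrings addressed to that cell by recursive quadrant
#' addressing (base layout `a` top-left, `c` top-right, `g` bottom-left,
#' `t` bottom-right). Windows containing degenerate symbols are expanded
#' into all compatible pure strings, each contributing a fractional weight,
#' so the total mass always equals the number of windows processed.
#'
#' @slot values numeric matrix of non-negative weighted counts
#' @slot frameLength the substring length L
#' @slot sourceName name of the sequence the matrix was built from
#' @aliases CGRMatrix-class
#' @exportClass CGRMatrix
setClass("CGRMatrix",
  representation(values = "matrix", frameLength = "integer",
                 sourceName = "character"),
  validity = function(object) {
    L <- object@frameLength
    if (length(L) != 1L || is.na(L) || L < 1L)
      return("'frameLength' must be a positive integer")
    side <- 2L^L
    if (!all(dim(object@values) == c(side, side)))
      return(sprintf("values must be %d x %d for frameLength %d", side, side, L))
    if (any(object@values < 0))
      return("all entries must be >= 0")
    TRUE
  }
)

#' BoxMassDistribution: gliding-box masses at one box size
#'
#' All masses observed when a `b x b` box glides with stride 1 over an image,
#' one mass per fully contained placement; the empirical distribution behind
#' one point of the lacunarity curve.
#'
#' @slot boxSize the box side b in pixels
#' @slot masses numeric vector, one box mass per placement (row-major order)
#' @slot imageDim dimensions (H, W) of the source image
#' @aliases BoxMassDistribution-class
#' @exportClass BoxMassDistribution
setClass("BoxMassDistribution",
  representation(boxSize = "integer", masses = "numeric", imageDim = "integer"),
  validity = function(object) {
    b <- object@boxSize
    d <- object@imageDim
    if (length(b) != 1L || b < 1L) return("'boxSize' must be a positive integer")
    if (length(d) != 2L || any(d < b)) return("box larger than image")
    if (length(object@masses) != prod(d - b + 1L))
      return("number of masses must equal (H-b+1)*(W-b+1)")
    if (any(object@masses < -1e-12)) return("masses must be >= 0")
    TRUE
  }
)

#' LacunarityCurve: the lacunarity function sampled at integer box sizes
#'
#' Lacunarity Lambda(b) = Z2 / Z1^2 (second over squared first moment of the
#' box-mass distribution) at every integer b between `bMin` and `bMax`.
#'
#' @slot b integer box sizes, strictly increasing in steps of 1
#' @slot lambda lacunarity values, one per box size
#' @slot distributions list of [BoxMassDistribution-class] (may be empty when
#'   the caller drops them to save memory)
#' @aliases LacunarityCurve-class
#' @exportClass LacunarityCurve
setClass("LacunarityCurve",
  representation(b = "integer", lambda = "numeric", distributions = "list"),
  validity = function(object) {
    if (length(object@b) < 1L) return("empty curve")
    if (length(object@lambda) != length(object@b))
      return("'b' and 'lambda' lengths differ")
    if (any(diff(object@b) != 1L))
      return("box sizes must increase in steps of 1")
    if (length(object@distributions) > 0 &&
        length(object@distributions) != length(object@b))
      return("when kept, distributions must match the box sizes")
    TRUE
  }
)

#' HyperbolaFit: least-squares hyperbola model of a lacunarity curve
#'
#' The model `L(b) = beta * b^(-alpha) + gamma` fitted to the sampled
#' lacunarity function. `alpha` relates to the fractal dimension of the
#' pattern, `beta` is the lacunarity amplitude used as the per-subject
#' biomarker, and `gamma` the large-box asymptote.
#'
#' @slot alpha decay exponent (bounded >= 0)
#' @slot beta lacunarity scale parameter, the biomarker
#' @slot gamma asymptote (bounded >= 0)
#' @slot residualNorm sum of squared residuals at the optimum
#' @slot converged whether the optimizer reported convergence
#' @slot nPoints number of (b, lambda) pairs fitted
#' @slot b,lambda the fitted data
#' @slot fitted model values at `b`
#' @slot initial the deterministic starting triplet (alpha0, beta0, gamma0)
#' @aliases HyperbolaFit-class
#' @exportClass HyperbolaFit
setClass("HyperbolaFit",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 residualNorm = "numeric", converged = "logical",
                 nPoints = "integer", b = "numeric", lambda = "numeric",
                 fitted = "numeric", initial = "numeric"),
  validity = function(object) {
    for (nm in c("alpha", "beta", "gamma", "residualNorm"))
      if (length(slot(object, nm)) != 1L)
        return(sprintf("'%s' must be a scalar", nm))
    if (object@converged &&
        !all(is.finite(c(object@alpha, object@beta, object@gamma,
                         object@residualNorm))))
      return("a converged fit must have finite parameters and residual norm")
    if (object@alpha < 0 || object@gamma < 0)
      return("alpha and gamma are bounded below by 0")
    TRUE
  }
)

#' MutationReport: per-sequence composition and mutation summary
#'
#' Mirrors the per-sequence report emitted alongside each CGR matrix: the
#' (fractional) base composition of the processed sequence and the list of
#' homoplasmic and heteroplasmic calls with their positions.
#'
#' @slot counts named numeric vector (a, c, g, t); ambiguous positions
#'   contribute fractionally so the four counts sum to the sequence length
#' @slot sequenceLength length of the processed sequence
#' @slot homoplasmic,heteroplasmic data frames with columns
#'   `position`, `ref_base`, `call`
#' @aliases MutationReport-class
#' @exportClass MutationReport
setClass("MutationReport",
  representation(counts = "numeric", sequenceLength = "integer",
                 homoplasmic = "data.frame", heteroplasmic = "data.frame"),
  validity = function(object) {
    if (!identical(names(object@counts), .PURE_BASES))
      return("counts must be named a, c, g, t")
    if (abs(sum(object@counts) - object@sequenceLength) > 1e-6)
      return("counts must sum to the sequence length")
    TRUE
  }
)

#' CohortComparison: two-group comparison and cutoff classification of beta
#'
#' Summary of a cohort analysis: per-group mean and SD of the biomarker,
#' one-tailed pooled-variance t-test, and the confusion matrix of the
#' beta <= cutoff classifier against the true group labels.
#'
#' @slot groupMeans,groupSds named per-group statistics of beta
#' @slot tStatistic,pValue pooled t and its one-tailed p-value
#' @slot nPerGroup named subject counts
#' @slot cutoff the beta threshold actually used (resolved from "median"
#'   when requested)
#' @slot confusion named integer vector (tp, fp, tn, fn)
#' @slot positiveGroup the group label treated as disease-like
#' @aliases CohortComparison-class
#' @exportClass CohortComparison
setClass("CohortComparison",
  representation(groupMeans = "numeric", groupSds = "numeric",
                 tStatistic = "numeric", pValue = "numeric",
                 nPerGroup = "integer", cutoff = "numeric",
                 confusion = "integer", positiveGroup = "character"),
  validity = function(object) {
    if (!identical(names(object@confusion), c("tp", "fp", "tn", "fn")))
      return("confusion must be named tp, fp, tn, fn")
    if (sum(object@confusion) != sum(object@nPerGroup))
      return("confusion counts must sum to the number of subjects")
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
      return("pValue must lie in [0, 1]")
    TRUE
  }
)
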