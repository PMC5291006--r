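#' @include AllClasses.R
NULL

#' Accessors for lacunaseq classes
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param x,object a lacunaseq object
#' @param ... unused
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seqSymbols", function(x) standardGeneric("seqSymbols"))
#' @rdname accessors
#' @export
setGeneric("seqName", function(x) standardGeneric("seqName"))
#' @rdname accessors
#' @export
setGeneric("cgrValues", function(x) standardGeneric("cgrValues"))
#' @rdname accessors
#' @export
setGeneric("frameLength", function(x) standardGeneric("frameLength"))
#' @rdname accessors
#' @export
setGeneric("boxSizes", function(x) standardGeneric("boxSizes"))
#' @rdname accessors
#' @export
setGeneric("lambdaValues", function(x) standardGeneric("lambdaValues"))
#' @rdname accessors
#' @export
setGeneric("boxMasses", function(x) standardGeneric("boxMasses"))
#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("baseCounts", function(x) standardGeneric("baseCounts"))
#' @rdname accessors
#' @export
setGeneric("mutationCalls", function(x, ...) standardGeneric("mutationCalls"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("betaCutoff", function(x) standardGeneric("betaCutoff"))

#' @rdname accessors
#' @export
setMethod("seqSymbols", "NucleotideSequence", function(x) x@symbols)
#' @rdname accessors
#' @export
setMethod("seqName", "NucleotideSequence", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("length", "NucleotideSequence", function(x) nchar(x@symbols))
#' @rdname accessors
#' @export
setMethod("as.character", "NucleotideSequence", function(x) x@symbols)

#' @rdname accessors
#' @export
setMethod("cgrValues", "CGRMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("frameLength", "CGRMatrix", function(x) x@frameLength)
#' @rdname accessors
#' @export
setMethod("dim", "CGRMatrix", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("boxSizes", "BoxMassDistribution", function(x) x@boxSize)
#' @rdname accessors
#' @export
setMethod("boxMasses", "BoxMassDistribution", function(x) x@masses)

#' @rdname accessors
#' @export
setMethod("boxSizes", "LacunarityCurve", function(x) x@b)
#' @rdname accessors
#' @export
setMethod("lambdaValues", "LacunarityCurve", function(x) x@lambda)
#' @rdname accessors
#' @export
setMethod("length", "LacunarityCurve", function(x) length(x@b))

#' @rdname accessors
#' @export
setMethod("coef", "HyperbolaFit", function(object, ...) {
  c(alpha = object@alpha, beta = object@beta, gamma = object@gamma)
})
#' @rdname accessors
#' @export
setMethod("fitted", "HyperbolaFit", function(object, ...) object@fitted)
#' @rdname accessors
#' @export
setMethod("residuals", "HyperbolaFit", function(object, ...) {
  object@lambda - object@fitted
})
#' @rdname accessors
#' @export
setMethod("converged", "HyperbolaFit", function(x) x@converged)

#' @rdname accessors
#' @export
setMethod("baseCounts", "MutationReport", function(x) x@counts)
#' @rdname accessors
#' @param type one of "homoplasmic", "heteroplasmic"
#' @export
setMethod("mutationCalls", "MutationReport",
  function(x, type = c("homoplasmic", "heteroplasmic")) {
    type <- match.arg(type)
    slot(x, type)
  })

#' @rdname accessors
#' @export
setMethod("confusionCounts", "CohortComparison", function(x) x@confusion)
#' @rdname accessors
#' @export
setMethod("betaCutoff", "CohortComparison", function(x) x@cutoff)

#' Goodness of fit of a hyperbola model
#'
#' R-squared of the fitted model against the lacunarity data.
#'
#' @param fit a [HyperbolaFit-class]
#' @return numeric R-squared (1 for a perfect fit; may be negative if the
#'   model does worse than the mean)
#' @export
rSquared <- function(fit) {
  stopifnot(is(fit, "HyperbolaFit"))
  tss <- sum((fit@lambda - mean(fit@lambda))^2)
  if (tss == 0) return(if (fit@residualNorm <= 1e-20) 1 else 0)
  1 - fit@residualNorm / tss
}

#' Coerce a LacunarityCurve to a data frame
#'
#' @param x a [LacunarityCurve-class]
#' @param ... unused
#' @return data.frame with columns `b` and `lambda`
#' @export
setMethod("as.data.frame", "LacunarityCurve", function(x, ...) {
  data.frame(b = x@b, lambda = x@lambda)
})

setMethod("show", "NucleotideSequence", function(object) {
  n <- nchar(object@symbols)
  preview <- if (n > 60) paste0(substr(object@symbols, 1, 57), "...")
             else object@symbols
  cat(sprintf("NucleotideSequence '%s': %d symbols\n  %s\n",
              object@name, n, preview))
})

setMethod("show", "CGRMatrix", function(object) {
  cat(sprintf("CGRMatrix of '%s': frame length L=%d (%d x %d), total mass %.6g\n",
              object@sourceName, object@frameLength,
              nrow(object@values), ncol(object@values), sum(object@values)))
})

setMethod("show", "BoxMassDistribution", function(object) {
  cat(sprintf("BoxMassDistribution: b=%d, %d boxes on a %d x %d image, mean mass %.4g\n",
              object@boxSize, length(object@masses),
              object@imageDim[1], object@imageDim[2], mean(object@masses)))
})

setMethod("show", "LacunarityCurve", function(object) {
  cat(sprintf("LacunarityCurve: b = %d..%d (%d points), Lambda in [%.4f, %.4f]\n",
              min(object@b), max(object@b), length(object@b),
              min(object@lambda), max(object@lambda)))
})

setMethod("show", "HyperbolaFit", function(object) {
  cat(sprintf(
    "HyperbolaFit: L(b) = beta * b^-alpha + gamma\n  alpha = %.6g, beta = %.6g, gamma = %.6g\n  RSS = %.4g over %d points; converged: %s\n",
    object@alpha, object@beta, object@gamma, object@residualNorm,
    object@nPoints, object@converged))
})

setMethod("show", "MutationReport", function(object) {
  cat(sprintf("MutationReport: %d nt; a=%.2f c=%.2f g=%.2f t=%.2f\n",
              object@sequenceLength, object@counts["a"], object@counts["c"],
              object@counts["g"], object@counts["t"]))
  cat(sprintf("  homoplasmic: %d, heteroplasmic: %d\n",
              nrow(object@homoplasmic), nrow(object@heteroplasmic)))
})

setMethod("show", "CohortComparison", function(object) {
  cat("CohortComparison\n")
  for (g in names(object@groupMeans))
    cat(sprintf("  %s: beta %.4f +/- %.4f (n=%d)\n", g,
                object@groupMeans[g], object@groupSds[g], object@nPerGroup[g]))
  cat(sprintf("  one-tail pooled t = %.4f, p = %.4g\n",
              object@tStatistic, object@pValue))
  cat(sprintf("  cutoff beta <= %.4f (positive group '%s'): tp=%d fp=%d tn=%d fn=%d\n",
              object@cutoff, object@positiveGroup,
              object@confusion["tp"], object@confusion["fp"],
              object@confusion["tn"], object@confusion["fn"]))
})
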