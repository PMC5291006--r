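#' Pipeline configuration
#'
#' Bundles the tunable parameters of the per-subject analysis. The defaults
#' are the operating point at which the method separates cohorts well:
#' frame length L = 5 (a 32 x 32 CGR image), sigmoid steepness k = 7 and
#' midpoint sigma = 0.7, boxes from bMin = 3 up to half the image side.
#'
#' @param frameLength CGR frame length L, 1..12 (default 5)
#' @param bMin smallest gliding-box size (>= 2; default 3)
#' @param bMax largest box size or `"auto"` (half the image side)
#' @param k,sigma sigmoid parameters (> 0; defaults 7 and 0.7)
#' @param circular count wraparound CGR windows (default FALSE)
#' @param keepIntermediates retain the CGR matrix, images and box-mass
#'   distributions inside each result (default TRUE)
#' @return a list of class `PipelineConfig`
#' @export
pipelineConfig <- function(frameLength = 5L, bMin = 3L, bMax = "auto",
                           k = 7, sigma = 0.7, circular = FALSE,
                           keepIntermediates = TRUE) {
  frameLength <- as.integer(frameLength)
  bMin <- as.integer(bMin)
  if (frameLength < 1L || frameLength > 12L)
    stop("frameLength must be in [1, 12]", call. = FALSE)
  if (bMin < 2L) stop("bMin must be >= 2", call. = FALSE)
  if (k <= 0 || sigma <= 0) stop("k and sigma must be > 0", call. = FALSE)
  if (!identical(bMax, "auto")) {
    bMax <- as.integer(bMax)
    if (bMax <= bMin) stop("bMax must exceed bMin", call. = FALSE)
  }
  structure(list(frameLength = frameLength, bMin = bMin, bMax = bMax,
                 k = k, sigma = sigma, circular = isTRUE(circular),
                 keepIntermediates = isTRUE(keepIntermediates)),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Analyze one subject end to end
#'
#' Runs the full pipeline: reconstruct the subject sequence from reference
#' plus calls, build the weighted CGR matrix, min-max normalize, sigmoid
#' preprocess, compute the lacunarity curve and fit the hyperbola model.
#' Every stage is deterministic, so repeated runs of the same inputs give
#' identical results.
#'
#' @param reference reference [NucleotideSequence-class]
#' @param calls CallTable data.frame (NULL or empty for the reference itself)
#' @param config a [pipelineConfig()]
#' @param subjectId,group labels carried into the result
#' @return a list of class `SubjectResult` with elements `subjectId`,
#'   `group`, `beta`, `alpha`, `gamma`, `fit` ([HyperbolaFit-class]),
#'   `curve` ([LacunarityCurve-class]), `report` ([MutationReport-class]),
#'   `config`, and (when `keepIntermediates`) `cgr` plus the two images
#' @export
analyzeSubject <- function(reference, calls = NULL,
                           config = pipelineConfig(),
                           subjectId = "subject", group = NA_character_) {
  stopifnot(inherits(config, "PipelineConfig"))
  mutated <- .stage("apply_calls", applyCalls(reference, calls))
  cgr <- .stage("cgr_matrix",
                cgrMatrix(mutated, L = config$frameLength,
                          circular = config$circular))
  img <- .stage("normalize", normalizeMatrix(cgr))
  simg <- .stage("sigmoid", sigmoidPreprocess(img, k = config$k,
                                              sigma = config$sigma))
  curve <- .stage("lacunarity",
                  lacunarityCurve(simg, bMin = config$bMin, bMax = config$bMax,
                                  keepDistributions = config$keepIntermediates))
  fit <- .stage("hyperbola_fit", fitHyperbola(curve))
  report <- .stage("report", mutationReport(reference, calls, mutated))
  pars <- coef(fit)
  res <- list(subjectId = subjectId, group = group,
              beta = unname(pars["beta"]), alpha = unname(pars["alpha"]),
              gamma = unname(pars["gamma"]),
              fit = fit, curve = curve, report = report, config = config)
  if (config$keepIntermediates) {
    res$cgr <- cgr
    res$grayImage <- img
    res$sigmoidImage <- simg
  }
  structure(res, class = "SubjectResult")
}

#' @export
print.SubjectResult <- function(x, ...) {
  cat(sprintf("SubjectResult '%s' (group %s): beta = %.6g, alpha = %.6g, gamma = %.6g\n",
              x$subjectId, x$group, x$beta, x$alpha, x$gamma))
  cat(sprintf("  mutations: %d homoplasmic, %d heteroplasmic; L=%d, b=%d..%d\n",
              nrow(mutationCalls(x$report, "homoplasmic")),
              nrow(mutationCalls(x$report, "heteroplasmic")),
              x$config$frameLength, min(boxSizes(x$curve)),
              max(boxSizes(x$curve))))
  invisible(x)
}

#' Analyze a batch of subjects against one reference
#'
#' @param reference reference [NucleotideSequence-class]
#' @param subjects list of lists, each with `subjectId`, `calls` (CallTable
#'   or NULL) and `group`
#' @param config a [pipelineConfig()]
#' @return list of `SubjectResult`
#' @export
analyzeBatch <- function(reference, subjects, config = pipelineConfig()) {
  lapply(subjects, function(s) {
    analyzeSubject(reference, calls = s$calls, config = config,
                   subjectId = s$subjectId, group = s$group)
  })
}

#' Tabulate a list of subject results
#'
#' @param results list of `SubjectResult` (from [analyzeBatch()] or repeated
#'   [analyzeSubject()] calls)
#' @return data.frame with columns `subjectId`, `group`, `alpha`, `beta`,
#'   `gamma`, `nHomoplasmic`, `nHeteroplasmic`, `converged` — the input
#'   expected by [classifyByCutoff()]
#' @export
subjectTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(subjectId = r$subjectId, group = r$group,
               alpha = r$alpha, beta = r$beta, gamma = r$gamma,
               nHomoplasmic = nrow(mutationCalls(r$report, "homoplasmic")),
               nHeteroplasmic = nrow(mutationCalls(r$report, "heteroplasmic")),
               converged = converged(r$fit),
               stringsAsFactors = FALSE)
  }))
}
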