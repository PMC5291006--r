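#' One-tailed pooled-variance Student t-test
#'
#' Pooled-variance two-sample t with `df = n_a + n_b - 2`; the one-tailed
#' p-value is taken in the direction of the observed mean difference, so
#' identical groups give p = 0.5.
#'
#' @param valuesA,valuesB numeric vectors, each with at least 2 values
#' @return list with elements `t`, `p`, `df`
#' @export
tTestOneTail <- function(valuesA, valuesB) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  nA <- length(valuesA)
  nB <- length(valuesB)
  pooledVar <- ((nA - 1) * stats::var(valuesA) +
                (nB - 1) * stats::var(valuesB)) / (nA + nB - 2)
  if (pooledVar == 0) {
    if (mean(valuesA) == mean(valuesB))
      stop("zero pooled variance with equal means: t undefined", call. = FALSE)
    return(list(t = sign(mean(valuesA) - mean(valuesB)) * Inf, p = 0,
                df = nA + nB - 2))
  }
  alt <- if (mean(valuesA) >= mean(valuesB)) "greater" else "less"
  tt <- stats::t.test(valuesA, valuesB, var.equal = TRUE, alternative = alt)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Classify subjects by a beta cutoff and compare groups
#'
#' Subjects with fitted `beta <= cutoff` are labeled positive (disease-like:
#' a lower beta corresponds to a higher degree of mutated frames); ties at
#' the cutoff count as positive. With `cutoff = "median"` the threshold is
#' the median beta of the whole sample. Also runs the one-tailed pooled
#' t-test on beta between the two groups.
#'
#' @param results data.frame with columns `subjectId`, `group`
#'   (exactly two distinct labels) and `beta` (see [subjectTable()])
#' @param cutoff numeric threshold, or `"median"` (the default) for the
#'   whole-sample median
#' @param positiveGroup which group label counts as truly positive; defaults
#'   to the first group in order of appearance
#' @return a [CohortComparison-class]
#' @examples
#' df <- data.frame(subjectId = paste0("s", 1:4),
#'                  group = c("AD", "AD", "CTR", "CTR"),
#'                  beta = c(1, 2, 3, 4))
#' classifyByCutoff(df, cutoff = "median", positiveGroup = "AD")
#' @export
classifyByCutoff <- function(results, cutoff = "median",
                             positiveGroup = NULL) {
  req <- c("subjectId", "group", "beta")
  if (!all(req %in% names(results)))
    stop("results must have columns subjectId, group, beta", call. = FALSE)
  if (nrow(results) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  groups <- unique(as.character(results$group))
  if (length(groups) != 2L)
    stop(sprintf("exactly two groups required, found %d", length(groups)),
         call. = FALSE)
  if (is.null(positiveGroup)) positiveGroup <- groups[1]
  if (!(positiveGroup %in% groups))
    stop(sprintf("positiveGroup '%s' not among the group labels", positiveGroup),
         call. = FALSE)
  beta <- as.numeric(results$beta)
  if (!all(is.finite(beta)))
    stop("non-finite beta values", call. = FALSE)

  cut <- if (identical(cutoff, "median")) stats::median(beta)
         else as.numeric(cutoff)
  predictedPositive <- beta <= cut
  trulyPositive <- as.character(results$group) == positiveGroup
  confusion <- c(tp = sum(predictedPositive & trulyPositive),
                 fp = sum(predictedPositive & !trulyPositive),
                 tn = sum(!predictedPositive & !trulyPositive),
                 fn = sum(!predictedPositive & trulyPositive))

  byGroup <- split(beta, factor(as.character(results$group), levels = groups))
  means <- vapply(byGroup, mean, numeric(1))
  sds <- vapply(byGroup, stats::sd, numeric(1))
  ns <- vapply(byGroup, length, integer(1))
  tp <- if (all(ns >= 2)) {
    # degenerate (all-equal) samples leave the t-test undefined but the
    # classification itself still stands
    tryCatch(tTestOneTail(byGroup[[1]], byGroup[[2]]),
             error = function(e) list(t = NA_real_, p = NA_real_))
  } else list(t = NA_real_, p = NA_real_)

  new("CohortComparison",
      groupMeans = means, groupSds = sds,
      tStatistic = tp$t, pValue = tp$p,
      nPerGroup = ns, cutoff = cut,
      confusion = stats::setNames(as.integer(confusion), names(confusion)),
      positiveGroup = positiveGroup)
}
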