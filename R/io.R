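# Plain-text exchange formats for matrices, images, curves and fit reports:
# dense CSV for CGR matrices, ASCII (P2) PGM for image tooling, "b,lambda"
# CSV for curves, JSON for fits and reports.

#' Write / read a CGR matrix as dense CSV
#'
#' Row-major dense CSV, row 0 = top of the image; no header.
#'
#' @param m a [CGRMatrix-class] or numeric matrix
#' @param path file path
#' @param frameLength frame length to attach on read; inferred from the
#'   matrix side when NULL
#' @return `writeCgrCsv` returns `path` invisibly; `readCgrCsv` a
#'   [CGRMatrix-class]
#' @export
writeCgrCsv <- function(m, path) {
  px <- if (is(m, "CGRMatrix")) cgrValues(m) else m
  utils::write.table(px, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeCgrCsv
#' @export
readCgrCsv <- function(path, frameLength = NULL) {
  px <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(px) <- NULL
  if (is.null(frameLength)) {
    frameLength <- as.integer(round(log2(nrow(px))))
    if (2L^frameLength != nrow(px) || nrow(px) != ncol(px))
      stop("matrix is not 2^L square; pass frameLength explicitly",
           call. = FALSE)
  }
  new("CGRMatrix", values = px, frameLength = as.integer(frameLength),
      sourceName = basename(path))
}

#' Write / read a gray image as ASCII PGM (P2)
#'
#' Values are scaled linearly from `[0, max]` onto 16-bit gray levels
#' (maxval 65535). Reading reverses the scaling to `[0, 1]`.
#'
#' @param img numeric matrix (non-negative)
#' @param path file path
#' @return `writePgm` returns `path` invisibly; `readPgm` a numeric matrix
#'   in `[0, 1]`
#' @export
writePgm <- function(img, path) {
  px <- if (is(img, "CGRMatrix")) cgrValues(img) else img
  if (any(px < 0)) stop("PGM requires non-negative values", call. = FALSE)
  maxval <- 65535L
  hi <- max(px)
  lev <- if (hi == 0) matrix(0L, nrow(px), ncol(px))
         else matrix(as.integer(round(px / hi * maxval)), nrow(px), ncol(px))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(px), nrow(px)),
               as.character(maxval)), con)
  utils::write.table(lev, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePgm
#' @export
readPgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop("only ASCII (P2) PGM is supported", call. = FALSE)
  tokens <- as.numeric(unlist(strsplit(paste(lines[-1], collapse = " "),
                                       "[[:space:]]+")))
  tokens <- tokens[!is.na(tokens)]
  w <- tokens[1]
  h <- tokens[2]
  maxval <- tokens[3]
  px <- tokens[-(1:3)]
  if (length(px) != w * h) stop("truncated PGM", call. = FALSE)
  matrix(px / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write / read a lacunarity curve as CSV
#'
#' Two-column CSV with header `b,lambda`.
#'
#' @param curve a [LacunarityCurve-class]
#' @param path file path
#' @return `writeCurveCsv` returns `path` invisibly; `readCurveCsv` a
#'   data.frame with columns `b`, `lambda` (accepted by [fitHyperbola()])
#' @export
writeCurveCsv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writeCurveCsv
#' @export
readCurveCsv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("b", "lambda") %in% names(df)))
    stop("curve CSV must have columns b, lambda", call. = FALSE)
  df
}

#' Write a hyperbola fit as JSON
#'
#' @param fit a [HyperbolaFit-class]
#' @param path file path
#' @param subjectId,group optional labels stored alongside the parameters
#' @return `path`, invisibly
#' @export
writeFitJson <- function(fit, path, subjectId = NULL, group = NULL) {
  pars <- coef(fit)
  obj <- list(alpha = unname(pars["alpha"]), beta = unname(pars["beta"]),
              gamma = unname(pars["gamma"]),
              residual_norm = fit@residualNorm,
              converged = converged(fit), n_points = fit@nPoints)
  if (!is.null(subjectId)) obj$subject_id <- subjectId
  if (!is.null(group)) obj$group <- group
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Collect per-subject fit JSONs into a results table
#'
#' Reads every `*.json` fit in a directory (as written by [writeFitJson()])
#' and joins group labels from a two-column TSV `subject_id  group`.
#'
#' @param dir directory of fit JSON files
#' @param groupsPath TSV with header `subject_id  group`
#' @return data.frame accepted by [classifyByCutoff()]
#' @export
collectFits <- function(dir, groupsPath) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0) stop("no .json fits found", call. = FALSE)
  rows <- lapply(files, function(f) {
    x <- jsonlite::read_json(f, simplifyVector = TRUE)
    data.frame(subjectId = if (!is.null(x$subject_id)) x$subject_id
                           else sub("\\.json$", "", basename(f)),
               alpha = x$alpha, beta = x$beta, gamma = x$gamma,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  groups <- utils::read.delim(groupsPath, colClasses = "character")
  if (!all(c("subject_id", "group") %in% names(groups)))
    stop("groups TSV must have columns subject_id, group", call. = FALSE)
  idx <- match(df$subjectId, groups$subject_id)
  if (anyNA(idx))
    stop(sprintf("no group label for subject(s): %s",
                 paste(df$subjectId[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  df$group <- groups$group[idx]
  df[, c("subjectId", "group", "alpha", "beta", "gamma")]
}

#' Write a mutation report as JSON
#'
#' @param report a [MutationReport-class]
#' @param path file path
#' @return `path`, invisibly
#' @export
writeReportJson <- function(report, path) {
  obj <- list(counts = as.list(baseCounts(report)),
              sequence_length = report@sequenceLength,
              n_homoplasmic = nrow(mutationCalls(report, "homoplasmic")),
              n_heteroplasmic = nrow(mutationCalls(report, "heteroplasmic")),
              homoplasmic = mutationCalls(report, "homoplasmic"),
              heteroplasmic = mutationCalls(report, "heteroplasmic"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
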