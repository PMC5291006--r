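# Chaos Game Representation: recursive quadrant addressing of k-mers with
# weighted expansion of degenerate (heteroplasmic) symbols.

# base layout M_1 = [[a, c], [g, t]]: row 0 = top
.ROW_BIT <- c(a = 0L, c = 0L, g = 1L, t = 1L)
.COL_BIT <- c(a = 0L, c = 1L, g = 0L, t = 1L)

#' Expand a substring with degenerate symbols into weighted pure strings
#'
#' Every degenerate IUPAC symbol is resolved into its candidate bases; the
#' Cartesian product over all positions gives the set of pure strings, each
#' carrying weight 1/(number of strings), so the weights always sum to 1.
#' For example `"tamcg"` expands to `"taacg"` and `"taccg"` with weight 1/2
#' each, and `"tavcg"` to three strings with weight 1/3.
#'
#' @param s substring (lowercase IUPAC)
#' @param maxExpansions error beyond this many generated strings
#'   (default `4^6`, i.e. six fully undetermined positions)
#' @return data.frame with columns `string` and `weight`
#' @export
expandAmbiguous <- function(s, maxExpansions = 4096L) {
  chars <- strsplit(tolower(s), "", fixed = TRUE)[[1]]
  .validateSymbols(chars, what = "substring")
  opts <- .IUPAC_EXPAND[chars]
  nExp <- prod(lengths(opts))
  if (nExp > maxExpansions)
    stop(sprintf("substring expands to %d strings (cap %d)", nExp,
                 maxExpansions), call. = FALSE)
  if (nExp == 1)
    return(data.frame(string = paste(chars, collapse = ""), weight = 1,
                      stringsAsFactors = FALSE))
  grid <- expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, rev(seq_along(opts)),
                                                drop = FALSE]
  strings <- do.call(paste0, grid)
  data.frame(string = strings, weight = rep(1 / nExp, nExp),
             stringsAsFactors = FALSE)
}

#' CGR cell address of a pure substring
#'
#' Recursive quadrant addressing: the first symbol selects the coarsest
#' quadrant, each following symbol a sub-quadrant, with base layout
#' `a` top-left, `c` top-right, `g` bottom-left, `t` bottom-right.
#'
#' @param s pure substring over a/c/g/t
#' @return integer vector `c(row, col)`, 0-based, in `[0, 2^L)`
#' @examples
#' substringPosition("ca")  # c(0, 2)
#' @export
substringPosition <- function(s) {
  chars <- strsplit(tolower(s), "", fixed = TRUE)[[1]]
  if (any(!(chars %in% .PURE_BASES)))
    stop("degenerate symbol: expand with expandAmbiguous() first", call. = FALSE)
  L <- length(chars)
  pow <- 2L^(L - seq_len(L))
  c(row = sum(.ROW_BIT[chars] * pow), col = sum(.COL_BIT[chars] * pow))
}

#' Weighted CGR matrix of a sequence
#'
#' Slides a length-`L` window along the sequence (stride 1, linear by
#' default); each window adds mass 1 at its cell, split across the cells of
#' its pure expansions when the window contains degenerate symbols. Total
#' mass therefore equals the number of windows, `length(seq) - L + 1`
#' (`length(seq)` with `circular = TRUE`).
#'
#' @param seq a [NucleotideSequence-class] (or a plain string)
#' @param L frame length, 1..12
#' @param circular also count the windows that wrap around the end
#'   (off by default; the contribution is immaterial for a 16.5 kb genome
#'   at small L)
#' @param maxExpansions per-window expansion cap, see [expandAmbiguous()]
#' @return a [CGRMatrix-class]
#' @examples
#' cgrMatrix(ntSequence("acgtacgt"), L = 1)
#' @export
cgrMatrix <- function(seq, L, circular = FALSE, maxExpansions = 4096L) {
  if (is.character(seq)) seq <- ntSequence(seq)
  stopifnot(is(seq, "NucleotideSequence"))
  L <- as.integer(L)
  if (L < 1L || L > 12L)
    stop("frame length L must be in [1, 12]", call. = FALSE)
  chars <- strsplit(seq@symbols, "", fixed = TRUE)[[1]]
  n0 <- length(chars)
  if (L > n0) stop("frame length exceeds sequence length", call. = FALSE)
  if (circular && L > 1L) chars <- c(chars, chars[seq_len(L - 1L)])
  n <- length(chars)
  nWin <- n - L + 1L

  rb <- unname(.ROW_BIT[chars])  # NA at degenerate symbols
  cb <- unname(.COL_BIT[chars])
  side <- 2L^L
  rows <- numeric(nWin)
  cols <- numeric(nWin)
  for (j in seq_len(L)) {
    p <- 2^(L - j)
    idx <- seq_len(nWin) + j - 1L
    rows <- rows + rb[idx] * p
    cols <- cols + cb[idx] * p
  }
  lin <- rows * side + cols + 1  # row-major linear index, NA if ambiguous

  acc <- numeric(side * side)
  pure <- !is.na(lin)
  if (any(pure)) {
    tab <- tabulate(lin[pure], nbins = side * side)
    acc <- acc + tab
  }
  for (i in which(!pure)) {
    ex <- expandAmbiguous(paste(chars[i:(i + L - 1L)], collapse = ""),
                          maxExpansions = maxExpansions)
    for (k in seq_len(nrow(ex))) {
      pos <- substringPosition(ex$string[k])
      acc[pos[1] * side + pos[2] + 1] <- acc[pos[1] * side + pos[2] + 1] +
        ex$weight[k]
    }
  }
  new("CGRMatrix", values = matrix(acc, nrow = side, ncol = side, byrow = TRUE),
      frameLength = L, sourceName = seq@name)
}

#' Per-sequence mutation and composition report
#'
#' Summarizes a processed sequence the way each CGR run reports it: the
#' base composition of the mutated sequence (degenerate symbols contribute
#' fractionally, so the four counts sum to the sequence length) and the
#' homoplasmic/heteroplasmic calls with their positions.
#'
#' @param reference reference [NucleotideSequence-class]
#' @param calls CallTable used to derive `mutated` (may be NULL or empty)
#' @param mutated the reconstructed sequence; defaults to
#'   `applyCalls(reference, calls)`
#' @return a [MutationReport-class]
#' @export
mutationReport <- function(reference, calls = NULL,
                           mutated = applyCalls(reference, calls)) {
  stopifnot(is(mutated, "NucleotideSequence"))
  chars <- strsplit(mutated@symbols, "", fixed = TRUE)[[1]]
  counts <- colSums(.BASE_FRACTION[match(chars, .IUPAC_LETTERS), , drop = FALSE])
  if (is.null(calls) || nrow(calls) == 0) {
    empty <- data.frame(position = integer(), ref_base = character(),
                        call = character(), stringsAsFactors = FALSE)
    homo <- hetero <- empty
  } else {
    cls <- classifyCalls(calls)
    cols <- c("position", "ref_base", "call")
    homo <- calls[cls == "homoplasmic", cols, drop = FALSE]
    hetero <- calls[cls == "heteroplasmic", cols, drop = FALSE]
    rownames(homo) <- rownames(hetero) <- NULL
  }
  new("MutationReport", counts = counts, sequenceLength = length(chars),
      homoplasmic = homo, heteroplasmic = hetero)
}
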