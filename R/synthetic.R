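# Synthetic fixtures: random sequences with controlled composition,
# homoplasmic/heteroplasmic call tables, and the deterministic/random test
# images (Sierpinski carpet, Bernoulli noise) with known lacunarity.

# default base probabilities: published rCRS composition
# (A/C/G/T = 5124/5181/2169/4094 of 16569)
.RCRS_BASE_PROBS <- c(a = 5124, c = 5181, g = 2169, t = 4094) / 16568

#' Random nucleotide sequence with configurable composition
#'
#' I.i.d. draws from `baseProbs`, optionally with forbidden dinucleotides
#' (e.g. `"cg"` to emulate CpG depletion): any occurrence is resolved by
#' redrawing the second base from the bases still allowed after the
#' preceding one, until no forbidden pair remains.
#'
#' @param length sequence length (>= 1)
#' @param baseProbs probabilities for a, c, g, t (must sum to 1); the
#'   default is the human mtDNA reference composition
#' @param forbiddenDinucleotides character vector of 2-mers that must not
#'   occur
#' @param seed integer seed for reproducibility (NULL leaves the RNG alone)
#' @param name sequence name
#' @return a [NucleotideSequence-class]
#' @export
randomSequence <- function(length, baseProbs = .RCRS_BASE_PROBS,
                           forbiddenDinucleotides = character(),
                           seed = NULL, name = "synthetic") {
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  baseProbs <- as.numeric(baseProbs)
  if (length(baseProbs) != 4L || any(baseProbs < 0) ||
      abs(sum(baseProbs) - 1) > 1e-12)
    stop("baseProbs must be 4 non-negative values summing to 1", call. = FALSE)
  forbiddenDinucleotides <- tolower(forbiddenDinucleotides)
  # feasibility: every usable first base must leave a usable second base
  usable <- .PURE_BASES[baseProbs > 0]
  for (first in usable) {
    allowed <- usable[!(paste0(first, usable) %in% forbiddenDinucleotides)]
    if (length(allowed) == 0)
      stop(sprintf("infeasible constraints: no base may follow '%s'", first),
           call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  chars <- sample(.PURE_BASES, length, replace = TRUE, prob = baseProbs)
  if (length(forbiddenDinucleotides) > 0 && length > 1L) {
    repeat {
      pairs <- paste0(chars[-length], chars[-1])
      bad <- which(pairs %in% forbiddenDinucleotides) + 1L
      if (length(bad) == 0) break
      for (i in bad) {
        allowed <- .PURE_BASES[baseProbs > 0 &
          !(paste0(chars[i - 1L], .PURE_BASES) %in% forbiddenDinucleotides)]
        p <- baseProbs[match(allowed, .PURE_BASES)]
        chars[i] <- if (length(allowed) == 1L) allowed
                    else sample(allowed, 1L, prob = p)
      }
    }
  }
  new("NucleotideSequence", symbols = paste(chars, collapse = ""),
      name = name)
}

#' Inject homoplasmic and heteroplasmic calls into a sequence
#'
#' Picks distinct positions (among those whose reference base is a plain
#' a/c/g/t). A homoplasmic row replaces the reference base with a uniformly
#' chosen different base; a heteroplasmic row uses the two-fold IUPAC symbol
#' containing the reference base and one uniformly chosen other base, as a
#' biological heteroplasmy is a mixture of reference and mutant molecules.
#'
#' @param seq reference [NucleotideSequence-class]
#' @param nHomoplasmic,nHeteroplasmic how many calls of each class
#' @param seed integer seed (NULL leaves the RNG alone)
#' @return a CallTable data.frame, positions sorted
#' @export
injectMutations <- function(seq, nHomoplasmic, nHeteroplasmic, seed = NULL) {
  stopifnot(is(seq, "NucleotideSequence"))
  nHomoplasmic <- as.integer(nHomoplasmic)
  nHeteroplasmic <- as.integer(nHeteroplasmic)
  if (nHomoplasmic < 0L || nHeteroplasmic < 0L)
    stop("mutation counts must be >= 0", call. = FALSE)
  total <- nHomoplasmic + nHeteroplasmic
  if (total == 0L)
    return(callTable())
  chars <- strsplit(seq@symbols, "", fixed = TRUE)[[1]]
  purePos <- which(chars %in% .PURE_BASES)
  if (total > length(purePos))
    stop(sprintf("requested %d mutations but only %d mutable positions",
                 total, length(purePos)), call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pos <- sample(purePos, total)
  ref <- chars[pos]
  call <- character(total)
  for (i in seq_len(total)) {
    other <- sample(setdiff(.PURE_BASES, ref[i]), 1L)
    call[i] <- if (i <= nHomoplasmic) other
               else .TWOFOLD_CODE[paste(sort(c(ref[i], other)), collapse = "")]
  }
  callTable(position = pos, ref_base = ref, call = call)
}

#' Sierpinski carpet test image
#'
#' Binary `3^depth x 3^depth` image: starting from a filled square, the
#' center ninth is removed recursively, leaving total mass `8^depth`. The
#' canonical known-lacunarity fixture, exactly representable on a square
#' pixel grid.
#'
#' @param depth recursion depth, 1..6
#' @return binary numeric matrix
#' @export
sierpinskiCarpet <- function(depth) {
  depth <- as.integer(depth)
  if (depth < 1L || depth > 6L) stop("depth must be in [1, 6]", call. = FALSE)
  block <- matrix(1, 3, 3)
  block[2, 2] <- 0
  img <- matrix(1, 1, 1)
  for (d in seq_len(depth)) img <- kronecker(block, img)
  img
}

#' Bernoulli random binary image
#'
#' I.i.d. pixels equal to 1 with probability `p`. On such images the
#' gliding-box lacunarity has the closed form
#' `Lambda(b) -> 1 + (1 - p) / (p * b^2)` as the image grows, which makes
#' them the analytic oracle for the lacunarity engine.
#'
#' @param h,w image dimensions
#' @param p success probability, strictly between 0 and 1
#' @param seed integer seed (NULL leaves the RNG alone)
#' @return binary numeric matrix
#' @export
bernoulliImage <- function(h, w, p, seed = NULL) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  matrix(stats::rbinom(h * w, 1L, p), nrow = h, ncol = w)
}
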