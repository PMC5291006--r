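# IUPAC nucleotide ambiguity tables (lowercase). Heteroplasmic calls arrive as
# degenerate symbols; every routine that touches sequence content funnels
# through these maps.

.IUPAC_EXPAND <- list(
  a = "a", c = "c", g = "g", t = "t",
  r = c("a", "g"), y = c("c", "t"), s = c("c", "g"), w = c("a", "t"),
  k = c("g", "t"), m = c("a", "c"),
  b = c("c", "g", "t"), d = c("a", "g", "t"), h = c("a", "c", "t"),
  v = c("a", "c", "g"),
  n = c("a", "c", "g", "t")
)

.IUPAC_LETTERS <- names(.IUPAC_EXPAND)

.PURE_BASES <- c("a", "c", "g", "t")

# two-fold code for an unordered base pair, keyed by sorted concatenation
.TWOFOLD_CODE <- c(ac = "m", ag = "r", at = "w", cg = "s", ct = "y", gt = "k")

# 15 x 4 fractional base contribution of each symbol (rows in .IUPAC_LETTERS
# order); an ambiguous symbol spreads unit mass uniformly over its candidates
.BASE_FRACTION <- local({
  m <- matrix(0, nrow = length(.IUPAC_EXPAND), ncol = 4,
              dimnames = list(.IUPAC_LETTERS, .PURE_BASES))
  for (sym in .IUPAC_LETTERS) {
    m[sym, .IUPAC_EXPAND[[sym]]] <- 1 / length(.IUPAC_EXPAND[[sym]])
  }
  m
})

.validateSymbols <- function(chars, what = "sequence") {
  bad <- which(!(chars %in% .IUPAC_LETTERS))
  if (length(bad) > 0) {
    stop(sprintf("illegal symbol '%s' in %s at position %d",
                 chars[bad[1]], what, bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

.isDegenerate <- function(chars) {
  !(chars %in% .PURE_BASES)
}
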