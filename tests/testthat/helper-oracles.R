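# Independent oracles, deliberately naive: these re-derive expected values by
# brute force and never share code with the implementation they check.

# naive gliding-box masses: explicit double loop over placements
naiveBoxMasses <- function(px, b) {
  H <- nrow(px)
  W <- ncol(px)
  out <- numeric((H - b + 1) * (W - b + 1))
  k <- 0L
  for (i in seq_len(H - b + 1)) {
    for (j in seq_len(W - b + 1)) {
      k <- k + 1L
      out[k] <- sum(px[i:(i + b - 1), j:(j + b - 1)])
    }
  }
  out
}

naiveLacunarity <- function(px, b) {
  m <- naiveBoxMasses(px, b)
  mean(m^2) / mean(m)^2
}

# brute-force k-mer counts of a pure sequence (linear windows)
bruteKmerCounts <- function(symbols, L) {
  chars <- strsplit(symbols, "", fixed = TRUE)[[1]]
  n <- length(chars)
  kmers <- vapply(seq_len(n - L + 1),
                  function(i) paste(chars[i:(i + L - 1)], collapse = ""),
                  character(1))
  table(kmers)
}

# random IUPAC sequence: pure backbone with degenerate symbols sprinkled in
randomIupacSymbols <- function(n, ambProb = 0.01) {
  degenerate <- c("r", "y", "s", "w", "k", "m", "b", "d", "h", "v", "n")
  chars <- sample(c("a", "c", "g", "t"), n, replace = TRUE)
  nAmb <- rbinom(1, n, ambProb)
  if (nAmb > 0) {
    pos <- sample(n, nAmb)
    chars[pos] <- sample(degenerate, nAmb, replace = TRUE)
  }
  paste(chars, collapse = "")
}

# brute-force Cartesian resolution of an IUPAC string (independent of
# expandAmbiguous): recursive prepend
bruteExpand <- function(s) {
  map <- list(a = "a", c = "c", g = "g", t = "t",
              r = c("a", "g"), y = c("c", "t"), s = c("c", "g"),
              w = c("a", "t"), k = c("g", "t"), m = c("a", "c"),
              b = c("c", "g", "t"), d = c("a", "g", "t"),
              h = c("a", "c", "t"), v = c("a", "c", "g"),
              n = c("a", "c", "g", "t"))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- ""
  for (ch in chars) out <- as.vector(outer(out, map[[ch]], paste0))
  sort(out)
}
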