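#' Construct a NucleotideSequence
#'
#' @param symbols single string over the lowercase IUPAC alphabet (uppercase
#'   input is folded; 'u' is mapped to 't')
#' @param name sequence identifier
#' @return a [NucleotideSequence-class]
#' @examples
#' ntSequence("acgt")
#' ntSequence("acmgt", name = "het-example")
#' @export
ntSequence <- function(symbols, name = "sequence") {
  symbols <- tolower(symbols)
  symbols <- gsub("u", "t", symbols, fixed = TRUE)
  new("NucleotideSequence", symbols = symbols, name = as.character(name))
}

#' Read a single-record FASTA file
#'
#' Reads the first record of a FASTA file (with a warning if more are
#' present), lowercases it, maps 'u' to 't' and validates every symbol
#' against the IUPAC alphabet.
#'
#' @param path FASTA file
#' @return a [NucleotideSequence-class]
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records found", call. = FALSE)
  if (length(set) > 1)
    warning(sprintf("%d records in %s; using the first", length(set), path))
  s <- tolower(as.character(set[[1]]))
  if (nchar(s) == 0) stop("empty FASTA record", call. = FALSE)
  s <- gsub("u", "t", s, fixed = TRUE)
  .validateSymbols(strsplit(s, "", fixed = TRUE)[[1]], what = basename(path))
  nm <- names(set)[1]
  if (is.null(nm) || is.na(nm) || nm == "") nm <- "sequence"
  new("NucleotideSequence", symbols = s, name = nm)
}

#' Write a NucleotideSequence to FASTA
#'
#' @param seq a [NucleotideSequence-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFasta <- function(seq, path) {
  stopifnot(is(seq, "NucleotideSequence"))
  set <- Biostrings::BStringSet(stats::setNames(seq@symbols, seq@name))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a per-subject call table
#'
#' The exchange format for resequencing calls is a minimal 3-column TSV with
#' header `position  ref_base  call`: 1-based nucleotide position, the
#' reference symbol there, and the called symbol (a plain base for a
#' homoplasmic substitution, a degenerate IUPAC code for a heteroplasmic
#' call, or the reference base itself for an identity row).
#'
#' @param path TSV file
#' @return data.frame with columns `position`, `ref_base`, `call` (a
#'   CallTable); positions are unique, symbols lowercase IUPAC
#' @export
readCallTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", strip.white = TRUE)
  if (!identical(names(df), c("position", "ref_base", "call")))
    stop("call table header must be 'position\tref_base\tcall'", call. = FALSE)
  callTable(position = suppressWarnings(as.integer(df$position)),
            ref_base = tolower(df$ref_base),
            call = tolower(df$call))
}

#' Construct a call table in memory
#'
#' @param position integer vector of 1-based positions
#' @param ref_base reference symbols at those positions
#' @param call called symbols (IUPAC; degenerate codes mark heteroplasmy)
#' @return validated CallTable data.frame
#' @export
callTable <- function(position = integer(), ref_base = character(),
                      call = character()) {
  if (length(position) != length(ref_base) || length(position) != length(call))
    stop("position, ref_base and call must have equal length", call. = FALSE)
  position <- as.integer(position)
  ref_base <- tolower(as.character(ref_base))
  call <- tolower(as.character(call))
  if (anyNA(position) || any(position < 1L))
    stop("malformed call table: positions must be positive integers", call. = FALSE)
  dup <- duplicated(position)
  if (any(dup))
    stop(sprintf("duplicate position(s) in call table: %s",
                 paste(unique(position[dup]), collapse = ", ")), call. = FALSE)
  .validateSymbols(ref_base, what = "call table ref_base")
  .validateSymbols(call, what = "call table call")
  df <- data.frame(position = position, ref_base = ref_base, call = call,
                   stringsAsFactors = FALSE)
  df[order(df$position), , drop = FALSE]
}

#' Write a call table to TSV
#'
#' @param calls a CallTable data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
writeCallTable <- function(calls, path) {
  utils::write.table(calls[, c("position", "ref_base", "call")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify call-table rows
#'
#' A row is homoplasmic when the call is a plain base different from the
#' reference (the substitution is carried by all mtDNA copies), heteroplasmic
#' when the call is a degenerate IUPAC symbol other than the reference (a
#' mixture of molecules), and an identity row when call equals ref_base.
#'
#' @param calls a CallTable data.frame
#' @return character vector, one of "identity", "homoplasmic", "heteroplasmic"
#' @export
classifyCalls <- function(calls) {
  cls <- rep("identity", nrow(calls))
  same <- calls$call == calls$ref_base
  pure <- calls$call %in% .PURE_BASES
  cls[!same & pure] <- "homoplasmic"
  cls[!same & !pure] <- "heteroplasmic"
  cls
}

#' Apply calls to a reference sequence
#'
#' Reconstructs a subject's mtDNA sequence: each called position's symbol in
#' the reference is replaced by the called symbol. Every row's `ref_base`
#' must match the reference; all mismatches are reported at once.
#'
#' @param reference a [NucleotideSequence-class]
#' @param calls a CallTable data.frame (may be empty)
#' @return a new [NucleotideSequence-class], same length as the reference
#' @examples
#' ref <- ntSequence("acgt")
#' applyCalls(ref, callTable(2, "c", "m"))
#' @export
applyCalls <- function(reference, calls) {
  stopifnot(is(reference, "NucleotideSequence"))
  chars <- strsplit(reference@symbols, "", fixed = TRUE)[[1]]
  if (is.null(calls) || nrow(calls) == 0)
    return(new("NucleotideSequence", symbols = reference@symbols,
               name = reference@name))
  if (any(calls$position > length(chars)))
    stop(sprintf("call position(s) beyond reference length %d: %s",
                 length(chars),
                 paste(calls$position[calls$position > length(chars)],
                       collapse = ", ")), call. = FALSE)
  mism <- which(chars[calls$position] != calls$ref_base)
  if (length(mism) > 0) {
    msg <- paste(sprintf("position %d: table says '%s', reference has '%s'",
                         calls$position[mism], calls$ref_base[mism],
                         chars[calls$position[mism]]), collapse = "; ")
    stop(sprintf("ref_base mismatch — %s", msg), call. = FALSE)
  }
  chars[calls$position] <- calls$call
  new("NucleotideSequence", symbols = paste(chars, collapse = ""),
      name = reference@name)
}
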