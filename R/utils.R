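# Sequence and coordinate helpers shared across modules.  All sequences are
# DNA (ACGTN, uppercase); RNA-world inputs are converted with U -> T at the
# boundary so a single alphabet flows through the package.

#' Reverse complement of DNA strings
#'
#' Vectorised, N-aware reverse complement over the ACGTN alphabet.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' revcomp("ATGC")   # "GCAT"
#' revcomp(c("AAA", "ACGTN"))
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# Uppercase, convert U -> T and reject anything outside ACGTN.  `what` names
# the offending input in error messages.
normalize_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside ACGTN (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  x
}

# BED half-open [start, end) <-> GTF 1-based closed [first, last].  Internal
# arithmetic is 0-based half-open; these are the only conversion points.
bed_to_gtf <- function(start, end) cbind(first = start + 1L, last = end)
gtf_to_bed <- function(first, last) cbind(start = first - 1L, end = last)

# Count of (possibly overlapping) occurrences of `word` in `s`.
count_occurrences <- function(word, s) {
  n <- nchar(s)
  w <- nchar(word)
  if (is.na(s) || n < w || w == 0L) return(0L)
  sum(substring(s, seq_len(n - w + 1L), seq.int(w, n)) == word)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
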