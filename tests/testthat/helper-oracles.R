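# Independent oracles and small builders shared across test files.
# Oracles deliberately avoid the code paths they check.

# Biostrings-backed reverse complement (oracle for circshrna::revcomp and
# for strand handling in sequence extraction).
bs_revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Exhaustive-enumeration hypergeometric upper tail: draw every size-n
# subset of {1..N} with elements 1..K marked, and count subsets holding at
# least k marked.  Feasible for N <= 12.
enum_hyper_upper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# Brute-force longest common substring by trying every substring of `a`
# (independent of the package's DP implementation).
brute_lcs <- function(a, b) {
  na <- nchar(a)
  for (len in na:1) {
    for (s in 1:(na - len + 1)) {
      if (grepl(substring(a, s, s + len - 1), b, fixed = TRUE)) return(len)
    }
  }
  0L
}

# iid random DNA under a local seed, leaving the global RNG alone
rdna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# single-chromosome genome with one single-exon circle, both strands
toy_circle_genome <- function(circle, flank = 30L, strand = "+", seed = 99L) {
  left <- rdna(flank, seed)
  right <- rdna(flank, seed + 1L)
  n <- nchar(circle)
  plus_insert <- if (strand == "+") circle else bs_revcomp(circle)
  genome <- c(chr1 = paste0(left, plus_insert, right))
  circ <- circ_model("circT", "chr1", strand, start = flank, end = flank + n)
  list(genome = genome, circ = circ)
}
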