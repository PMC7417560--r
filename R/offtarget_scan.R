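# Perfect-complementarity off-target scanning and seed-site counting.
#
# "Complementary" is contiguous Watson-Crick pairing, no wobble, no gaps:
# a stretch of k complementary bases between guide and transcript is
# exactly a shared k-substring between revcomp(guide) (the target-sense
# sequence) and the transcript.  The scanner is a k-mer seed-and-extend;
# longest_complementary_stretch() is the quadratic oracle kept alongside
# it for dual-route testing.

#' Longest perfect complementary stretch between a guide and a transcript
#'
#' Dynamic-programming longest common substring between `revcomp(guide)`
#' and `transcript`, i.e. the length of the longest run of contiguous
#' Watson-Crick pairs the guide can form with the transcript.
#'
#' @param guide guide DNA string (antisense to its target).
#' @param transcript transcript DNA string (sense).
#' @return integer stretch length (0 when nothing pairs).
#' @export
longest_complementary_stretch <- function(guide, transcript) {
  stopifnot(nzchar(guide), nzchar(transcript))
  a <- strsplit(revcomp(guide), "", fixed = TRUE)[[1]]
  b <- strsplit(transcript, "", fixed = TRUE)[[1]]
  nb <- length(b)
  prev <- integer(nb)
  best <- 0L
  for (i in seq_along(a)) {
    hit <- b == a[i]
    cur <- integer(nb)
    cur[hit] <- c(0L, prev[-nb])[hit] + 1L
    m <- max(cur)
    if (m > best) best <- m
    prev <- cur
  }
  best
}

# All maximal shared substrings of length >= k between `tsense` and `seq`,
# via k-mer seeding on `seq` and bidirectional extension.  Returns a matrix
# with columns a_start, b_start, len (1-based starts).
maximal_shared_substrings <- function(tsense, seq, k) {
  na <- nchar(tsense)
  nb <- nchar(seq)
  if (na < k || nb < k) return(NULL)
  b_starts <- seq_len(nb - k + 1L)
  b_kmers <- substring(seq, b_starts, b_starts + k - 1L)
  achars <- strsplit(tsense, "", fixed = TRUE)[[1]]
  bchars <- strsplit(seq, "", fixed = TRUE)[[1]]
  seen <- NULL
  for (ia in seq_len(na - k + 1L)) {
    ibs <- which(b_kmers == substring(tsense, ia, ia + k - 1L))
    for (ib in ibs) {
      # extend the seeded k-mer maximally in both directions
      s_a <- ia; s_b <- ib
      while (s_a > 1L && s_b > 1L && achars[s_a - 1L] == bchars[s_b - 1L]) {
        s_a <- s_a - 1L; s_b <- s_b - 1L
      }
      e_a <- ia + k - 1L; e_b <- ib + k - 1L
      while (e_a < na && e_b < nb && achars[e_a + 1L] == bchars[e_b + 1L]) {
        e_a <- e_a + 1L; e_b <- e_b + 1L
      }
      seen <- rbind(seen, c(a_start = s_a, b_start = s_b, len = e_a - s_a + 1L))
    }
  }
  if (is.null(seen)) return(NULL)
  unique(seen)
}

#' Scan transcripts for perfect complementary stretches to a guide
#'
#' Reports one hit per maximal run of at least `min_len` contiguous
#' complementary bases between the guide and a transcript; per transcript,
#' hits are sorted longest first.  The default threshold of 12 nt reflects
#' the shortest complementarity reported to suffice for slicing.
#'
#' @param guide guide DNA string.
#' @param transcripts either a named character vector of transcript
#'   sequences (names = transcript ids, gene ids taken equal), or a
#'   data.frame with columns `transcript_id`, `gene_id`, `sequence`.
#' @param min_len minimum stretch length (nt).  Values below 8 trigger a
#'   cost warning but are allowed.
#' @param guide_id identifier recorded on the hits.
#' @return data.frame of class `offtarget_hits` with columns guide_id,
#'   transcript_id, gene_id, match_length, guide_offset, transcript_offset
#'   (offsets 0-based; guide_offset on the target-sense sequence).
#' @export
scan_offtargets <- function(guide, transcripts, min_len = 12L,
                            guide_id = "guide") {
  stopifnot(nzchar(guide))
  min_len <- as.integer(min_len)
  if (min_len > nchar(guide)) {
    stop("min_len exceeds guide length", call. = FALSE)
  }
  if (min_len < 8L) {
    warning("min_len < 8 nt: scan may be slow and hits unspecific",
            call. = FALSE)
  }
  if (is.character(transcripts)) {
    stopifnot(!is.null(names(transcripts)))
    transcripts <- data.frame(transcript_id = names(transcripts),
                              gene_id = names(transcripts),
                              sequence = unname(transcripts),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("transcript_id", "gene_id", "sequence") %in%
                  names(transcripts)))
  tsense <- revcomp(guide)
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    mm <- maximal_shared_substrings(tsense, transcripts$sequence[i], min_len)
    if (is.null(mm)) return(NULL)
    mm <- mm[order(-mm[, "len"], mm[, "b_start"]), , drop = FALSE]
    data.frame(guide_id = guide_id,
               transcript_id = transcripts$transcript_id[i],
               gene_id = transcripts$gene_id[i],
               match_length = as.integer(mm[, "len"]),
               guide_offset = as.integer(mm[, "a_start"] - 1L),
               transcript_offset = as.integer(mm[, "b_start"] - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty_hits())))
  class(out) <- c("offtarget_hits", "data.frame")
  out
}

empty_hits <- function() {
  data.frame(guide_id = character(0), transcript_id = character(0),
             gene_id = character(0), match_length = integer(0),
             guide_offset = integer(0), transcript_offset = integer(0),
             stringsAsFactors = FALSE)
}

#' Guide and star (passenger) seed specifications of a design
#'
#' The seed is nucleotides 2-8 (a 7-mer) of each strand; the site sought
#' in 3' UTRs is the seed's reverse complement.
#'
#' @param d an `shrna_design` (needs fields `guide` and `passenger`).
#' @return data.frame with columns source ("guide"/"star"), seed, site.
#' @export
extract_seeds <- function(d) {
  stopifnot(nchar(d$guide) >= 8L, nchar(d$passenger) >= 8L)
  seeds <- c(guide = substring(d$guide, 2L, 8L),
             star = substring(d$passenger, 2L, 8L))
  data.frame(source = names(seeds), seed = unname(seeds),
             site = revcomp(unname(seeds)), stringsAsFactors = FALSE)
}

#' Count seed-site occurrences in 3' UTRs
#'
#' Sliding-window counts (overlapping occurrences included) of each spec's
#' site in each gene's UTR.
#'
#' @param specs data.frame from [extract_seeds()] (columns source, site).
#' @param utrs named character vector, gene_id -> UTR sequence.
#' @return integer matrix, genes x specs (rownames gene ids, colnames spec
#'   sources).
#' @export
count_seed_matches <- function(specs, utrs) {
  stopifnot(all(c("source", "site") %in% names(specs)))
  out <- vapply(specs$site, function(site) {
    vapply(utrs, function(u) count_occurrences(site, u), integer(1))
  }, integer(length(utrs)))
  out <- matrix(out, nrow = length(utrs),
                dimnames = list(names(utrs), specs$source))
  out
}
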