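# Readers, writers and sequence extraction for the package's four input
# kinds: genome FASTA, circRNA BED, transcript GTF, and DE result TSV.
#
# Coordinate conventions (fixed package-wide):
#   * BED inputs stay 0-based half-open; circ_model stores them unchanged.
#   * GTF inputs stay 1-based closed; transcript_model stores them unchanged.
#   * Conversions go through bed_to_gtf()/gtf_to_bed() only.

## ---- genome FASTA -----------------------------------------------------

#' Read a genome (or transcriptome) FASTA file
#'
#' Sequences are uppercased, U is converted to T, and any character outside
#' ACGTN is rejected with the offending line number.  Duplicate headers are
#' an error.  The first whitespace-delimited word of each header is used as
#' the sequence name.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one uppercase DNA string per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgu"), fa)
#' read_genome(fa)  # c(chr1 = "ACGT")
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    stop(sprintf("malformed FASTA: sequence before first header at line %d",
                 line_no[1]), call. = FALSE)
  }
  bad <- !is_header & grepl("[^ACGTUNacgtun]", lines)
  if (any(bad)) {
    stop(sprintf("malformed FASTA: invalid sequence character at line %d",
                 line_no[which(bad)[1]]), call. = FALSE)
  }
  names_raw <- sub("^>\\s*", "", lines[is_header])
  nm <- vapply(strsplit(names_raw, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  rec <- cumsum(is_header)
  seqs <- vapply(split(lines[!is_header], rec[!is_header]),
                 paste, character(1), collapse = "")
  out <- character(length(nm))
  names(out) <- nm
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out))) {
    stop("empty sequence for header: ", nm[!nzchar(out)][1], call. = FALSE)
  }
  normalize_dna(out, what = paste0("FASTA ", path))
}

#' Write named DNA strings as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## ---- circRNA models (BED) ---------------------------------------------

#' Construct a circRNA model
#'
#' A circle is defined by its back-splice span on the genome: the interval
#' from the back-splice acceptor (5' end of the first circularised exon) to
#' the back-splice donor (3' end of the last), in BED 0-based half-open
#' coordinates.  Optional exon blocks subdivide the span; by default the
#' whole span is one exon.
#'
#' @param circ_id circle identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end span, 0-based half-open.
#' @param exons optional integer matrix with columns `start`, `end`
#'   (0-based half-open), sorted, non-overlapping, with the first exon
#'   starting at `start` and the last ending at `end`.
#' @return object of class `circ_model`.
#' @export
circ_model <- function(circ_id, chrom, strand, start, end, exons = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for circle ", circ_id, call. = FALSE)
  }
  if (end <= start) {
    stop(sprintf("degenerate span [%d, %d) for circle %s", start, end, circ_id),
         call. = FALSE)
  }
  if (is.null(exons)) {
    exons <- cbind(start = start, end = end)
  } else {
    exons <- matrix(as.integer(exons), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
    if (any(exons[, "end"] <= exons[, "start"]))
      stop("degenerate exon block in circle ", circ_id, call. = FALSE)
    if (is.unsorted(exons[, "start"], strictly = TRUE))
      stop("exon blocks must be sorted by start in circle ", circ_id, call. = FALSE)
    if (nrow(exons) > 1 &&
        any(exons[-1, "start"] < exons[-nrow(exons), "end"]))
      stop("overlapping exon blocks in circle ", circ_id, call. = FALSE)
    if (exons[1, "start"] != start || exons[nrow(exons), "end"] != end)
      stop("exon blocks must start and end at the circle span in ", circ_id,
           call. = FALSE)
    if (any(exons[, "start"] < start) || any(exons[, "end"] > end))
      stop("exon block outside circle span in ", circ_id, call. = FALSE)
  }
  structure(list(circ_id = circ_id, chrom = chrom, strand = strand,
                 start = start, end = end, exons = exons),
            class = "circ_model")
}

#' @export
print.circ_model <- function(x, ...) {
  cat(sprintf("<circ_model> %s %s:%d-%d(%s), %d exon(s), %d nt\n",
              x$circ_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), sum(x$exons[, "end"] - x$exons[, "start"])))
  invisible(x)
}

#' Read circRNA definitions from BED
#'
#' Accepts BED6 (the whole span is one exon) or BED12 (blocks become the
#' circularised exons).  Coordinates are kept 0-based half-open; strand is
#' mandatory.
#'
#' @param path path to a BED file.
#' @return list of [circ_model()] objects.
#' @export
read_circrnas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) {
    stop("BED6 minimum required (chrom, start, end, name, score, strand): ",
         path, call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    strand <- as.character(row[[6]])
    exons <- NULL
    if (ncol(tab) >= 12L) {
      n_blocks <- as.integer(row[[10]])
      sizes <- as.integer(strsplit(as.character(row[[11]]), ",")[[1]])
      offs <- as.integer(strsplit(as.character(row[[12]]), ",")[[1]])
      if (length(sizes) != n_blocks || length(offs) != n_blocks) {
        stop("BED12 block count mismatch at line ", i, call. = FALSE)
      }
      exons <- cbind(start = as.integer(row[[2]]) + offs,
                     end = as.integer(row[[2]]) + offs + sizes)
    }
    circ_model(circ_id = as.character(row[[4]]), chrom = as.character(row[[1]]),
               strand = strand, start = row[[2]], end = row[[3]], exons = exons)
  })
}

#' Write circRNA models as BED12
#'
#' Inverse of [read_circrnas()]: a written file re-reads to the same models
#' field-for-field.
#'
#' @param circs list of [circ_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_circrnas <- function(circs, path) {
  rows <- vapply(circs, function(cc) {
    sizes <- cc$exons[, "end"] - cc$exons[, "start"]
    offs <- cc$exons[, "start"] - cc$start
    paste(cc$chrom, cc$start, cc$end, cc$circ_id, 0L, cc$strand,
          cc$start, cc$end, "0", nrow(cc$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

## ---- transcript models (GTF) ------------------------------------------

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `first`, `last` (GTF 1-based
#'   closed), non-overlapping, sorted by genomic start.
#' @param cds_end optional genomic position of the last coding base
#'   (transcript orientation); the 3' UTR is everything downstream of it.
#' @param utr3 optional explicit 3' UTR intervals (1-based closed matrix),
#'   taking precedence over `cds_end`.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_end = NA_integer_, utr3 = NULL) {
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for transcript ", transcript_id,
         call. = FALSE)
  }
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("first", "last")))
  if (nrow(exons) == 0L) stop("empty exon list for ", transcript_id, call. = FALSE)
  if (any(exons[, "last"] < exons[, "first"]))
    stop("degenerate exon in ", transcript_id, call. = FALSE)
  o <- order(exons[, "first"])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, "first"] <= exons[-nrow(exons), "last"]))
    stop("overlapping exons in ", transcript_id, call. = FALSE)
  if (!is.null(utr3)) {
    utr3 <- matrix(as.integer(utr3), ncol = 2,
                   dimnames = list(NULL, c("first", "last")))
    utr3 <- utr3[order(utr3[, "first"]), , drop = FALSE]
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_end = as.integer(cds_end), utr3 = utr3),
            class = "transcript_model")
}

#' Read transcript models from GTF/GFF
#'
#' Uses `rtracklayer` for parsing.  `exon` features are grouped by
#' `transcript_id`; `three_prime_utr` features (when present) give explicit
#' 3' UTRs, otherwise the UTR boundary is derived from the downstream-most
#' `stop_codon`/`CDS` end.  Transcripts without any CDS have no annotated
#' UTR boundary and contribute their full sequence to UTR scans (see
#' [utr3_sequence()]).
#'
#' @param path path to a GTF/GFF file.
#' @return list of [transcript_model()] objects.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!all(c("type", "transcript_id", "gene_id") %in% names(df))) {
    stop("GTF must carry type, transcript_id and gene_id attributes: ", path,
         call. = FALSE)
  }
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exon features in ", path, call. = FALSE)
  lapply(split(ex, ex$transcript_id), function(e) {
    tid <- e$transcript_id[1]
    sub <- df[!is.na(df$transcript_id) & df$transcript_id == tid, , drop = FALSE]
    strand <- as.character(e$strand[1])
    utr <- sub[sub$type == "three_prime_utr", , drop = FALSE]
    utr3 <- if (nrow(utr)) cbind(first = utr$start, last = utr$end) else NULL
    cds <- sub[sub$type %in% c("CDS", "stop_codon"), , drop = FALSE]
    cds_end <- NA_integer_
    if (nrow(cds)) {
      cds_end <- if (strand == "+") max(cds$end) else min(cds$start)
    }
    transcript_model(transcript_id = tid, gene_id = e$gene_id[1],
                     chrom = as.character(e$seqnames[1]), strand = strand,
                     exons = cbind(first = e$start, last = e$end),
                     cds_end = cds_end, utr3 = utr3)
  })
}

#' Write transcript models as GTF
#'
#' Emits `exon` lines plus a `CDS` line per transcript when `cds_end` is
#' set (spanning the coding part of each exon), enough for
#' [read_transcripts()] to round-trip exon structure and UTR boundary.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  fmt <- function(t, type, first, last) {
    sprintf('%s\tcircshrna\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            t$chrom, type, first, last, t$strand, t$gene_id, t$transcript_id)
  }
  lines <- unlist(lapply(transcripts, function(t) {
    out <- fmt(t, "exon", t$exons[, "first"], t$exons[, "last"])
    if (!is.na(t$cds_end)) {
      cds <- t$exons
      if (t$strand == "+") {
        cds <- cds[cds[, "first"] <= t$cds_end, , drop = FALSE]
        cds[, "last"] <- pmin(cds[, "last"], t$cds_end)
      } else {
        cds <- cds[cds[, "last"] >= t$cds_end, , drop = FALSE]
        cds[, "first"] <- pmax(cds[, "first"], t$cds_end)
      }
      if (nrow(cds)) out <- c(out, fmt(t, "CDS", cds[, "first"], cds[, "last"]))
    }
    out
  }))
  writeLines(lines, path)
  invisible(path)
}

## ---- sequence extraction ----------------------------------------------

extract_interval <- function(genome, chrom, first, last, what) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' absent from genome (", what, ")",
         call. = FALSE)
  }
  len <- nchar(genome[[chrom]])
  if (any(first < 1L) || any(last > len)) {
    stop(what, " outside chromosome bounds of ", chrom, call. = FALSE)
  }
  paste(substring(genome[[chrom]], first, last), collapse = "")
}

#' Spliced transcript sequence, 5' to 3' in transcript orientation
#'
#' @param t a [transcript_model()].
#' @param genome named character vector from [read_genome()].
#' @return DNA string; minus-strand transcripts are reverse-complemented.
#' @export
spliced_sequence <- function(t, genome) {
  stopifnot(inherits(t, "transcript_model"))
  s <- extract_interval(genome, t$chrom, t$exons[, "first"], t$exons[, "last"],
                        paste0("transcript ", t$transcript_id))
  if (t$strand == "-") revcomp(s) else s
}

#' Mature circular RNA sequence, read 5' to 3' from the back-splice acceptor
#'
#' Concatenates the circle's exons in transcription order
#' (reverse-complemented for minus-strand circles).  Position 1 of the
#' returned string is the back-splice acceptor, i.e. the first base after
#' the junction; the junction therefore sits between the last and first
#' characters of the string.
#'
#' @param circ a [circ_model()].
#' @param genome named character vector from [read_genome()].
#' @return DNA string of the mature circle.
#' @export
circular_sequence <- function(circ, genome) {
  stopifnot(inherits(circ, "circ_model"))
  g1 <- bed_to_gtf(circ$exons[, "start"], circ$exons[, "end"])
  s <- extract_interval(genome, circ$chrom, g1[, "first"], g1[, "last"],
                        paste0("circle ", circ$circ_id))
  if (circ$strand == "-") revcomp(s) else s
}

#' 3' UTR sequence of a transcript
#'
#' Resolution order: explicit `three_prime_utr` intervals; else the suffix
#' of the spliced sequence downstream of `cds_end`; else (no CDS at all)
#' the full spliced sequence, flagged via the `"no_cds"` attribute so
#' callers can report how many scans used whole transcripts.
#'
#' @param t a [transcript_model()].
#' @param genome named character vector from [read_genome()].
#' @return DNA string (possibly empty), with attribute `no_cds = TRUE` when
#'   the transcript has no annotated CDS.
#' @export
utr3_sequence <- function(t, genome) {
  stopifnot(inherits(t, "transcript_model"))
  if (!is.null(t$utr3)) {
    s <- extract_interval(genome, t$chrom, t$utr3[, "first"], t$utr3[, "last"],
                          paste0("3' UTR of ", t$transcript_id))
    return(if (t$strand == "-") revcomp(s) else s)
  }
  full <- spliced_sequence(t, genome)
  if (is.na(t$cds_end)) {
    return(structure(full, no_cds = TRUE))
  }
  # transcript-space offset of cds_end: bases at or before it in
  # transcription order
  ex <- t$exons
  if (t$strand == "+") {
    covered <- pmax(0L, pmin(ex[, "last"], t$cds_end) - ex[, "first"] + 1L)
  } else {
    covered <- pmax(0L, ex[, "last"] - pmax(ex[, "first"], t$cds_end) + 1L)
  }
  offset <- sum(covered)
  if (offset >= nchar(full)) "" else substring(full, offset + 1L, nchar(full))
}

#' Gene-level 3' UTR sequences
#'
#' One UTR string per gene: the longest 3' UTR among the gene's
#' transcripts (ties broken by transcript_id).  The number of genes whose
#' representative has no annotated CDS is reported with a message.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param genome named character vector from [read_genome()].
#' @return named character vector, gene_id -> UTR sequence.
#' @export
gene_utrs <- function(transcripts, genome) {
  genes <- vapply(transcripts, `[[`, character(1), "gene_id")
  out <- vapply(split(transcripts, genes), function(ts) {
    ts <- ts[order(vapply(ts, `[[`, character(1), "transcript_id"))]
    utrs <- lapply(ts, utr3_sequence, genome = genome)
    best <- which.max(vapply(utrs, nchar, integer(1)))
    utrs[[best]]
  }, character(1))
  n_flag <- sum(vapply(split(transcripts, genes), function(ts) {
    any(vapply(ts, function(t) is.na(t$cds_end) && is.null(t$utr3), logical(1)))
  }, logical(1)))
  if (n_flag > 0) {
    message(n_flag, " gene(s) without annotated CDS: full transcript used as UTR")
  }
  out
}

## ---- DE tables ---------------------------------------------------------

#' Read a differential-expression result table
#'
#' Tab-separated with header columns `gene_id`, `log2fc`, `pvalue`, `padj`;
#' `NA` marks missing values (e.g. genes DESeq2 set to `padj = NA` as
#' low-count or Cook's-distance outliers).  Gene ids must be unique and p
#' values, when present, must lie in \[0, 1\].
#'
#' @param path path to a TSV file.
#' @return data.frame with the four columns above.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, na.strings = "NA",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "pvalue", "padj")
  if (!all(need %in% names(tab))) {
    stop("DE table must have columns ", paste(need, collapse = ", "), ": ",
         path, call. = FALSE)
  }
  tab <- tab[, need]
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id in DE table: ",
         tab$gene_id[duplicated(tab$gene_id)][1], call. = FALSE)
  }
  for (col in c("pvalue", "padj")) {
    v <- tab[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop(col, " outside [0, 1] in ", path, call. = FALSE)
    }
  }
  tab
}

#' Write a DE table in the dialect [read_de_table()] accepts
#'
#' @param tab data.frame with columns gene_id, log2fc, pvalue, padj.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(tab, path) {
  utils::write.table(tab[, c("gene_id", "log2fc", "pvalue", "padj")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
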