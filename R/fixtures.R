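# Deterministic synthetic-data generators.  Every generator is a pure
# function of its fixture_spec: all randomness flows through
# withr::with_seed(spec$rng_seed, ...), so identical specs give
# byte-identical outputs and the global RNG state is left untouched.

#' Specification for the synthetic-data generators
#'
#' @param rng_seed integer seed driving all randomness.
#' @param n_genes number of genes/transcripts to simulate.
#' @param utr_length integer bounds (uniform) for 3' UTR lengths, nt.
#' @param tx_length integer bounds (uniform) for transcript lengths, nt.
#' @param planted_offtargets data.frame (or NULL) with columns
#'   `match_length` (nt of perfect complementarity to plant) and optional
#'   `log2fc`, `padj` carried into DE planting; one row per planted
#'   transcript.
#' @param planted_seed_enrichment list with `top_n` (default
#'   `min(100, n_genes)`), `site_rate_top`,
#'   `site_rate_background`: the seed site is planted in that fraction of
#'   the `top_n` most-downregulated genes' UTRs versus the background rate
#'   elsewhere.
#' @param circ_layout list with `n_exons`, `exon_lengths`,
#'   `intron_length`, `strand` describing the synthetic circRNA locus.
#' @param gc GC fraction of background sequence (i.i.d. composition).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(rng_seed = 1L, n_genes = 2000L,
                         utr_length = c(100L, 300L),
                         tx_length = c(200L, 1000L),
                         planted_offtargets = NULL,
                         planted_seed_enrichment = list(
                           top_n = NULL, site_rate_top = 0.6,
                           site_rate_background = 0.05),
                         circ_layout = list(n_exons = 2L,
                                            exon_lengths = c(120L, 90L),
                                            intron_length = 70L,
                                            strand = "+"),
                         gc = 0.5) {
  stopifnot(length(utr_length) == 2, utr_length[1] <= utr_length[2],
            length(tx_length) == 2, tx_length[1] <= tx_length[2],
            gc > 0, gc < 1)
  pe <- planted_seed_enrichment
  pe$top_n <- as.integer(pe$top_n %||% min(100L, n_genes))
  stopifnot(pe$site_rate_top >= 0, pe$site_rate_top <= 1,
            pe$site_rate_background >= 0, pe$site_rate_background <= 1,
            pe$top_n <= n_genes)
  stopifnot(circ_layout$strand %in% c("+", "-"),
            length(circ_layout$exon_lengths) == circ_layout$n_exons)
  structure(list(rng_seed = as.integer(rng_seed),
                 n_genes = as.integer(n_genes),
                 utr_length = as.integer(utr_length),
                 tx_length = as.integer(tx_length),
                 planted_offtargets = planted_offtargets,
                 planted_seed_enrichment = pe,
                 circ_layout = circ_layout, gc = gc),
            class = "fixture_spec")
}

# uniform integer in [lo, hi], safe for lo == hi (unlike sample())
runif_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# genomic position (1-based) of the base at 1-based transcript coordinate
# `pos` of transcript model `t`
tx_coord_to_genomic <- function(t, pos) {
  ex <- t$exons
  lens <- ex[, "last"] - ex[, "first"] + 1L
  ord <- if (t$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  for (i in ord) {
    if (pos <= lens[i]) {
      return(if (t$strand == "+") ex[i, "first"] + pos - 1L
             else ex[i, "last"] - pos + 1L)
    }
    pos <- pos - lens[i]
  }
  stop("transcript coordinate out of range", call. = FALSE)
}

#' Synthesise a circRNA locus with recorded ground truth
#'
#' Builds one chromosome carrying a host gene whose middle exons are
#' circularised: flanking exons belong only to the linear transcript, so
#' the back-splice junction sequence exists nowhere in the linear mRNA.
#' The mature circle sequence is recorded as ground truth from the
#' generated exon strings, independently of [circular_sequence()].  The
#' generator rejects (and redraws) layouts in which any junction-spanning
#' 21-mer occurs by chance in the linear transcript.
#'
#' @param spec a [fixture_spec()]; `circ_layout` and `gc` are used.
#' @param guide_length window length used for the junction-uniqueness
#'   rejection check (default 21).
#' @return list with `genome` (named character vector), `transcripts`
#'   (list of one [transcript_model()]), `circs` (list of one
#'   [circ_model()]), and `truth` (`circle_seq`, `linear_seq`,
#'   `utr3_seq`).
#' @export
synth_locus <- function(spec, guide_length = 21L) {
  stopifnot(inherits(spec, "fixture_spec"))
  lay <- spec$circ_layout
  withr::with_seed(spec$rng_seed, {
    for (attempt in 1:50) {
      flank <- rand_dna(100L, spec$gc)
      exon_f5 <- rand_dna(80L, spec$gc)
      exon_f3 <- rand_dna(80L, spec$gc)
      circ_exons <- vapply(lay$exon_lengths, rand_dna, character(1),
                           gc = spec$gc)
      introns <- replicate(lay$n_exons + 1L,
                           rand_dna(lay$intron_length, spec$gc))
      circle_seq <- paste(circ_exons, collapse = "")
      linear_seq <- paste(c(exon_f5, circ_exons, exon_f3), collapse = "")
      # junction-spanning windows (>=1 nt each side) must be unique to
      # the circle
      w_ok <- TRUE
      ctx2 <- paste0(substring(circle_seq, nchar(circle_seq) - guide_length + 2L),
                     substring(circle_seq, 1L, guide_length - 1L))
      for (s in seq_len(nchar(ctx2) - guide_length + 1L)) {
        if (grepl(substring(ctx2, s, s + guide_length - 1L), linear_seq,
                  fixed = TRUE)) {
          w_ok <- FALSE
          break
        }
      }
      if (!w_ok) next

      # sense-orientation locus layout (transcription left -> right),
      # 0-based half-open offsets within the locus string
      parts <- c(flank, exon_f5, introns[1])
      for (i in seq_len(lay$n_exons)) {
        parts <- c(parts, circ_exons[i],
                   if (i < lay$n_exons) introns[i + 1L] else introns[lay$n_exons + 1L])
      }
      parts <- c(parts, exon_f3, flank)
      lens <- nchar(parts)
      offs <- cumsum(c(0L, lens[-length(lens)]))
      locus <- paste(parts, collapse = "")
      L <- nchar(locus)
      # element indices within `parts`
      i_f5 <- 2L
      i_circ <- 2L + 2L * seq_len(lay$n_exons)  # 4, 6, ...
      i_f3 <- length(parts) - 1L
      iv <- function(i) c(offs[i], offs[i] + lens[i])  # 0-based half-open
      sense_exons <- rbind(iv(i_f5), t(vapply(i_circ, iv, numeric(2))),
                           iv(i_f3))
      sense_circ <- t(vapply(i_circ, iv, numeric(2)))
      if (lay$strand == "-") {
        locus <- revcomp(locus)
        mirror <- function(m) {
          m2 <- cbind(L - m[, 2], L - m[, 1])
          m2[order(m2[, 1]), , drop = FALSE]
        }
        sense_exons <- mirror(sense_exons)
        sense_circ <- mirror(sense_circ)
      }
      chrom_seq <- locus
      g1 <- bed_to_gtf(as.integer(sense_exons[, 1]),
                       as.integer(sense_exons[, 2]))
      tx <- transcript_model("tHost", "gHost", "chrS", lay$strand,
                             exons = g1)
      # 3' UTR = last 50 nt of the transcript
      tx_len <- sum(g1[, "last"] - g1[, "first"] + 1L)
      tx$cds_end <- tx_coord_to_genomic(tx, tx_len - 50L)
      circ <- circ_model("circS", "chrS", lay$strand,
                         start = min(sense_circ[, 1]),
                         end = max(sense_circ[, 2]),
                         exons = cbind(start = as.integer(sense_circ[, 1]),
                                       end = as.integer(sense_circ[, 2])))
      truth_linear <- paste(c(exon_f5, circ_exons, exon_f3), collapse = "")
      return(list(genome = c(chrS = chrom_seq), transcripts = list(tx),
                  circs = list(circ),
                  truth = list(circle_seq = circle_seq,
                               linear_seq = truth_linear,
                               utr3_seq = substring(truth_linear,
                                                    nchar(truth_linear) - 49L))))
    }
    stop("synth_locus: rejection budget exceeded", call. = FALSE)
  })
}

#' Synthesise a transcriptome with planted complementarity off-targets
#'
#' Transcript `i` (for each row `i` of `spec$planted_offtargets`) carries a
#' planted perfect-complementarity stretch of exactly `match_length` nt to
#' `guide`; all other transcripts are rejection-sampled until their longest
#' complementary stretch (checked with the DP oracle
#' [longest_complementary_stretch()]) is below `min_len`.  Planted lengths
#' below `min_len` are inserted but excluded from the ground-truth hit
#' list.
#'
#' @param spec a [fixture_spec()].
#' @param guide guide DNA string.
#' @param min_len off-target stretch threshold (default 12).
#' @param budget rejection-sampling retries per transcript.
#' @return list with `transcripts` (data.frame transcript_id, gene_id,
#'   sequence), `truth` (data.frame of planted hits with match_length >=
#'   min_len), `planted` (all plants).
#' @export
synth_transcriptome <- function(spec, guide, min_len = 12L, budget = 200L) {
  stopifnot(inherits(spec, "fixture_spec"), nzchar(guide))
  plants <- spec$planted_offtargets
  n_plant <- if (is.null(plants)) 0L else nrow(plants)
  stopifnot(n_plant <= spec$n_genes)
  if (n_plant > 0 && any(plants$match_length > nchar(guide))) {
    stop("planted match_length exceeds guide length", call. = FALSE)
  }
  tsense <- revcomp(guide)
  withr::with_seed(spec$rng_seed, {
    ids <- sprintf("t%04d", seq_len(spec$n_genes))
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    seqs <- character(spec$n_genes)
    for (i in seq_len(spec$n_genes)) {
      len <- runif_int(spec$tx_length[1], spec$tx_length[2])
      target <- if (i <= n_plant) plants$match_length[i] else NA_integer_
      ok <- FALSE
      for (try in seq_len(budget)) {
        s <- rand_dna(len, spec$gc)
        if (is.na(target)) {
          if (longest_complementary_stretch(guide, s) < min_len) {
            ok <- TRUE
            break
          }
        } else {
          frag_start <- sample.int(nchar(tsense) - target + 1L, 1L)
          frag <- substring(tsense, frag_start, frag_start + target - 1L)
          pos <- sample.int(len - target + 1L, 1L)
          s <- paste0(substring(s, 1L, pos - 1L), frag,
                      substring(s, pos + target, len))
          if (longest_complementary_stretch(guide, s) == target) {
            ok <- TRUE
            break
          }
        }
      }
      if (!ok) stop("synth_transcriptome: rejection budget exceeded for ",
                    ids[i], call. = FALSE)
      seqs[i] <- s
    }
    tx <- data.frame(transcript_id = ids, gene_id = genes, sequence = seqs,
                     stringsAsFactors = FALSE)
    planted_df <- if (n_plant > 0) {
      cbind(data.frame(transcript_id = ids[seq_len(n_plant)],
                       gene_id = genes[seq_len(n_plant)],
                       stringsAsFactors = FALSE), plants)
    } else NULL
    truth <- if (!is.null(planted_df)) {
      planted_df[planted_df$match_length >= min_len, , drop = FALSE]
    } else {
      data.frame(transcript_id = character(0), gene_id = character(0),
                 match_length = integer(0))
    }
    list(transcripts = tx, truth = truth, planted = planted_df)
  })
}

#' Synthesise a DE table with planted effects
#'
#' Null genes draw log2fc ~ Normal(0, 0.2) and pvalue ~ Uniform(0, 1)
#' (padj by Benjamini-Hochberg over the nulls); planted genes carry their
#' exact specified log2fc and padj (padj may be NA to exercise the
#' not_testable path).
#'
#' @param spec a [fixture_spec()].
#' @param gene_ids genes to populate the table with.
#' @param planted optional data.frame with columns gene_id, log2fc, padj.
#' @return DE data.frame (gene_id, log2fc, pvalue, padj).
#' @export
synth_de_table <- function(spec, gene_ids, planted = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$rng_seed, {
    n <- length(gene_ids)
    log2fc <- stats::rnorm(n, 0, 0.2)
    pvalue <- stats::runif(n)
    padj <- stats::p.adjust(pvalue, method = "BH")
    tab <- data.frame(gene_id = gene_ids, log2fc = log2fc, pvalue = pvalue,
                      padj = padj, stringsAsFactors = FALSE)
    if (!is.null(planted)) {
      stopifnot(all(planted$gene_id %in% gene_ids))
      idx <- match(planted$gene_id, tab$gene_id)
      tab$log2fc[idx] <- planted$log2fc
      tab$padj[idx] <- planted$padj
      tab$pvalue[idx] <- planted$padj
    }
    tab
  })
}

#' Synthesise a ranked gene list with planted seed-site enrichment
#'
#' All UTRs are rejection-sampled free of `seed_site`; the site is then
#' inserted with probability `site_rate_top` in the `top_n`
#' most-downregulated genes and `site_rate_background` elsewhere, so site
#' presence matches the planting exactly.  log2fc values are a sorted
#' Normal(0, 1) sample (ascending), making gene order the ranking order.
#'
#' @param spec a [fixture_spec()]; `planted_seed_enrichment`, `n_genes`,
#'   `utr_length` are used.
#' @param seed_site the 7-nt site to plant (what is matched in UTRs).
#' @param budget rejection-sampling retries per UTR.
#' @return list with `ranked` ([ranked_gene_list()]), `utrs`, `de`, and
#'   `truth` (data.frame gene_id, in_top, has_site).
#' @export
synth_ranked_enrichment <- function(spec, seed_site, budget = 200L) {
  stopifnot(inherits(spec, "fixture_spec"), nzchar(seed_site))
  pe <- spec$planted_seed_enrichment
  withr::with_seed(spec$rng_seed, {
    n <- spec$n_genes
    ids <- sprintf("g%04d", seq_len(n))
    log2fc <- sort(stats::rnorm(n))
    in_top <- seq_len(n) <= pe$top_n
    rate <- ifelse(in_top, pe$site_rate_top, pe$site_rate_background)
    has_site <- stats::runif(n) < rate
    utrs <- character(n)
    for (i in seq_len(n)) {
      len <- runif_int(spec$utr_length[1], spec$utr_length[2])
      ok <- FALSE
      for (try in seq_len(budget)) {
        u <- rand_dna(len, spec$gc)
        if (!grepl(seed_site, u, fixed = TRUE)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("synth_ranked_enrichment: rejection budget exceeded",
                    call. = FALSE)
      if (has_site[i]) {
        w <- nchar(seed_site)
        pos <- sample.int(len - w + 1L, 1L)
        u <- paste0(substring(u, 1L, pos - 1L), seed_site,
                    substring(u, pos + w, len))
      }
      utrs[i] <- u
    }
    names(utrs) <- ids
    de <- data.frame(gene_id = ids, log2fc = log2fc,
                     pvalue = stats::runif(n), padj = NA_real_,
                     stringsAsFactors = FALSE)
    de$padj <- stats::p.adjust(de$pvalue, method = "BH")
    ranked <- ranked_gene_list(de, utrs)
    list(ranked = ranked, utrs = utrs, de = de,
         truth = data.frame(gene_id = ids, in_top = in_top,
                            has_site = has_site, stringsAsFactors = FALSE))
  })
}
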