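# Hypergeometric word-enrichment landscapes over ranked gene lists.
#
# Genes are ranked from most down- to most upregulated; for each leading
# bin the number of genes whose 3' UTR contains a seed site is compared to
# the whole-universe count with a hypergeometric tail test.  This is a
# gene-level-presence simplification of SYLAMER-style landscapes: no
# word-composition bias correction is attempted (see the methods
# vignette), which keeps the statistic exactly testable.

#' Hypergeometric upper-tail probability P\[X >= k\]
#'
#' X ~ Hypergeometric(N, K, n): `k` or more marked genes in a draw of `n`
#' from a universe of `N` containing `K` marked.  Computed in log space via
#' [stats::phyper()].
#'
#' @param N universe size.
#' @param K marked genes in the universe.
#' @param n draw (leading-bin) size.
#' @param k observed marked genes in the draw.
#' @return probability in (0, 1\].
#' @examples
#' hypergeom_upper_tail(10, 4, 5, 3)  # 66/252
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  if (k <= 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric lower-tail probability P\[X <= k\]
#'
#' @inheritParams hypergeom_upper_tail
#' @return probability in (0, 1\].
#' @export
hypergeom_lower_tail <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  exp(stats::phyper(k, K, N - K, n, log.p = TRUE))
}

check_hyper_args <- function(N, K, n, k) {
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n)) {
    stop(sprintf("invalid hypergeometric arguments N=%d K=%d n=%d k=%d",
                 N, K, n, k), call. = FALSE)
  }
  invisible(TRUE)
}

#' Rank genes from most down- to most upregulated
#'
#' Sort key: log2fc ascending, ties by p value ascending, then gene_id.
#' Genes without a UTR entry, or with missing log2fc, are dropped with a
#' message giving the count.
#'
#' @param de data.frame in the [read_de_table()] layout.
#' @param utrs named character vector, gene_id -> UTR sequence.
#' @return object of class `ranked_gene_list` with fields `genes` (ordered
#'   ids), `log2fc` (parallel), `n`.
#' @export
ranked_gene_list <- function(de, utrs) {
  stopifnot(all(c("gene_id", "log2fc", "pvalue") %in% names(de)))
  if (anyDuplicated(de$gene_id)) stop("duplicate gene_id", call. = FALSE)
  keep <- de$gene_id %in% names(utrs) & !is.na(de$log2fc)
  if (any(!keep)) {
    message(sum(!keep), " gene(s) dropped from ranking (no UTR or no log2fc)")
  }
  de <- de[keep, , drop = FALSE]
  if (nrow(de) == 0L) stop("empty ranked gene list", call. = FALSE)
  p <- de$pvalue
  p[is.na(p)] <- Inf
  o <- order(de$log2fc, p, de$gene_id)
  structure(list(genes = de$gene_id[o], log2fc = de$log2fc[o], n = nrow(de)),
            class = "ranked_gene_list")
}

#' Gene x word presence table
#'
#' A gene is "present" for a word when its 3' UTR contains at least one
#' occurrence of the word's reverse-complement site (same convention as
#' [count_seed_matches()]: words are seeds, sites are what is matched).
#'
#' @param words character vector of seed words (DNA).
#' @param utrs named character vector, gene_id -> UTR sequence.
#' @return logical matrix, genes x words.
#' @export
build_presence_table <- function(words, utrs) {
  stopifnot(length(words) > 0)
  specs <- data.frame(source = words, site = revcomp(words),
                      stringsAsFactors = FALSE)
  count_seed_matches(specs, utrs) > 0L
}

#' Seed-word enrichment landscape over leading bins of a ranking
#'
#' For each leading-bin size n in `bin_step, 2*bin_step, ..., N` (N always
#' included), tests whether genes carrying the word are over-represented
#' among the n most-downregulated genes.  The signed log p is
#' `-log10 P[X >= k]` when the bin holds at least its expected share of
#' word-carrying genes (enrichment; positive values), and
#' `+log10 P[X <= k]` otherwise (depletion; negative values).  At n = N
#' the statistic is 0 by construction.
#'
#' @param ranked a [ranked_gene_list()].
#' @param presence logical matrix from [build_presence_table()].
#' @param word which word (column of `presence`) to profile.
#' @param bin_step leading-bin increment (genes); default 50.
#' @return object of class `enrichment_landscape` with fields `word`,
#'   `bin_edges`, `signed_logp`, `k`, `K`, `N`, `p_upper`.
#' @export
enrichment_landscape <- function(ranked, presence, word, bin_step = 50L) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  if (!word %in% colnames(presence)) {
    stop("word '", word, "' not in presence table", call. = FALSE)
  }
  if (!all(ranked$genes %in% rownames(presence))) {
    stop("ranked genes missing from presence table", call. = FALSE)
  }
  N <- ranked$n
  edges <- unique(c(seq.int(bin_step, N, by = bin_step), N))
  pres <- presence[ranked$genes, word]
  K <- sum(pres)
  kcum <- unname(cumsum(pres)[edges])
  lp_up <- stats::phyper(kcum - 1, K, N - K, edges,
                         lower.tail = FALSE, log.p = TRUE) / log(10)
  lp_lo <- stats::phyper(kcum, K, N - K, edges, log.p = TRUE) / log(10)
  enriched_side <- kcum >= edges * (K / N)
  signed <- ifelse(enriched_side, -lp_up, lp_lo)
  structure(list(word = word, bin_edges = edges,
                 signed_logp = as.numeric(signed),
                 k = as.integer(kcum), K = as.integer(K), N = as.integer(N),
                 p_upper = 10^lp_up),
            class = "enrichment_landscape")
}

#' @export
print.enrichment_landscape <- function(x, ...) {
  cat(sprintf("<enrichment_landscape> word %s: N=%d, K=%d, peak |logp|=%.3f\n",
              x$word, x$N, x$K, max(abs(x$signed_logp))))
  invisible(x)
}

#' Enrichment verdict across seed landscapes
#'
#' A seed is called enriched when its minimum upper-tail p over the
#' downregulated bins, Bonferroni-corrected by (number of tested bins x
#' number of seeds), falls below `alpha`.  Only bins lying entirely within
#' the downregulated part of the ranking (edge <= number of genes with
#' log2fc < 0) are tested -- enrichment among upregulated genes is the
#' wrong tail for off-target detection.
#'
#' @param landscapes named list of [enrichment_landscape()] objects sharing
#'   `bin_edges` (typically guide and star seeds).
#' @param ranked the [ranked_gene_list()] the landscapes were built on.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per landscape: word, min_p,
#'   p_bonferroni, enriched.
#' @export
landscape_verdict <- function(landscapes, ranked, alpha = 0.05) {
  stopifnot(length(landscapes) > 0, inherits(ranked, "ranked_gene_list"))
  edges <- landscapes[[1]]$bin_edges
  for (l in landscapes) {
    if (!identical(l$bin_edges, edges)) {
      stop("landscapes do not share bin_edges", call. = FALSE)
    }
  }
  n_down <- sum(ranked$log2fc < 0)
  test_bins <- which(edges <= n_down)
  m <- length(test_bins) * length(landscapes)
  min_p <- vapply(landscapes, function(l) {
    if (length(test_bins) == 0L) 1 else min(l$p_upper[test_bins])
  }, numeric(1))
  p_bonf <- pmin(1, min_p * max(m, 1L))
  data.frame(word = vapply(landscapes, `[[`, character(1), "word"),
             min_p = unname(min_p), p_bonferroni = unname(p_bonf),
             enriched = unname(p_bonf < alpha),
             row.names = names(landscapes) %||% NULL,
             stringsAsFactors = FALSE)
}
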