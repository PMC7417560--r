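# Differential-expression filters, cross-strain exclusion, and off-target
# verdict rules.
#
# Two distinct threshold sets are deliberately kept apart:
#   * transcriptome characterisation: linear fold change > 1.5 (as
#     magnitude, |log2fc| > log2 1.5) and RAW p < 0.05;
#   * off-target calls: |log2fc| > 1 and ADJUSTED p < 0.05.
# Inequalities are strict, exactly as printed in the source filters.

#' Filtering thresholds for DE screens
#'
#' @param fc_threshold linear fold-change cutoff for calling a gene
#'   significantly changing (default 1.5; applied to |log2fc| >
#'   log2(fc_threshold)).
#' @param p_threshold raw p cutoff for the same call (default 0.05).
#' @param ot_log2fc_threshold |log2fc| cutoff for calling a putative
#'   off-target changed (default 1).
#' @param ot_padj_threshold adjusted-p cutoff for the off-target call
#'   (default 0.05).
#' @return object of class `filter_params`.
#' @export
filter_params <- function(fc_threshold = 1.5, p_threshold = 0.05,
                          ot_log2fc_threshold = 1.0,
                          ot_padj_threshold = 0.05) {
  stopifnot(fc_threshold > 0, p_threshold > 0, p_threshold <= 1,
            ot_log2fc_threshold > 0, ot_padj_threshold > 0,
            ot_padj_threshold <= 1)
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 ot_log2fc_threshold = ot_log2fc_threshold,
                 ot_padj_threshold = ot_padj_threshold),
            class = "filter_params")
}

#' Significantly changing genes
#'
#' Keeps genes with |log2fc| > log2(fc_threshold) and raw p < p_threshold;
#' the fold-change cutoff is symmetric (up- or downregulation).  Genes with
#' missing log2fc or p cannot pass and are dropped.
#'
#' @param table DE data.frame ([read_de_table()] layout).
#' @param fp a [filter_params()].
#' @return the significant subset of `table`.
#' @export
significant_genes <- function(table, fp = filter_params()) {
  keep <- !is.na(table$log2fc) & !is.na(table$pvalue) &
    abs(table$log2fc) > log2(fp$fc_threshold) &
    table$pvalue < fp$p_threshold
  table[keep, , drop = FALSE]
}

#' Remove genes that change in every knockdown strain
#'
#' Genes significant in all strains are treated as non-specific (driver or
#' background effects) and removed from every strain's set.  Idempotent.
#'
#' @param per_strain named list of character vectors (significant gene ids
#'   per strain).
#' @return the same list with ubiquitous genes removed.
#' @export
exclude_ubiquitous <- function(per_strain) {
  stopifnot(is.list(per_strain), length(per_strain) >= 1)
  if (length(per_strain) == 1L) {
    warning("single strain: cross-strain exclusion is the identity",
            call. = FALSE)
    return(per_strain)
  }
  ubiquitous <- Reduce(intersect, per_strain)
  lapply(per_strain, setdiff, y = ubiquitous)
}

#' DE-based verdicts for putative off-target genes
#'
#' One verdict per unique gene in `hits`:
#' * `changed` -- |log2fc| > ot_log2fc_threshold and padj <
#'   ot_padj_threshold;
#' * `not_testable` -- in the table but padj (or log2fc) is NA, as DESeq2
#'   reports for low-count genes and Cook's-distance outliers;
#' * `not_detected` -- absent from the DE table (not expressed);
#' * `unchanged` -- everything else.
#'
#' @param hits data.frame from [scan_offtargets()] (or any frame with
#'   gene_id and match_length columns).
#' @param table DE data.frame.
#' @param fp a [filter_params()].
#' @return data.frame of class `offtarget_verdicts`: gene_id, status,
#'   log2fc, padj, evidence.  A summary of counts per status is attached as
#'   attribute `summary` and shown by the print method.
#' @export
offtarget_verdicts <- function(hits, table, fp = filter_params()) {
  genes <- unique(hits$gene_id)
  idx <- match(genes, table$gene_id)
  log2fc <- table$log2fc[idx]
  padj <- table$padj[idx]
  status <- ifelse(is.na(idx), "not_detected",
            ifelse(is.na(padj) | is.na(log2fc), "not_testable",
            ifelse(abs(log2fc) > fp$ot_log2fc_threshold &
                     padj < fp$ot_padj_threshold, "changed", "unchanged")))
  evidence <- vapply(genes, function(g) {
    if ("match_length" %in% names(hits)) {
      sprintf("complementarity_%dnt",
              max(hits$match_length[hits$gene_id == g]))
    } else "seed"
  }, character(1))
  out <- data.frame(gene_id = genes, status = status, log2fc = log2fc,
                    padj = padj, evidence = evidence,
                    stringsAsFactors = FALSE, row.names = NULL)
  counts <- table(factor(out$status, levels = c("unchanged", "changed",
                                                "not_testable",
                                                "not_detected")))
  attr(out, "summary") <- counts
  class(out) <- c("offtarget_verdicts", "data.frame")
  out
}

#' @export
print.offtarget_verdicts <- function(x, ...) {
  NextMethod()
  s <- attr(x, "summary")
  cat("--\n", paste(names(s), s, sep = ": ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Specificity report for a set of knockdown designs
#'
#' Bundles, per design, the guide, its host-linear warnings, off-target
#' verdict counts by status, and the seed-enrichment verdicts, plus an
#' overall flag: `"no detectable off-targets"` when no verdict is
#' `changed` and no seed is enriched, `"candidate off-target effect"`
#' otherwise.
#'
#' @param designs list of `shrna_design` objects (or a single one).
#' @param hits data.frame from [scan_offtargets()]; its `guide_id` values
#'   must all be design ids.
#' @param verdicts [offtarget_verdicts()] frame covering the hit genes.
#' @param enrichment optional [landscape_verdict()] frame, or a named list
#'   of them keyed by design id.
#' @return object of class `knockdown_report` (a list with fields
#'   `designs`, `overall`); `as_report_json()` renders it machine-readable,
#'   the print method renders it for humans.
#' @export
knockdown_report <- function(designs, hits, verdicts, enrichment = NULL) {
  if (inherits(designs, "shrna_design")) designs <- list(designs)
  ids <- vapply(designs, `[[`, character(1), "design_id")
  if (nrow(hits) > 0 && !all(hits$guide_id %in% ids)) {
    stop("hits reference unknown design ids: ",
         paste(setdiff(unique(hits$guide_id), ids), collapse = ", "),
         call. = FALSE)
  }
  missing_verdict <- setdiff(unique(hits$gene_id), verdicts$gene_id)
  if (length(missing_verdict)) {
    stop("hit genes without a verdict: ",
         paste(missing_verdict, collapse = ", "), call. = FALSE)
  }
  per_design <- lapply(designs, function(d) {
    dh <- hits[hits$guide_id == d$design_id, , drop = FALSE]
    dv <- verdicts[verdicts$gene_id %in% dh$gene_id, , drop = FALSE]
    counts <- table(factor(dv$status, levels = c("unchanged", "changed",
                                                 "not_testable",
                                                 "not_detected")))
    enr <- if (is.list(enrichment) && !is.data.frame(enrichment)) {
      enrichment[[d$design_id]]
    } else enrichment
    list(design_id = d$design_id, circ_id = d$circ_id, guide = d$guide,
         side_5p = d$side_5p, side_3p = d$side_3p, warnings = d$warnings,
         n_offtarget_genes = length(unique(dh$gene_id)),
         status_counts = as.list(counts),
         seed_enrichment = enr)
  })
  names(per_design) <- ids
  any_changed <- any(vapply(per_design, function(p)
    p$status_counts$changed > 0, logical(1)))
  any_enriched <- any(vapply(per_design, function(p) {
    !is.null(p$seed_enrichment) && any(p$seed_enrichment$enriched)
  }, logical(1)))
  overall <- if (any_changed || any_enriched) {
    "candidate off-target effect"
  } else "no detectable off-targets"
  structure(list(designs = per_design, overall = overall),
            class = "knockdown_report")
}

#' @export
print.knockdown_report <- function(x, ...) {
  cat("Knockdown specificity report\n")
  for (p in x$designs) {
    cat(sprintf("  %s (%s): guide %s, sides %d|%d%s\n", p$design_id,
                p$circ_id, p$guide, p$side_5p, p$side_3p,
                if (length(p$warnings))
                  paste0(" [", paste(p$warnings, collapse = ","), "]") else ""))
    cat(sprintf("    off-target genes: %d (%s)\n", p$n_offtarget_genes,
                paste(names(p$status_counts), unlist(p$status_counts),
                      sep = "=", collapse = ", ")))
    if (!is.null(p$seed_enrichment)) {
      cat(sprintf("    seed enrichment: %s\n",
                  paste(p$seed_enrichment$word,
                        ifelse(p$seed_enrichment$enriched, "ENRICHED", "ns"),
                        collapse = ", ")))
    }
  }
  cat("  overall:", x$overall, "\n")
  invisible(x)
}

#' Render a knockdown report as JSON
#'
#' @param report a [knockdown_report()].
#' @param path optional output path; when given, the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
as_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "knockdown_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
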