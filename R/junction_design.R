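# Back-splice junction context and junction-spanning guide design.
#
# The guide strand is antisense to the circle, so "target window" always
# refers to the circle (target-sense) sequence read 5'->3' across the
# junction; the guide is its exact reverse complement.

#' Guide design parameters
#'
#' @param guide_length guide length in nt.  Default 21, the length used for
#'   junction-spanning hairpins cloned into miR-1-scaffold vectors.
#' @param min_overhang minimum nt of the target window on each side of the
#'   junction.  Junction specificity requires both sides > 0; the default 5
#'   keeps every emitted guide well anchored across the junction while
#'   still permitting shifted alternate designs.
#' @param context_width nt of circle sequence taken on each side of the
#'   junction when building the context (default 30).
#' @param shift signed offset of the alternate design in nt; positive moves
#'   the window toward the target's 3' side.  Default +3, the published
#'   alternate-design step.
#' @return object of class `design_params`.
#' @export
design_params <- function(guide_length = 21L, min_overhang = 5L,
                          context_width = 30L, shift = 3L) {
  guide_length <- as.integer(guide_length)
  min_overhang <- as.integer(min_overhang)
  context_width <- as.integer(context_width)
  shift <- as.integer(shift)
  if (guide_length < 2L * min_overhang) {
    stop("guide_length must be >= 2 * min_overhang", call. = FALSE)
  }
  if (context_width < guide_length) {
    stop("context_width must be >= guide_length", call. = FALSE)
  }
  structure(list(guide_length = guide_length, min_overhang = min_overhang,
                 context_width = context_width, shift = shift),
            class = "design_params")
}

#' Build the back-splice junction context of a circle
#'
#' The context is the circle sequence read across the junction: the last
#' `context_width` nt of the mature circle followed by its first
#' `context_width` nt.  `junction_index` bases of the context lie 5' of the
#' junction (the junction sits between positions `junction_index` and
#' `junction_index + 1`, 1-based).
#'
#' @param circ a [circ_model()].
#' @param genome named character vector from [read_genome()].
#' @param params a [design_params()].
#' @return object of class `junction_context` with fields `circ_id`,
#'   `sequence`, `junction_index`.
#' @export
build_junction_context <- function(circ, genome, params = design_params()) {
  circle <- circular_sequence(circ, genome)
  w <- params$context_width
  n <- nchar(circle)
  if (n < 2L * w) {
    stop(sprintf(paste0("circle %s is %d nt, shorter than 2 * context_width ",
                        "= %d; use a context_width of at most %d"),
                 circ$circ_id, n, 2L * w, n %/% 2L), call. = FALSE)
  }
  structure(list(circ_id = circ$circ_id,
                 sequence = paste0(substring(circle, n - w + 1L, n),
                                   substring(circle, 1L, w)),
                 junction_index = w),
            class = "junction_context")
}

#' @export
print.junction_context <- function(x, ...) {
  w <- x$junction_index
  cat(sprintf("<junction_context> %s: %s|%s\n", x$circ_id,
              substring(x$sequence, 1, w),
              substring(x$sequence, w + 1, nchar(x$sequence))))
  invisible(x)
}

# Build one design from a window start (1-based within the context).
make_design <- function(ctx, start, params, design_id,
                        offtarget_min_len = 12L) {
  L <- params$guide_length
  w <- ctx$junction_index
  window <- substring(ctx$sequence, start, start + L - 1L)
  side_5p <- w - start + 1L             # window bases 5' of the junction
  side_3p <- L - side_5p
  d <- structure(list(circ_id = ctx$circ_id, design_id = design_id,
                      target_window = c(start = start, end = start + L - 1L),
                      guide = revcomp(window), passenger = window,
                      side_5p = side_5p, side_3p = side_3p,
                      warnings = character(0)),
                 class = "shrna_design")
  host_linear_safety(d, offtarget_min_len)
}

#' @export
print.shrna_design <- function(x, ...) {
  cat(sprintf("<shrna_design> %s (%s): guide %s, sides %d|%d%s\n",
              x$design_id, x$circ_id, x$guide, x$side_5p, x$side_3p,
              if (length(x$warnings))
                paste0(" [", paste(x$warnings, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Enumerate all junction-spanning guide windows
#'
#' Every window of `guide_length` nt within the context whose two sides of
#' the junction are both at least `min_overhang` nt.  There are
#' `guide_length - 2 * min_overhang + 1` such windows.
#'
#' @param ctx a [junction_context()].
#' @param params a [design_params()].
#' @param offtarget_min_len threshold forwarded to [host_linear_safety()].
#' @return list of `shrna_design` objects (possibly empty).
#' @export
enumerate_guide_windows <- function(ctx, params = design_params(),
                                    offtarget_min_len = 12L) {
  L <- params$guide_length
  m <- params$min_overhang
  w <- ctx$junction_index
  # side_5p = w - start + 1 >= m  and  side_3p = start + L - 1 - w >= m
  lo <- max(1L, w + m - L + 1L)
  hi <- min(w - m + 1L, 2L * w - L + 1L)
  if (hi < lo) return(list())
  lapply(seq.int(lo, hi), function(s) {
    make_design(ctx, s, params,
                design_id = sprintf("%s_w%02d", ctx$circ_id, s),
                offtarget_min_len = offtarget_min_len)
  })
}

#' Primary (centred) junction-spanning design
#'
#' The window is centred on the junction; for odd `guide_length` the extra
#' base goes to the 5' (upstream-of-junction) side, so a 21-nt guide splits
#' 11|10.
#'
#' @inheritParams enumerate_guide_windows
#' @return a single `shrna_design`.
#' @export
design_primary <- function(ctx, params = design_params(),
                           offtarget_min_len = 12L) {
  L <- params$guide_length
  w <- ctx$junction_index
  side_5p <- (L + 1L) %/% 2L
  start <- w - side_5p + 1L
  if (side_5p < params$min_overhang || L - side_5p < params$min_overhang ||
      start < 1L || start + L - 1L > 2L * w) {
    stop("infeasible design parameters for centred window", call. = FALSE)
  }
  make_design(ctx, start, params, design_id = paste0(ctx$circ_id, "_primary"),
              offtarget_min_len = offtarget_min_len)
}

#' Shifted alternate design
#'
#' The primary window moved `params$shift` nt along the target: positive
#' shifts move toward the target's 3' side (past the junction), so the
#' published +3 alternate of a 21-nt 11|10 primary splits 8|13.
#'
#' @inheritParams enumerate_guide_windows
#' @return a single `shrna_design`.
#' @export
design_shifted <- function(ctx, params = design_params(),
                           offtarget_min_len = 12L) {
  L <- params$guide_length
  m <- params$min_overhang
  w <- ctx$junction_index
  s <- params$shift
  primary_5p <- (L + 1L) %/% 2L
  start <- w - primary_5p + 1L + s
  side_5p <- w - start + 1L
  side_3p <- L - side_5p
  if (side_5p < m || side_3p < m || start < 1L || start + L - 1L > 2L * w) {
    max_pos <- primary_5p - m
    max_neg <- (L - primary_5p) - m
    stop(sprintf(paste0("shift %+d violates min_overhang %d; feasible shifts ",
                        "are %+d to %+d"), s, m, -max_neg, max_pos),
         call. = FALSE)
  }
  make_design(ctx, start, params,
              design_id = sprintf("%s_shift%+d", ctx$circ_id, s),
              offtarget_min_len = offtarget_min_len)
}

#' Flag designs whose one-sided overlap could slice the linear host mRNA
#'
#' A guide's window crosses the junction, so the full window never occurs
#' in the linear host transcript -- but each side of the window separately
#' does.  If either side is itself as long as the off-target stretch
#' threshold, that contiguous match alone may suffice for slicing of the
#' host (or any other) mRNA, and the design gets a `host_linear_risk`
#' warning.
#'
#' @param d an `shrna_design`.
#' @param offtarget_min_len contiguous-complementarity threshold (nt);
#'   12 matches the off-target scan default.
#' @return `d`, with the warning appended when triggered.
#' @export
host_linear_safety <- function(d, offtarget_min_len = 12L) {
  stopifnot(inherits(d, "shrna_design"))
  d$warnings <- setdiff(d$warnings, "host_linear_risk")
  if (max(d$side_5p, d$side_3p) >= offtarget_min_len) {
    d$warnings <- c(d$warnings, "host_linear_risk")
  }
  d
}

#' Flatten designs to a data.frame (the TSV dialect of the CLI)
#'
#' @param designs list of `shrna_design` objects (or a single one).
#' @return data.frame with columns circ_id, design_id, guide, passenger,
#'   side_5p, side_3p, warnings (comma-joined).
#' @export
designs_to_df <- function(designs) {
  if (inherits(designs, "shrna_design")) designs <- list(designs)
  do.call(rbind, lapply(designs, function(d) {
    data.frame(circ_id = d$circ_id, design_id = d$design_id, guide = d$guide,
               passenger = d$passenger, side_5p = d$side_5p,
               side_3p = d$side_3p,
               warnings = paste(d$warnings, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
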