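test_that("junction context is circle end + circle start", {
  tg <- toy_circle_genome("AAAAATTTTT")
  p <- design_params(guide_length = 2L, min_overhang = 1L, context_width = 3L)
  ctx <- build_junction_context(tg$circ, tg$genome, p)
  expect_identical(ctx$sequence, "TTTAAA")
  expect_identical(ctx$junction_index, 3L)

  # 60-nt circle with context_width 30: the context is the circle rotated
  # by half its length (string-rotation oracle)
  circle <- rdna(60, seed = 5)
  tg60 <- toy_circle_genome(circle)
  ctx60 <- build_junction_context(tg60$circ, tg60$genome, design_params())
  rotation <- paste0(substring(circle, 31, 60), substring(circle, 1, 30))
  expect_identical(ctx60$sequence, rotation)

  # too-short circle errors and suggests a feasible context_width
  tg5 <- toy_circle_genome("ACGTA")
  expect_error(build_junction_context(tg5$circ, tg5$genome, design_params()),
               "context_width of at most 2")
})

test_that("multi-exon and minus-strand circles honour the mature sequence", {
  e1 <- rdna(40, seed = 41)
  e2 <- rdna(35, seed = 42)
  genome <- c(chr1 = paste0(rdna(20, 43), e1, rdna(25, 44), e2, rdna(20, 45)))
  cc <- circ_model("cmx", "chr1", "+", 20, 120,
                   exons = cbind(start = c(20L, 85L), end = c(60L, 120L)))
  ctx <- build_junction_context(cc, genome, design_params(context_width = 25L))
  mature <- paste0(e1, e2)
  expect_identical(ctx$sequence,
                   paste0(substring(mature, 51, 75), substring(mature, 1, 25)))

  tgm <- toy_circle_genome(rdna(80, 46), strand = "-")
  ctxm <- build_junction_context(tgm$circ, tgm$genome, design_params())
  mat <- circular_sequence(tgm$circ, tgm$genome)
  expect_identical(ctxm$sequence,
                   paste0(substring(mat, 51, 80), substring(mat, 1, 30)))
})

test_that("enumerate_guide_windows matches the brute-force count formula", {
  tg <- toy_circle_genome(rdna(100, seed = 6))
  ctx <- build_junction_context(tg$circ, tg$genome, design_params())
  expect_length(enumerate_guide_windows(ctx, design_params()), 12L)
  expect_length(enumerate_guide_windows(ctx, design_params(min_overhang = 10L)), 2L)
  splits <- vapply(enumerate_guide_windows(ctx, design_params(min_overhang = 10L)),
                   function(d) paste(d$side_5p, d$side_3p), character(1))
  expect_setequal(splits, c("11 10", "10 11"))

  # property: count = guide_length - 2*min_overhang + 1, brute-force checked
  for (L in c(12L, 18L, 21L, 24L)) {
    for (m in c(2L, 5L, L %/% 2L)) {
      p <- design_params(guide_length = L, min_overhang = m)
      ws <- enumerate_guide_windows(ctx, p)
      brute <- 0L
      w <- ctx$junction_index
      for (s in seq_len(2L * w - L + 1L)) {
        side5 <- w - s + 1L
        if (side5 >= m && (L - side5) >= m && side5 <= L) brute <- brute + 1L
      }
      expect_length(ws, L - 2L * m + 1L)
      expect_length(ws, brute)
      for (d in ws) {
        expect_identical(d$side_5p + d$side_3p, L)
        expect_gte(min(d$side_5p, d$side_3p), m)
        expect_identical(revcomp(d$guide), d$passenger)
      }
    }
  }
})

test_that("guides are exact reverse complements of junction-spanning windows", {
  tg <- toy_circle_genome(rdna(90, seed = 7))
  ctx <- build_junction_context(tg$circ, tg$genome)
  for (d in enumerate_guide_windows(ctx, design_params())) {
    win <- substring(ctx$sequence, d$target_window["start"],
                     d$target_window["end"])
    expect_identical(d$guide, bs_revcomp(win))
    # window crosses the junction
    expect_lte(d$target_window["start"], ctx$junction_index)
    expect_gt(d$target_window["end"], ctx$junction_index)
  }
})

test_that("primary design centres the window with the 5' tie-break", {
  tg <- toy_circle_genome(rdna(100, seed = 8))
  ctx <- build_junction_context(tg$circ, tg$genome)
  d21 <- design_primary(ctx)
  expect_identical(nchar(d21$guide), 21L)
  expect_identical(c(d21$side_5p, d21$side_3p), c(11L, 10L))
  d20 <- design_primary(ctx, design_params(guide_length = 20L))
  expect_identical(c(d20$side_5p, d20$side_3p), c(10L, 10L))
})

test_that("shifted design moves the window toward the target 3' side", {
  tg <- toy_circle_genome(rdna(100, seed = 9))
  ctx <- build_junction_context(tg$circ, tg$genome)
  prim <- design_primary(ctx)
  sh3 <- design_shifted(ctx, design_params(shift = 3L))
  expect_identical(c(sh3$side_5p, sh3$side_3p), c(8L, 13L))
  expect_identical(unname(sh3$target_window["start"] - prim$target_window["start"]), 3L)

  sh0 <- design_shifted(ctx, design_params(shift = 0L))
  expect_identical(sh0$target_window, prim$target_window)
  expect_identical(sh0$guide, prim$guide)

  expect_error(design_shifted(ctx, design_params(shift = 7L)),
               "feasible shifts are -5 to \\+6")

  # shifting by +s then -s recovers the primary window
  for (s in c(-4L, -1L, 2L, 5L)) {
    once <- design_shifted(ctx, design_params(shift = s))
    back_start <- once$target_window["start"] - s
    expect_identical(unname(back_start), unname(prim$target_window["start"]))
  }
})

test_that("host_linear_safety warns when one side alone reaches the threshold", {
  tg <- toy_circle_genome(rdna(100, seed = 10))
  ctx <- build_junction_context(tg$circ, tg$genome)
  prim <- design_primary(ctx)  # sides 11|10
  expect_false("host_linear_risk" %in% host_linear_safety(prim, 12L)$warnings)
  sh <- design_shifted(ctx, design_params(shift = 3L))  # sides 8|13
  expect_true("host_linear_risk" %in% host_linear_safety(sh, 12L)$warnings)
  expect_true("host_linear_risk" %in% sh$warnings)  # applied at construction
  d20 <- design_primary(ctx, design_params(guide_length = 20L))
  expect_false("host_linear_risk" %in% host_linear_safety(d20, 21L)$warnings)
  # idempotent
  twice <- host_linear_safety(host_linear_safety(sh, 12L), 12L)
  expect_identical(sum(twice$warnings == "host_linear_risk"), 1L)
})

test_that("windows span the junction but never occur in the linear host mRNA", {
  for (seed in c(101L, 102L)) {
    for (strand in c("+", "-")) {
      spec <- fixture_spec(rng_seed = seed, n_genes = 5,
                           circ_layout = list(n_exons = 2L,
                                              exon_lengths = c(110L, 80L),
                                              intron_length = 60L,
                                              strand = strand))
      loc <- synth_locus(spec)
      ctx <- build_junction_context(loc$circs[[1]], loc$genome)
      linear <- spliced_sequence(loc$transcripts[[1]], loc$genome)
      for (d in enumerate_guide_windows(ctx, design_params())) {
        expect_false(grepl(d$passenger, linear, fixed = TRUE))
        expect_true(grepl(d$passenger, ctx$sequence, fixed = TRUE))
      }
    }
  }
})

test_that("design parameter invariants are enforced", {
  expect_error(design_params(guide_length = 8L, min_overhang = 5L),
               "2 \\* min_overhang")
  expect_error(design_params(context_width = 10L), "context_width")
})
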