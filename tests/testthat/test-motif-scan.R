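aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("default matrix encodes the 1-4-7-8 weighting scheme", {
  m <- build_default_matrix()
  expect_equal(m$width, 15L)
  expect_equal(m$anchor_offset, 4L)
  w <- m$weights
  a <- m$anchor_offset
  # the anchor tryptophan weight is the single largest weight anywhere
  expect_equal(unname(w[a, "W"]), max(w))
  expect_true(w[a, "W"] > max(w[-a, ]))
  expect_true(all(w[a, setdiff(aa20, "W")] < w[a, "W"]))
  # K and R equal at motif positions 5 and 6
  expect_equal(unname(w[a + 4, "K"]), unname(w[a + 4, "R"]))
  expect_equal(unname(w[a + 5, "K"]), unname(w[a + 5, "R"]))
  # hydrophobics dominate positions 4, 7, 8, with intermediate A/C
  for (k in c(3, 6, 7)) {
    expect_true(all(w[a + k, c("L", "I", "V", "M", "F", "W")] >
                      w[a + k, "A"]))
    expect_true(w[a + k, "A"] > w[a + k, "G"])
  }
  expect_true(all(w >= 0))
})

test_that("window scores are bounded, anchored at the extremes, and match a
           hand-summed oracle", {
  m <- build_default_matrix()
  best <- consensus_window(m)
  worst <- paste(aa20[apply(m$weights, 1, which.min)], collapse = "")
  expect_equal(score_window(m, best), 0)
  expect_equal(score_window(m, worst), 1)

  # hand-summed oracle on the AKAP79 binding window padded with X:
  # W79 at motif position 1 -> window starts 3 residues upstream
  win <- "XGAWASLKRLVTRRK"  # 15-mer, W at window index 4
  letters_w <- strsplit(win, "")[[1]]
  pos_min <- apply(m$weights, 1, min)
  pos_max <- apply(m$weights, 1, max)
  raw <- sum(vapply(seq_len(15), function(p) {
    if (letters_w[p] == "X") pos_min[p] else m$weights[p, letters_w[p]]
  }, numeric(1)))
  oracle <- (sum(pos_max) - raw) / (sum(pos_max) - sum(pos_min))
  expect_equal(score_window(m, win), oracle, tolerance = 1e-6)

  # X scores the position minimum: all-X equals the worst window
  expect_equal(score_window(m, strrep("X", 15)), 1)
  expect_error(score_window(m, "TOOSHORT"), "width")
})

test_that("normalized score is invariant to positive affine weight rescaling", {
  m <- build_default_matrix()
  m2 <- motif_matrix(m$weights * 3.7 + 2, anchor_offset = m$anchor_offset)
  set.seed(5)
  for (i in 1:20) {
    win <- paste(sample(aa20, 15, TRUE), collapse = "")
    expect_equal(score_window(m, win), score_window(m2, win),
                 tolerance = 1e-12)
  }
})

test_that("scanning finds the AKAP79 anchor and respects thresholds", {
  m <- build_default_matrix()
  # peptide spanning AKAP79 77-92 placed at its full-length offset,
  # padded with X so every window is complete
  frag <- paste0(strrep("X", 6), "GAWASLKRLVTRRKRS", strrep("X", 10))
  hits <- scan_sequence(m, data.frame(id = "AKAP79", seq = frag),
                        threshold = 0.99, offset = 71)
  expect_gt(nrow(hits), 1)
  expect_equal(hits$anchor_pos[1], 79)
  expect_equal(hits$score[1], 0)
  expect_false(is.unsorted(hits$score))

  # poly-G scores worse than 0.5 everywhere
  polyg <- data.frame(id = "g", seq = strrep("G", 60))
  expect_equal(nrow(scan_sequence(m, polyg, threshold = 0.5)), 0)

  # sequences shorter than the window yield an empty result, not an error
  expect_equal(nrow(scan_sequence(m, data.frame(id = "s", seq = "GAWASL"))),
               0)
})

test_that("hit positions are translation-invariant under prepending", {
  m <- build_default_matrix()
  set.seed(31)
  body <- paste(sample(aa20, 80, TRUE), collapse = "")
  seq1 <- paste0(body, "XGAWASLKRLVTRRKX", body)
  pre <- paste(sample(setdiff(aa20, "W"), 7, TRUE), collapse = "")
  h1 <- scan_sequence(m, data.frame(id = "s", seq = seq1), 0.45)
  h2 <- scan_sequence(m, data.frame(id = "s", seq = paste0(pre, seq1)), 0.45)
  # prepended windows can only add hits wholly inside the prepend margin;
  # every original hit shifts by exactly nchar(pre)
  shifted <- h1$start + nchar(pre)
  expect_true(all(shifted %in% h2$start))
  common <- h2[h2$start %in% shifted, ]
  expect_equal(common$score[order(common$start)],
               h1$score[order(h1$start)])
})

test_that("proteome scans recover planted motifs and summarize scores", {
  m <- build_default_matrix()
  pr <- make_proteome(100, c(120, 300), n_planted = 10, seed = 7)
  res <- scan_proteome(m, pr$records, threshold = 0.5)
  expect_gte(res$summary$n_sites, 10)
  for (i in seq_len(nrow(pr$truth))) {
    expect_true(any(res$hits$id == pr$truth$id[i] &
                      res$hits$anchor_pos == pr$truth$anchor_pos[i]))
  }
  # W-dominance: no hit at threshold 0.5 lacks W at the anchor index
  expect_true(all(substr(res$hits$window, m$anchor_offset,
                         m$anchor_offset) == "W"))

  # summary arithmetic: median and unscaled MAD
  fake <- list(
    res1 = data.frame(id = "a", start = 1:3, anchor_pos = 4:6,
                      window = "w", score = c(0.2, 0.6, 0.7)))
  med <- median(c(0.2, 0.6, 0.7))
  expect_equal(med, 0.6)
  expect_equal(median(abs(c(0.2, 0.6, 0.7) - med)), 0.1)
  # and through the function on a constructed record set
  one <- scan_proteome(m, data.frame(id = "x", desc = "",
                                     seq = "XXXWASLKRLVXXXX"), 0.5)
  expect_equal(one$summary$n_sites, 1)
  expect_equal(one$summary$mad_score, 0)
})
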