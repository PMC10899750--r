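test_that("min-max rescaling maps to [0, 100] with degenerate handling", {
  expect_equal(minmax_rescale(c(5, 10, 15)), c(0, 50, 100))
  expect_equal(minmax_rescale(c(0, 1)), c(0, 100))
  expect_equal(minmax_rescale(c(3, 3, 3)), c(0, 0, 0))
  r <- minmax_rescale(c(2, NA, 4, 8))
  expect_equal(r, c(0, NA, 100 / 3, 100))
  # extremes attained
  set.seed(12)
  v <- runif(50)
  rs <- minmax_rescale(v)
  expect_equal(min(rs), 0)
  expect_equal(max(rs), 100)
})

test_that("motif score averages available windows", {
  expect_equal(motif_score(c(100, 100, 100)), 100)
  expect_equal(motif_score(c(0, 50, 100)), 50)
  # YCR fallback: DC22 unavailable, average of DC20/DC21
  expect_equal(motif_score(c(40, 60, NA)), 50)
  expect_true(is.na(motif_score(c(NA, NA, NA))))
})

test_that("pattern predicates encode the consensus definitions", {
  # canonical mWCU: A-U, C-C mismatch, U-containing third pair
  expect_true(is_mwcu_pattern("ACUUCU"))
  expect_false(is_mwcu_pattern("GCUCCU"))    # G-C first pair: not weak
  expect_false(is_mwcu_pattern("ACUUGU"))    # C-G second pair: no mismatch
  # canonical YCR: Y-containing, C-G, R-Y
  expect_true(is_ycr_pattern("CCGUGC"))
  expect_true(is_ycr_pattern("UCAAGU"))      # U-A / C-G / A-U
  expect_false(is_ycr_pattern("ACGAGC"))     # A-A first pair fails Y
  expect_false(is_ycr_pattern("CCGUGG"))     # G-G third pair not R-Y
  # strengths peak at the consensus
  expect_equal(mwcu_strength("ACUUCU"), 1)
  expect_equal(ycr_strength("CCGUGC"), 1)
  expect_equal(mwcu_strength("ACGUGU"), 0)   # paired second position
  expect_equal(ycr_strength("ACGAGC"), 0)    # R-R first position
  expect_true(all(mwcu_strength(c("GCUCCU", "UUCACA")) > 0))
})

test_that("window accuracy averages per motif over the right variants", {
  d <- default_design
  v <- build_variant_library(d, groups = 4)   # window 17-19
  pick <- v[v$fill5 %in% c("ACT", "CCT") & v$fill3 %in% c("TCT", "GGT"), ]
  acc <- data.frame(
    ref_id = rep(pick$variant_id, each = 1),
    site = 21L,
    accuracy = seq(0.1, by = 0.1, length.out = nrow(pick)),
    stringsAsFactors = FALSE
  )
  wa <- window_accuracy(acc, v, window_start = 17, site = 21, design = d)
  expect_equal(nrow(wa), 4)                   # 2 x 2 distinct motifs
  m1 <- pair_triple(pick$sequence[1], 17, d)
  expect_equal(wa$accuracy[wa$motif == m1],
               mean(acc$accuracy[pick$variant_id == pick$variant_id[1]]))
  # hand check one motif mean against a direct subset mean
  for (m in wa$motif) {
    ids <- pick$variant_id[pair_triple(pick$sequence, 17, d) == m]
    expect_equal(wa$accuracy[wa$motif == m],
                 mean(acc$accuracy[acc$ref_id %in% ids]))
  }
})

test_that("score_motifs assembles rescaled windows and counts availability", {
  d <- default_design
  v <- build_variant_library(d, groups = c(3, 4, 5, 6))
  truth <- simulate_library(v[v$window_start %in% 16:18, ],
                            cleavage_model("WT"), d,
                            n_reads = 300, seed = 91)
  acc <- truth_dc_accuracy(truth)
  sc <- score_motifs(acc, v, d, type = "mWCU")
  expect_equal(nrow(sc), 4096)
  expect_equal(unique(sc$n_windows), 3L)
  expect_true(all(sc$score >= 0 & sc$score <= 100, na.rm = TRUE))
  # each rescaled window attains 0 and 100
  for (col in c("mWCU_DC20", "mWCU_DC21", "mWCU_DC22")) {
    expect_equal(min(sc[[col]], na.rm = TRUE), 0)
    expect_equal(max(sc[[col]], na.rm = TRUE), 100)
  }

  # YCR windows: the 20-22 window reads its third pair from the backbone,
  # so only matching motifs have three windows; the rest use the fallback
  truth_y <- simulate_library(v[v$window_start %in% 18:19, ],
                              cleavage_model("dsRBD_del"), d,
                              n_reads = 300, seed = 92)
  sy <- score_motifs(truth_dc_accuracy(truth_y), v, d, type = "YCR")
  expect_true(all(sy$n_windows %in% c(2L, 3L)))
  expect_true(any(sy$n_windows == 2L) && any(sy$n_windows == 3L))
  two <- sy[sy$n_windows == 2L, ]
  expect_equal(two$score,
               unname(rowMeans(two[, c("YCR_DC20", "YCR_DC21")], na.rm = TRUE)))
})

test_that("top composition pools sub-threshold combinations", {
  motifs <- c(rep("AAAAAA", 49), rep("CAAGAA", 951))
  scores <- data.frame(motif = motifs, score = 1, stringsAsFactors = FALSE)
  tc <- top_composition(scores)
  expect_equal(nrow(tc$top), 1000)            # uniform scores: all tied at cut
  p1 <- tc$composition[tc$composition$position == 1, ]
  expect_true("other" %in% p1$combo)          # A-A at 4.9% pooled
  expect_equal(p1$frequency[p1$combo == "C-G"], 0.951)
  expect_equal(p1$frequency[p1$combo == "other"], 0.049)
  # exactly at threshold is shown individually
  scores2 <- data.frame(motif = c(rep("AAAAAA", 50), rep("CAAGAA", 950)),
                        score = 1, stringsAsFactors = FALSE)
  p2 <- top_composition(scores2)$composition
  expect_true("A-A" %in% p2$combo[p2$position == 1])
})

test_that("motif_class ranks by score-table percentile", {
  set.seed(13)
  motifs <- replicate(200, paste(sample(c("A", "C", "G", "U"), 6,
                                        replace = TRUE), collapse = ""))
  motifs <- unique(motifs)
  mw <- data.frame(motif = motifs, score = seq_along(motifs),
                   stringsAsFactors = FALSE)
  yc <- data.frame(motif = motifs, score = rev(seq_along(motifs)),
                   stringsAsFactors = FALSE)
  top_m <- mw$motif[mw$score >= quantile(mw$score, 0.97)]
  bottom <- mw$motif[mw$score < quantile(mw$score, 0.03)]
  expect_true(all(motif_class(top_m, mw, yc) == "mWCU"))
  expect_true(all(motif_class(bottom, mw, yc) == "YCR"))
  mid <- mw$motif[round(length(motifs) / 2)]
  expect_equal(motif_class(mid, mw, yc), "neither")
})

test_that("stem filter excludes variants with altered stems", {
  d <- default_design
  v <- build_variant_library(d, groups = 4)[1:400, ]
  prof <- profile_variants(v, d)
  # sabotage half the profiles to a shorter stem
  prof$stem_len[seq_len(200)] <- d$stem_len - 1L
  acc <- data.frame(ref_id = v$variant_id, site = 21L, accuracy = 0.5,
                    stringsAsFactors = FALSE)
  wa <- window_accuracy(acc, v, 17, 21, d, profiles = prof)
  expect_equal(sum(wa$n_variants), 200)
})
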