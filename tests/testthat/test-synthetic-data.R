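test_that("library enumeration yields every variant of every group", {
  d <- default_design
  g1 <- build_variant_library(d, groups = 1)
  expect_equal(nrow(g1), 4096)
  expect_equal(length(unique(g1$sequence)), 4096)
  expect_true(all(nchar(g1$sequence) == d$full_len))
  # the all-backbone fill reconstructs the reference substrate
  expect_true(reference_flos(d) %in% g1$sequence)
})

test_that("windows outside the stem are a configuration error", {
  expect_error(library_design(window_starts = c(14, 21)), "outside")
})

test_that("dedup over overlapping groups matches the closed form", {
  d <- default_design
  all6 <- build_variant_library(d)
  ref <- dedup_reference(all6)
  expect_equal(nrow(all6), 6 * 4096)
  expect_equal(nrow(ref), 23296)
  expect_equal(count_unique_variants(d$window_starts, d$window_len), 23296)

  # two disjoint windows share only the all-backbone fill
  suppressWarnings(d2 <- library_design(window_starts = c(14, 17)))
  ref2 <- dedup_reference(build_variant_library(d2))
  expect_equal(nrow(ref2), 2 * 4096 - 1)
  expect_equal(count_unique_variants(c(14, 17)), 2 * 4096 - 1)
})

test_that("closed-form unique count matches set enumeration on random layouts", {
  # oracle: explicit enumeration over assignments with a reduced alphabet
  enumerate_unique <- function(starts, wlen, alpha) {
    positions <- sort(unique(unlist(lapply(starts, function(s) s:(s + wlen - 1)))))
    seen <- character(0)
    for (g in seq_along(starts)) {
      win <- starts[g]:(starts[g] + wlen - 1)
      grid <- expand.grid(rep(list(seq_len(alpha)), length(win)))
      fills <- apply(grid, 1, function(row) {
        full <- rep(1L, length(positions))
        full[match(win, positions)] <- row
        paste(full, collapse = ",")
      })
      seen <- union(seen, fills)
    }
    length(seen)
  }
  set.seed(20)
  for (rep in 1:5) {
    starts <- sort(sample(1:8, sample(2:4, 1)))
    wlen <- 2
    alpha <- 4
    expect_equal(count_unique_variants(starts, wlen, pair_alphabet = alpha),
                 enumerate_unique(starts, wlen, alpha))
  }
})

test_that("simulate_cleavage: baseline, gating, and softmax limit", {
  d <- default_design
  v <- build_variant_library(d, groups = c(1, 4, 6))
  # all betas zero: identical distribution for every variant
  m0 <- cleavage_model("WT", beta_mwcu = 0, beta_ycr = 0,
                       ycr_sc_suppression = 0)
  p <- cleavage_probabilities(v[sample.int(nrow(v), 50), ], m0, d)
  expect_true(all(abs(sweep(p, 2, p[1, ])) < 1e-12))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-12)

  # planted 17-mWCU gated off under dsRBD deletion
  mwcu_v <- v[v$window_start == 17 & v$fill5 == "ACT" & v$fill3 == "TCT", ]
  ctrl_v <- v[v$window_start == 17 & v$fill5 == substr(d$backbone_5p, 17, 19) &
                v$sequence == reference_flos(d), ]
  expect_equal(mwcu_strength(pair_triple(mwcu_v$sequence, 17, d)), 1)
  mdel <- cleavage_model("dsRBD_del")
  p_planted <- simulate_cleavage(mwcu_v, mdel, d)
  p_ctrl <- simulate_cleavage(ctrl_v$sequence[1], mdel, d, window_start = 17)
  y_ctrl <- ycr_strength(pair_triple(ctrl_v$sequence[1], 17, d))
  expect_equal(y_ctrl, 0)  # backbone carries no YCR at 17
  expect_equal(as.numeric(p_planted), as.numeric(p_ctrl), tolerance = 1e-12)
  # but stimulates DC21 under WT
  mwt <- cleavage_model("WT")
  expect_gt(simulate_cleavage(mwcu_v, mwt, d)["DC21"],
            simulate_cleavage(ctrl_v$sequence[1], mwt, d, 17)["DC21"])

  # extreme beta_ycr with a planted 19-YCR drives DC21 to the DC maximum
  ycr_v <- v[v$window_start == 19 & v$fill5 == "CCG" & v$fill3 == "TGC", ]
  expect_equal(ycr_strength(pair_triple(ycr_v$sequence, 19, d)), 1)
  mbig <- cleavage_model("WT", beta_ycr = 50)
  pb <- simulate_cleavage(ycr_v, mbig, d)
  dc <- pb[paste0("DC", 19:23)]
  expect_equal(names(which.max(dc)), "DC21")
  expect_gt(dc["DC21"], 0.99)
})

test_that("emit_reads layout, determinism and degenerate input", {
  d <- default_design
  v <- build_variant_library(d, groups = 2)[7:10, ]
  m <- cleavage_model("WT")
  truth <- simulate_library(v, m, d, n_reads = 40, os_reads = 5, seed = 5)
  r1 <- emit_reads(truth, seed = 9)
  r2 <- emit_reads(truth, seed = 9)
  expect_identical(r1, r2)
  r3 <- emit_reads(truth, seed = 10)
  expect_false(identical(r1$dc$seq, r3$dc$seq))

  # DC read structure: UMIs + fragment(x+1..y with the loop) + adapter
  dc1 <- r1$dc[1, ]
  info <- strsplit(dc1$id, "_")[[1]]
  vid <- paste(info[3:5], collapse = "_")
  site <- as.integer(sub("DC", "", info[6]))
  flos <- v$sequence[v$variant_id == vid]
  body <- substr(dc1$seq, d$umi5_len_dc + 1,
                 nchar(dc1$seq) - d$umi3_len - nchar(d$adapter3))
  sp <- split_two_loop(body, d$loop_delim_left, d$loop_delim_right)
  expect_length(sp$part, 1)
  expect_identical(sp$part, substr(flos, site + 1, d$coord_const - site))
  loc <- locate_product(sp$part, flos)
  expect_identical(c(loc$x, loc$y), c(site, d$coord_const - site))

  # zero reads: empty but valid FASTQ
  t0 <- simulate_library(v, m, d, n_reads = 0, os_reads = 0, seed = 5)
  tmp <- withr::local_tempdir()
  r0 <- emit_reads(t0, seed = 9, dir = tmp)
  expect_equal(nrow(r0$dc), 0)
  p <- attr(r0, "paths")
  expect_true(all(file.exists(p[c("os", "dc", "sc")])))
  expect_equal(file.size(p[["dc"]]), 0)
  expect_equal(nrow(read_fastq(p[["os"]])), 0)

  # file emission is byte-identical for identical seeds
  tmp2 <- withr::local_tempdir()
  emit_reads(truth, seed = 9, dir = tmp2, prefix = "a")
  emit_reads(truth, seed = 9, dir = tmp2, prefix = "b")
  expect_identical(readLines(file.path(tmp2, "a_dc.fastq")),
                   readLines(file.path(tmp2, "b_dc.fastq")))
})

test_that("ground truth counts are reproducible multinomial draws", {
  d <- default_design
  v <- build_variant_library(d, groups = 1)[1:6, ]
  m <- cleavage_model("WT")
  t1 <- simulate_library(v, m, d, n_reads = 500, seed = 42)
  t2 <- simulate_library(v, m, d, n_reads = 500, seed = 42)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$barcodes, t2$barcodes)
  expect_equal(unname(rowSums(t1$counts)), rep(500, 6))
})
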