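# 22-bp perfect hairpin: arm 1..22, loop 23..30, arm 31..52, 2-nt tail.
# Pairing table partner(i) = 53 - i, so a 5'-strand cut at x pairs the 3p
# 5' end at 53 - (x - 2) = 55 - x.

test_that("cleavage site from mature annotations via pairing geometry", {
  r <- toy_hairpin(mature5p = c(1, 21), mature3p = c(34, 54))
  cs <- find_cleavage_site(r)
  expect_false(cs$flagged)
  expect_equal(cs$x, 21)
  expect_equal(cs$y, 33)

  # 3p-only annotation infers x through the pairing table (2-nt overhang)
  r3 <- toy_hairpin(mature3p = c(34, 54))
  expect_equal(find_cleavage_site(r3)$x, 21)
  # 5p-only annotation reads x directly from the mature 3' end
  r5 <- toy_hairpin(mature5p = c(1, 21))
  expect_equal(find_cleavage_site(r5)$x, 21)

  # disagreeing annotations flag the record
  rbad <- toy_hairpin(mature5p = c(1, 20), mature3p = c(34, 54))
  cs_bad <- find_cleavage_site(rbad)
  expect_true(cs_bad$flagged)
  expect_equal(cs_bad$reason, "mature_annotations_disagree")

  # no annotation: skipped with reason
  r0 <- toy_hairpin()
  expect_equal(find_cleavage_site(r0)$reason, "no_mature_annotation")
})

test_that("positional scores look up pairing-table motif triples", {
  arm <- "GACGTCATAGACTACTGGTCAT"
  r <- toy_hairpin(arm5 = arm)
  # motif at 17: the three 5'-strand nt plus their complements, pair order
  m17 <- chartr("T", "U", paste0(substr(arm, 17, 19),
                                 chartr("ACGT", "TGCA", substr(arm, 17, 19))))
  tab <- data.frame(motif = m17, score = 39.9, stringsAsFactors = FALSE)
  sc <- assign_scores(r, mwcu_scores = tab, positions = 17)
  expect_equal(sc$motif, m17)
  expect_equal(sc$mwcu_score, 39.9)
  # motif absent from the table: no score
  sc22 <- assign_scores(r, mwcu_scores = tab, positions = 18)
  expect_true(is.na(sc22$mwcu_score))
  # windows broken by the loop give no motif
  sc_loop <- assign_scores(r, mwcu_scores = tab, positions = 22)
  expect_true(is.na(sc_loop$motif))
})

test_that("symmetric mismatches are part of motif triples", {
  arm <- "GACGTCATAGACTACTGGTCAT"
  r <- toy_hairpin_mismatch(arm, mm = 18)
  m <- hairpin_triple(r, 17)
  expect_equal(substr(m, 2, 2), "C")
  expect_equal(substr(m, 5, 5), "C")        # the planted C-C mismatch
  expect_equal(nchar(m), 6)
})

test_that("SNP selection uses the 20-unit score threshold", {
  arm_wt <- "GACGTCATAGACTACTGGTCAT"
  r_wt <- toy_hairpin(arm5 = arm_wt)
  arm_snp <- arm_wt
  substr(arm_snp, 18, 18) <- "A"
  r_snp <- toy_hairpin(arm5 = arm_snp, id = "toy_snp")
  m_wt <- hairpin_triple(r_wt, 17)
  m_snp <- hairpin_triple(r_snp, 17)
  tab <- data.frame(motif = c(m_wt, m_snp), score = c(39.9, 19.8),
                    stringsAsFactors = FALSE)
  ev <- snp_impact(r_wt, r_snp, 17, tab)
  expect_equal(ev$delta, -20.1)
  expect_true(ev$selected)                   # |delta| = 20.1 >= 20
  tab2 <- data.frame(motif = c(m_wt, m_snp), score = c(39.9, 29.9),
                     stringsAsFactors = FALSE)
  expect_false(snp_impact(r_wt, r_snp, 17, tab2)$selected)   # |delta| = 10
  # wt vs wt has delta 0
  expect_equal(snp_impact(r_wt, r_wt, 17, tab)$delta, 0)
})

test_that("upstream motif enrichment counts carriers per species", {
  # control arm without any C in 5'-strand positions 14-22, so no C-G pair
  # (hence no YCR) can sit in the upstream window; the carrier plants
  # C-G/C-G/G-C at positions 19-21, 3 nt upstream of x = 21
  arm_n <- "GACGTCATAGACTAAGTGGTAT"
  arm_y <- arm_n
  substr(arm_y, 19, 21) <- "CCG"
  recs <- list()
  for (i in 1:4) recs[[i]] <- toy_hairpin(arm5 = arm_y, id = paste0("y", i),
                                          mature5p = c(1, 21))
  for (i in 5:10) recs[[i]] <- toy_hairpin(arm5 = arm_n, id = paste0("n", i),
                                           mature5p = c(1, 21))
  m_planted <- hairpin_triple(recs[[1]], 19)
  expect_true(is_ycr_pattern(m_planted))
  enr <- motif_enrichment(recs, predicate = is_ycr_pattern, window = 5)
  expect_equal(enr$frequency, 4 / 10)
  # all carriers
  enr1 <- motif_enrichment(recs[1:4], predicate = is_ycr_pattern, window = 5)
  expect_equal(enr1$frequency, 1)
  # exclusion honoured (family removal)
  enr_ex <- motif_enrichment(recs, predicate = is_ycr_pattern, window = 5,
                             exclude = c("y1", "y2"))
  expect_equal(enr_ex$frequency, 2 / 8)
  # no records: missing
  expect_equal(nrow(motif_enrichment(list())), 0)
})

test_that("isomiR DCx classification skips bulges and applies filters", {
  # hairpin with a bulge at 5'-arm position 10
  arm1 <- "GACGTCATA"; arm2 <- "GACTACTGGTCAT"
  seqh <- paste0(arm1, "G", arm2, strrep("A", 8),
                 revcomp(paste0(arm1, arm2)), "AT")
  db <- paste0(strrep("(", 9), ".", strrep("(", 13), strrep(".", 8),
               strrep(")", 22), "..")
  rec <- premirna_record("mir-b", seqh, db)
  pt <- rec$profile$pairs
  # 3p read whose first duplexed partner is 5'-arm position 20 implies
  # x_cut = 22 on the sequence; with the bulge excluded the register is 21
  m3s <- pt[20]
  reads <- data.frame(
    mirna_id = "mir-b",
    start = m3s,
    reads = c(100, 80),
    modified = FALSE,
    sample = c("WT", "dsRBD_del"),
    stringsAsFactors = FALSE
  )
  res <- isomir_dcx(reads, list("mir-b" = rec))
  expect_equal(unique(res$calls$dcx), 21L)

  # strictly more than 10 raw reads required
  reads10 <- transform(reads, reads = c(10, 80))
  res10 <- isomir_dcx(reads10, list("mir-b" = rec))
  expect_false("WT" %in% res10$calls$sample)

  # modified ends are excluded
  readsmod <- transform(reads, modified = TRUE)
  expect_equal(nrow(isomir_dcx(readsmod, list("mir-b" = rec))$calls), 0)

  # DC21 share must exceed 5% of all DCs in the reference sample
  rec2 <- toy_hairpin(id = "mir-c")
  pt2 <- rec2$profile$pairs
  reads2 <- data.frame(
    mirna_id = "mir-c",
    start = c(pt2[19], pt2[18], pt2[19], pt2[18]),
    reads = c(4, 96, 50, 50),
    modified = FALSE,
    sample = c("WT", "WT", "dsRBD_del", "dsRBD_del"),
    stringsAsFactors = FALSE
  )
  res2 <- isomir_dcx(reads2, list("mir-c" = rec2))
  expect_equal(nrow(res2$dc21_fold_change), 0)   # DC21 at 4% in WT: excluded
  reads3 <- transform(reads2, reads = c(10, 90, 50, 50))
  res3 <- isomir_dcx(reads3, list("mir-c" = rec2))
  expect_equal(nrow(res3$dc21_fold_change), 1)
  expect_equal(res3$dc21_fold_change$fold_change, 0.5 / 0.1)
})
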