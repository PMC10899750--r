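#' A pre-miRNA hairpin record
#'
#' Bundles a hairpin sequence with its predicted secondary structure and the
#' annotated mature 5p/3p spans (1-based, inclusive, on the hairpin).
#'
#' @param id Identifier.
#' @param sequence Hairpin sequence (RNA or DNA; stored as RNA).
#' @param dotbracket Dot-bracket secondary structure of the hairpin.
#' @param mature5p,mature3p Optional integer `c(start, end)` spans.
#' @param species Optional species label.
#' @return An object of class `"premirna_record"`.
#' @export
premirna_record <- function(id, sequence, dotbracket, mature5p = NULL,
                            mature3p = NULL, species = NA_character_) {
  sequence <- chartr("Tt", "Uu", toupper(sequence))
  n <- nchar(sequence)
  if (nchar(dotbracket) != n)
    stop("sequence and dot-bracket lengths differ")
  chk <- function(span, what) {
    if (is.null(span)) return(NULL)
    span <- as.integer(span)
    if (length(span) != 2 || span[1] < 1 || span[2] > n || span[1] > span[2])
      stop("invalid ", what, " span")
    span
  }
  structure(list(id = id, sequence = sequence, dotbracket = dotbracket,
                 mature5p = chk(mature5p, "mature5p"),
                 mature3p = chk(mature3p, "mature3p"),
                 species = species,
                 profile = annotate_structure(dotbracket, sequence)),
            class = "premirna_record")
}

# Pairing table augmented with symmetric-mismatch partners: positions inside
# equal-length internal loops are paired off outside-in, so motif triples can
# include mismatched pairs. Bulged (B) and asymmetric (A) positions keep no
# partner.
augmented_pairs <- function(profile) {
  pt <- profile$pairs
  sym <- strsplit(profile$symbols, "")[[1]]
  n <- length(pt)
  paired_i <- which(!is.na(pt) & seq_len(n) < pt)   # 5'-side pair positions
  for (k in seq_len(max(0, length(paired_i) - 1))) {
    i1 <- paired_i[k]; i2 <- paired_i[k + 1]
    j1 <- pt[i1]; j2 <- pt[i2]
    g5 <- i2 - i1 - 1L; g3 <- j1 - j2 - 1L
    if (g5 > 0 && g5 == g3 && all(sym[(i1 + 1):(i2 - 1)] == "M")) {
      for (t in seq_len(g5)) {
        pt[i1 + t] <- j1 - t
        pt[j1 - t] <- i1 + t
      }
    }
  }
  pt
}

#' Locate the DICER cleavage site of a pre-miRNA
#'
#' The 5'-strand cut coordinate `x` (cut between `x` and `x+1`) is taken
#' from the 3' end of the mature 5p miRNA when annotated. When only the
#' mature 3p is annotated, `x` is inferred from the 3p 5' end through the
#' pairing table with 2-nt 3'-overhang geometry: the first paired position
#' at or after the 3p start, whose partner plus two (plus any skipped
#' unpaired offset) gives `x`. When both matures are annotated the two
#' estimates must agree, otherwise the record is flagged.
#'
#' @param record A [premirna_record()].
#' @return A list `x` (5'-strand cut), `y` (3'-strand cut: last position of
#'   the loop-side fragment), `flagged` (logical) and `reason`.
#' @export
find_cleavage_site <- function(record) {
  r <- record
  if (is.null(r$mature5p) && is.null(r$mature3p))
    return(list(x = NA_integer_, y = NA_integer_, flagged = TRUE,
                reason = "no_mature_annotation"))
  x5 <- if (!is.null(r$mature5p)) r$mature5p[2] else NA_integer_
  x3 <- NA_integer_
  y <- if (!is.null(r$mature3p)) r$mature3p[1] - 1L else NA_integer_
  if (!is.null(r$mature3p)) {
    pt <- augmented_pairs(r$profile)
    m3s <- r$mature3p[1]
    off <- 0L
    while (m3s + off <= length(pt) && is.na(pt[m3s + off])) off <- off + 1L
    if (m3s + off <= length(pt)) {
      # partner of the first duplexed 3p position, +2 for the overhang,
      # +off to undo the walked-over unpaired nucleotides
      x3 <- pt[m3s + off] + 2L + off
    }
  }
  x <- if (!is.na(x5)) x5 else x3
  flagged <- !is.na(x5) && !is.na(x3) && x5 != x3
  if (is.na(y) && !is.na(x)) y <- NA_integer_
  list(x = as.integer(x), y = as.integer(y), flagged = flagged,
       reason = if (flagged) "mature_annotations_disagree" else NA_character_)
}

#' Pair-triple motif at a 5'-strand position of a folded hairpin
#'
#' Reads the three consecutive pair combinations starting at `position` from
#' the mismatch-augmented pairing table. Bulged positions (`B`) encountered
#' on the walk are skipped (up to `max_skip`); a loop, terminal or
#' asymmetric-loop position breaks the triple and yields `NA`.
#'
#' @param record A [premirna_record()].
#' @param position First pair position of the motif on the 5' strand.
#' @param max_skip Maximum number of bulged positions skipped.
#' @return A 6-character motif string, or `NA`.
#' @export
hairpin_triple <- function(record, position, max_skip = 2L) {
  pt <- augmented_pairs(record$profile)
  sym <- strsplit(record$profile$symbols, "")[[1]]
  seq <- strsplit(record$sequence, "")[[1]]
  pos <- integer(0)
  i <- position
  skips <- 0L
  while (length(pos) < 3L && i <= length(pt)) {
    if (!is.na(pt[i])) {
      pos <- c(pos, i)
    } else if (sym[i] == "B" && skips < max_skip && length(pos) > 0) {
      skips <- skips + 1L
    } else {
      return(NA_character_)
    }
    i <- i + 1L
  }
  if (length(pos) < 3L) return(NA_character_)
  paste0(paste(seq[pos], collapse = ""),
         paste(seq[pt[pos]], collapse = ""))
}

#' Assign positional mWCU and YCR scores to a pre-miRNA
#'
#' For each candidate motif position, extracts the three consecutive pair
#' combinations from the (mismatch-augmented) pairing table and looks the
#' motif up in the supplied score tables. Windows broken by loops or
#' asymmetric internal loops, and motifs absent from a table, yield `NA`.
#'
#' @param record A [premirna_record()].
#' @param mwcu_scores,ycr_scores Score tables from [score_motifs()] (or any
#'   data.frame with `motif` and `score`).
#' @param positions Candidate first-pair positions (default 17:22).
#' @return Data.frame `position`, `motif`, `mwcu_score`, `ycr_score`.
#' @export
assign_scores <- function(record, mwcu_scores = NULL, ycr_scores = NULL,
                          positions = 17:22) {
  motif <- vapply(positions, function(p) hairpin_triple(record, p), "")
  lookup <- function(tab) {
    if (is.null(tab)) return(rep(NA_real_, length(motif)))
    tab$score[match(motif, tab$motif)]
  }
  data.frame(position = positions, motif = motif,
             mwcu_score = lookup(mwcu_scores),
             ycr_score = lookup(ycr_scores),
             stringsAsFactors = FALSE)
}

#' Score impact of a single-nucleotide change
#'
#' Compares the positional motif score of a wild-type record and its SNP
#' counterpart (each folded independently) at one position; events moving
#' the score by at least `min_delta` units are selected.
#'
#' @param wt_record,snp_record [premirna_record()]s.
#' @param position Motif first-pair position.
#' @param scores Score table (`motif`, `score`).
#' @param type Label for the score used (informational).
#' @param min_delta Selection threshold on `|delta|` (default 20).
#' @return A one-row data.frame `id`, `position`, `type`, `wt_score`,
#'   `snp_score`, `delta`, `selected`.
#' @export
snp_impact <- function(wt_record, snp_record, position, scores,
                       type = "mWCU", min_delta = 20) {
  wt <- assign_scores(wt_record, mwcu_scores = scores,
                      positions = position)$mwcu_score
  sn <- assign_scores(snp_record, mwcu_scores = scores,
                      positions = position)$mwcu_score
  delta <- sn - wt
  data.frame(id = wt_record$id, position = position, type = type,
             wt_score = wt, snp_score = sn, delta = delta,
             selected = !is.na(delta) & abs(delta) >= min_delta,
             stringsAsFactors = FALSE)
}

#' Upstream motif enrichment across pre-miRNAs
#'
#' Fraction of pre-miRNAs (per species) carrying at least one class-member
#' motif whose first pair position falls within the stated window upstream
#' of the DICER cleavage site. "1 nt from the site" is the position
#' immediately 5' of the cut (`x` itself), so a window of `k` nt covers
#' first positions `x - k + 1 .. x`.
#'
#' @param records List of [premirna_record()]s.
#' @param predicate Motif membership predicate, e.g. [is_ycr_pattern()]
#'   (default) or [is_mwcu_pattern()].
#' @param window Window size in nt upstream of the cut (5 for YCR, 7 for
#'   mWCU).
#' @param exclude Character vector of record ids to exclude (e.g. a
#'   structurally redundant miRNA family).
#' @return Data.frame `species`, `n`, `n_with_motif`, `frequency`
#'   (`NA` frequency when a species has no usable records).
#' @export
motif_enrichment <- function(records, predicate = is_ycr_pattern, window = 5,
                             exclude = NULL) {
  if (length(exclude))
    records <- Filter(function(r) !(r$id %in% exclude), records)
  rows <- lapply(records, function(r) {
    cs <- find_cleavage_site(r)
    if (is.na(cs$x) || cs$flagged) return(NULL)
    first_pos <- seq.int(max(1L, cs$x - window + 1L), cs$x)
    hit <- FALSE
    for (p in first_pos) {
      m <- hairpin_triple(r, p)
      if (!is.na(m) && predicate(m)) { hit <- TRUE; break }
    }
    data.frame(species = r$species, hit = hit, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(species = character(), n = integer(),
                      n_with_motif = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  n <- tapply(rows$hit, rows$species, length)
  k <- tapply(rows$hit, rows$species, sum)
  data.frame(species = names(n), n = as.integer(n),
             n_with_motif = as.integer(k),
             frequency = as.numeric(k) / as.numeric(n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify 3p isomiRs by cleavage register (DCx)
#'
#' Each 3p small-RNA read implies a DICER double-cleavage register: the
#' 5'-strand cut inferred from the read's 5' end through the pairing table
#' (2-nt overhang geometry), expressed as `x` = the number of duplex
#' positions — base pairs and symmetric mismatches, bulges and asymmetric
#' positions excluded — from the hairpin 5' end to the cut. Reads must have
#' unmodified ends and each miRNA must exceed `min_reads` raw reads in a
#' sample to be kept. The DC21 analysis is restricted to miRNAs where DC21
#' exceeds `min_dc_fraction` of all DC calls in the reference sample, and
#' reports the fold change of the DC21 proportion between the two samples.
#'
#' @param reads Data.frame with columns `mirna_id`, `start` (hairpin
#'   coordinate of the read 5' end), `reads` (raw count), `modified`
#'   (logical: any untemplated / shifted end), `sample`.
#' @param records Named list of [premirna_record()]s keyed by `mirna_id`.
#' @param ref_sample,alt_sample Sample labels compared in the fold-change
#'   step (reference first, e.g. `"WT"` vs `"dsRBD_del"`).
#' @param min_reads Strict lower bound on raw reads per miRNA per sample.
#' @param min_dc_fraction Strict lower bound on the DC21 share of all DCs.
#' @return A list with `calls` (per miRNA/sample/DCx proportions) and
#'   `dc21_fold_change` (per miRNA fold change of the DC21 proportion).
#' @export
isomir_dcx <- function(reads, records, ref_sample = "WT",
                       alt_sample = "dsRBD_del", min_reads = 10,
                       min_dc_fraction = 0.05) {
  r <- reads[!reads$modified, , drop = FALSE]
  dcx <- mapply(function(id, start) {
    rec <- records[[id]]
    if (is.null(rec)) return(NA_integer_)
    pt <- augmented_pairs(rec$profile)
    sym <- strsplit(rec$profile$symbols, "")[[1]]
    off <- 0L
    while (start + off <= length(pt) && is.na(pt[start + off])) off <- off + 1L
    if (start + off > length(pt)) return(NA_integer_)
    x_cut <- pt[start + off] + 2L + off
    if (x_cut < 1L || x_cut > length(sym)) return(NA_integer_)
    sum(sym[seq_len(x_cut)] %in% c("b", "M"))
  }, r$mirna_id, r$start)
  r$dcx <- as.integer(dcx)
  r <- r[!is.na(r$dcx), , drop = FALSE]
  empty <- list(
    calls = data.frame(mirna_id = character(), sample = character(),
                       dcx = integer(), reads = numeric(), total = numeric(),
                       proportion = numeric(), stringsAsFactors = FALSE),
    dc21_fold_change = data.frame(mirna_id = character(),
                                  proportion_ref = numeric(),
                                  proportion_alt = numeric(),
                                  fold_change = numeric(),
                                  stringsAsFactors = FALSE))
  if (!nrow(r)) return(empty)

  tot <- stats::aggregate(list(total = r$reads),
                          by = list(mirna_id = r$mirna_id, sample = r$sample),
                          FUN = sum)
  keep <- tot[tot$total > min_reads, c("mirna_id", "sample")]
  r <- merge(r, keep, by = c("mirna_id", "sample"))
  if (!nrow(r)) return(empty)
  calls <- stats::aggregate(list(reads = r$reads),
                            by = list(mirna_id = r$mirna_id,
                                      sample = r$sample, dcx = r$dcx),
                            FUN = sum)
  totals <- stats::aggregate(list(total = calls$reads),
                             by = list(mirna_id = calls$mirna_id,
                                       sample = calls$sample),
                             FUN = sum)
  calls <- merge(calls, totals, by = c("mirna_id", "sample"))
  calls$proportion <- calls$reads / calls$total
  calls <- calls[order(calls$mirna_id, calls$sample, calls$dcx), , drop = FALSE]
  rownames(calls) <- NULL

  p21 <- calls[calls$dcx == 21L, , drop = FALSE]
  ref <- p21[p21$sample == ref_sample, c("mirna_id", "proportion")]
  alt <- p21[p21$sample == alt_sample, c("mirna_id", "proportion")]
  fc <- merge(ref, alt, by = "mirna_id", suffixes = c("_ref", "_alt"))
  fc <- fc[fc$proportion_ref > min_dc_fraction, , drop = FALSE]
  fc$fold_change <- fc$proportion_alt / fc$proportion_ref
  rownames(fc) <- NULL
  list(calls = calls, dc21_fold_change = fc)
}
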