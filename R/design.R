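#' Two-loop shRNA library design
#'
#' Describes the geometry of the two-loop short-hairpin construct used in the
#' high-throughput dicing assays: a 22-bp stem whose pair positions 14-21 are
#' randomized in six overlapping 3-bp windows, an apical (primary) loop, and a
#' secondary loop carrying a 32-nt random barcode flanked by fixed delimiter
#' sequences. The full-length original substrate (FL-OS) is the hairpin with
#' the delimiters and barcode removed; all cleavage coordinates are expressed
#' on the FL-OS.
#'
#' Pair position `i` on the 5' strand (`i` in 1..stem_len) pairs with FL-OS
#' position `full_len + 1 - i`. With the default `full_len = 70` and
#' `coord_const = 72`, a double cleavage at `x` on the 5' strand cuts the 3'
#' strand at `y = 72 - x`, leaving the canonical 2-nt 3' overhang on the
#' product duplex.
#'
#' @param backbone_5p 5'-strand stem sequence (one nt per pair position,
#'   5' to 3'; DNA alphabet).
#' @param loop_seq Apical-loop sequence between the two stem arms.
#' @param backbone_3p 3'-strand stem sequence as it appears in the construct
#'   (5' to 3'). Defaults to the reverse complement of `backbone_5p`.
#' @param window_starts 1-based pair-position offsets of the randomized 3-bp
#'   windows, one per group.
#' @param window_len Number of pair positions per randomized window.
#' @param barcode_len Length of the random secondary-loop barcode in nt.
#' @param umi5_len,umi3_len Lengths of the terminal randomized nt for OS/SC
#'   reads; DC reads use `umi5_len_dc`.
#' @param umi5_len_dc 5'-terminal randomized length for DC reads.
#' @param adapter3 3' sequencing adapter appended to emitted reads.
#' @param loop_delim_left,loop_delim_right Fixed sequences flanking the
#'   barcode inside the secondary loop.
#' @param loop_insert_pos FL-OS position after which the secondary loop
#'   (left delimiter + barcode + right delimiter) is inserted.
#' @param coord_const The constant `C` of the coordinate rule `y = C - x`.
#'
#' @return An object of class `"library_design"`.
#' @export
library_design <- function(backbone_5p = "GACGTCATAGACTACTGGTCAT",
                           loop_seq = "TCTCATTCAGATATCAACTCTTATCA",
                           backbone_3p = revcomp(backbone_5p),
                           window_starts = 14:19,
                           window_len = 3,
                           barcode_len = 32,
                           umi5_len = 6,
                           umi3_len = 4,
                           umi5_len_dc = 4,
                           adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                           loop_delim_left = "GCTTGC",
                           loop_delim_right = "GCAAGC",
                           loop_insert_pos = NULL,
                           coord_const = 72L) {
  stem_len <- nchar(backbone_5p)
  if (nchar(backbone_3p) != stem_len)
    stop("backbone_5p and backbone_3p must have equal length")
  full_len <- 2L * stem_len + nchar(loop_seq)
  if (full_len != coord_const - 2L)
    stop("design implies full_len ", full_len, " but coord_const - 2 = ",
         coord_const - 2L, "; adjust stem or loop length")
  win_ok <- all(window_starts >= 1 & window_starts + window_len - 1 <= stem_len)
  if (!win_ok)
    stop("randomized windows fall outside the stem (configuration error)")
  if (any(window_starts + window_len - 1 > 21) || any(window_starts < 14)) {
    # permitted, but the canonical library randomizes pair positions 14..21
    warning("windows extend outside pair positions 14..21")
  }
  if (is.null(loop_insert_pos))
    loop_insert_pos <- stem_len + ceiling(nchar(loop_seq) / 2)
  if (loop_insert_pos <= stem_len || loop_insert_pos >= full_len - stem_len)
    stop("loop_insert_pos must lie inside the apical loop")
  structure(list(
    backbone_5p = toupper(backbone_5p),
    backbone_3p = toupper(backbone_3p),
    loop_seq = toupper(loop_seq),
    stem_len = stem_len,
    window_starts = as.integer(window_starts),
    window_len = as.integer(window_len),
    barcode_len = as.integer(barcode_len),
    umi5_len = as.integer(umi5_len),
    umi3_len = as.integer(umi3_len),
    umi5_len_dc = as.integer(umi5_len_dc),
    adapter3 = toupper(adapter3),
    loop_delim_left = toupper(loop_delim_left),
    loop_delim_right = toupper(loop_delim_right),
    loop_insert_pos = as.integer(loop_insert_pos),
    full_len = as.integer(full_len),
    coord_const = as.integer(coord_const)
  ), class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("Two-loop shRNA library design\n")
  cat("  stem:", x$stem_len, "bp; FL-OS length:", x$full_len, "nt; C =",
      x$coord_const, "\n")
  cat("  randomized windows (pair positions):",
      paste(sprintf("%d-%d", x$window_starts,
                    x$window_starts + x$window_len - 1L), collapse = ", "),
      "\n")
  cat("  barcode:", x$barcode_len, "nt between", x$loop_delim_left, "and",
      x$loop_delim_right, "\n")
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Reference FL-OS sequence of a design
#'
#' The full-length original substrate with every randomized window at its
#' backbone (wild-type) fill.
#'
#' @param design A [library_design()].
#' @return A single DNA string of length `design$full_len`.
#' @export
reference_flos <- function(design) {
  paste0(design$backbone_5p, design$loop_seq, design$backbone_3p)
}

#' FL-OS position pairing with a 5'-strand pair position
#'
#' @param i Pair position(s) on the 5' strand.
#' @param design A [library_design()].
#' @return FL-OS coordinate(s) of the 3'-strand partner.
#' @export
partner_position <- function(i, design) {
  design$full_len + 1L - as.integer(i)
}

#' Enumerate all variants of the randomized library
#'
#' Each group randomizes `window_len` consecutive stem pair positions; both
#' strands of each pair position are free, so a 3-bp window yields
#' 16^3 = 4,096 variants per group. The variant's `fill5`/`fill3` record the
#' window nucleotides on the 5' and 3' strands in pair-position order.
#'
#' @param design A [library_design()].
#' @param groups Integer vector of group indices to enumerate (default: all).
#' @return A data.frame with columns `variant_id`, `group`, `window_start`,
#'   `fill5`, `fill3`, `sequence` (the FL-OS).
#' @export
build_variant_library <- function(design, groups = seq_along(design$window_starts)) {
  nt <- c("A", "C", "G", "T")
  w <- design$window_len
  ref <- reference_flos(design)
  out <- lapply(groups, function(g) {
    ws <- design$window_starts[g]
    cols <- expand.grid(rep(list(nt), 2L * w), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    # first w columns: 5'-strand fill; last w: 3'-strand fill (pair order)
    fill5 <- do.call(paste0, cols[seq_len(w)])
    fill3 <- do.call(paste0, cols[w + seq_len(w)])
    seqs <- apply_fill(ref, ws, fill5, fill3, design)
    data.frame(
      variant_id = sprintf("g%d_%s_%s", g, fill5, fill3),
      group = g,
      window_start = ws,
      fill5 = fill5,
      fill3 = fill3,
      sequence = seqs,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# Substitute a window fill into the reference FL-OS. fill3 is given in
# pair-position order; on the construct the partner positions run reversed.
apply_fill <- function(ref, window_start, fill5, fill3, design) {
  w <- design$window_len
  p5 <- window_start:(window_start + w - 1L)
  p3 <- partner_position(p5, design)          # decreasing FL-OS coordinates
  n <- max(length(fill5), length(fill3))
  seqs <- rep(ref, n)
  for (k in seq_len(w)) {
    substr(seqs, p5[k], p5[k]) <- substr(fill5, k, k)
    substr(seqs, p3[k], p3[k]) <- substr(fill3, k, k)
  }
  seqs
}

#' Collapse variants identical across groups
#'
#' Overlapping randomized windows generate identical full-length sequences in
#' more than one group (a sequence belongs to every group whose window covers
#' all of its deviations from the backbone). The reference set used for
#' exact matching keeps one canonical entry per distinct sequence.
#'
#' @param variants Output of [build_variant_library()].
#' @return A data.frame of unique sequences with columns `ref_id`,
#'   `sequence`, plus the originating `variant_id` of the canonical entry.
#' @export
dedup_reference <- function(variants) {
  keep <- !duplicated(variants$sequence)
  out <- variants[keep, c("variant_id", "group", "window_start", "fill5",
                          "fill3", "sequence")]
  out$ref_id <- out$variant_id
  rownames(out) <- NULL
  out
}

#' Closed-form count of unique library sequences
#'
#' Inclusion-exclusion over groups: a sequence is generated by group `g` iff
#' all of its deviations from the backbone lie inside window `g`, so the
#' intersection over a set of groups contributes `16^k` sequences where `k`
#' is the size of the windows' common overlap.
#'
#' @param window_starts Window start pair positions, one per group.
#' @param window_len Window length in pair positions.
#' @param pair_alphabet Number of distinct values per pair position
#'   (16 = 4 nt on each strand).
#' @return Integer count of unique sequences.
#' @export
count_unique_variants <- function(window_starts, window_len = 3,
                                  pair_alphabet = 16) {
  g <- length(window_starts)
  windows <- lapply(window_starts, function(s) s:(s + window_len - 1L))
  total <- 0
  for (mask in seq_len(2^g - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(g) - 1)) > 0)
    inter <- Reduce(intersect, windows[idx])
    total <- total + (-1)^(length(idx) + 1) * pair_alphabet^length(inter)
  }
  as.integer(round(total))
}

#' Assemble the full two-loop construct for a variant
#'
#' Inserts the delimiter-flanked barcode into the FL-OS at the secondary-loop
#' insertion point.
#'
#' @param flos FL-OS sequence(s).
#' @param barcode Barcode sequence(s) (recycled against `flos`).
#' @param design A [library_design()].
#' @return Character vector of full construct sequences.
#' @export
construct_sequence <- function(flos, barcode, design) {
  if (!length(flos)) return(character(0))
  p <- design$loop_insert_pos
  paste0(substr(flos, 1L, p),
         design$loop_delim_left, barcode, design$loop_delim_right,
         substring(flos, p + 1L))
}

#' Extract the pair-triple motif at a stem position
#'
#' Reads the three consecutive base pairs whose first pair sits at
#' `position`, returning the 6-character motif string: three 5'-strand nt
#' followed by their three 3'-strand partners, both in pair-position order,
#' in the RNA alphabet (T written as U).
#'
#' @param flos FL-OS sequence(s).
#' @param position First pair position of the motif.
#' @param design A [library_design()].
#' @return Character vector of 6-character motif strings.
#' @export
pair_triple <- function(flos, position, design) {
  p5 <- position:(position + 2L)
  if (any(p5 > design$stem_len))
    stop("motif window extends beyond the stem")
  p3 <- partner_position(p5, design)
  m <- paste0(substr(flos, p5[1], p5[1]), substr(flos, p5[2], p5[2]),
              substr(flos, p5[3], p5[3]),
              substr(flos, p3[1], p3[1]), substr(flos, p3[2], p3[2]),
              substr(flos, p3[3], p3[3]))
  chartr("T", "U", m)
}
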