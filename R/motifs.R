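#' @name motif-patterns
#' @title mWCU and YCR sequence-pattern predicates
#'
#' @description
#' A motif is an ordered triple of base pairs written as a 6-character RNA
#' string: the three 5'-strand nucleotides followed by their three 3'-strand
#' partners, both in pair-position order (e.g. `"AC U UCA"` without spaces,
#' first pair = A-U).
#'
#' `is_mwcu_pattern()` tests the mWCU consensus: a weak Watson-Crick pair
#' (A-U or U-A) in the first position, a C-C mismatch in the second, and a
#' U-containing combination in the third.
#'
#' `is_ycr_pattern()` tests the YCR consensus: a pyrimidine-containing
#' combination (excluding R-R) in the first position, a C-G pair in the
#' second, and an R-Y pair (G-C or A-U) in the third.
#'
#' These are the descriptive (sequence) predicates; classification of
#' observed motifs by score rank is done by [motif_class()].
NULL

motif_pairs <- function(motif) {
  motif <- chartr("Tt", "Uu", toupper(motif))
  if (any(nchar(motif) != 6L)) stop("motifs must be 6-character strings")
  lapply(1:3, function(k) {
    cbind(substr(motif, k, k), substr(motif, 3L + k, 3L + k))
  })
}

WC_PAIRS <- c("A-U", "U-A", "G-C", "C-G")
WOBBLE_PAIRS <- c("G-U", "U-G")

pair_key <- function(p) paste(p[, 1], p[, 2], sep = "-")

#' @rdname motif-patterns
#' @param motif Character vector of 6-character motif strings (RNA or DNA
#'   alphabet; T is read as U).
#' @return Logical vector.
#' @export
is_mwcu_pattern <- function(motif) {
  pr <- motif_pairs(motif)
  k1 <- pair_key(pr[[1]]); k2 <- pair_key(pr[[2]])
  p3 <- pr[[3]]
  (k1 %in% c("A-U", "U-A")) &
    (k2 == "C-C") &
    (p3[, 1] == "U" | p3[, 2] == "U")
}

#' @rdname motif-patterns
#' @export
is_ycr_pattern <- function(motif) {
  pr <- motif_pairs(motif)
  p1 <- pr[[1]]
  k2 <- pair_key(pr[[2]]); k3 <- pair_key(pr[[3]])
  has_y <- p1[, 1] %in% c("C", "U") | p1[, 2] %in% c("C", "U")
  has_y & (k2 == "C-G") & (k3 %in% c("G-C", "A-U"))
}

#' Graded motif strengths used by the cleavage simulator
#'
#' The simulator treats motif activity as continuous rather than all-or-none:
#' each of the three pair positions contributes a grade in \[0, 1\] reflecting
#' how closely it matches the consensus, and the overall strength is the
#' central (required) component times the mean of the two flanking grades.
#' A motif matching the strict consensus has strength 1; a motif lacking the
#' required central feature (a mismatch for mWCU, a C-G pair for YCR) has
#' strength 0.
#'
#' @param motif Character vector of 6-character motif strings.
#' @return Numeric vector of strengths in \[0, 1\].
#' @export
mwcu_strength <- function(motif) {
  pr <- motif_pairs(motif)
  k1 <- pair_key(pr[[1]]); k2 <- pair_key(pr[[2]]); p3 <- pr[[3]]
  w1 <- ifelse(k1 %in% c("A-U", "U-A"), 1,
        ifelse(k1 %in% WOBBLE_PAIRS, 0.5,
        ifelse(k1 %in% c("G-C", "C-G"), 0.35, 0.15)))
  # central component requires a mismatch; C-C is the consensus
  paired2 <- k2 %in% c(WC_PAIRS, WOBBLE_PAIRS)
  w2 <- ifelse(paired2, 0,
        ifelse(k2 == "C-C", 1,
        ifelse(pr[[2]][, 1] == "C" | pr[[2]][, 2] == "C", 0.6, 0.35)))
  w3 <- ifelse(p3[, 1] == "U" | p3[, 2] == "U", 1,
        ifelse(p3[, 1] == "C" | p3[, 2] == "C", 0.6, 0.3))
  w2 * (w1 + w3) / 2
}

#' @rdname mwcu_strength
#' @export
ycr_strength <- function(motif) {
  pr <- motif_pairs(motif)
  p1 <- pr[[1]]; k2 <- pair_key(pr[[2]]); k3 <- pair_key(pr[[3]])
  n_y <- (p1[, 1] %in% c("C", "U")) + (p1[, 2] %in% c("C", "U"))
  # required components: a pyrimidine-containing first pair (R-R excluded)
  # and the central C-G pair; the R-Y third position is graded
  w1 <- ifelse(n_y == 2, 1, ifelse(n_y == 1, 0.8, 0))
  w2 <- ifelse(k2 == "C-G", 1, 0)
  w3 <- ifelse(k3 %in% c("G-C", "A-U"), 1,
        ifelse(k3 %in% WOBBLE_PAIRS, 0.5,
        ifelse(k3 %in% c("C-G", "U-A"), 0.3, 0.15)))
  w1 * w2 * (0.4 + 0.6 * w3)
}
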