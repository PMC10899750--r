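#' Pairing table of a single-hairpin dot-bracket
#'
#' @param dotbracket Dot-bracket string using only `(`, `)` and `.`.
#' @return Integer vector: position of the partner, `NA` for unpaired.
#' @export
pairing_table <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("unsupported structure: only '(', ')' and '.' are handled")
  opens <- which(ch == "(")
  closes <- which(ch == ")")
  if (length(opens) != length(closes))
    stop("unbalanced dot-bracket")
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(opens) && length(closes) && max(opens) > min(closes))
    stop("unsupported structure: multiple hairpins or multiloop")
  pt
}

#' Six-symbol positional structure annotation
#'
#' Converts a single-hairpin dot-bracket into the six-symbol positional
#' code, one symbol per nucleotide:
#'
#' * `b` — base pair;
#' * `L` — apical loop (the unpaired block inside the innermost pair);
#' * `M` — symmetric internal mismatch (equal-length unpaired runs on both
#'   strands, paired off outside-in);
#' * `A` — asymmetric internal loop (unequal non-zero runs; every unpaired
#'   position on both sides);
#' * `B` — bulge (unpaired run on one strand only);
#' * `T` — terminal single-stranded overhang. Canonical substrates carry
#'   this only at the 3' terminus; a 5'-terminal dangling run, when present
#'   in user-supplied structures, is annotated the same way.
#'
#' @param dotbracket Dot-bracket string (balanced, single hairpin).
#' @param sequence Optional sequence of equal length (checked only).
#' @return An object of class `"structure_profile"`: list with `symbols`
#'   (single string), `stem_len`, `structure_id` and `pairs` (the pairing
#'   table).
#' @export
annotate_structure <- function(dotbracket, sequence = NULL) {
  pt <- pairing_table(dotbracket)
  n <- length(pt)
  if (!is.null(sequence) && nchar(sequence) != n)
    stop("sequence and dot-bracket lengths differ")
  sym <- rep(NA_character_, n)
  paired <- !is.na(pt)
  if (!any(paired)) stop("unsupported structure: no base pairs")
  sym[paired] <- "b"
  op <- which(substring(dotbracket, 1:n, 1:n) == "(")
  first_i <- min(which(paired)); last_j <- max(which(paired))
  if (first_i > 1) sym[seq_len(first_i - 1)] <- "T"
  if (last_j < n) sym[(last_j + 1):n] <- "T"
  # apical loop: inside the innermost pair
  inner_i <- max(op)
  inner_j <- pt[inner_i]
  if (inner_j > inner_i + 1) sym[(inner_i + 1):(inner_j - 1)] <- "L"
  # internal gaps between consecutive pairs of the stem
  stem5 <- op                      # ascending
  for (k in seq_len(length(stem5) - 1)) {
    i1 <- stem5[k]; i2 <- stem5[k + 1]
    j1 <- pt[i1]; j2 <- pt[i2]
    g5 <- i2 - i1 - 1L
    g3 <- j1 - j2 - 1L
    if (g5 == 0 && g3 == 0) next
    lab <- if (g5 == g3) "M" else if (g5 == 0 || g3 == 0) "B" else "A"
    if (g5 > 0) sym[(i1 + 1):(i2 - 1)] <- lab
    if (g3 > 0) sym[(j2 + 1):(j1 - 1)] <- lab
  }
  symbols <- paste(sym, collapse = "")
  structure(list(symbols = symbols,
                 stem_len = stem_length(symbols),
                 structure_id = symbols,
                 pairs = pt),
            class = "structure_profile")
}

#' Stem length of a structure profile
#'
#' Counts base pairs and symmetric mismatches on the 5' strand from the
#' first stem pair to the apical loop; bulged and asymmetric positions are
#' excluded by the rule.
#'
#' @param symbols A symbol string (or a `structure_profile`).
#' @return Integer stem length.
#' @export
stem_length <- function(symbols) {
  if (inherits(symbols, "structure_profile")) symbols <- symbols$symbols
  ch <- strsplit(symbols, "")[[1]]
  lpos <- which(ch == "L")
  end5 <- if (length(lpos)) min(lpos) - 1L else length(ch)
  sum(ch[seq_len(end5)] %in% c("b", "M"))
}

#' Group variants into structure classes and select populated classes
#'
#' @param profiles Data.frame with columns `variant_id` and `symbols`.
#' @param min_variants Minimum class size to keep (default 50).
#' @return A list with `classes` (data.frame `structure_id`, `n_variants`,
#'   `kept`) and `membership` (data.frame `variant_id`, `structure_id`,
#'   `kept`).
#' @export
select_structures <- function(profiles, min_variants = 50) {
  tab <- table(profiles$symbols)
  classes <- data.frame(structure_id = names(tab),
                        n_variants = as.integer(tab),
                        stringsAsFactors = FALSE)
  classes$kept <- classes$n_variants >= min_variants
  classes <- classes[order(-classes$n_variants), , drop = FALSE]
  rownames(classes) <- NULL
  membership <- data.frame(variant_id = profiles$variant_id,
                           structure_id = profiles$symbols,
                           stringsAsFactors = FALSE)
  membership$kept <- membership$structure_id %in%
    classes$structure_id[classes$kept]
  list(classes = classes, membership = membership)
}

#' Rule-based duplex annotation for library hairpins
#'
#' Stand-in for an external minimum-free-energy folder: pairs the two stem
#' arms of a designed hairpin position-wise (Watson-Crick and G-U wobble
#' count as paired) and leaves the apical loop unpaired. Register shifts,
#' bulges and refolding are outside this model — mismatched pair positions
#' stay in place as symmetric mismatches, so every library variant keeps the
#' designed stem length. Dot-bracket strings from a real folder can be
#' supplied to [annotate_structure()] instead.
#'
#' @param flos FL-OS sequence(s).
#' @param design The [library_design()].
#' @return Character vector of dot-bracket strings.
#' @export
fold_duplex <- function(flos, design) {
  s <- design$stem_len
  vapply(flos, function(f) {
    ch <- strsplit(f, "")[[1]]
    db <- rep(".", design$full_len)
    for (i in seq_len(s)) {
      j <- partner_position(i, design)
      if (is_paired_nt(ch[i], ch[j])) { db[i] <- "("; db[j] <- ")" }
    }
    # keep only the outermost-consistent nesting: with position-wise pairing
    # of complementary arms the result is always properly nested
    paste(db, collapse = "")
  }, "", USE.NAMES = FALSE)
}

is_paired_nt <- function(a, b) {
  k <- paste0(chartr("T", "U", a), "-", chartr("T", "U", b))
  k %in% c("A-U", "U-A", "G-C", "C-G", "G-U", "U-G")
}

#' Structure profiles for a variant table
#'
#' Convenience wrapper: folds every variant with [fold_duplex()] and
#' annotates it, returning a data.frame usable by [select_structures()] and
#' the motif-scoring stem filter.
#'
#' @param variants Data.frame with `variant_id` and `sequence` columns.
#' @param design The [library_design()].
#' @return Data.frame `variant_id`, `symbols`, `stem_len`.
#' @export
profile_variants <- function(variants, design) {
  db <- fold_duplex(variants$sequence, design)
  prof <- lapply(db, annotate_structure)
  data.frame(variant_id = variants$variant_id,
             symbols = vapply(prof, function(p) p$symbols, ""),
             stem_len = vapply(prof, function(p) p$stem_len, integer(1)),
             stringsAsFactors = FALSE)
}
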