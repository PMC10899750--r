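# Shared fixtures, built in code at test time.

default_design <- library_design()

# canonical reference id for a set of variants (variants duplicated across
# groups alias to the first group's entry)
canonical_ids <- function(variants, reference) {
  reference$ref_id[match(variants$sequence, reference$sequence)]
}

# --- random single-hairpin structures with known annotation ----------------
# Builds a dot-bracket by composing typed segments, so the expected symbol
# string is known by construction, independently of annotate_structure().
random_hairpin <- function(max_internal = 4) {
  left_db <- character(0); right_db <- character(0)
  left_sym <- character(0); right_sym <- character(0)
  push <- function(ldb, lsym, rdb, rsym) {
    left_db <<- c(left_db, ldb); left_sym <<- c(left_sym, lsym)
    right_db <<- c(right_db, rdb); right_sym <<- c(right_sym, rsym)
  }
  brun <- function() {
    k <- sample(1:5, 1)
    push(strrep("(", k), strrep("b", k), strrep(")", k), strrep("b", k))
  }
  brun()
  for (s in seq_len(sample(0:max_internal, 1))) {
    kind <- sample(c("M", "B5", "B3", "A"), 1)
    if (kind == "M") {
      g <- sample(1:3, 1)
      push(strrep(".", g), strrep("M", g), strrep(".", g), strrep("M", g))
    } else if (kind == "B5") {
      g <- sample(1:3, 1)
      push(strrep(".", g), strrep("B", g), "", "")
    } else if (kind == "B3") {
      g <- sample(1:3, 1)
      push("", "", strrep(".", g), strrep("B", g))
    } else {
      g5 <- sample(1:3, 1)
      g3 <- sample(setdiff(1:4, g5), 1)
      push(strrep(".", g5), strrep("A", g5), strrep(".", g3), strrep("A", g3))
    }
    brun()
  }
  loop <- sample(3:8, 1)
  tail <- sample(0:3, 1)
  db <- paste0(paste(left_db, collapse = ""), strrep(".", loop),
               paste(rev(right_db), collapse = ""), strrep(".", tail))
  sym <- paste0(paste(left_sym, collapse = ""), strrep("L", loop),
                paste(rev(right_sym), collapse = ""), strrep("T", tail))
  list(db = db, symbols = sym)
}

# --- toy pre-miRNA hairpins -------------------------------------------------
# Perfect-duplex hairpin: arm5 + loop + revcomp(arm5) + tail.
toy_hairpin <- function(arm5 = "GACGTCATAGACTACTGGTCAT", loop_len = 8,
                        tail = "AT", id = "toy", species = "hsa",
                        mature5p = NULL, mature3p = NULL) {
  arm5 <- toupper(arm5)
  s <- nchar(arm5)
  seq <- paste0(arm5, strrep("A", loop_len), revcomp(arm5), tail)
  db <- paste0(strrep("(", s), strrep(".", loop_len), strrep(")", s),
               strrep(".", nchar(tail)))
  premirna_record(id, seq, db, mature5p = mature5p, mature3p = mature3p,
                  species = species)
}

# Hairpin with a C-C mismatch at 5'-arm position mm (both strands unpaired
# there), otherwise a perfect duplex.
toy_hairpin_mismatch <- function(arm5, mm, loop_len = 8, tail = "AT",
                                 id = "toy_mm", species = "hsa", ...) {
  arm5 <- toupper(arm5)
  s <- nchar(arm5)
  substr(arm5, mm, mm) <- "C"
  arm3 <- revcomp(arm5)
  p3 <- s - mm + 1L                     # position of mm partner within arm3
  substr(arm3, p3, p3) <- "C"
  seq <- paste0(arm5, strrep("A", loop_len), arm3, tail)
  db5 <- strrep("(", s); substr(db5, mm, mm) <- "."
  db3 <- strrep(")", s); substr(db3, p3, p3) <- "."
  db <- paste0(db5, strrep(".", loop_len), db3, strrep(".", nchar(tail)))
  premirna_record(id, seq, db, species = species, ...)
}
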