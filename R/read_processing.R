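#' Remove the 3' sequencing adapter
#'
#' Exact-match search for the first occurrence of the adapter; everything
#' from the match onward is trimmed. Reads without the adapter are kept
#' unchanged; reads shorter than `min_len` after trimming are discarded.
#'
#' @param seqs Character vector of read sequences.
#' @param adapter Adapter sequence.
#' @param min_len Minimum retained length.
#' @return Character vector of trimmed reads with attribute `"discarded"`
#'   (integer indices of dropped reads).
#' @export
remove_adapter <- function(seqs, adapter, min_len = 10) {
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  out <- ifelse(pos > 0, substr(seqs, 1L, pos - 1L), seqs)
  drop <- which(nchar(out) < min_len)
  res <- if (length(drop)) out[-drop] else out
  attr(res, "discarded") <- drop
  res
}

#' Trim terminal randomized nucleotides (UMIs)
#'
#' Removes `n5` nt from the 5' end and `n3` nt from the 3' end of each read,
#' returning the removed UMIs alongside the remaining body. Reads too short
#' to leave a non-empty body are discarded with a logged reason.
#'
#' @param seqs Character vector of read sequences.
#' @param n5,n3 Number of nt to remove from each end.
#' @return A list with `umi5`, `body`, `umi3` (parallel character vectors of
#'   the kept reads), `kept` (indices into `seqs`) and `discards` (data.frame
#'   `index`, `reason`).
#' @export
trim_ends <- function(seqs, n5, n3) {
  len <- nchar(seqs)
  ok <- len > n5 + n3
  discards <- data.frame(index = which(!ok),
                         reason = rep("too_short", sum(!ok)),
                         stringsAsFactors = FALSE)
  s <- seqs[ok]
  l <- len[ok]
  list(umi5 = substr(s, 1L, n5),
       body = substr(s, n5 + 1L, l - n3),
       umi3 = substring(s, l - n3 + 1L),
       kept = which(ok),
       discards = discards)
}

#' Collapse duplicate reads by UMI-pair plus body
#'
#' Reads sharing both terminal randomized barcodes and an identical body are
#' treated as amplification duplicates of one molecule: a single
#' representative is kept (collapser semantics; the survivor counts once).
#'
#' @param trimmed A [trim_ends()] result, or a data.frame with columns
#'   `umi5`, `body`, `umi3`.
#' @return The input restricted to unique keys, with `n_removed` attribute.
#' @export
dedup_reads <- function(trimmed) {
  key <- paste(trimmed$umi5, trimmed$umi3, trimmed$body, sep = "\r")
  keep <- !duplicated(key)
  out <- list(umi5 = trimmed$umi5[keep],
              body = trimmed$body[keep],
              umi3 = trimmed$umi3[keep])
  if (!is.null(trimmed$kept)) out$kept <- trimmed$kept[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Split a read body into hairpin part and 32N barcode
#'
#' The barcode is the exactly `barcode_len`-nt segment between the first
#' occurrence of the left delimiter and the following right delimiter
#' (forward strand, exact match). The hairpin part is the concatenation of
#' the sequence before the left delimiter and after the right delimiter.
#' Reads lacking a delimited segment of exactly `barcode_len` nt are
#' discarded.
#'
#' @param body Character vector of read bodies.
#' @param left_delim,right_delim Delimiter sequences.
#' @param barcode_len Required barcode length.
#' @return A list with `part` (hairpin part), `barcode`, `kept` (indices into
#'   `body`) and `discards` (data.frame `index`, `reason` in
#'   `no_delimiter` / `bad_barcode_length`).
#' @export
split_two_loop <- function(body, left_delim, right_delim, barcode_len = 32) {
  if (!nzchar(left_delim) || !nzchar(right_delim))
    stop("delimiters must be non-empty")
  nl <- nchar(left_delim); nr <- nchar(right_delim)
  lpos <- regexpr(left_delim, body, fixed = TRUE)
  tail_after <- ifelse(lpos > 0, substring(body, lpos + nl), "")
  rpos <- regexpr(right_delim, tail_after, fixed = TRUE)
  has_both <- lpos > 0 & rpos > 0
  bclen_obs <- ifelse(has_both, rpos - 1L, NA_integer_)
  ok <- has_both & !is.na(bclen_obs) & bclen_obs == barcode_len
  reason <- ifelse(!has_both, "no_delimiter", "bad_barcode_length")
  discards <- data.frame(index = which(!ok), reason = reason[!ok],
                         stringsAsFactors = FALSE)
  i <- which(ok)
  barcode <- substr(tail_after[i], 1L, barcode_len)
  part <- paste0(substr(body[i], 1L, lpos[i] - 1L),
                 substring(tail_after[i], barcode_len + nr + 1L))
  list(part = part, barcode = barcode, kept = i, discards = discards)
}

#' Build the unique FL-OS / 32N barcode dictionary
#'
#' Aggregates observed (FL-OS, barcode) pairs from the OS library and removes
#' every barcode seen with two or more distinct FL-OS sequences; the
#' surviving one-to-one pairs retain their read counts.
#'
#' @param flos Character vector of FL-OS sequences (one per read).
#' @param barcode Parallel character vector of 32N barcodes.
#' @return A data.frame `barcode`, `flos`, `count` (one row per retained
#'   pair), with attribute `"n_ambiguous"` (number of barcodes removed).
#' @export
build_os_dictionary <- function(flos, barcode) {
  if (length(flos) != length(barcode))
    stop("flos and barcode must be parallel")
  if (!length(flos)) {
    out <- data.frame(barcode = character(), flos = character(),
                      count = integer(), stringsAsFactors = FALSE)
    attr(out, "n_ambiguous") <- 0L
    return(out)
  }
  key <- paste(barcode, flos, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(barcode = vapply(parts, `[`, "", 1L),
                    flos = vapply(parts, `[`, "", 2L),
                    count = agg$Freq,
                    stringsAsFactors = FALSE)
  dup_bc <- unique(out$barcode[duplicated(out$barcode)])
  res <- out[!(out$barcode %in% dup_bc), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_ambiguous") <- length(dup_bc)
  res
}

#' Match FL-OS sequences against the enumerated reference
#'
#' Exact full-length string matching only; any sequence with even a single
#' mismatch to every reference variant is dropped (`NA`).
#'
#' @param flos Character vector of FL-OS sequences.
#' @param reference Output of [dedup_reference()].
#' @return Character vector of `ref_id` (or `NA` for unmatched).
#' @export
match_reference <- function(flos, reference) {
  reference$ref_id[match(flos, reference$sequence)]
}

#' Per-variant raw counts and counts-per-million
#'
#' The raw count of a variant is the sum of read counts over its retained
#' barcodes in the dictionary; CPM normalizes each library to one million.
#'
#' @param dictionary A [build_os_dictionary()] result with an added `ref_id`
#'   column, or a data.frame with `ref_id` and `count`.
#' @return Data.frame `ref_id`, `count`, `cpm`.
#' @export
count_table <- function(dictionary) {
  d <- dictionary[!is.na(dictionary$ref_id), , drop = FALSE]
  raw <- tapply(d$count, d$ref_id, sum)
  out <- data.frame(ref_id = names(raw), count = as.numeric(raw),
                    stringsAsFactors = FALSE)
  out$cpm <- out$count / sum(out$count) * 1e6
  rownames(out) <- NULL
  out
}
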