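#' Locate a cleaved product within its substrate
#'
#' Finds the best local alignment of the cleaved product (CP) inside its
#' barcode-assigned FL-OS and reports the cut coordinates
#' `(x, y) = (alignment start - 1, alignment end)` on the FL-OS (1-based;
#' `x` is the last retained 5'-side position, the cut falling between `x`
#' and `x + 1`).
#'
#' Exact substring occurrences are searched first; a unique occurrence gives
#' the coordinates directly, multiple equally good placements are discarded
#' as ambiguous. Products without an exact placement fall back to
#' Smith-Waterman local alignment (match +2, mismatch -3, gap open -5, gap
#' extend -2 by default); alignments shorter than `min_len` are discarded.
#'
#' @param cp Cleaved-product sequence (single string).
#' @param flos Substrate FL-OS sequence (single string).
#' @param min_len Minimum alignment length.
#' @param match,mismatch,gap_open,gap_extend Local alignment scoring.
#' @return A list `x`, `y` on success, or `NULL` with attribute-free
#'   `NA`-list `list(x = NA, y = NA, reason = <why>)` when discarded.
#' @export
locate_product <- function(cp, flos, min_len = 15, match = 2, mismatch = -3,
                           gap_open = -5, gap_extend = -2) {
  if (nchar(cp) > nchar(flos))
    return(list(x = NA_integer_, y = NA_integer_, reason = "cp_longer_than_flos"))
  hits <- gregexpr(cp, flos, fixed = TRUE)[[1]]
  if (hits[1] > 0) {
    if (length(hits) > 1)
      return(list(x = NA_integer_, y = NA_integer_, reason = "ambiguous"))
    if (nchar(cp) < min_len)
      return(list(x = NA_integer_, y = NA_integer_, reason = "too_short"))
    return(list(x = hits[1] - 1L, y = hits[1] - 1L + nchar(cp), reason = NA))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(cp, flos, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = abs(gap_open),
                                       gapExtension = abs(gap_extend))
  s <- Biostrings::subject(aln)
  a <- Biostrings::start(s)
  b <- Biostrings::end(s)
  if (b - a + 1L < min_len)
    return(list(x = NA_integer_, y = NA_integer_, reason = "no_alignment"))
  list(x = a - 1L, y = b, reason = NA)
}

#' Locate many products, grouped by unique (product, substrate) pairs
#'
#' @param cp,flos Parallel character vectors.
#' @param ... Passed to [locate_product()].
#' @return Data.frame `x`, `y`, `reason`, one row per input read.
#' @export
locate_products <- function(cp, flos, ...) {
  key <- paste(cp, flos, sep = "\r")
  u <- !duplicated(key)
  res <- mapply(function(a, b) locate_product(a, b, ...),
                cp[u], flos[u], SIMPLIFY = FALSE, USE.NAMES = FALSE)
  ux <- vapply(res, function(r) as.integer(r$x), integer(1))
  uy <- vapply(res, function(r) as.integer(r$y), integer(1))
  ur <- vapply(res, function(r) as.character(r$reason), character(1))
  i <- match(key, key[u])
  data.frame(x = ux[i], y = uy[i], reason = ur[i], stringsAsFactors = FALSE)
}

#' Classify a cleavage event from its cut coordinates
#'
#' Applies the coordinate rules, with `C = coord_const` (default 72):
#'
#' * `DC` at `x` if `19 <= x <= 23` and `y = C - x` (2-nt overhang);
#' * `Other` if `19 <= x <= 23`, `49 <= y <= 53` and `y != C - x`
#'   (non-2-nt-overhang double cleavage; corrected y-range — see Details);
#' * `5'-SC` at `x` if `19 <= x <= 23` and `68 <= y <= 72`;
#' * `3'-SC` at `C - y` if `0 <= x <= 4` and `49 <= y <= 53`;
#' * otherwise `unclassified`.
#'
#' Precedence: DC > Other > 3'-SC > 5'-SC.
#'
#' @details The published rule table gives `Other` the y-range `68..72`,
#' which duplicates the 5'-SC region and makes its `y != C - x` clause
#' vacuous (no `x` in 19..23 has `C - x` in 68..72). This implementation
#' defaults to the corrected range `49..53` — the only window in which
#' `y = C - x` is attainable, so `Other` captures genuinely non-2-nt-overhang
#' double cleavages. `rules = "printed"` reproduces the published table
#' verbatim.
#'
#' @param x,y Integer vectors of cut coordinates.
#' @param C Coordinate constant.
#' @param rules `"corrected"` (default) or `"printed"`.
#' @return Data.frame `mode` (factor-like character: `DC`, `Other`, `SC5`,
#'   `SC3`, `unclassified`) and `site` (integer in 19..23, `NA` when
#'   unclassified).
#' @export
classify_cleavage <- function(x, y, C = 72, rules = c("corrected", "printed")) {
  rules <- match.arg(rules)
  x <- as.integer(x); y <- as.integer(y)
  in_x_dc <- !is.na(x) & x >= 19 & x <= 23
  in_x_sc3 <- !is.na(x) & x >= 0 & x <= 4
  y_low <- !is.na(y) & y >= C - 23 & y <= C - 19        # 49..53 for C = 72
  y_high <- !is.na(y) & y >= 68 & y <= 72
  is_dc <- in_x_dc & !is.na(y) & y == C - x
  other_y <- if (rules == "corrected") y_low else y_high
  is_other <- in_x_dc & other_y & !is.na(y) & y != C - x
  is_sc3 <- in_x_sc3 & y_low
  is_sc5 <- in_x_dc & y_high
  mode <- rep("unclassified", length(x))
  site <- rep(NA_integer_, length(x))
  # precedence: DC > Other > 3'-SC > 5'-SC
  sel <- is_sc5; mode[sel] <- "SC5"; site[sel] <- x[sel]
  sel <- is_sc3; mode[sel] <- "SC3"; site[sel] <- C - y[sel]
  sel <- is_other; mode[sel] <- "Other"; site[sel] <- x[sel]
  sel <- is_dc; mode[sel] <- "DC"; site[sel] <- x[sel]
  data.frame(mode = mode, site = site, stringsAsFactors = FALSE)
}

#' Tabulate cleavage calls by variant, mode and site
#'
#' @param calls Data.frame with columns `ref_id`, `mode`, `site` (rows with
#'   `unclassified` mode are ignored).
#' @return Data.frame `ref_id`, `mode`, `site`, `count`; the total count
#'   equals the number of classified calls.
#' @export
site_counts <- function(calls) {
  k <- calls[calls$mode != "unclassified" & !is.na(calls$site), , drop = FALSE]
  if (!nrow(k)) {
    return(data.frame(ref_id = character(), mode = character(),
                      site = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(k))),
                          by = list(ref_id = k$ref_id, mode = k$mode,
                                    site = k$site),
                          FUN = sum)
  agg <- agg[order(agg$ref_id, agg$mode, agg$site), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
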