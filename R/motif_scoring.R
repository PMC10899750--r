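#' Min-max rescaling to 0-100
#'
#' Linearly rescales so that the minimum maps to 0 and the maximum to 100;
#' ties are permitted. When all values are equal (degenerate range) every
#' value maps to 0, preventing spurious maximal scores. `NA`s are ignored
#' for the range and propagated.
#'
#' @param values Numeric vector.
#' @return Numeric vector in \[0, 100\].
#' @export
minmax_rescale <- function(values) {
  lo <- min(values, na.rm = TRUE)
  hi <- max(values, na.rm = TRUE)
  if (!is.finite(lo) || hi == lo) return(ifelse(is.na(values), NA_real_, 0))
  (values - lo) / (hi - lo) * 100
}

# window start -> (group window, DC site) tables for the two motif types:
# an mWCU whose first pair sits at N targets DC(N+4); a YCR at N targets
# DC(N+2). The variants scored for a window are those randomized in the
# group window given by `group_start`.
motif_window_table <- function(type = c("mWCU", "YCR")) {
  type <- match.arg(type)
  if (type == "mWCU")
    data.frame(window_start = c(16L, 17L, 18L), group_start = c(16L, 17L, 18L),
               site = c(20L, 21L, 22L))
  else
    data.frame(window_start = c(18L, 19L, 20L), group_start = c(18L, 19L, 19L),
               site = c(20L, 21L, 22L))
}

#' Mean cleavage accuracy per motif in one randomized window
#'
#' Restricts to variants randomized in the group whose window starts at
#' `group_start` (and, when structure profiles are given, to variants with
#' the consistent designed stem length), reads the pair-triple motif at
#' `window_start` from each variant's sequence, and averages the DC accuracy
#' at `site` per motif.
#'
#' @param acc Data.frame of DC accuracies with columns `ref_id`, `site`,
#'   `accuracy`.
#' @param variants Variant table (must include the scored group) with
#'   columns `variant_id`, `window_start`, `sequence`.
#' @param window_start First pair position of the motif window.
#' @param site DC site scored for this window.
#' @param design The [library_design()].
#' @param group_start Window start of the variant group supplying the
#'   observations (defaults to `window_start`; they differ when the motif
#'   window extends past the randomized region and the third pair is fixed).
#' @param profiles Optional [profile_variants()] output for the stem filter.
#' @param stem_len Required stem length when `profiles` is given.
#' @return Data.frame `motif`, `accuracy`, `n_variants`.
#' @export
window_accuracy <- function(acc, variants, window_start, site, design,
                            group_start = window_start, profiles = NULL,
                            stem_len = design$stem_len) {
  v <- variants[variants$window_start == group_start, , drop = FALSE]
  if (!nrow(v)) stop("no variants with randomized window at ", group_start)
  if (!is.null(profiles)) {
    ok <- profiles$variant_id[profiles$stem_len == stem_len]
    v <- v[v$variant_id %in% ok, , drop = FALSE]
  }
  motif <- pair_triple(v$sequence, window_start, design)
  a <- acc[acc$site == site, , drop = FALSE]
  val <- a$accuracy[match(v$variant_id, a$ref_id)]
  keep <- !is.na(val)
  if (!any(keep)) {
    return(data.frame(motif = character(), accuracy = numeric(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  }
  m <- tapply(val[keep], motif[keep], mean)
  n <- tapply(val[keep], motif[keep], length)
  data.frame(motif = names(m), accuracy = as.numeric(m),
             n_variants = as.integer(n), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Averaged motif score over rescaled windows
#'
#' @param rescaled Numeric vector of per-window rescaled accuracies for one
#'   motif (`NA` for unavailable windows).
#' @return Mean of the available windows (`NA` if none); the YCR fallback —
#'   averaging DC20 and DC21 when DC22 is unobtainable — is this rule.
#' @export
motif_score <- function(rescaled) {
  if (all(is.na(rescaled))) return(NA_real_)
  mean(rescaled, na.rm = TRUE)
}

#' Compute the full mWCU or YCR score table
#'
#' Runs [window_accuracy()] for each of the three motif windows, min-max
#' rescales each window to 0-100, and averages the available windows per
#' motif. mWCU windows 16-18 / 17-19 / 18-20 score DC20 / DC21 / DC22;
#' YCR windows 18-20 / 19-21 / 20-22 score DC20 / DC21 / DC22 (the 20-22
#' window reads its third pair from the fixed backbone, so most motifs have
#' only two windows available there — their score is the DC20/DC21 average).
#'
#' YCR scores are conventionally computed from dsRBD-deleted enzyme data to
#' remove the dsRBD-dependent (mWCU) contribution; that choice is the
#' caller's, via `acc`.
#'
#' @inheritParams window_accuracy
#' @param type `"mWCU"` or `"YCR"`.
#' @return Data.frame `motif`, one rescaled column per window
#'   (`<type>_DC<site>`), `score`, `n_windows`.
#' @export
score_motifs <- function(acc, variants, design, type = c("mWCU", "YCR"),
                         profiles = NULL, stem_len = design$stem_len) {
  type <- match.arg(type)
  tab <- motif_window_table(type)
  per_win <- lapply(seq_len(nrow(tab)), function(k) {
    wa <- window_accuracy(acc, variants, tab$window_start[k], tab$site[k],
                          design, group_start = tab$group_start[k],
                          profiles = profiles, stem_len = stem_len)
    wa$rescaled <- minmax_rescale(wa$accuracy)
    wa
  })
  motifs <- sort(unique(unlist(lapply(per_win, function(w) w$motif))))
  out <- data.frame(motif = motifs, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(tab))) {
    col <- sprintf("%s_DC%d", type, tab$site[k])
    out[[col]] <- per_win[[k]]$rescaled[match(motifs, per_win[[k]]$motif)]
  }
  win_cols <- sprintf("%s_DC%d", type, tab$site)
  mat <- as.matrix(out[win_cols])
  out$score <- apply(mat, 1, motif_score)
  out$n_windows <- rowSums(!is.na(mat))
  out
}

#' Pair-combination composition of top-scoring motifs
#'
#' Takes the motifs at or above the given score percentile (ties included)
#' and tabulates, per motif position, the frequency of each of the 16
#' ordered 5'/3' nucleotide combinations; combinations below the display
#' threshold are pooled as `"other"`.
#'
#' @param scores Data.frame with `motif` and `score` columns.
#' @param percentile Percentile cut (default 97: top 3%).
#' @param display_threshold Minimum frequency shown individually.
#' @return A list with `top` (the selected motifs) and `composition`
#'   (data.frame `position`, `combo`, `frequency`).
#' @export
top_composition <- function(scores, percentile = 97, display_threshold = 0.05) {
  s <- scores[!is.na(scores$score), , drop = FALSE]
  cut <- stats::quantile(s$score, percentile / 100, names = FALSE)
  top <- s[s$score >= cut, , drop = FALSE]
  comp <- do.call(rbind, lapply(1:3, function(k) {
    combo <- paste0(substr(top$motif, k, k), "-",
                    substr(top$motif, 3L + k, 3L + k))
    f <- table(combo) / length(combo)
    keep <- f >= display_threshold
    freq <- c(f[keep], if (any(!keep)) c(other = sum(f[!keep])))
    data.frame(position = k, combo = names(freq),
               frequency = as.numeric(freq), stringsAsFactors = FALSE)
  }))
  rownames(comp) <- NULL
  list(top = top, composition = comp, cutoff = cut)
}

#' Classify a motif by score-table rank
#'
#' A motif is labelled `mWCU` when it belongs to the top percentile of the
#' mWCU score table, `YCR` when it belongs to the top percentile of the YCR
#' score table, and `neither` otherwise. A motif qualifying under both
#' tables is labelled `mWCU` (arbitrary precedence; use the pattern
#' predicates [is_mwcu_pattern()] / [is_ycr_pattern()] for the sequence
#' description).
#'
#' @param motif Character vector of 6-character motif strings.
#' @param mwcu_scores,ycr_scores Score tables from [score_motifs()].
#' @param percentile Percentile cut (default 97).
#' @return Character vector in `mWCU` / `YCR` / `neither`.
#' @export
motif_class <- function(motif, mwcu_scores, ycr_scores, percentile = 97) {
  motif <- chartr("Tt", "Uu", toupper(motif))
  top_set <- function(scores) {
    s <- scores[!is.na(scores$score), , drop = FALSE]
    cut <- stats::quantile(s$score, percentile / 100, names = FALSE)
    s$motif[s$score >= cut]
  }
  in_m <- motif %in% top_set(mwcu_scores)
  in_y <- motif %in% top_set(ycr_scores)
  ifelse(in_m, "mWCU", ifelse(in_y, "YCR", "neither"))
}
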