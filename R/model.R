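#' Two-motif multinomial cleavage model
#'
#' Defines the probability model under which the simulator draws cleavage
#' events. Every cleavage read falls in one of fifteen categories: double
#' cleavage (DC) at sites 19-23, single cleavage on the 5' strand (5'-SC) at
#' sites 19-23, or single cleavage on the 3' strand (3'-SC) at sites 19-23.
#' Category probabilities are a softmax over logits:
#'
#' * DC site `s`: `base_logits[s]` plus motif effects;
#' * 5'-SC / 3'-SC site `s`: `base_logits[s] + sc_logit` minus any YCR
#'   single-cleavage suppression.
#'
#' A planted mWCU motif whose first pair sits at stem position `N` adds
#' `beta_mwcu * strength` to the DC logit at site `N + 4`; a planted YCR at
#' `N` adds `beta_ycr * strength` to DC at `N + 2` and subtracts
#' `ycr_sc_suppression * strength` from the single-cleavage logit. Strengths
#' come from [mwcu_strength()] / [ycr_strength()].
#'
#' The enzyme gates the mWCU effect: it is fully active for `WT`, abolished
#' for `dsRBD_del` and `R1855A`, and attenuated for `E1859A`. Deleting the
#' dsRBD additionally raises the single-cleavage propensity. YCR acts
#' identically in all enzymes.
#'
#' @param enzyme One of `"WT"`, `"dsRBD_del"`, `"R1855A"`, `"E1859A"`.
#' @param base_logits Named numeric vector of baseline site logits for sites
#'   `"19"`..`"23"`. The default favours sites 21 and 22, where the enzyme
#'   predominantly cuts.
#' @param sc_logit Baseline single-cleavage logit offset (per SC branch).
#' @param beta_mwcu,beta_ycr Motif effect sizes on the targeted DC logit.
#' @param ycr_sc_suppression Reduction of the SC logit per unit YCR strength.
#' @param e1859a_attenuation Multiplier applied to the mWCU effect for the
#'   E1859A enzyme (mildly reduced recognition).
#' @param dsrbd_del_sc_boost Added to `sc_logit` when the dsRBD is deleted.
#' @param error_rate Uniform per-base substitution rate applied to emitted
#'   reads (default 0; quality filtering upstream of the pipeline is modelled
#'   as a pass-through).
#' @return An object of class `"cleavage_model"`.
#' @export
cleavage_model <- function(enzyme = c("WT", "dsRBD_del", "R1855A", "E1859A"),
                           base_logits = c("19" = -2, "20" = -0.5,
                                           "21" = 1.5, "22" = 1.0,
                                           "23" = -2),
                           sc_logit = -1.2,
                           beta_mwcu = 2.5,
                           beta_ycr = 2.5,
                           ycr_sc_suppression = 1.5,
                           e1859a_attenuation = 0.5,
                           dsrbd_del_sc_boost = 0.8,
                           error_rate = 0) {
  enzyme <- match.arg(enzyme)
  if (!identical(names(base_logits), as.character(19:23)))
    stop("base_logits must be named '19'..'23'")
  gate <- switch(enzyme,
                 WT = 1,
                 dsRBD_del = 0,
                 R1855A = 0,
                 E1859A = e1859a_attenuation)
  structure(list(
    enzyme = enzyme,
    base_logits = base_logits,
    sc_logit = sc_logit,
    beta_mwcu = beta_mwcu,
    beta_ycr = beta_ycr,
    ycr_sc_suppression = ycr_sc_suppression,
    dsrbd_gate = gate,
    dsrbd_del_sc_boost = dsrbd_del_sc_boost,
    error_rate = error_rate
  ), class = "cleavage_model")
}

#' @export
print.cleavage_model <- function(x, ...) {
  cat("Cleavage model (", x$enzyme, ")\n", sep = "")
  cat("  base logits:", paste(names(x$base_logits), round(x$base_logits, 2),
                              sep = "=", collapse = " "), "\n")
  cat("  sc_logit:", x$sc_logit, " beta_mwcu:", x$beta_mwcu,
      "(gate ", x$dsrbd_gate, ") beta_ycr:", x$beta_ycr, "\n")
  invisible(x)
}

SITES <- 19:23

category_names <- function() {
  c(paste0("DC", SITES), paste0("SC5_", SITES), paste0("SC3_", SITES))
}

#' Site and mode probabilities for one variant
#'
#' Detects the planted motif in the variant's randomized window, applies the
#' model's motif effects, and returns the softmax probability over the
#' fifteen cleavage categories.
#'
#' @param variant One row of [build_variant_library()] output (or any list
#'   with `window_start` and `sequence`), or an FL-OS string together with
#'   `window_start`.
#' @param model A [cleavage_model()].
#' @param design The [library_design()].
#' @param window_start Override for the randomized window start (needed when
#'   `variant` is a bare sequence).
#' @return Named numeric vector of probabilities over
#'   `DC19..DC23, SC5_19..SC5_23, SC3_19..SC3_23`, summing to 1, with
#'   attributes `mwcu_strength` and `ycr_strength`.
#' @export
simulate_cleavage <- function(variant, model, design, window_start = NULL) {
  if (is.character(variant)) {
    seqs <- variant
    if (is.null(window_start)) stop("window_start required for bare sequences")
    ws <- window_start
  } else {
    seqs <- variant$sequence
    ws <- if (is.null(window_start)) variant$window_start else window_start
  }
  motif <- pair_triple(seqs, ws, design)
  s_m <- mwcu_strength(motif) * model$dsrbd_gate
  s_y <- ycr_strength(motif)

  dc <- model$base_logits
  mw_site <- as.character(ws + 4L)
  yc_site <- as.character(ws + 2L)
  if (mw_site %in% names(dc)) dc[mw_site] <- dc[mw_site] + model$beta_mwcu * s_m
  if (yc_site %in% names(dc)) dc[yc_site] <- dc[yc_site] + model$beta_ycr * s_y

  sc_l <- model$sc_logit - model$ycr_sc_suppression * s_y +
    if (model$enzyme == "dsRBD_del") model$dsrbd_del_sc_boost else 0
  logits <- c(dc, model$base_logits + sc_l, model$base_logits + sc_l)
  names(logits) <- category_names()
  z <- exp(logits - max(logits))
  p <- z / sum(z)
  attr(p, "mwcu_strength") <- s_m
  attr(p, "ycr_strength") <- s_y
  p
}

#' Category probability matrix for a set of variants
#'
#' Vectorized version of [simulate_cleavage()] over the rows of a variant
#' table.
#'
#' @param variants Data.frame from [build_variant_library()].
#' @param model A [cleavage_model()].
#' @param design The [library_design()].
#' @return Numeric matrix (variants x 15 categories) with row names set to
#'   `variant_id`.
#' @export
cleavage_probabilities <- function(variants, model, design) {
  motif <- mapply(function(s, w) pair_triple(s, w, design),
                  variants$sequence, variants$window_start, USE.NAMES = FALSE)
  s_m <- mwcu_strength(motif) * model$dsrbd_gate
  s_y <- ycr_strength(motif)
  n <- nrow(variants)
  base <- matrix(model$base_logits, n, 5, byrow = TRUE,
                 dimnames = list(NULL, names(model$base_logits)))
  dc <- base
  mw_site <- variants$window_start + 4L
  yc_site <- variants$window_start + 2L
  for (s in SITES) {
    cs <- as.character(s)
    dc[, cs] <- dc[, cs] + ifelse(mw_site == s, model$beta_mwcu * s_m, 0) +
      ifelse(yc_site == s, model$beta_ycr * s_y, 0)
  }
  sc_l <- model$sc_logit - model$ycr_sc_suppression * s_y +
    if (model$enzyme == "dsRBD_del") model$dsrbd_del_sc_boost else 0
  logits <- cbind(dc, base + sc_l, base + sc_l)
  colnames(logits) <- category_names()
  z <- exp(logits - apply(logits, 1, max))
  p <- z / rowSums(z)
  rownames(p) <- variants$variant_id
  attr(p, "mwcu_strength") <- s_m
  attr(p, "ycr_strength") <- s_y
  attr(p, "motif") <- motif
  p
}
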