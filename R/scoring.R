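#' Cleavage efficiency, accuracy and ratio statistics
#'
#' The score formulas operate on counts-per-million (CPM): `NP` is the
#' normalized count of a cleaved product at site `P` in its library, `NS`
#' the normalized count of the original substrate that produced it. A
#' pseudocount of 0.1 keeps all logs finite.
#'
#' * local efficiency at P: `log2(NP + 0.1) - log2(NS + 0.1)`
#' * total efficiency (per mode): `log2(sum(NP) + 0.1) - log2(NS + 0.1)`
#' * accuracy at P (per mode): `NP / sum(NP)`
#' * log2 DC/SC ratio: `log2(sum(NP_DC) + 0.1) - log2(sum(NP_SC) + 0.1)`
#'
#' @param np CPM of the cleaved product at one site.
#' @param ns CPM of the original substrate.
#' @param pseudocount Pseudocount added inside each log (default 0.1).
#' @return Numeric value(s).
#' @name efficiency
NULL

#' @rdname efficiency
#' @export
local_efficiency <- function(np, ns, pseudocount = 0.1) {
  if (any(np < 0, na.rm = TRUE) || any(ns < 0, na.rm = TRUE))
    stop("normalized counts must be non-negative")
  log2(np + pseudocount) - log2(ns + pseudocount)
}

#' @rdname efficiency
#' @param np_list Numeric vector of per-site CPM values for one mode.
#' @export
total_efficiency <- function(np_list, ns, pseudocount = 0.1) {
  if (any(np_list < 0, na.rm = TRUE) || any(ns < 0, na.rm = TRUE))
    stop("normalized counts must be non-negative")
  log2(sum(np_list) + pseudocount) - log2(ns + pseudocount)
}

#' Cleavage accuracy per site
#'
#' `NP / sum(NP)` over the sites of one mode. When every count is zero the
#' accuracy is undefined and an empty result is returned (such variants are
#' excluded from averages rather than imputed as zero).
#'
#' @param np_by_site Named numeric vector (names = sites).
#' @return Named numeric vector of accuracies summing to 1, or a
#'   zero-length vector when undefined.
#' @export
accuracy <- function(np_by_site) {
  tot <- sum(np_by_site)
  if (!length(np_by_site) || tot <= 0) return(stats::setNames(numeric(0), character(0)))
  np_by_site / tot
}

#' @rdname efficiency
#' @param np_dc_list,np_sc_list Per-site CPM vectors for double and single
#'   cleavage products.
#' @export
log2_dc_sc <- function(np_dc_list, np_sc_list, pseudocount = 0.1) {
  log2(sum(np_dc_list) + pseudocount) - log2(sum(np_sc_list) + pseudocount)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `d = (M1 - M2) / pooled_SD` with
#' `pooled_SD = sqrt(SD1^2/2 + SD2^2/2)` — the two variances are averaged
#' with equal weight regardless of sample sizes. Standard deviations use the
#' conventional n-1 denominator.
#'
#' @param sample1,sample2 Numeric vectors with at least two values each.
#' @return A list of class `"effect_size"` with `m1`, `m2`, `sd1`, `sd2`,
#'   `pooled_sd`, `d` (`d` is `NA` when `pooled_sd` is zero).
#' @export
cohens_d <- function(sample1, sample2) {
  if (length(sample1) < 2 || length(sample2) < 2)
    stop("each sample needs n >= 2")
  m1 <- mean(sample1); m2 <- mean(sample2)
  sd1 <- stats::sd(sample1); sd2 <- stats::sd(sample2)
  pooled <- sqrt(sd1^2 / 2 + sd2^2 / 2)
  d <- if (pooled == 0) NA_real_ else (m1 - m2) / pooled
  structure(list(m1 = m1, m2 = m2, sd1 = sd1, sd2 = sd2,
                 pooled_sd = pooled, d = d),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.4f  (M1 = %.4g, M2 = %.4g, pooled SD = %.4g)\n",
              x$d, x$m1, x$m2, x$pooled_sd))
  invisible(x)
}

#' Average a statistic over replicates
#'
#' Means per variant over however many replicates reported a value; a
#' replicate with an undefined value (NA) for a variant is excluded from
#' that variant's mean rather than imputed.
#'
#' @param values Numeric vector of per-replicate values.
#' @param ids Parallel vector of variant ids.
#' @return Data.frame `ref_id`, `mean`, `n_replicates`.
#' @export
replicate_average <- function(values, ids) {
  ok <- !is.na(values)
  m <- tapply(values[ok], ids[ok], mean)
  n <- tapply(values[ok], ids[ok], length)
  data.frame(ref_id = names(m), mean = as.numeric(m),
             n_replicates = as.integer(n), stringsAsFactors = FALSE,
             row.names = NULL)
}
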