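#' Process one sequencing library into hairpin parts and barcodes
#'
#' Applies the per-library preprocessing chain: 3' adapter removal, terminal
#' UMI trimming (6+4 nt for OS/SC reads, 4+4 for DC reads), duplicate
#' collapsing on the UMI-pair-plus-body key, and the delimiter split that
#' separates the hairpin part from the 32N barcode. Pair joining and
#' quality filtering are accepted as upstream steps; an optional mean
#' quality filter can be applied by the caller beforehand.
#'
#' @param reads FASTQ path or data.frame with `id`, `seq` columns.
#' @param type `"OS"`, `"DC"` or `"SC"`.
#' @param design The [library_design()].
#' @return A list with `part`, `barcode` (parallel character vectors),
#'   `n_input`, and `discards` (data.frame `stage`, `reason`, `n`).
#' @export
process_library <- function(reads, type = c("OS", "DC", "SC"), design) {
  type <- match.arg(type)
  if (is.character(reads)) reads <- read_fastq(reads)
  n_input <- nrow(reads)
  disc <- list()
  seqs <- remove_adapter(reads$seq, design$adapter3)
  disc$adapter <- length(attr(seqs, "discarded"))
  n5 <- if (type == "DC") design$umi5_len_dc else design$umi5_len
  tr <- trim_ends(seqs, n5, design$umi3_len)
  disc$too_short <- nrow(tr$discards)
  dd <- dedup_reads(tr)
  disc$duplicate <- attr(dd, "n_removed")
  sp <- split_two_loop(dd$body, design$loop_delim_left,
                       design$loop_delim_right, design$barcode_len)
  dt <- table(sp$discards$reason)
  discards <- data.frame(
    stage = c("adapter", "trim", "dedup", rep("split", length(dt))),
    reason = c("short_after_adapter", "too_short", "duplicate", names(dt)),
    n = c(disc$adapter, disc$too_short, disc$duplicate, as.integer(dt)),
    stringsAsFactors = FALSE
  )
  list(part = sp$part, barcode = sp$barcode, n_input = n_input,
       n_kept = length(sp$part), discards = discards)
}

#' Run the full dicing-assay analysis on one replicate
#'
#' Consumes the three libraries of one replicate and produces per-variant
#' cleavage calls and scores:
#'
#' 1. OS reads build the unique FL-OS/32N dictionary (ambiguous barcodes
#'    discarded) and per-variant substrate counts via exact reference
#'    matching;
#' 2. DC/SC cleaved products are assigned to substrates through their
#'    barcode, located by local alignment, and classified into
#'    DC / Other / 5'-SC / 3'-SC calls with sites 19-23;
#' 3. counts are CPM-normalized per library and turned into local/total
#'    efficiencies, per-site accuracies and the log2 DC/SC ratio.
#'
#' @param os,dc,sc FASTQ paths or read data.frames for the three libraries.
#' @param design The [library_design()].
#' @param reference [dedup_reference()] output.
#' @param rules Classification rule set (see [classify_cleavage()]).
#' @return An object of class `"dicing_result"`: list with `dictionary`,
#'   `os_counts`, `calls`, `site_table`, `variant_table`, `discards`.
#' @export
run_dicing_pipeline <- function(os, dc, sc, design, reference,
                                rules = "corrected") {
  p_os <- process_library(os, "OS", design)
  dict <- build_os_dictionary(p_os$part, p_os$barcode)
  dict$ref_id <- match_reference(dict$flos, reference)
  os_counts <- count_table(dict)

  map_idx <- function(bc) match(bc, dict$barcode)
  do_lib <- function(proc) {
    i <- map_idx(proc$barcode)
    ok <- !is.na(i) & !is.na(dict$ref_id[i])
    cp <- proc$part[ok]
    flos <- dict$flos[i[ok]]
    loc <- locate_products(cp, flos)
    cls <- classify_cleavage(loc$x, loc$y, design$coord_const, rules)
    data.frame(ref_id = dict$ref_id[i[ok]], x = loc$x, y = loc$y,
               mode = cls$mode, site = cls$site,
               loc_reason = loc$reason, stringsAsFactors = FALSE)
  }
  p_dc <- process_library(dc, "DC", design)
  p_sc <- process_library(sc, "SC", design)
  calls_dc <- do_lib(p_dc)
  calls_sc <- do_lib(p_sc)
  calls_dc$library <- "DC"
  calls_sc$library <- "SC"
  calls <- rbind(calls_dc, calls_sc)

  site_dc <- site_counts(calls_dc)
  site_sc <- site_counts(calls_sc)
  site_dc$library <- "DC"
  site_sc$library <- "SC"
  add_cpm <- function(s) {
    s$cpm <- if (nrow(s)) s$count / sum(s$count) * 1e6 else numeric(0)
    s
  }
  site_table <- rbind(add_cpm(site_dc), add_cpm(site_sc))

  variant_table <- score_variants(os_counts, site_table)
  site_table <- add_site_scores(os_counts, site_table)

  structure(list(dictionary = dict, os_counts = os_counts, calls = calls,
                 site_table = site_table, variant_table = variant_table,
                 discards = list(os = p_os$discards, dc = p_dc$discards,
                                 sc = p_sc$discards)),
            class = "dicing_result")
}

# per-site local efficiency and per-mode accuracy columns
add_site_scores <- function(os_counts, site_table) {
  ns <- os_counts$cpm[match(site_table$ref_id, os_counts$ref_id)]
  ns[is.na(ns)] <- 0
  site_table$local_eff <- local_efficiency(site_table$cpm, ns)
  grp <- paste(site_table$ref_id, site_table$library, site_table$mode)
  tot <- tapply(site_table$cpm, grp, sum)[grp]
  site_table$accuracy <- ifelse(tot > 0, site_table$cpm / tot, NA_real_)
  site_table
}

# per-variant totals: NS, total efficiencies, log2 DC/SC
score_variants <- function(os_counts, site_table) {
  ids <- sort(unique(c(os_counts$ref_id, site_table$ref_id)))
  ns <- os_counts$cpm[match(ids, os_counts$ref_id)]
  ns[is.na(ns)] <- 0
  sum_mode <- function(lib, modes) {
    s <- site_table[site_table$library == lib & site_table$mode %in% modes, ]
    v <- tapply(s$cpm, s$ref_id, sum)
    out <- as.numeric(v[ids]); out[is.na(out)] <- 0
    out
  }
  np_dc <- sum_mode("DC", "DC")
  np_sc <- sum_mode("SC", c("SC5", "SC3"))
  data.frame(
    ref_id = ids,
    ns_cpm = ns,
    total_eff_dc = mapply(total_efficiency, np_dc, ns),
    total_eff_sc = mapply(total_efficiency, np_sc, ns),
    log2_dc_sc = mapply(function(a, b) log2_dc_sc(a, b), np_dc, np_sc),
    stringsAsFactors = FALSE
  )
}

#' DC accuracy table from a dicing result
#'
#' Extracts the per-variant DC accuracies in the shape consumed by
#' [window_accuracy()] / [score_motifs()].
#'
#' @param result A [run_dicing_pipeline()] result, or any site table with
#'   `ref_id`, `library`, `mode`, `site`, `accuracy`.
#' @return Data.frame `ref_id`, `site`, `accuracy`.
#' @export
dc_accuracy <- function(result) {
  s <- if (inherits(result, "dicing_result")) result$site_table else result
  s <- s[s$library == "DC" & s$mode == "DC" & !is.na(s$accuracy), ]
  s[, c("ref_id", "site", "accuracy")]
}

#' DC accuracy table directly from simulated ground-truth counts
#'
#' Bypasses read emission and mapping: treats the ground truth's DC category
#' counts as the DC library and computes per-variant site accuracies. Used
#' for motif-recovery analyses where read-level fidelity is established
#' separately.
#'
#' @param truth A [simulate_library()] result.
#' @return Data.frame `ref_id`, `site`, `accuracy`.
#' @export
truth_dc_accuracy <- function(truth) {
  dc <- truth$counts[, paste0("DC", SITES), drop = FALSE]
  tot <- rowSums(dc)
  acc <- dc / ifelse(tot > 0, tot, NA_real_)
  data.frame(ref_id = rep(rownames(acc), ncol(acc)),
             site = rep(SITES, each = nrow(acc)),
             accuracy = as.vector(acc),
             stringsAsFactors = FALSE)
}

#' @export
print.dicing_result <- function(x, ...) {
  cat("Dicing-assay analysis result\n")
  cat("  dictionary barcodes:", nrow(x$dictionary),
      " matched variants:", nrow(x$os_counts), "\n")
  tab <- table(x$calls$mode)
  cat("  calls:", paste(names(tab), as.integer(tab), sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}
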