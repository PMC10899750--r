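#' Simulate a dicing assay on a variant library
#'
#' Draws, for every variant, a barcode pool for the secondary loop and a
#' multinomial sample of cleavage events from the model's category
#' probabilities. The returned ground truth is the contract every downstream
#' stage is tested against.
#'
#' RNG contract: a single generator seeded with `seed`; the stream order is
#' barcodes (all variants, in row order), then one multinomial draw per
#' variant. [emit_reads()] uses its own seed for UMIs and per-read barcode
#' choice, so truth and read emission are independently reproducible.
#'
#' @param variants Data.frame from [build_variant_library()] (optionally
#'   subset).
#' @param model A [cleavage_model()].
#' @param design The [library_design()].
#' @param n_reads Cleavage reads drawn per variant (split across DC and SC
#'   categories by the model probabilities).
#' @param os_reads Original-substrate reads per variant.
#' @param barcodes_per_variant Number of distinct 32N barcodes per variant.
#' @param seed Integer seed.
#' @return An object of class `"ground_truth"`: list with `variants`,
#'   `probs` (variant x category matrix), `counts` (same shape, multinomial
#'   draws), `barcodes` (data.frame variant_id/barcode), `os_reads`,
#'   `model`, `design`, `seed`.
#' @export
simulate_library <- function(variants, model, design, n_reads = 2000,
                             os_reads = 30, barcodes_per_variant = 3,
                             seed = 1) {
  set.seed(seed)
  n <- nrow(variants)
  probs <- cleavage_probabilities(variants, model, design)
  bc <- random_dna(n * barcodes_per_variant, design$barcode_len)
  barcodes <- data.frame(
    variant_id = rep(variants$variant_id, each = barcodes_per_variant),
    barcode = bc,
    stringsAsFactors = FALSE
  )
  counts <- t(vapply(seq_len(n),
                     function(i) as.numeric(stats::rmultinom(1, n_reads, probs[i, ])),
                     numeric(ncol(probs))))
  dimnames(counts) <- dimnames(probs)
  structure(list(
    variants = variants,
    probs = probs,
    counts = counts,
    barcodes = barcodes,
    os_reads = os_reads,
    model = model,
    design = design,
    seed = seed
  ), class = "ground_truth")
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# Fragment of the full construct corresponding to FL-OS coordinates a..b
# (1-based, inclusive), carrying the secondary loop whenever a..b spans the
# insertion point.
construct_fragment <- function(flos, barcode, a, b, design) {
  p <- design$loop_insert_pos
  if (any(a < 1 | b > design$full_len | a > b))
    stop("fragment bounds outside sequence (internal error)")
  loop <- paste0(design$loop_delim_left, barcode, design$loop_delim_right)
  ifelse(a <= p & b > p,
         paste0(substr(flos, a, p), loop, substr(flos, p + 1L, b)),
         substr(flos, a, b))
}

#' Emit OS/DC/SC sequencing reads for a simulated assay
#'
#' Builds 4-line FASTQ records for the three libraries. OS reads carry the
#' full construct; DC reads the middle fragment spanning FL-OS positions
#' `x+1..y`; 5'-SC reads span `x+1..full_len`; 3'-SC reads span `1..y`
#' (all fragments carry the delimiter-flanked barcode). Every read gets
#' random terminal UMIs and the 3' adapter, and output is byte-identical for
#' identical seeds.
#'
#' @param truth A [simulate_library()] result.
#' @param seed Integer seed for UMIs, barcode choice per read, and
#'   sequencing errors.
#' @param dir Output directory; when `NULL` the reads are returned as
#'   data.frames instead of written to disk.
#' @param prefix File name prefix.
#' @return Invisibly, a list of data.frames `os`, `dc`, `sc` with columns
#'   `id`, `seq`, `qual`; when `dir` is given, also writes
#'   `<prefix>_{os,dc,sc}.fastq` and `<prefix>_truth.tsv` there and returns
#'   the paths in attribute `"paths"`.
#' @export
emit_reads <- function(truth, seed = 1, dir = NULL, prefix = "sim") {
  set.seed(seed)
  design <- truth$design
  v <- truth$variants
  n <- nrow(v)
  C <- truth$counts
  err <- truth$model$error_rate

  bc_pool <- split(truth$barcodes$barcode, truth$barcodes$variant_id)

  # --- OS library: one read per (variant, replicate slot), barcodes cycled
  os_n <- truth$os_reads
  os_variant <- rep(seq_len(n), each = os_n)
  os_bc <- unlist(lapply(seq_len(n), function(i) {
    pool <- bc_pool[[v$variant_id[i]]]
    rep_len(pool, os_n)
  }))
  os_body <- construct_sequence(v$sequence[os_variant], os_bc, design)

  # --- cleavage libraries: expand category counts into per-read rows
  cat_names <- colnames(C)
  idx <- which(C > 0, arr.ind = TRUE)
  reps <- C[idx]
  read_variant <- rep(idx[, 1], reps)
  read_cat <- rep(cat_names[idx[, 2]], reps)
  ord <- order(read_variant, read_cat)
  read_variant <- read_variant[ord]
  read_cat <- read_cat[ord]
  mode <- ifelse(startsWith(read_cat, "DC"), "DC",
          ifelse(startsWith(read_cat, "SC5"), "SC5", "SC3"))
  site <- as.integer(sub(".*?([0-9]+)$", "\\1", read_cat))
  y <- ifelse(mode == "SC5", design$full_len, design$coord_const - site)
  a <- ifelse(mode == "SC3", 1L, site + 1L)
  b <- y
  bcm <- matrix(truth$barcodes$barcode, nrow = nrow(truth$barcodes) / n)
  choice <- sample.int(nrow(bcm), length(read_variant), replace = TRUE)
  rbc <- bcm[cbind(choice, read_variant)]
  frag <- construct_fragment(v$sequence[read_variant], rbc, a, b, design)

  is_dc <- mode == "DC"
  u5len <- ifelse(is_dc, design$umi5_len_dc, design$umi5_len)
  umi5 <- random_dna_varlen(u5len)
  umi3 <- random_dna(length(frag), design$umi3_len)
  body <- if (length(frag)) paste0(umi5, frag, umi3, design$adapter3)
          else character(0)
  if (err > 0) body <- add_errors(body, err)

  os_read <- if (length(os_body))
    paste0(random_dna(length(os_body), design$umi5_len), os_body,
           random_dna(length(os_body), design$umi3_len), design$adapter3)
  else character(0)
  if (err > 0) os_read <- add_errors(os_read, err)

  mk <- function(ids, seqs) {
    data.frame(id = ids, seq = seqs,
               qual = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
  }
  os_df <- mk(sprintf("os_%d_%s", seq_along(os_read), v$variant_id[os_variant]),
              os_read)
  dc_df <- mk(sprintf("dc_%d_%s_%s", seq_len(sum(is_dc)),
                      v$variant_id[read_variant[is_dc]], read_cat[is_dc]),
              body[is_dc])
  sc_df <- mk(sprintf("sc_%d_%s_%s", seq_len(sum(!is_dc)),
                      v$variant_id[read_variant[!is_dc]], read_cat[!is_dc]),
              body[!is_dc])
  out <- list(os = os_df, dc = dc_df, sc = sc_df)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(prefix, "_", names(out), ".fastq"))
    names(paths) <- names(out)
    for (k in names(out)) write_fastq(out[[k]], paths[[k]])
    tp <- file.path(dir, paste0(prefix, "_truth.tsv"))
    write_ground_truth(truth, tp)
    attr(out, "paths") <- c(paths, truth = tp)
  }
  invisible(out)
}

random_dna_varlen <- function(lens) {
  if (!length(lens)) return(character(0))
  full <- random_dna(length(lens), max(lens))
  substr(full, 1L, lens)
}

add_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) {
      for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Write per-variant ground truth to TSV
#'
#' @param truth A [simulate_library()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  pm <- as.data.frame(truth$probs)
  names(pm) <- paste0("p_", colnames(truth$probs))
  cm <- as.data.frame(truth$counts)
  names(cm) <- paste0("n_", colnames(truth$counts))
  df <- cbind(data.frame(variant_id = truth$variants$variant_id,
                         group = truth$variants$group,
                         stringsAsFactors = FALSE),
              pm, cm)
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write 4-line FASTQ
#'
#' Thin wrappers around Biostrings FASTQ support working on plain
#' data.frames with columns `id`, `seq`, `qual`.
#'
#' @param reads Data.frame with `id`, `seq` and optionally `qual`.
#' @param path File path.
#' @return `write_fastq()` returns the path invisibly; `read_fastq()`
#'   returns a data.frame with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  qual <- if (!is.null(reads$qual)) Biostrings::BStringSet(reads$qual)
          else Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}
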