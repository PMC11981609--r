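#' Tally barcode expression per sample
#'
#' Counts exact occurrences of mapped barcodes in each sample's reads
#' and assembles the modelling count table. Every mapped barcode gets a
#' row in every sample; a (barcode, sample) combination never observed
#' is stored as an explicit 0 — in an expression readout, absence of a
#' mapped barcode is evidence of low expression, not missing data, so
#' barcodes are never deleted for missingness.
#'
#' @param sample_barcodes Named list: one character vector of observed
#'   barcode sequences per sample (one element per read). Sample names
#'   must match the sample sheet's `sample_id`.
#' @param map A `variant_barcode_map` from [filter_map()] (or any frame
#'   with `barcode`, `variant`, `position`, `subregion`).
#' @param samples A `sample_sheet`; defaults to a sheet inferred from
#'   the list names (condition/replicate parsed from `"<cond>_r<rep>"`).
#' @return A `count_table` with attribute `unmapped_fraction` (named
#'   per-sample fraction of reads whose barcode is not in the map).
#' @export
tally_expression <- function(sample_barcodes, map, samples = NULL) {
  stopifnot(is.list(sample_barcodes), !is.null(names(sample_barcodes)))
  out <- data.frame(barcode = map$barcode, variant = map$variant,
                    position = map$position, subregion = map$subregion,
                    stringsAsFactors = FALSE)
  unmapped <- numeric(length(sample_barcodes))
  names(unmapped) <- names(sample_barcodes)
  for (s in names(sample_barcodes)) {
    bcs <- sample_barcodes[[s]]
    hit <- bcs %in% map$barcode
    if (!any(hit))
      stop("sample '", s, "' has zero mapped reads", call. = FALSE)
    unmapped[s] <- 1 - mean(hit)
    tab <- table(bcs[hit])
    cnt <- as.integer(tab[out$barcode])
    cnt[is.na(cnt)] <- 0L
    out[[s]] <- cnt
  }
  attr(out, "unmapped_fraction") <- unmapped
  class(out) <- unique(c("count_table", class(out)))
  out
}

#' Stop-codon-derived sample offsets
#'
#' The per-sample technical offset \eqn{\gamma_m} is the natural log of
#' the sum, over all nonsense-variant barcodes library-wide, of counts
#' in sample m. Stop variants produce a dead receptor whose reporter
#' output does not respond to stimulation, so their summed counts track
#' sequencing depth and library composition but not treatment.
#'
#' @param counts A `count_table` whose `variant` column labels nonsense
#'   variants with an `"*"` substitution (e.g. `"12_K*"`).
#' @param samples A `sample_sheet`; its `offset` column is replaced.
#' @return The sample sheet with computed offsets.
#' @export
compute_offsets <- function(counts, samples) {
  is_stop <- grepl("\\*$", counts$variant)
  if (!any(is_stop))
    stop("no nonsense (stop) variant barcodes in the count table; ",
         "offsets are undefined", call. = FALSE)
  cols <- count_columns(counts)
  miss <- setdiff(samples$sample_id, cols)
  if (length(miss) > 0)
    stop("count table lacks sample columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sums <- vapply(samples$sample_id,
                 function(s) sum(counts[[s]][is_stop]), numeric(1))
  if (any(sums == 0))
    stop("zero stop-variant counts in sample(s): ",
         paste(samples$sample_id[sums == 0], collapse = ", "),
         "; offset undefined", call. = FALSE)
  samples$offset <- log(sums)
  samples
}

#' Count-table quality summaries
#'
#' @param counts A `count_table`.
#' @param samples A `sample_sheet`.
#' @return A list: `median_reads_per_barcode` (median count over all
#'   barcode-sample cells), `median_of_median_barcodes_per_variant`
#'   (per sample, the median over variants of the number of barcodes
#'   with nonzero count; then the median over samples — the "median of
#'   medians"), and `replicate_correlation` (mean Pearson correlation of
#'   `log1p` counts between replicate pairs within each condition).
#' @export
qc_summaries <- function(counts, samples) {
  cols <- samples$sample_id
  cnt <- as.matrix(counts[, cols, drop = FALSE])
  med_reads <- median(cnt)
  bc_per_var <- apply(cnt, 2, function(col)
    median(tapply(col > 0, counts$variant, sum)))
  med_of_med <- median(bc_per_var)
  cors <- c()
  for (cond in unique(samples$condition)) {
    ids <- samples$sample_id[samples$condition == cond]
    if (length(ids) < 2) next
    prs <- utils::combn(ids, 2)
    for (j in seq_len(ncol(prs)))
      cors <- c(cors, cor(log1p(cnt[, prs[1, j]]), log1p(cnt[, prs[2, j]])))
  }
  list(median_reads_per_barcode = med_reads,
       median_of_median_barcodes_per_variant = med_of_med,
       replicate_correlation = if (length(cors)) mean(cors) else NA_real_)
}
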