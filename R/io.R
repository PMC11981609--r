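#' Read and write pipeline tables
#'
#' All pipeline artifacts are plain tab-separated text (optionally
#' gzip-compressed by extension) so that fixtures are diff-able.
#'
#' @param path File path; a `.gz` suffix triggers gzip (de)compression.
#' @return `read_tsv_file()` returns a `data.frame`; writers return the
#'   path invisibly.
#' @keywords internal
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname read_tsv_file
#' @param x Data frame to write.
#' @keywords internal
write_tsv_file <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an oligo design table
#'
#' The design table describes the synthesised oligo library: one row per
#' designed variant with columns `oligo_id`, `position` (1-based residue
#' index), `wt_aa`, `alt_aa` (`*` for nonsense; equal to `wt_aa` for
#' wild-type control oligos), `insert_seq` and `subregion` (the cloning
#' segment whose wild-type barcodes are shared during model fitting).
#'
#' @param path TSV file path.
#' @return A validated `oligo_design` data.frame.
#' @export
read_design <- function(path) {
  as_oligo_design(read_tsv_file(path))
}

#' @rdname read_design
#' @param design An `oligo_design` data.frame.
#' @export
write_design <- function(design, path) {
  write_tsv_file(design, path)
}

#' Validate an oligo design table
#'
#' @param x A data.frame with the columns documented in [read_design()].
#' @return `x` with class `oligo_design` prepended, after validation.
#' @export
as_oligo_design <- function(x) {
  need <- c("oligo_id", "position", "wt_aa", "alt_aa", "insert_seq",
            "subregion")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("design is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$oligo_id))
    stop("oligo_id values must be unique", call. = FALSE)
  if (any(!nzchar(x$insert_seq)))
    stop("insert_seq must be non-empty", call. = FALSE)
  key <- paste(x$position, x$alt_aa)
  if (anyDuplicated(key))
    stop("exactly one design record per (position, alt_aa) is required",
         call. = FALSE)
  x$variant <- variant_label(x$position, x$wt_aa, x$alt_aa)
  class(x) <- unique(c("oligo_design", class(x)))
  x
}

#' Canonical variant labels
#'
#' Wild-type control oligos (`alt_aa == wt_aa`) are labelled `"WT"`;
#' every other variant is `"<position>_<wt><alt>"` (e.g. `"104_IV"`),
#' the position-substitution key used throughout the pipeline.
#'
#' @param position Integer residue positions.
#' @param wt_aa,alt_aa Amino-acid codes (`*` allowed for nonsense).
#' @return Character vector of labels.
#' @export
variant_label <- function(position, wt_aa, alt_aa) {
  ifelse(alt_aa == wt_aa, "WT", paste0(position, "_", wt_aa, alt_aa))
}

#' Read/write a sample sheet
#'
#' Columns: `sample_id`, `condition`, `replicate`, `offset` (natural-log
#' scale technical offset; may be NA before [compute_offsets()] runs).
#'
#' @param path TSV path.
#' @return A `sample_sheet` data.frame.
#' @export
read_sample_sheet <- function(path) {
  x <- read_tsv_file(path)
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(x$offset)) x$offset <- NA_real_
  if (anyDuplicated(paste(x$condition, x$replicate)))
    stop("(condition, replicate) pairs must be unique", call. = FALSE)
  class(x) <- unique(c("sample_sheet", class(x)))
  x
}

#' @rdname read_sample_sheet
#' @param sheet A `sample_sheet` data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv_file(sheet, path)
}

#' Read/write a barcode count table
#'
#' Rows are barcodes annotated with `barcode`, `variant`, `position`,
#' `subregion`; remaining columns are one integer count column per
#' sample. Unobserved cells are explicit zeros.
#'
#' @param path TSV path.
#' @return A `count_table` data.frame.
#' @export
read_count_table <- function(path) {
  x <- read_tsv_file(path)
  need <- c("barcode", "variant", "position", "subregion")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("count table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  class(x) <- unique(c("count_table", class(x)))
  x
}

#' @rdname read_count_table
#' @param counts A `count_table` data.frame.
#' @export
write_count_table <- function(counts, path) {
  write_tsv_file(counts, path)
}

count_columns <- function(counts) {
  setdiff(names(counts), c("barcode", "variant", "position", "subregion"))
}

#' Write FASTQ records
#'
#' @param reads Character vector of read sequences.
#' @param path Output path (`.gz` supported).
#' @param ids Optional read names; defaults to `read_1 ... read_n`.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  n <- length(reads)
  if (is.null(ids)) ids <- paste0("read_", seq_len(n))
  qual <- vapply(nchar(reads), function(k) strrep("I", k), character(1))
  out <- character(4L * n)
  out[seq(1, by = 4, length.out = n)] <- paste0("@", ids)
  out[seq(2, by = 4, length.out = n)] <- reads
  out[seq(3, by = 4, length.out = n)] <- "+"
  out[seq(4, by = 4, length.out = n)] <- qual
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read FASTQ sequences
#'
#' Minimal 4-line FASTQ reader returning only the sequence lines; quality
#' strings are ignored because the pipeline works on exact barcode and
#' insert matches.
#'
#' @param path FASTQ path (`.gz` supported).
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (line count not a multiple of 4): ", path,
         call. = FALSE)
  lines[seq(2, length(lines), by = 4)]
}
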