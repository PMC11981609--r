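#' Split merged reads into barcode and insert
#'
#' The first 21 nt of each merged fragment are the barcode; the
#' remainder is the insert to be matched against the designed oligo
#' library. Reads of 21 nt or shorter carry no insert and are skipped.
#'
#' @param reads Character vector of merged read sequences.
#' @param barcode_len Barcode length (default 21).
#' @return A list with `barcode`, `insert` (character vectors over the
#'   usable reads) and `n_skipped` (reads too short to split).
#' @export
extract_barcodes <- function(reads, barcode_len = 21L) {
  ok <- nchar(reads) > barcode_len
  list(barcode = substr(reads[ok], 1L, barcode_len),
       insert = substr(reads[ok], barcode_len + 1L, nchar(reads[ok])),
       n_skipped = sum(!ok))
}

#' Match an insert against the designed oligo library
#'
#' Exact-match lookup standing in for strictly-unique alignment against
#' the designed reference: an insert maps only if it equals exactly one
#' designed sequence. An optional edit-distance-1 rescue (off by
#' default) accepts inserts one substitution away from a unique design
#' sequence.
#'
#' @param insert Character vector of insert sequences.
#' @param design An `oligo_design`.
#' @param rescue_1mm If `TRUE`, unmatched inserts are rescued when
#'   exactly one design sequence of equal length is within Hamming
#'   distance 1.
#' @return Character vector: the matching `oligo_id`, `"ambiguous"` if
#'   several designs share the sequence (forbidden by design invariants,
#'   kept for safety), or `"unmatched"`.
#' @export
match_insert <- function(insert, design, rescue_1mm = FALSE) {
  tab <- table(design$insert_seq)
  dup <- names(tab)[tab > 1]
  hit <- match(insert, design$insert_seq)
  out <- ifelse(is.na(hit), "unmatched", design$oligo_id[hit])
  out[insert %in% dup] <- "ambiguous"
  if (rescue_1mm) {
    for (i in which(out == "unmatched")) {
      if (!nzchar(insert[i])) next
      cand <- design$insert_seq[nchar(design$insert_seq) == nchar(insert[i])]
      ids <- design$oligo_id[nchar(design$insert_seq) == nchar(insert[i])]
      d1 <- vapply(cand, function(s) hamming_dist(s, insert[i]) == 1L,
                   logical(1))
      if (sum(d1) == 1L) out[i] <- ids[d1]
    }
  }
  out
}

hamming_dist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Purity of an oligo-barcode pair
#'
#' The read count of the pair divided by the total number of reads
#' containing that barcode.
#'
#' @param pair_reads Reads supporting the pair.
#' @param barcode_total_reads All reads carrying the barcode.
#' @return Fraction in \[0, 1\]; `NA` when the denominator is 0 (such
#'   pairs are excluded downstream).
#' @export
compute_purity <- function(pair_reads, barcode_total_reads) {
  stopifnot(all(pair_reads >= 0), all(pair_reads <= barcode_total_reads))
  ifelse(barcode_total_reads > 0, pair_reads / barcode_total_reads,
         NA_real_)
}

#' Tabulate oligo-barcode pairs for one mapping replicate
#'
#' Extracts barcodes, matches inserts exactly against the design, and
#' summarises each barcode by its majority oligo with per-pair depth and
#' purity. Ambiguous and unmatched inserts count toward a barcode's
#' total read depth (they dilute purity) but never form a pair.
#'
#' @param reads Character vector of merged reads.
#' @param design An `oligo_design`.
#' @param barcode_len Barcode length (default 21); reads are split, and
#'   the observed barcode length is checked downstream by [filter_map()].
#' @param rescue_1mm Passed to [match_insert()].
#' @return A `data.frame` (one row per barcode) with columns `barcode`,
#'   `oligo_id` (majority oligo), `pair_reads`, `barcode_total_reads`,
#'   `purity`, plus attributes `n_skipped`, `n_unmatched`.
#' @export
build_pair_stats <- function(reads, design, barcode_len = 21L,
                             rescue_1mm = FALSE) {
  ex <- extract_barcodes(reads, barcode_len)
  oligo <- match_insert(ex$insert, design, rescue_1mm)
  df <- data.frame(barcode = ex$barcode, oligo = oligo,
                   stringsAsFactors = FALSE)
  total <- table(df$barcode)
  mapped <- df[!(df$oligo %in% c("unmatched", "ambiguous")), , drop = FALSE]
  if (nrow(mapped) == 0) {
    out <- data.frame(barcode = character(0), oligo_id = character(0),
                      pair_reads = integer(0),
                      barcode_total_reads = integer(0),
                      purity = numeric(0), stringsAsFactors = FALSE)
  } else {
    pair <- as.data.frame(table(mapped$barcode, mapped$oligo),
                          stringsAsFactors = FALSE)
    names(pair) <- c("barcode", "oligo_id", "pair_reads")
    pair <- pair[pair$pair_reads > 0, , drop = FALSE]
    # majority oligo per barcode; deterministic tie-break on oligo_id
    pair <- pair[order(pair$barcode, -pair$pair_reads, pair$oligo_id), ]
    out <- pair[!duplicated(pair$barcode), , drop = FALSE]
    out$barcode_total_reads <- as.integer(total[out$barcode])
    out$purity <- compute_purity(out$pair_reads, out$barcode_total_reads)
    rownames(out) <- NULL
  }
  attr(out, "n_skipped") <- ex$n_skipped
  attr(out, "n_unmatched") <- sum(oligo == "unmatched")
  out
}

#' Filter oligo-barcode pairs into a variant-barcode map
#'
#' A pair survives only if, in *both* mapping replicates, it has the
#' correct barcode length, total read depth strictly greater than
#' `depth_min`, and purity strictly greater than `purity_min` — and the
#' majority oligo agrees between replicates (a barcode whose best oligo
#' differs across replicates, or which is absent from either replicate,
#' fails).
#'
#' @param stats A list of per-replicate [build_pair_stats()] frames
#'   (normally length 2).
#' @param design An `oligo_design` used to annotate the map.
#' @param depth_min Depth threshold (default 10, strict `>`).
#' @param purity_min Purity threshold (default 0.75, strict `>`).
#' @param barcode_len Required barcode length (default 21).
#' @param allow_single_replicate Explicit override to accept a
#'   single-replicate `stats` list.
#' @return A `variant_barcode_map` data.frame with columns `barcode`,
#'   `oligo_id`, `variant`, `position`, `wt_aa`, `alt_aa`, `subregion`,
#'   and per-replicate `depth_rep<i>` / `purity_rep<i>`; attribute
#'   `removed` counts pairs dropped per rule, `thresholds` records the
#'   filter settings.
#' @export
filter_map <- function(stats, design, depth_min = 10, purity_min = 0.75,
                       barcode_len = 21L, allow_single_replicate = FALSE) {
  if (!is.list(stats) || is.data.frame(stats)) stats <- list(stats)
  if (length(stats) < 2 && !allow_single_replicate)
    stop("two mapping replicates are required ",
         "(set allow_single_replicate = TRUE to override)", call. = FALSE)
  removed <- c(absent = 0L, length = 0L, depth = 0L, purity = 0L,
               discordant = 0L)

  all_bc <- unique(unlist(lapply(stats, `[[`, "barcode")))
  present <- Reduce(intersect, lapply(stats, `[[`, "barcode"))
  removed["absent"] <- length(all_bc) - length(present)

  keep <- present
  # per-rule pass sets (order of application is irrelevant: intersection)
  len_ok <- nchar(keep) == barcode_len
  removed["length"] <- sum(!len_ok)
  keep <- keep[len_ok]
  for (st in stats) {
    i <- match(keep, st$barcode)
    d_ok <- st$barcode_total_reads[i] > depth_min
    removed["depth"] <- removed["depth"] + sum(!d_ok)
    keep <- keep[d_ok]
  }
  for (st in stats) {
    i <- match(keep, st$barcode)
    p_ok <- !is.na(st$purity[i]) & st$purity[i] > purity_min
    removed["purity"] <- removed["purity"] + sum(!p_ok)
    keep <- keep[p_ok]
  }
  oligos <- sapply(stats, function(st) st$oligo_id[match(keep, st$barcode)])
  if (length(keep) == 1L) oligos <- matrix(oligos, nrow = 1L)
  if (length(keep) > 0 && length(stats) > 1) {
    same <- apply(oligos, 1, function(z) length(unique(z)) == 1L)
    removed["discordant"] <- sum(!same)
    keep <- keep[same]
    oligos <- oligos[same, , drop = FALSE]
  }

  oligo_id <- if (length(keep) > 0) oligos[, 1] else character(0)
  di <- match(oligo_id, design$oligo_id)
  map <- data.frame(barcode = keep, oligo_id = oligo_id,
                    variant = design$variant[di],
                    position = design$position[di],
                    wt_aa = design$wt_aa[di], alt_aa = design$alt_aa[di],
                    subregion = design$subregion[di],
                    stringsAsFactors = FALSE)
  for (r in seq_along(stats)) {
    i <- match(keep, stats[[r]]$barcode)
    map[[paste0("depth_rep", r)]] <- stats[[r]]$barcode_total_reads[i]
    map[[paste0("purity_rep", r)]] <- stats[[r]]$purity[i]
  }
  rownames(map) <- NULL
  attr(map, "removed") <- removed
  attr(map, "thresholds") <- list(depth_min = depth_min,
                                  purity_min = purity_min,
                                  barcode_len = barcode_len)
  class(map) <- unique(c("variant_barcode_map", class(map)))
  map
}
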