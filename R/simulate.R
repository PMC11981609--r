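#' Simulation configuration for barcode-level DMS data
#'
#' Describes the generative model used by [simulate_counts()]: for
#' condition i, variant j, barcode k and sample m,
#' \deqn{count_{ijkm} \sim NB(\mu_{ij}, \theta), \quad
#'       \log \mu_{ij} = \log(\mathrm{baseline}) + c_i + e_{ji} +
#'       \alpha_k + \gamma_m}
#' with barcode random intercepts \eqn{\alpha_k \sim N(0, \sigma^2)}
#' shared across every sample of a barcode, per-sample technical offsets
#' \eqn{\gamma_m \sim N(0, \mathrm{offset\_jitter}^2)}, and NB dispersion
#' \eqn{\theta} in the mean/dispersion convention
#' \eqn{Var = \mu + \mu^2/\theta}.
#'
#' Each position carries `n_variants_per_position` non-wild-type variants
#' of which exactly one is a nonsense (stop, `*`) variant; wild-type
#' control barcodes are attached to one WT oligo per subregion. By
#' default stop variants receive a deviation of `-condition_effects[i]`
#' in every condition, so their expected counts stay at the unstimulated
#' baseline in all samples — the property that justifies using summed
#' stop counts as a depth offset. Missense true effects default to 0 and
#' are supplied through `effect_table_truth` (the library's true effect
#' distribution is a user choice, not an assumption of the generator).
#'
#' @param n_positions Number of mutagenised residue positions.
#' @param n_variants_per_position Variants per position, including the
#'   one nonsense variant.
#' @param barcodes_per_variant Barcodes tagging each variant.
#' @param conditions Character vector of condition labels
#'   (Drug_Concentration style, e.g. `"aMSH_low"`).
#' @param condition_effects Per-condition shift \eqn{c_i} of the mean on
#'   the natural-log scale; default 0 for the first (basal) condition and
#'   `log(4)` for the rest (agonist stimulation raising reporter output).
#' @param replicates_per_condition Biological replicates per condition.
#' @param sigma Barcode random-intercept SD (natural-log scale).
#' @param theta NB dispersion (`Var = mu + mu^2/theta`).
#' @param baseline_mean Expected wild-type count in the basal condition
#'   at offset 0; default 10 (of the order of the median reads per
#'   barcode per sample in a typical run).
#' @param effect_table_truth Optional matrix of true deviations
#'   (natural-log scale), variants in rows (labelled as in
#'   [variant_label()]), conditions in columns. Missing variants default
#'   to 0 (missense) or the nonsense rule.
#' @param nonsense_effect `NULL` (default) applies `-condition_effects`
#'   to stop variants (constant stop counts across conditions); a scalar
#'   applies that natural-log deviation in stimulated conditions
#'   (`condition_effects > 0`) and 0 elsewhere.
#' @param offset_jitter SD of per-sample technical log-offsets.
#' @param dropout_prob Probability a barcode is absent from the map
#'   entirely (not per-sample; per-sample zeros arise from the NB).
#' @param wt_barcodes_per_subregion Wild-type barcodes per subregion.
#' @param positions_per_subregion Positions grouped per cloning
#'   subregion; default all positions in one subregion.
#' @param insert_len Length of designed insert sequences (nt).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_positions = 4,
                       n_variants_per_position = 5,
                       barcodes_per_variant = 30,
                       conditions = c("DMSO_0", "aMSH_low"),
                       condition_effects = NULL,
                       replicates_per_condition = 4,
                       sigma = 0.5,
                       theta = 5,
                       baseline_mean = 10,
                       effect_table_truth = NULL,
                       nonsense_effect = NULL,
                       offset_jitter = 0.3,
                       dropout_prob = 0,
                       wt_barcodes_per_subregion = barcodes_per_variant,
                       positions_per_subregion = n_positions,
                       insert_len = 30,
                       seed = 1L) {
  if (is.null(condition_effects))
    condition_effects <- c(0, rep(log(4), length(conditions) - 1L))
  cfg <- list(n_positions = as.integer(n_positions),
              n_variants_per_position = as.integer(n_variants_per_position),
              barcodes_per_variant = as.integer(barcodes_per_variant),
              conditions = as.character(conditions),
              condition_effects = as.numeric(condition_effects),
              replicates_per_condition = as.integer(replicates_per_condition),
              sigma = sigma, theta = theta, baseline_mean = baseline_mean,
              effect_table_truth = effect_table_truth,
              nonsense_effect = nonsense_effect,
              offset_jitter = offset_jitter, dropout_prob = dropout_prob,
              wt_barcodes_per_subregion = as.integer(wt_barcodes_per_subregion),
              positions_per_subregion = as.integer(positions_per_subregion),
              insert_len = as.integer(insert_len),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_positions >= 1L, cfg$n_variants_per_position >= 1L,
            cfg$barcodes_per_variant >= 1L,
            cfg$replicates_per_condition >= 1L,
            cfg$wt_barcodes_per_subregion >= 1L)
  if (length(cfg$conditions) < 1L)
    stop("at least one condition is required", call. = FALSE)
  if (length(cfg$condition_effects) != length(cfg$conditions))
    stop("condition_effects must match conditions in length", call. = FALSE)
  if (!is.finite(cfg$theta) || cfg$theta <= 0)
    stop("theta must be positive and finite", call. = FALSE)
  if (!is.finite(cfg$baseline_mean) || cfg$baseline_mean <= 0)
    stop("baseline_mean must be positive", call. = FALSE)
  if (cfg$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (cfg$dropout_prob < 0 || cfg$dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Generate random DNA barcodes
#'
#' @param n Number of distinct sequences.
#' @param len Sequence length (default 21, the barcode length of the
#'   assay design).
#' @return Character vector of `n` unique sequences. Uses the current
#'   RNG state (seed it with `set.seed()` upstream).
#' @export
random_barcodes <- function(n, len = 21L) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE),
                nrow = k)
    apply(m, 1, paste0, collapse = "")
  }
  out <- unique(draw(n))
  while (length(out) < n) out <- unique(c(out, draw(n - length(out))))
  out[seq_len(n)]
}

#' Build a synthetic oligo design table
#'
#' One WT control oligo per subregion plus `n_variants_per_position - 1`
#' missense and one nonsense variant per position, each with a unique
#' random insert sequence.
#'
#' @param config A [sim_config()].
#' @return An `oligo_design` data.frame (uses the current RNG state).
#' @export
sim_design <- function(config) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  nsub <- ceiling(config$n_positions / config$positions_per_subregion)
  sub_of <- function(pos) paste0("S", (pos - 1L) %/%
                                   config$positions_per_subregion + 1L)
  rows <- list()
  for (p in seq_len(config$n_positions)) {
    wt <- sample(aa, 1L)
    n_mis <- config$n_variants_per_position - 1L
    alts <- c(sample(setdiff(aa, wt), n_mis), "*")
    rows[[p]] <- data.frame(position = p, wt_aa = wt, alt_aa = alts,
                            subregion = sub_of(p),
                            stringsAsFactors = FALSE)
  }
  var_rows <- do.call(rbind, rows)
  # one WT oligo per subregion, anchored at the subregion's first position
  first_pos <- tapply(var_rows$position, var_rows$subregion, min)
  wt_rows <- data.frame(position = as.integer(first_pos),
                        wt_aa = var_rows$wt_aa[match(first_pos,
                                                     var_rows$position)],
                        alt_aa = var_rows$wt_aa[match(first_pos,
                                                      var_rows$position)],
                        subregion = names(first_pos),
                        stringsAsFactors = FALSE)
  des <- rbind(var_rows, wt_rows)
  des$oligo_id <- sprintf("oligo_%03d", seq_len(nrow(des)))
  des$insert_seq <- random_barcodes(nrow(des), config$insert_len)
  as_oligo_design(des[, c("oligo_id", "position", "wt_aa", "alt_aa",
                          "insert_seq", "subregion")])
}

default_truth <- function(design, config) {
  vars <- unique(design$variant)
  truth <- matrix(0, nrow = length(vars), ncol = length(config$conditions),
                  dimnames = list(vars, config$conditions))
  stops <- design$variant[design$alt_aa == "*"]
  if (length(stops) > 0) {
    if (is.null(config$nonsense_effect)) {
      truth[stops, ] <- matrix(-config$condition_effects,
                               nrow = length(stops),
                               ncol = length(config$conditions),
                               byrow = TRUE)
    } else {
      stim <- config$condition_effects > 0
      truth[stops, stim] <- config$nonsense_effect
    }
  }
  if (!is.null(config$effect_table_truth)) {
    supplied <- config$effect_table_truth
    if (is.null(rownames(supplied)) || is.null(colnames(supplied)))
      stop("effect_table_truth needs variant rownames and condition colnames",
           call. = FALSE)
    keep <- intersect(rownames(supplied), vars)
    truth[keep, colnames(supplied)] <- supplied[keep, , drop = FALSE]
  }
  truth["WT", ] <- 0
  truth
}

#' Simulate a barcode count table with known truth
#'
#' Draws barcode-by-sample counts from the negative binomial mixed model
#' described in [sim_config()] and records every latent quantity
#' (assignments, barcode intercepts, sample offsets, true effects) so
#' downstream estimates can be checked against ground truth.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a `count_table`), `samples`
#'   (a `sample_sheet` whose `offset` column holds the true \eqn{\gamma_m};
#'   [compute_offsets()] re-derives them from stop counts), `truth`
#'   (a `sim_truth` list) and `design` (the `oligo_design`).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  design <- sim_design(config)
  truth_mat <- default_truth(design, config)

  nbc <- ifelse(design$variant == "WT", config$wt_barcodes_per_subregion,
                config$barcodes_per_variant)
  assignment <- data.frame(
    oligo_id = rep(design$oligo_id, nbc),
    variant = rep(design$variant, nbc),
    position = rep(design$position, nbc),
    subregion = rep(design$subregion, nbc),
    stringsAsFactors = FALSE)
  assignment$barcode <- random_barcodes(nrow(assignment))
  if (config$dropout_prob > 0) {
    keep <- runif(nrow(assignment)) >= config$dropout_prob
    assignment <- assignment[keep, , drop = FALSE]
  }
  if (nrow(assignment) == 0)
    stop("all barcodes dropped out; lower dropout_prob", call. = FALSE)

  K <- nrow(assignment)
  alpha <- rnorm(K, 0, config$sigma)
  names(alpha) <- assignment$barcode

  samples <- expand.grid(replicate = seq_len(config$replicates_per_condition),
                         condition = config$conditions,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "replicate")]
  samples$sample_id <- paste0(samples$condition, "_r", samples$replicate)
  gamma <- rnorm(nrow(samples), 0, config$offset_jitter)
  names(gamma) <- samples$sample_id
  samples$offset <- gamma
  class(samples) <- unique(c("sample_sheet", class(samples)))

  eff <- truth_mat[assignment$variant, , drop = FALSE]  # K x n_cond
  counts <- assignment[, c("barcode", "variant", "position", "subregion")]
  for (m in seq_len(nrow(samples))) {
    ci <- match(samples$condition[m], config$conditions)
    mu <- exp(log(config$baseline_mean) + config$condition_effects[ci] +
                eff[, ci] + alpha + gamma[m])
    counts[[samples$sample_id[m]]] <- rnbinom(K, size = config$theta, mu = mu)
  }
  class(counts) <- unique(c("count_table", class(counts)))

  truth <- structure(list(true_effects = truth_mat,
                          barcode_intercepts = alpha,
                          sample_offsets = gamma,
                          condition_effects = setNames(
                            config$condition_effects, config$conditions),
                          variant_barcode_assignment = assignment,
                          config = config),
                     class = "sim_truth")
  list(counts = counts, samples = samples, truth = truth, design = design)
}

#' Simulate mapping-run reads (barcode + insert)
#'
#' Emulates the plasmid-library mapping sequencing: each read is the
#' 21-nt barcode followed by its assigned oligo's insert sequence. With
#' probability `chimera_rate` the insert is swapped for a different
#' oligo's insert (an impure, chimeric pair), and independent nucleotide
#' substitution errors are applied at `error_rate` per base.
#'
#' @param truth A `sim_truth` from [simulate_counts()] (supplies the
#'   barcode-variant assignment).
#' @param design The `oligo_design` the truth was generated from.
#' @param n_reads Number of reads to draw (barcodes sampled uniformly).
#' @param chimera_rate,error_rate Fractions in \[0, 1).
#' @param seed Integer seed for the read stream; independent of the
#'   count stream so adding read simulation never perturbs count draws.
#' @return A list with `reads` (character vector) and `read_info`
#'   (data.frame: `barcode`, `true_oligo`, `emitted_oligo`, `chimeric`).
#' @export
simulate_reads <- function(truth, design, n_reads, chimera_rate = 0,
                           error_rate = 0, seed = 1L) {
  if (nrow(design) == 0) stop("empty design", call. = FALSE)
  if (chimera_rate < 0 || chimera_rate >= 1)
    stop("chimera_rate must be in [0, 1)", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)", call. = FALSE)
  assignment <- truth$variant_barcode_assignment
  set.seed(seed)
  idx <- sample.int(nrow(assignment), n_reads, replace = TRUE)
  bc <- assignment$barcode[idx]
  oligo <- assignment$oligo_id[idx]
  emitted <- oligo
  chim <- runif(n_reads) < chimera_rate
  if (any(chim) && nrow(design) > 1) {
    swap <- function(o) sample(setdiff(design$oligo_id, o), 1L)
    emitted[chim] <- vapply(oligo[chim], swap, character(1))
  }
  ins <- design$insert_seq[match(emitted, design$oligo_id)]
  reads <- paste0(bc, ins)
  if (error_rate > 0) reads <- mutate_reads(reads, error_rate)
  list(reads = reads,
       read_info = data.frame(barcode = bc, true_oligo = oligo,
                              emitted_oligo = emitted, chimeric = chim,
                              stringsAsFactors = FALSE))
}

mutate_reads <- function(reads, rate) {
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    reads[i] <- paste0(s, collapse = "")
  }
  reads
}
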