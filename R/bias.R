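#' Build the mutant-by-condition test-statistic matrix
#'
#' Rows are individual mutants (Position_Substitution labels), columns
#' are conditions (Drug_Concentration labels), values are the Wald
#' statistic (log2 fold change divided by its standard error) taken
#' directly from the effect tables. Only complete rows are kept; the
#' number of dropped mutants is recorded.
#'
#' @param effects An `effect_table` covering all conditions (e.g. the
#'   row-bound output of [effect_table()] over many positions).
#' @param conditions Condition labels to use as columns (default: all in
#'   the table); at least 2 required.
#' @return A numeric matrix with attribute `n_dropped` (incomplete
#'   mutants removed).
#' @export
build_stat_matrix <- function(effects, conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(effects$condition)
  if (length(conditions) < 2)
    stop("at least 2 conditions are required", call. = FALSE)
  sub <- effects[effects$condition %in% conditions & effects$estimable, ]
  variants <- unique(sub$variant)
  m <- matrix(NA_real_, length(variants), length(conditions),
              dimnames = list(variants, conditions))
  m[cbind(sub$variant, sub$condition)] <- sub$z
  complete <- complete.cases(m)
  if (sum(complete) < 2)
    stop("fewer than 2 mutants with complete condition coverage",
         call. = FALSE)
  out <- m[complete, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!complete)
  out
}

#' Principal component analysis of the test-statistic matrix
#'
#' Column-centered, unscaled PCA via singular value decomposition (the
#' `prcomp` default). Because SVD component signs are arbitrary, a
#' deterministic orientation is imposed: PC1 is flipped so nonsense
#' variants (labels ending in `*`) have positive mean score — anchoring
#' "PC1 separates variants by overall loss of function" — or, if no
#' nonsense variant is present, so its largest-magnitude loading is
#' positive; every other component gets the largest-loading rule.
#'
#' @param mat Matrix from [build_stat_matrix()].
#' @return A `bias_pca` list: `scores` (mutants x components), `loadings`
#'   (conditions x components), `var_explained` (fractions summing to 1
#'   over all components; zero-variance components beyond the matrix
#'   rank get 0).
#' @export
run_pca <- function(mat) {
  if (ncol(mat) < 2) stop("need >= 2 columns", call. = FALSE)
  ctr <- scale(mat, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  loadings <- sv$v
  ncomp <- length(sv$d)
  is_stop <- grepl("\\*$", rownames(mat))
  for (j in seq_len(ncomp)) {
    flip <- FALSE
    if (j == 1 && any(is_stop)) {
      flip <- mean(scores[is_stop, 1]) < 0
    } else {
      l <- loadings[, j]
      flip <- l[which.max(abs(l))] < 0
    }
    if (flip) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  dimnames(scores) <- list(rownames(mat), paste0("PC", seq_len(ncomp)))
  dimnames(loadings) <- list(colnames(mat), paste0("PC", seq_len(ncomp)))
  ve <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = setNames(ve, paste0("PC", seq_len(ncomp)))),
            class = "bias_pca")
}

#' Flag signaling-biased variants from PC2
#'
#' Mutants whose PC2 score strictly exceeds the cutoff in absolute value
#' are flagged; the score's sign assigns the direction label. The
#' orientation convention of [run_pca()] is deterministic, but which
#' biological pathway a PC2 sign corresponds to must be validated
#' against planted truth or known variants — it is supplied through
#' `labels`, not assumed.
#'
#' @param pca A `bias_pca`.
#' @param cutoff Absolute PC2 threshold (default 7.5, strict `>`).
#' @param labels Length-2 character vector naming the positive and
#'   negative PC2 directions.
#' @return A `bias_table` data.frame: `variant`, `pc1`, `pc2`, `bias`
#'   (one of `labels` or `"none"`).
#' @export
flag_biased <- function(pca, cutoff = 7.5,
                        labels = c(positive = "Gq-biased",
                                   negative = "Gs-biased")) {
  pc2 <- pca$scores[, "PC2"]
  bias <- rep("none", length(pc2))
  bias[pc2 > cutoff] <- labels[[1]]
  bias[pc2 < -cutoff] <- labels[[2]]
  out <- data.frame(variant = rownames(pca$scores),
                    pc1 = pca$scores[, "PC1"], pc2 = pc2, bias = bias,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- unique(c("bias_table", class(out)))
  out
}
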