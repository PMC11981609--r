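#' Marginal means per variant and treatment
#'
#' On the link (natural-log) scale the marginal mean of variant v under
#' treatment t is \eqn{\beta_t^{cond} + \beta_{vt}^{var}}, evaluated at
#' random-effect mean 0 and at the fit's average offset, then converted
#' to log2. The average-offset constant is shared by every entry of the
#' fit and cancels in any within-fit contrast.
#'
#' @param fit A `position_fit` containing the treatment condition(s).
#' @param treatment Condition label(s); default all conditions in the fit.
#' @return A `marginal_means` data.frame: `variant` (including `"WT"`),
#'   `condition`, `mm` (log2), `se` (log2). SEs propagate the full
#'   fixed-effect covariance.
#' @export
marginal_means <- function(fit, treatment = fit$conditions) {
  miss <- setdiff(treatment, fit$conditions)
  if (length(miss) > 0)
    stop("treatment(s) absent from fit: ", paste(miss, collapse = ", "),
         call. = FALSE)
  grid <- expand.grid(variant = c("WT", fit$variants), condition = treatment,
                      stringsAsFactors = FALSE)
  p <- length(fit$beta)
  mm <- se <- rep(NA_real_, nrow(grid))
  for (r in seq_len(nrow(grid))) {
    v <- grid$variant[r]; cc <- grid$condition[r]
    cvec <- mm_contrast_vec(fit, v, cc)
    if (is.null(cvec)) next
    mm[r] <- (sum(cvec * fit$beta) + fit$mean_offset) / log(2)
    se[r] <- sqrt(drop(t(cvec) %*% fit$cov %*% cvec)) / log(2)
  }
  out <- data.frame(variant = grid$variant, condition = grid$condition,
                    mm = mm, se = se, stringsAsFactors = FALSE)
  class(out) <- unique(c("marginal_means", class(out)))
  out
}

# contrast vector selecting beta_cond (+ beta_dev for non-WT variants);
# NULL when the cell is non-estimable
mm_contrast_vec <- function(fit, variant, condition) {
  cvec <- numeric(length(fit$beta))
  names(cvec) <- names(fit$beta)
  cvec[condition] <- 1
  if (variant != "WT") {
    if (!isTRUE(fit$estimable[variant, condition])) return(NULL)
    cvec[paste(variant, condition, sep = "|")] <- 1
  }
  cvec
}

#' Corrector-response contrasts: defect and rescue
#'
#' *Defect* is the marginal mean of a variant under the untreated
#' (DMSO) condition minus the wild-type marginal mean under the same
#' condition — the variant's intrinsic activity deficit. *Rescue* is the
#' variant's marginal mean under corrector treatment minus its own
#' untreated marginal mean — the activity gained upon treatment. Both
#' are linear contrasts of one positional fit; SEs use the full
#' fixed-effect covariance, Wald p-values the standard normal.
#'
#' @param fit A `position_fit` whose conditions include both arms.
#' @param untreated Untreated (DMSO) condition label.
#' @param treated Corrector-treated condition label (for
#'   [rescue_contrast()]).
#' @return A data.frame with `variant`, `estimate` (log2), `se`, `p`.
#'   The wild-type defect is identically 0 with SE 0 and p NA (it is the
#'   reference, not a test).
#' @export
defect_contrast <- function(fit, untreated) {
  if (!untreated %in% fit$conditions)
    stop("untreated condition '", untreated, "' absent from fit",
         call. = FALSE)
  vars <- c("WT", fit$variants)
  est <- se <- rep(NA_real_, length(vars))
  est[1] <- 0; se[1] <- 0
  for (i in seq_along(vars)[-1]) {
    v <- vars[i]
    cv <- mm_contrast_vec(fit, v, untreated)
    cw <- mm_contrast_vec(fit, "WT", untreated)
    if (is.null(cv)) next
    d <- cv - cw
    est[i] <- sum(d * fit$beta) / log(2)
    se[i] <- sqrt(drop(t(d) %*% fit$cov %*% d)) / log(2)
  }
  p <- ifelse(se > 0, 2 * pnorm(-abs(est / se)), NA_real_)
  data.frame(variant = vars, estimate = est, se = se, p = p,
             stringsAsFactors = FALSE)
}

#' @rdname defect_contrast
#' @export
rescue_contrast <- function(fit, treated, untreated) {
  miss <- setdiff(c(treated, untreated), fit$conditions)
  if (length(miss) > 0)
    stop("condition(s) absent from fit: ", paste(miss, collapse = ", "),
         call. = FALSE)
  vars <- c("WT", fit$variants)
  est <- se <- rep(NA_real_, length(vars))
  for (i in seq_along(vars)) {
    v <- vars[i]
    ct <- mm_contrast_vec(fit, v, treated)
    cu <- mm_contrast_vec(fit, v, untreated)
    if (is.null(ct) || is.null(cu)) next
    d <- ct - cu
    est[i] <- sum(d * fit$beta) / log(2)
    se[i] <- sqrt(drop(t(d) %*% fit$cov %*% d)) / log(2)
  }
  p <- ifelse(se > 0, 2 * pnorm(-abs(est / se)), NA_real_)
  data.frame(variant = vars, estimate = est, se = se, p = p,
             stringsAsFactors = FALSE)
}

#' Build the defect/rescue contrast table for a set of fits
#'
#' Runs [defect_contrast()] and [rescue_contrast()] on each positional
#' fit, BH-adjusts each statistic across all variants, and classifies
#' treatment response via [classify_rescue()].
#'
#' @param fits A `position_fit` or list of them.
#' @param treated,untreated Condition labels for the corrector arm and
#'   the DMSO arm.
#' @param fdr FDR level for the classification (default 0.05).
#' @return A `contrast_table` data.frame: `variant`, `position`,
#'   `defect`, `defect_se`, `defect_p`, `defect_q`, `rescue`,
#'   `rescue_se`, `rescue_p`, `rescue_q`, `rescue_class`.
#' @export
rescue_table <- function(fits, treated, untreated, fdr = 0.05) {
  if (inherits(fits, "position_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    d <- defect_contrast(f, untreated)
    r <- rescue_contrast(f, treated, untreated)
    keep <- d$variant != "WT"
    data.frame(variant = d$variant[keep], position = f$position,
               defect = d$estimate[keep], defect_se = d$se[keep],
               defect_p = d$p[keep],
               rescue = r$estimate[keep], rescue_se = r$se[keep],
               rescue_p = r$p[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$defect_q <- bh_adjust(out$defect_p)
  out$rescue_q <- bh_adjust(out$rescue_p)
  out <- classify_rescue(out, fdr = fdr)
  class(out) <- unique(c("contrast_table", class(out)))
  out
}

#' Classify corrector response
#'
#' `defect-rescued`: defect significantly negative AND rescue
#' significantly positive at the FDR threshold; `defect-not-rescued`:
#' only the defect test passes; `no-defect`: otherwise. Variants with NA
#' contrasts are labelled `"NA"`.
#'
#' @param contrasts A data.frame with `defect`, `defect_q`, `rescue`,
#'   `rescue_q` columns.
#' @param fdr FDR threshold (default 0.05).
#' @return The table with a `rescue_class` column.
#' @export
classify_rescue <- function(contrasts, fdr = 0.05) {
  defect_sig <- !is.na(contrasts$defect_q) & contrasts$defect_q < fdr &
    contrasts$defect < 0
  rescue_sig <- !is.na(contrasts$rescue_q) & contrasts$rescue_q < fdr &
    contrasts$rescue > 0
  cls <- ifelse(defect_sig & rescue_sig, "defect-rescued",
                ifelse(defect_sig, "defect-not-rescued", "no-defect"))
  cls[is.na(contrasts$defect) | is.na(contrasts$rescue)] <- "NA"
  contrasts$rescue_class <- cls
  contrasts
}
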