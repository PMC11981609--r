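#' Control parameters for the position model fit
#'
#' @param maxit Maximum L-BFGS-B iterations for the outer optimisation.
#' @param restarts Jittered restarts attempted on non-convergence before
#'   the fit is flagged non-estimable.
#' @param log_sigma_bounds,log_theta_bounds Box constraints for the
#'   variance parameters (log scale). The lower sigma bound effectively
#'   allows sigma = 0 (random effect switched off) without a boundary
#'   singularity: the Laplace correction is computed as
#'   `log1p(sigma^2 * W)` and is exact in that limit.
#' @param beta_bound Symmetric box for fixed effects (natural log).
#' @return A list of class `nb_control`.
#' @export
nb_control <- function(maxit = 500L, restarts = 3L,
                       log_sigma_bounds = c(-10, 2),
                       log_theta_bounds = c(-5, 14),
                       beta_bound = 30) {
  structure(list(maxit = as.integer(maxit), restarts = as.integer(restarts),
                 log_sigma_bounds = log_sigma_bounds,
                 log_theta_bounds = log_theta_bounds,
                 beta_bound = beta_bound),
            class = "nb_control")
}

#' Assemble the modelling dataset for one position
#'
#' Collects all variants at the position together with every wild-type
#' barcode of the same cloning subregion, in long format with one row
#' per (barcode, sample) and explicit zeros.
#'
#' @param counts A `count_table`.
#' @param position Residue position (must occur in the table).
#' @param samples A `sample_sheet` with finite offsets (run
#'   [compute_offsets()] first, or set offsets to 0 deliberately).
#' @return A `position_dataset` list: `long` (data.frame with `barcode`,
#'   `variant`, `condition`, `replicate`, `sample_id`, `offset`,
#'   `count`), `position`, `subregion`, `variants` (non-WT labels),
#'   `conditions`.
#' @export
build_position_dataset <- function(counts, position, samples) {
  if (any(!is.finite(samples$offset)))
    stop("sample sheet offsets must be finite; run compute_offsets() ",
         "or set them explicitly", call. = FALSE)
  at_pos <- counts$position == position & counts$variant != "WT"
  if (!any(at_pos))
    stop("no variants at position ", position, call. = FALSE)
  subregion <- unique(counts$subregion[at_pos])
  if (length(subregion) != 1)
    stop("position ", position, " spans multiple subregions", call. = FALSE)
  wt <- counts$variant == "WT" & counts$subregion == subregion
  if (!any(wt))
    stop("no wild-type barcodes in subregion ", subregion, call. = FALSE)
  sub <- counts[at_pos | wt, , drop = FALSE]

  n_bc <- nrow(sub)
  n_s <- nrow(samples)
  long <- data.frame(
    barcode = rep(sub$barcode, each = n_s),
    variant = rep(sub$variant, each = n_s),
    condition = rep(samples$condition, n_bc),
    replicate = rep(samples$replicate, n_bc),
    sample_id = rep(samples$sample_id, n_bc),
    offset = rep(samples$offset, n_bc),
    stringsAsFactors = FALSE)
  cnt <- as.matrix(sub[, samples$sample_id, drop = FALSE])
  long$count <- as.integer(t(cnt))
  structure(list(long = long, position = position, subregion = subregion,
                 variants = setdiff(unique(sub$variant), "WT"),
                 conditions = unique(samples$condition)),
            class = "position_dataset")
}

#' Down-sample barcodes within a position dataset
#'
#' Uniform sampling without replacement of `n_barcodes` barcodes per
#' variant (wild-type included, same rule), used to study how standard
#' errors shrink with barcode representation.
#'
#' @param data A `position_dataset`.
#' @param n_barcodes Barcodes to retain per variant (at least 2; at most
#'   the number available for every variant).
#' @param seed Integer seed.
#' @return A `position_dataset` with the subset of barcodes.
#' @export
downsample_barcodes <- function(data, n_barcodes, seed = 1L) {
  if (n_barcodes < 2) stop("n_barcodes must be >= 2", call. = FALSE)
  bc_var <- unique(data$long[, c("barcode", "variant")])
  avail <- table(bc_var$variant)
  if (any(avail < n_barcodes))
    stop("n_barcodes exceeds available barcodes for variant(s): ",
         paste(names(avail)[avail < n_barcodes], collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  keep <- unlist(lapply(split(bc_var$barcode, bc_var$variant),
                        function(b) sample(b, n_barcodes)))
  out <- data
  out$long <- data$long[data$long$barcode %in% keep, , drop = FALSE]
  out
}

#' Fit the mixed-effects negative binomial model at one position
#'
#' Maximum likelihood for
#' \deqn{count_{ijkm} \sim NB(\mu_{ij}, \theta), \quad
#'       \log \mu_{ij} = \beta_i^{cond} + \beta_{ij}^{var} + \alpha_k +
#'       \gamma_m, \quad \alpha_k \sim N(0, \sigma^2)}
#' with the barcode random intercepts integrated out by a Laplace
#' approximation (scalar inner Newton per barcode). Wild-type deviations
#' are fixed at 0 by reference coding, so \eqn{\beta_{ij}^{var}} is the
#' variant's natural-log shift from wild-type in condition i. One shared
#' \eqn{\theta} and one shared \eqn{\sigma^2} apply across conditions.
#' Standard errors come from the inverse observed information of the
#' Laplace objective at the optimum.
#'
#' A variant-condition cell whose counts are all zero is flagged
#' non-estimable and its rows are excluded from the likelihood (its ML
#' deviation would diverge). Non-convergence triggers up to
#' `control$restarts` jittered restarts before the fit is flagged.
#'
#' @param data A `position_dataset`.
#' @param control An [nb_control()].
#' @return A `position_fit` list: `beta` (named: condition intercepts,
#'   then `"<variant>|<condition>"` deviations), `cov` (fixed-effect
#'   covariance), `sigma2`, `theta`, `loglik`, `converged`, `estimable`
#'   (variant x condition logical matrix), `conditions`, `variants`,
#'   `position`, `mean_offset`.
#' @export
fit_position_model <- function(data, control = nb_control()) {
  long <- data$long
  if (nrow(long) < 2) stop("need at least 2 observations", call. = FALSE)
  conditions <- data$conditions
  variants <- data$variants

  # estimability: a (variant, condition) deviation needs a nonzero total
  tot <- tapply(long$count, list(long$variant, long$condition), sum)
  estimable <- matrix(FALSE, length(variants), length(conditions),
                      dimnames = list(variants, conditions))
  for (v in variants) for (cc in conditions) {
    t_vc <- tot[v, cc]
    estimable[v, cc] <- !is.na(t_vc) && t_vc > 0
  }
  drop_row <- rep(FALSE, nrow(long))
  for (v in variants) for (cc in conditions) {
    if (!estimable[v, cc])
      drop_row <- drop_row | (long$variant == v & long$condition == cc)
  }
  long <- long[!drop_row, , drop = FALSE]
  long <- long[order(long$barcode, long$sample_id), , drop = FALSE]

  cond_idx <- match(long$condition, conditions)
  dev_names <- as.vector(t(outer(variants, conditions, paste, sep = "|")))
  dev_names <- dev_names[as.vector(t(estimable))]
  dev_key <- paste(long$variant, long$condition, sep = "|")
  dev_idx <- match(dev_key, dev_names)
  dev_idx[long$variant == "WT"] <- NA
  p_cond <- length(conditions)
  p_dev <- length(dev_names)
  dev_col <- ifelse(is.na(dev_idx), 0L, p_cond + dev_idx)

  bc <- factor(long$barcode, levels = unique(long$barcode))
  bc_start <- c(0L, cumsum(as.integer(table(bc))))

  y <- as.numeric(long$count)
  offs <- long$offset
  cond_i <- as.integer(cond_idx)
  dev_i <- as.integer(dev_col)
  bs <- as.integer(bc_start)

  # starting values: offset-weighted log mean ratios
  wexp <- exp(offs)
  b0 <- numeric(p_cond)
  for (i in seq_len(p_cond)) {
    wt_i <- long$variant == "WT" & cond_i == i
    b0[i] <- if (any(wt_i))
      log((sum(y[wt_i]) + 0.5) / sum(wexp[wt_i])) else 0
  }
  d0 <- numeric(p_dev)
  for (d in seq_len(p_dev)) {
    rows <- dev_i == (p_cond + d)
    i <- cond_i[rows][1]
    d0[d] <- log((sum(y[rows]) + 0.5) / sum(wexp[rows])) - b0[i]
  }
  d0 <- pmin(pmax(d0, -10), 10)
  par0 <- c(b0, d0, log(0.3), log(2))

  np <- length(par0)
  lower <- c(rep(-control$beta_bound, p_cond + p_dev),
             control$log_sigma_bounds[1], control$log_theta_bounds[1])
  upper <- c(rep(control$beta_bound, p_cond + p_dev),
             control$log_sigma_bounds[2], control$log_theta_bounds[2])
  fn <- function(par) nbml_nll(par, y, cond_i, dev_i, offs, bs)
  gr <- function(par)
    nbml_nll_grad(par, y, cond_i, dev_i, offs, bs)$grad

  fit_once <- function(p0) {
    tryCatch(optim(p0, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = control$maxit, factr = 1e7)),
             error = function(e) NULL)
  }
  opt <- fit_once(par0)
  attempt <- 0L
  while ((is.null(opt) || opt$convergence != 0) &&
         attempt < control$restarts) {
    attempt <- attempt + 1L
    jit <- par0 + rnorm(np, 0, 0.2)
    jit <- pmin(pmax(jit, lower + 1e-6), upper - 1e-6)
    cand <- fit_once(jit)
    if (!is.null(cand) &&
        (is.null(opt) || cand$value < opt$value || cand$convergence == 0))
      opt <- cand
  }
  converged <- !is.null(opt) && opt$convergence == 0
  if (is.null(opt))
    stop("position model optimisation failed outright", call. = FALSE)

  par_hat <- opt$par
  # observed information: central differences of the analytic gradient
  H <- matrix(0, np, np)
  for (i in seq_len(np)) {
    h <- 1e-5 * (1 + abs(par_hat[i]))
    pp <- par_hat; pp[i] <- par_hat[i] + h
    gp <- nbml_nll_grad(pp, y, cond_i, dev_i, offs, bs)$grad
    pp[i] <- par_hat[i] - h
    gm <- nbml_nll_grad(pp, y, cond_i, dev_i, offs, bs)$grad
    H[i, ] <- (gp - gm) / (2 * h)
  }
  H <- (H + t(H)) / 2
  cov_all <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov_all) || any(!is.finite(diag(cov_all))) ||
      any(diag(cov_all)[seq_len(p_cond + p_dev)] < 0)) {
    # pseudo-inverse fallback for near-singular information
    eg <- eigen(H, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    cov_all <- eg$vectors[, pos, drop = FALSE] %*%
      diag(1 / eg$values[pos], sum(pos)) %*%
      t(eg$vectors[, pos, drop = FALSE])
    converged <- converged && all(diag(cov_all)[seq_len(p_cond + p_dev)] >= 0)
  }
  beta <- par_hat[seq_len(p_cond + p_dev)]
  names(beta) <- c(conditions, dev_names)
  cov_fix <- cov_all[seq_len(p_cond + p_dev), seq_len(p_cond + p_dev),
                     drop = FALSE]
  dimnames(cov_fix) <- list(names(beta), names(beta))

  structure(list(beta = beta, cov = cov_fix,
                 sigma2 = exp(2 * par_hat[np - 1]),
                 theta = exp(par_hat[np]),
                 log_sigma = par_hat[np - 1], log_theta = par_hat[np],
                 loglik = -opt$value, converged = converged,
                 estimable = estimable, conditions = conditions,
                 variants = variants, position = data$position,
                 subregion = data$subregion,
                 mean_offset = mean(long$offset),
                 n_obs = nrow(long),
                 n_barcodes = length(unique(long$barcode))),
            class = "position_fit")
}

#' @export
print.position_fit <- function(x, ...) {
  cat("NB mixed-model fit, position", x$position,
      sprintf("(%d barcodes, %d obs)\n", x$n_barcodes, x$n_obs))
  cat(sprintf("  sigma^2 = %.4g, theta = %.4g, logLik = %.2f, %s\n",
              x$sigma2, x$theta, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Per-variant, per-condition effect table
#'
#' Converts natural-log deviation estimates into log2 fold changes over
#' wild-type with Wald inference: z = estimate / SE, two-sided p against
#' the standard normal, and (optionally) Benjamini-Hochberg q within the
#' chosen scope. Non-estimable cells carry NA estimates, keep their
#' `estimable = FALSE` flag, and are excluded from the BH denominator.
#'
#' @param fit A `position_fit` (or list of them, rbind-ed; q-values are
#'   then computed across all positions, the default pipeline scope).
#' @param bh_scope `"condition"` (BH within each condition across
#'   variants; default), `"global"`, or `"none"`.
#' @return An `effect_table` data.frame: `variant`, `position`,
#'   `condition`, `log2fc`, `se`, `z`, `p`, `q`, `estimable`.
#' @export
effect_table <- function(fit, bh_scope = c("condition", "global", "none")) {
  bh_scope <- match.arg(bh_scope)
  fits <- if (inherits(fit, "position_fit")) list(fit) else fit
  rows <- lapply(fits, function(f) {
    grid <- expand.grid(variant = f$variants, condition = f$conditions,
                        stringsAsFactors = FALSE)
    key <- paste(grid$variant, grid$condition, sep = "|")
    est <- unname(f$beta[key])
    se_nat <- unname(sqrt(diag(f$cov))[key])
    ok <- f$estimable[cbind(grid$variant, grid$condition)] & f$converged &
      !is.na(est) & !is.na(se_nat) & se_nat > 0
    data.frame(variant = grid$variant, position = f$position,
               condition = grid$condition,
               log2fc = ifelse(ok, est / log(2), NA_real_),
               se = ifelse(ok, se_nat / log(2), NA_real_),
               estimable = ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$z <- out$log2fc / out$se
  out$p <- 2 * pnorm(-abs(out$z))
  out$q <- NA_real_
  if (bh_scope == "condition") {
    for (cc in unique(out$condition)) {
      i <- out$condition == cc
      out$q[i] <- bh_adjust(out$p[i])
    }
  } else if (bh_scope == "global") {
    out$q <- bh_adjust(out$p)
  }
  out <- out[, c("variant", "position", "condition", "log2fc", "se",
                 "z", "p", "q", "estimable")]
  class(out) <- unique(c("effect_table", class(out)))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values; NA p-values are excluded from the denominator
#' and returned as NA (their count is available as an attribute).
#'
#' @param p Numeric p-values in \[0, 1\] (NAs allowed).
#' @return q-values of the same length, attribute `n_na`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  attr(q, "n_na") <- sum(!ok)
  q
}

#' Classify variants as LoF / GoF / WT-like
#'
#' @param effects An `effect_table` with q-values.
#' @param fdr FDR threshold (default 0.01).
#' @return The table with a `class` column: `"LoF"` (q < fdr and
#'   log2fc < 0), `"GoF"` (q < fdr and log2fc > 0), `"WT-like"`
#'   otherwise; `"NA"` for non-estimable entries.
#' @export
classify_variants <- function(effects, fdr = 0.01) {
  cls <- rep("WT-like", nrow(effects))
  sig <- !is.na(effects$q) & effects$q < fdr
  cls[sig & effects$log2fc < 0] <- "LoF"
  cls[sig & effects$log2fc > 0] <- "GoF"
  cls[!effects$estimable] <- "NA"
  effects$class <- cls
  effects
}

#' Residue-level sensitivity score
#'
#' For one position and condition: the mean log2 fold change across
#' estimable missense variants divided by the square root of the sum of
#' their squared standard errors, nonsense variants excluded. As any
#' variant's SE grows without bound the denominator dominates and the
#' score tends to 0.
#'
#' @param effects An `effect_table` restricted (or restrictable) to one
#'   condition.
#' @param position Residue position.
#' @param condition Condition label (defaults to the single condition
#'   present).
#' @return Numeric score, or NA if no estimable missense variant exists.
#' @export
residue_sensitivity <- function(effects, position,
                                condition = unique(effects$condition)) {
  if (length(condition) != 1)
    stop("specify a single condition", call. = FALSE)
  i <- effects$position == position & effects$condition == condition &
    effects$estimable & !grepl("\\*$", effects$variant)
  if (!any(i)) return(NA_real_)
  mean(effects$log2fc[i]) / sqrt(sum(effects$se[i]^2))
}
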