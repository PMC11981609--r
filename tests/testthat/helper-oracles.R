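# Independent oracles for the mixed-model likelihood, written against the
# model definition only (base-R dnbinom, Golub-Welsch quadrature); they
# share no code with the package's Laplace path.

# Gauss-Hermite nodes/weights for weight exp(-x^2) via the Jacobi matrix
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  eg <- eigen(J, symmetric = TRUE)
  ord <- order(eg$values)
  list(nodes = eg$values[ord],
       weights = sqrt(pi) * eg$vectors[1, ord]^2)
}

# joint log density of one barcode's counts and random intercept a
joint_ll_barcode <- function(a, y, eta0, sigma, theta) {
  sum(dnbinom(y, size = theta, mu = exp(eta0 + a), log = TRUE)) +
    dnorm(a, 0, sigma, log = TRUE)
}

# adaptive Gauss-Hermite marginal log-likelihood for a position dataset
# laid out long (data.frame with barcode, count, offset, and a linear
# predictor eta_fix computed by the caller from candidate parameters)
agq_loglik <- function(par, long, cond_levels, dev_levels, n_nodes = 64) {
  p_cond <- length(cond_levels)
  beta <- par[seq_len(p_cond + length(dev_levels))]
  sigma <- exp(par[length(par) - 1])
  theta <- exp(par[length(par)])
  eta0 <- beta[match(long$condition, cond_levels)] + long$offset
  key <- paste(long$variant, long$condition, sep = "|")
  di <- match(key, dev_levels)
  has_dev <- long$variant != "WT" & !is.na(di)
  eta0[has_dev] <- eta0[has_dev] + beta[p_cond + di[has_dev]]
  gh <- gauss_hermite(n_nodes)
  total <- 0
  for (b in unique(long$barcode)) {
    i <- long$barcode == b
    yb <- long$count[i]; eb <- eta0[i]
    # mode and curvature found independently via optimize / numeric diff
    g <- function(a) joint_ll_barcode(a, yb, eb, sigma, theta)
    opt <- optimize(g, c(-12, 12), maximum = TRUE, tol = 1e-10)
    m <- opt$maximum
    h <- 1e-4
    d2 <- (g(m + h) - 2 * g(m) + g(m - h)) / h^2
    s_hat <- sqrt(-1 / d2)
    z <- m + sqrt(2) * s_hat * gh$nodes
    lg <- vapply(z, g, numeric(1))
    total <- total + log(sum(gh$weights * exp(lg - opt$objective +
                                                gh$nodes^2))) +
      opt$objective + log(sqrt(2) * s_hat)
  }
  total
}

# full ML fit under the AGQ objective, crude independent starting values
agq_fit <- function(pd, n_nodes = 64) {
  long <- pd$long
  cond_levels <- pd$conditions
  dev_levels <- as.vector(t(outer(pd$variants, cond_levels, paste,
                                  sep = "|")))
  b0 <- vapply(cond_levels, function(cc) {
    i <- long$variant == "WT" & long$condition == cc
    log((sum(long$count[i]) + 0.5) / sum(exp(long$offset[i])))
  }, numeric(1))
  d0 <- vapply(dev_levels, function(k) {
    vc <- strsplit(k, "|", fixed = TRUE)[[1]]
    i <- long$variant == vc[1] & long$condition == vc[2]
    log((sum(long$count[i]) + 0.5) / sum(exp(long$offset[i]))) -
      b0[vc[2]]
  }, numeric(1))
  par0 <- c(b0, d0, log(0.3), log(2))
  nll <- function(par) -agq_loglik(par, long, cond_levels, dev_levels,
                                   n_nodes)
  opt <- optim(par0, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  np <- length(opt$par)
  list(beta = setNames(opt$par[seq_len(np - 2)],
                       c(cond_levels, dev_levels)),
       log_sigma = opt$par[np - 1], log_theta = opt$par[np],
       loglik = -opt$value, convergence = opt$convergence)
}

# fixed-effect NB GLM oracle (MASS::glm.nb) on the same design coding
glm_nb_oracle <- function(pd) {
  long <- pd$long
  cond <- factor(long$condition, levels = pd$conditions)
  key <- paste(long$variant, long$condition, sep = "|")
  dev_levels <- sort(unique(key[long$variant != "WT"]))
  X <- matrix(0, nrow(long), length(pd$conditions) + length(dev_levels))
  X[cbind(seq_len(nrow(long)), as.integer(cond))] <- 1
  di <- match(key, dev_levels)
  nz <- long$variant != "WT"
  X[cbind(which(nz), length(pd$conditions) + di[nz])] <- 1
  colnames(X) <- c(pd$conditions, dev_levels)
  off <- long$offset
  fit <- MASS::glm.nb(long$count ~ X - 1 + offset(off))
  setNames(coef(fit), colnames(X))
}
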