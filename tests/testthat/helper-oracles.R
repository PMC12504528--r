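# Independent oracles used to pin the mixed-model implementations.
# Everything here is dense-matrix / quadrature brute force and shares no code
# path with the package's lme4-based fits.

# --- REML oracle for the crossed random-intercept Gaussian model ----------
# -2 * restricted log-likelihood, up to an additive constant, computed from
# the dense marginal covariance V = s2*I + tu*Zu Zu' + ti*Zi Zi', with the
# GLS profile for beta.
oracle_reml_crit <- function(par, y, X, Zu, Zi) {
  tu <- exp(par[1]); ti <- exp(par[2]); s2 <- exp(par[3])
  n <- length(y)
  V <- s2 * diag(n) + tu * tcrossprod(Zu) + ti * tcrossprod(Zi)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
               t(r) %*% Vi %*% r)
}

oracle_gls_beta <- function(par, y, X, Zu, Zi) {
  tu <- exp(par[1]); ti <- exp(par[2]); s2 <- exp(par[3])
  V <- s2 * diag(length(y)) + tu * tcrossprod(Zu) + ti * tcrossprod(Zi)
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# Coarse grid over the variance components followed by a Nelder-Mead polish
# from the best grid point.
oracle_reml_fit <- function(y, X, Zu, Zi) {
  grid <- expand.grid(ltu = log(c(1e-4, 1e-2, 0.1, 1)),
                      lti = log(c(1e-4, 1e-2, 0.1, 1)),
                      ls2 = log(c(0.01, 0.1, 1, 10)))
  vals <- vapply(seq_len(nrow(grid)), function(g) {
    oracle_reml_crit(as.numeric(grid[g, ]), y = y, X = X, Zu = Zu, Zi = Zi)
  }, 0)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, oracle_reml_crit, y = y, X = X, Zu = Zu, Zi = Zi,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  list(par = opt$par, crit = opt$value,
       beta = oracle_gls_beta(opt$par, y, X, Zu, Zi))
}

# --- Exact marginal likelihood for the crossed binomial GLMM --------------
# Gauss-Hermite quadrature over all item effects jointly (tensor grid) and,
# per item-effect combination, over each subject effect. Exponentially sized
# in the number of items, so only for tiny fixtures.
gauss_hermite <- function(n) {
  # Golub-Welsch from the Jacobi matrix of the (physicists') Hermite weight.
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- sqrt(k / 2)
  J[cbind(k + 1, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# d: data frame with columns y (0/1), eta0 (fixed-effect linear predictor),
# subj (1..S), item (1..I). sd_u, sd_w: random-effect SDs.
oracle_glmm_loglik <- function(d, sd_u, sd_w, n_nodes = 15) {
  gh <- gauss_hermite(n_nodes)
  t_std <- sqrt(2) * gh$nodes          # N(0,1) abscissae
  wt <- gh$weights / sqrt(pi)          # N(0,1) weights
  S <- max(d$subj)
  I <- max(d$item)
  widx <- as.matrix(expand.grid(rep(list(seq_along(t_std)), I))) # G x I
  G <- nrow(widx)
  wgrid <- matrix(sd_w * t_std[widx], G, I)
  log_f <- matrix(0, G, S)
  for (s in seq_len(S)) {
    rows <- which(d$subj == s)
    inner <- matrix(0, G, length(t_std)) # P(obs of subject s | u_k, w combo)
    for (k in seq_along(t_std)) {
      prodl <- rep(1, G)
      for (r in rows) {
        eta <- d$eta0[r] + sd_u * t_std[k] + wgrid[, d$item[r]]
        p <- stats::plogis(eta)
        prodl <- prodl * (if (d$y[r] == 1) p else 1 - p)
      }
      inner[, k] <- prodl
    }
    log_f[, s] <- log(inner %*% wt)
  }
  log_wprior <- rowSums(matrix(log(wt)[widx], G, I))
  # log sum over the item-effect grid
  tot <- log_wprior + rowSums(log_f)
  m <- max(tot)
  m + log(sum(exp(tot - m)))
}
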