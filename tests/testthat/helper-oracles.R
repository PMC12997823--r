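# Independent brute-force oracles used to check the implementation paths.

# Shannon diversity of class proportions, direct evaluation.
oracle_shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Focal Shannon by a literal double loop over cells and window offsets.
oracle_shannon_focal <- function(landcover, radius) {
  v <- landcover$values
  cs <- landcover$cell_size
  r <- ceiling(radius / cs)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      if (sqrt(di^2 + dj^2) * cs > radius) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nrow(v) || jj < 1 || jj > ncol(v)) next
      if (!is.na(v[ii, jj])) vals <- c(vals, v[ii, jj])
    }
    if (length(vals) > 0)
      out[i, j] <- oracle_shannon(table(vals) / length(vals))
  }
  out
}

# Nearest-river-cell distance by exhaustive scan.
oracle_distance <- function(rivers) {
  v <- rivers$values
  riv <- which(!is.na(v) & v == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
    out[i, j] <- sqrt(min((riv[, 1] - i)^2 + (riv[, 2] - j)^2)) *
      rivers$cell_size
  out
}

# Convex hull via the O(n^3) halfplane definition: a point is a hull vertex
# iff it is not strictly inside any triangle of three other points; here we
# check hull membership by testing, for every pair, whether all points lie
# on one side of the line through the pair (then both are hull vertices).
oracle_hull_vertices <- function(x, y) {
  n <- length(x)
  on_hull <- rep(FALSE, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    cr <- (x[b] - x[a]) * (y - y[a]) - (y[b] - y[a]) * (x - x[a])
    if (all(cr <= 1e-9) || all(cr >= -1e-9)) {
      on_hull[a] <- TRUE; on_hull[b] <- TRUE
    }
  }
  which(on_hull)
}

# Single-factor binomial GLMM marginal log-likelihood via 25-node adaptive
# Gauss-Hermite quadrature, maximised with optim. Independent of lme4.
oracle_agq_loglik <- function(beta, log_sigma, y, X, g, nodes = 25) {
  if (!all(is.finite(c(beta, log_sigma))) || abs(log_sigma) > 10)
    return(-1e10)
  gh <- statmod_gauss_hermite(nodes)
  sigma <- exp(log_sigma)
  eta0 <- as.vector(X %*% beta)
  ll <- 0
  for (lev in levels(g)) {
    rows <- which(g == lev)
    f <- function(u) {
      # log joint density of (y_group, u)
      eta <- eta0[rows] + u
      val <- sum(stats::dbinom(y[rows], 1, stats::plogis(eta), log = TRUE)) +
        stats::dnorm(u, 0, sigma, log = TRUE)
      if (is.finite(val)) val else -1e10
    }
    # adaptive: centre at the conditional mode, scale by the curvature
    opt <- stats::optimize(function(u) -f(u), c(-15, 15), tol = 1e-9)
    mu <- opt$minimum
    if (!is.finite(opt$objective)) return(-1e10)
    h <- 1e-4
    curv <- -(f(mu + h) - 2 * f(mu) + f(mu - h)) / h^2
    s <- 1 / sqrt(max(curv, 1e-8))
    lw <- vapply(seq_len(nodes), function(k) {
      u <- mu + sqrt(2) * s * gh$nodes[k]
      log(gh$weights[k]) + f(u) + gh$nodes[k]^2 + log(sqrt(2) * s)
    }, 0)
    m <- max(lw)
    ll <- ll + m + log(sum(exp(lw - m)))
  }
  if (!is.finite(ll)) return(-1e10)
  ll
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix).
statmod_gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values,
       weights = sqrt(pi) * e$vectors[1, ]^2)
}

oracle_agq_fit <- function(y, X, g, nodes = 25) {
  p <- ncol(X)
  start <- c(stats::coef(stats::glm.fit(X, y, family = stats::binomial())), 0)
  opt <- stats::optim(start, function(par)
    -oracle_agq_loglik(par[seq_len(p)], par[p + 1], y, X, g, nodes),
    method = "BFGS", control = list(maxit = 500, reltol = 1e-10))
  list(beta = opt$par[seq_len(p)], sigma = exp(opt$par[p + 1]),
       logLik = -opt$value)
}
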