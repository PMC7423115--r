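# Shared fixtures and independent oracles for the test suite.

# Link coefficients reproducing the identity H(y) = y - knots[1] exactly
# (a monotone linear function lies in the span of order-3 I-splines with
# non-negative coefficients).
identity_link <- function(knots = c(0, 20, 100)) {
  lk <- link_spline(knots)
  grid <- seq(knots[1], knots[length(knots)], length.out = 200)
  B <- ispline_basis(grid, lk)
  cc <- qr.solve(B, grid - knots[1])
  stopifnot(max(abs(B %*% cc - (grid - knots[1]))) < 1e-8, all(cc > -1e-8))
  lk$w <- sqrt(pmax(cc, 0))
  lk
}

# Dense multivariate-normal log-density via Cholesky; independent of the
# package's Woodbury closed form.
dmvnorm_log <- function(x, mu, S) {
  L <- chol(S)
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z * z)
}

# Brute-force mixture log-likelihood on the transformed scale: h and
# hprime give the link and its derivative as plain functions.
oracle_loglik <- function(series, tbasis, pi_g, beta, sigma,
                          h = function(y) y, hprime = function(y) rep(1, length(y))) {
  ids <- unique(series$subject_id)
  G <- length(pi_g)
  total <- 0
  for (id in ids) {
    d <- series[series$subject_id == id, ]
    X <- ncs_design(d$t, tbasis)
    hy <- h(d$value)
    n <- nrow(d)
    lse <- vapply(seq_len(G), function(g) {
      S <- sigma[g]^2 * matrix(1, n, n) + diag(n)
      log(pi_g[g]) + dmvnorm_log(hy, drop(X %*% beta[, g]), S)
    }, numeric(1))
    m <- max(lse)
    total <- total + m + log(sum(exp(lse - m))) + sum(log(hprime(d$value)))
  }
  total
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) for (k in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# modal classification accuracy after optimal label matching
match_accuracy <- function(modal, labels, G) {
  max(vapply(perms(G), function(p) mean(p[modal] == labels), numeric(1)))
}

# small long-format series fixture: two flat latent groups (8 vs 22),
# windows 25-45 years, unit measurement noise, truncation at zero
tiny_series <- function(n = 10, seed = 5) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    lev <- if (i %% 2) 8 else 22
    tt <- seq(sample(25:45, 1), 0)
    data.frame(subject_id = sprintf("T%03d", i), t = tt,
               value = pmax(0, lev + rnorm(1, 0, 2) + rnorm(length(tt))))
  }))
}
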