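# Small fixtures only: heavier simulation properties live in the
# acceptance suite.

make_spec <- function(G, n_starts = 6, seed = 1, link = identity_link(),
                      control = lcmm_control()) {
  lcmm_spec(G, link, time_basis(boundary_knots = c(0, 50)),
            n_starts = n_starts, seed = seed, control = control)
}

test_that("mixture log-likelihood matches the dense-matrix oracle", {
  ser <- tiny_series(n = 8, seed = 11)
  lk <- identity_link()
  sp <- make_spec(2, link = lk)
  tb <- time_basis(c(12, 24, 36), boundary_knots = c(0, 50))
  beta <- cbind(c(8, 0.5, -0.3, 0.2, 0), c(22, -0.4, 0.1, 0, 0.3))
  params <- list(xi = 0.4, beta = beta, sigma = c(1.5, 2.5), w = lk$w)
  pi_g <- exp(c(0.4, 0)) / sum(exp(c(0.4, 0)))
  ll <- lcmm_loglik(params, ser, sp)
  ll_oracle <- oracle_loglik(ser, tb, pi_g, beta, c(1.5, 2.5))
  expect_equal(ll, ll_oracle, tolerance = 1e-10)
})

test_that("duplicating subjects doubles the log-likelihood", {
  ser <- tiny_series(n = 6, seed = 3)
  sp <- make_spec(2)
  params <- list(xi = 0, beta = cbind(c(8, 0, 0, 0, 0), c(22, 0, 0, 0, 0)),
                 sigma = c(2, 2), w = sp$link$w)
  ll1 <- lcmm_loglik(params, ser, sp)
  s2 <- ser
  s2$subject_id <- paste0(s2$subject_id, "_copy")
  ll2 <- lcmm_loglik(params, rbind(ser, s2), sp)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-12)
})

test_that("log-likelihood is invariant to a consistent class relabelling", {
  ser <- tiny_series(n = 6, seed = 3)
  sp <- make_spec(2)
  beta <- cbind(c(8, 0, 0, 0, 0), c(22, 0, 0, 0, 0))
  p1 <- list(xi = 0.7, beta = beta, sigma = c(1, 3), w = sp$link$w)
  # swap classes: pi' = (pi2, pi1) => xi' = -xi
  p2 <- list(xi = -0.7, beta = beta[, 2:1], sigma = c(3, 1), w = sp$link$w)
  expect_equal(lcmm_loglik(p1, ser, sp),
               lcmm_loglik(p2, ser, sp), tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  ser <- tiny_series(n = 10, seed = 9)
  sp <- make_spec(2)
  prep <- expotraj:::.lcmm_prep(ser, sp)
  set.seed(21)
  th <- c(0.3, 8, rnorm(4, 0, 0.4), 22, rnorm(4, 0, 0.4), 1.2, 0.9,
          sqrt(c(0.2, 0.1, 0.06, 0.03)))
  o <- expotraj:::.lcmm_obj(th, prep, 2L)
  g_num <- vapply(seq_along(th), function(j) {
    e <- 1e-6; tp <- th; tm <- th
    tp[j] <- tp[j] + e; tm[j] <- tm[j] - e
    (expotraj:::.lcmm_obj(tp, prep, 2L, FALSE)$value -
       expotraj:::.lcmm_obj(tm, prep, 2L, FALSE)$value) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(o$grad - g_num)) / max(1, max(abs(g_num))), 1e-6)
})

test_that("posterior probabilities: G=1, symmetry, and log-space accuracy", {
  ser <- tiny_series(n = 6, seed = 13)
  sp1 <- make_spec(1)
  p1 <- list(xi = numeric(0), beta = cbind(c(10, 0, 0, 0, 0)), sigma = 1,
             w = sp1$link$w)
  post1 <- posterior_probs(p1, ser, sp1)
  expect_equal(drop(post1), rep(1, 6), ignore_attr = TRUE)

  # one subject equidistant from two symmetric class means
  sym <- data.frame(subject_id = "s", t = c(10, 5, 0), value = 15)
  sp2 <- make_spec(2)
  p2 <- list(xi = 0, beta = cbind(c(10, 0, 0, 0, 0), c(20, 0, 0, 0, 0)),
             sigma = c(1, 1), w = sp2$link$w)
  expect_equal(drop(posterior_probs(p2, sym, sp2)), c(0.5, 0.5),
               ignore_attr = TRUE, tolerance = 1e-12)

  # naive direct computation agrees with the log-sum-exp path
  ser2 <- tiny_series(n = 5, seed = 17)
  beta <- cbind(c(8, 0.3, 0, 0, 0), c(22, 0, -0.2, 0, 0))
  p3 <- list(xi = 0.5, beta = beta, sigma = c(1.5, 2), w = sp2$link$w)
  post <- posterior_probs(p3, ser2, sp2)
  tb <- time_basis(c(12, 24, 36), boundary_knots = c(0, 50))
  pi_g <- exp(c(0.5, 0)) / sum(exp(c(0.5, 0)))
  for (i in seq_len(5)) {
    id <- unique(ser2$subject_id)[i]
    d <- ser2[ser2$subject_id == id, ]
    X <- ncs_design(d$t, tb)
    f <- vapply(1:2, function(g) {
      S <- p3$sigma[g]^2 * matrix(1, nrow(d), nrow(d)) + diag(nrow(d))
      pi_g[g] * exp(dmvnorm_log(d$value, drop(X %*% beta[, g]), S))
    }, numeric(1))
    expect_equal(unname(post[i, ]), f / sum(f), tolerance = 1e-10)
  }
})

test_that("with sigma = 0 and G = 1 the ML profile is penalised least squares", {
  ser <- tiny_series(n = 8, seed = 23)
  sp <- make_spec(1)
  prep <- expotraj:::.lcmm_prep(ser, sp)
  X <- prep$X
  b_ols <- qr.solve(X, ser$value)
  params <- list(xi = numeric(0), beta = cbind(b_ols), sigma = 0, w = sp$link$w)
  ll <- lcmm_loglik(params, ser, sp)
  rss <- sum((ser$value - X %*% b_ols)^2)
  expect_equal(ll, -0.5 * (nrow(ser) * log(2 * pi) + rss),
               tolerance = 1e-8)
})

test_that("scale change of data and knots shifts loglik by the exact Jacobian", {
  ser <- tiny_series(n = 6, seed = 29)
  cfac <- 2.5
  sp_y <- make_spec(2, link = link_spline(c(0, 20, 100), w = c(1, .5, .4, .3)))
  sp_z <- make_spec(2, link = link_spline(cfac * c(0, 20, 100),
                                          w = c(1, .5, .4, .3)))
  params <- list(xi = 0.2, beta = cbind(c(8, 0, 0, 0, 0), c(22, 0, 0, 0, 0)),
                 sigma = c(1, 2), w = c(1, .5, .4, .3))
  sz <- ser
  sz$value <- sz$value * cfac
  ll_y <- lcmm_loglik(params, ser, sp_y)
  ll_z <- lcmm_loglik(params, sz, sp_z)
  expect_equal(ll_z, ll_y - nrow(sz) * log(cfac), tolerance = 1e-8)
})

test_that("one-class fit recovers the generating trajectory and variance", {
  tb <- time_basis(boundary_knots = c(0, 50))
  # linear latent trend: 18 - 0.15 t, representable in the natural spline
  tt <- 0:50
  X <- ncs_design(tt, tb)
  beta_lin <- qr.solve(X, 18 - 0.15 * tt)
  truth <- synthetic_truth(pi = 1, beta = cbind(beta_lin), sigma = 2,
                           window = data.frame(first_min = 30, first_max = 50,
                                               cess_min = 0, cess_max = 0),
                           theta = 0, tbasis = tb)
  dat <- generate_trajectories(truth, 300, seed = 31)
  fit <- lcmm_fit(dat$series, make_spec(1, seed = 7))
  expect_true(fit$converged)
  tgrid <- seq(2, 40, 2)
  pred <- predict_trajectory(fit, 1, tgrid, scale = "natural")
  expect_lt(max(abs(pred - (18 - 0.15 * tgrid))), 0.6)
  expect_lt(abs(fit$params$sigma - 2), 0.35)
})

test_that("multi-start fit is deterministic given the seed and stable across seeds", {
  ser <- tiny_series(n = 120, seed = 37)
  f1 <- lcmm_fit(ser, make_spec(2, n_starts = 6, seed = 5))
  f2 <- lcmm_fit(ser, make_spec(2, n_starts = 6, seed = 5))
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params$beta, f2$params$beta)
  f3 <- lcmm_fit(ser, make_spec(2, n_starts = 6, seed = 6))
  expect_lt(abs(f1$loglik - f3$loglik), 1e-4)
})

test_that("best log-likelihood is non-decreasing in the number of classes", {
  ser <- generate_trajectories(preset_three_class(), 100, seed = 41)$series
  lls <- vapply(1:3, function(G)
    lcmm_fit(ser, make_spec(G, n_starts = 6, seed = G))$loglik,
    numeric(1))
  expect_true(all(diff(lls) > -1e-6))
  # posterior rows sum to one; information criteria tie out
  fit <- lcmm_fit(ser, make_spec(2, n_starts = 6, seed = 2))
  expect_lt(max(abs(rowSums(fit$posterior) - 1)), 1e-10)
  expect_equal(fit$BIC, -2 * fit$loglik + fit$n_params * log(fit$n_subjects))
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$n_params)
})

test_that("natural-scale predictions are bounded and quadrature-stable", {
  ser <- tiny_series(n = 100, seed = 43)
  fit <- lcmm_fit(ser, make_spec(2, n_starts = 6, seed = 3))
  tgrid <- seq(0, 45, 5)
  for (g in 1:2) {
    nat <- predict_trajectory(fit, g, tgrid, scale = "natural")
    expect_true(all(nat >= 0 - 1e-9 & nat <= 100 + 1e-9))
    nat60 <- predict_trajectory(fit, g, tgrid, scale = "natural", gh_nodes = 60)
    expect_lt(max(abs(nat - nat60)), 1e-4)
  }
  # an effectively-identity link keeps natural close to latent
  lat <- predict_trajectory(fit, 2, tgrid, scale = "latent")
  nat <- predict_trajectory(fit, 2, tgrid, scale = "natural")
  expect_lt(max(abs(lat - nat)), 1.0)
})
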