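#' Latent class mixed model specification
#'
#' Describes the LCMM for annual exposure-intensity trajectories: a
#' multinomial class-membership sub-model with class-specific intercepts
#' only, and per-class latent-process trajectories over natural cubic
#' splines of years-before-index, with a class-specific random intercept.
#' Observed intensities enter through a monotone I-spline link whose
#' Jacobian is part of the likelihood. For identifiability the link
#' intercept is fixed at 0 and the measurement-error SD at 1; the latent
#' process carries free location and scale per class.
#'
#' @param n_classes number of latent classes G (>= 1).
#' @param link a [link_spline()] giving the knots of the monotone
#'   transformation of intensity.
#' @param tbasis a [time_basis()] for the backward time axis.
#' @param n_starts size of the multi-start grid for G > 1 (default 50).
#' @param seed integer seed making the multi-start grid reproducible.
#' @param control a [lcmm_control()] list.
#' @return object of class `"lcmm_spec"`.
#' @export
lcmm_spec <- function(n_classes, link, tbasis = time_basis(),
                      n_starts = 50, seed = NULL, control = lcmm_control()) {
  stopifnot(n_classes >= 1, inherits(link, "link_spline"),
            inherits(tbasis, "time_basis"), n_starts >= 1)
  structure(list(n_classes = as.integer(n_classes), link = link,
                 tbasis = tbasis, n_starts = as.integer(n_starts),
                 seed = seed, control = control),
            class = "lcmm_spec")
}

#' Optimisation and convergence settings for [lcmm_fit()]
#'
#' @param burn_iter BFGS iterations spent on each multi-start candidate
#'   before the best one is refined to convergence.
#' @param max_iter BFGS iteration cap for each refinement pass.
#' @param tol_param convergence: max absolute parameter change between the
#'   two refinement passes.
#' @param tol_loglik convergence: log-likelihood change between passes.
#' @param tol_grad convergence: mean squared gradient at the optimum.
#' @param min_class_size a start whose posterior mass in any class falls
#'   below this many subjects is discarded (guards against degenerate
#'   single-subject classes).
#' @param gh_nodes Gauss-Hermite nodes for natural-scale predictions.
#' @export
lcmm_control <- function(burn_iter = 15, max_iter = 500, tol_param = 1e-4,
                         tol_loglik = 1e-8, tol_grad = 1e-4,
                         min_class_size = 5, gh_nodes = 30) {
  list(burn_iter = burn_iter, max_iter = max_iter, tol_param = tol_param,
       tol_loglik = tol_loglik, tol_grad = tol_grad,
       min_class_size = min_class_size, gh_nodes = gh_nodes)
}

# Precompute everything the likelihood needs: spline bases at the observed
# intensities, the time design matrix, and the subject index.
.lcmm_prep <- function(series, spec) {
  stopifnot(is.data.frame(series),
            all(c("subject_id", "t", "value") %in% names(series)))
  if (any(series$value < 0)) stop("negative annual intensities")
  if (any(series$t < 0)) stop("negative times before index")
  id <- factor(series$subject_id, levels = unique(series$subject_id))
  tb <- spec$tbasis
  if (is.null(tb$boundary_knots)) tb$boundary_knots <- range(series$t)
  X <- ncs_design(series$t, tb)
  list(y = series$value, t = series$t, idx = as.integer(id),
       ids = levels(id), ni = tabulate(as.integer(id)),
       N = nlevels(id), n_obs = nrow(series),
       X = X, p = ncol(X),
       B = ispline_basis(series$value, spec$link),
       M = mspline_basis(series$value, spec$link),
       K = spec$link$n_basis, tbasis = tb)
}

# theta = c(xi_{1..G-1}, vec(beta p x G), s_{1..G}, w_{1..K});
# sigma_g = |s_g|, link coefficients enter squared.
.lcmm_unpack <- function(theta, G, p, K) {
  i <- 0L
  xi <- if (G > 1) theta[seq_len(G - 1L)] else numeric(0); i <- G - 1L
  beta <- matrix(theta[i + seq_len(p * G)], p, G); i <- i + p * G
  s <- theta[i + seq_len(G)]; i <- i + G
  w <- theta[i + seq_len(K)]
  list(xi = xi, beta = beta, s = s, w = w)
}

.lcmm_npar <- function(G, p, K) (G - 1L) + p * G + G + K

# Joint log-likelihood and analytic gradient. The random-intercept
# covariance sigma_g^2 11' + I is handled in closed form (Woodbury), the
# class mixture by log-sum-exp; each observation contributes log H'(y)
# once, independent of class.
.lcmm_obj <- function(theta, prep, G, want_grad = TRUE) {
  if (any(!is.finite(theta))) return(list(value = -Inf))
  par <- .lcmm_unpack(theta, G, prep$p, prep$K)
  w2 <- par$w^2
  hp <- drop(prep$M %*% w2)
  if (any(hp <= 0)) return(list(value = -Inf))
  h <- drop(prep$B %*% w2)
  logjac_i <- rowsum(log(hp), prep$idx)
  eta <- c(par$xi, 0)
  logpi <- eta - log(sum(exp(eta - max(eta)))) - max(eta)
  pi_g <- exp(logpi)
  sig2 <- par$s^2
  Mu <- prep$X %*% par$beta              # n_obs x G
  R <- h - Mu                            # residuals per class
  S1 <- rowsum(R, prep$idx)              # N x G
  S2 <- rowsum(R^2, prep$idx)
  denom <- 1 + outer(prep$ni, sig2)      # 1 + n_i sigma_g^2
  quad <- S2 - sweep(S1^2 / denom, 2, sig2, `*`)
  logf <- -0.5 * (prep$ni * log(2 * pi) + log(denom) + quad) +
    as.vector(logjac_i)
  a <- sweep(logf, 2, logpi, `+`)
  amax <- a[cbind(seq_len(prep$N), max.col(a, ties.method = "first"))]
  li <- amax + log(rowSums(exp(a - amax)))
  value <- sum(li)
  if (!is.finite(value)) return(list(value = -Inf))
  post <- exp(a - li)
  if (!want_grad) return(list(value = value, post = post, logpi = logpi))

  grad_xi <- if (G > 1) colSums(post)[seq_len(G - 1L)] -
    prep$N * pi_g[seq_len(G - 1L)] else numeric(0)
  grad_beta <- matrix(0, prep$p, G)
  grad_s <- numeric(G)
  v_obs <- numeric(prep$n_obs)           # sum_g post * V^-1 r, obs level
  for (g in seq_len(G)) {
    cg <- sig2[g] * S1[, g] / denom[, g]
    vr <- R[, g] - cg[prep$idx]          # (V_g^-1 r)_j
    pw <- post[prep$idx, g]
    grad_beta[, g] <- crossprod(prep$X, pw * vr)
    grad_s[g] <- 2 * par$s[g] *
      sum(post[, g] * (-0.5) * (prep$ni / denom[, g] - (S1[, g] / denom[, g])^2))
    v_obs <- v_obs + pw * vr
  }
  grad_w2 <- drop(crossprod(prep$B, -v_obs)) + colSums(prep$M / hp)
  grad_w <- 2 * par$w * grad_w2
  list(value = value, post = post, logpi = logpi,
       grad = c(grad_xi, as.vector(grad_beta), grad_s, grad_w))
}

#' Log-likelihood of an LCMM at given parameters
#'
#' Exposes the observed-data log-likelihood
#' \deqn{\sum_i \log \sum_g \pi_g \, \phi(H(Y_i); X_i\beta_g, \sigma_g^2
#'   11' + I)\, \prod_j H'(y_{ij})}
#' for testing and external optimisation.
#'
#' @param params list with components `xi` (length G-1), `beta` (p x G
#'   matrix), `sigma` (length G, >= 0), `w` (link coefficients).
#' @param series long data.frame (`subject_id`, `t`, `value`).
#' @param spec an [lcmm_spec()].
#' @return scalar log-likelihood (`-Inf` for inadmissible parameters).
#' @export
lcmm_loglik <- function(params, series, spec) {
  prep <- .lcmm_prep(series, spec)
  G <- spec$n_classes
  theta <- c(params$xi, as.vector(params$beta), params$sigma, params$w)
  stopifnot(length(theta) == .lcmm_npar(G, prep$p, prep$K))
  .lcmm_obj(theta, prep, G, want_grad = FALSE)$value
}

#' Posterior class-membership probabilities
#'
#' Bayes posterior \eqn{p_{ig} = \pi_g f_g(Y_i) / \sum_l \pi_l f_l(Y_i)},
#' computed with log-sum-exp stabilisation. Every row sums to 1.
#'
#' @inheritParams lcmm_loglik
#' @return N x G matrix with subject ids as row names.
#' @export
posterior_probs <- function(params, series, spec) {
  prep <- .lcmm_prep(series, spec)
  theta <- c(params$xi, as.vector(params$beta), params$sigma, params$w)
  o <- .lcmm_obj(theta, prep, spec$n_classes, want_grad = FALSE)
  if (!is.finite(o$value)) stop("parameters give a -Inf likelihood")
  post <- o$post
  dimnames(post) <- list(prep$ids, paste0("class", seq_len(spec$n_classes)))
  post
}

.lcmm_optim <- function(theta0, prep, G, maxit) {
  fn <- function(th) {
    v <- .lcmm_obj(th, prep, G, want_grad = FALSE)$value
    if (is.finite(v)) -v else 1e12
  }
  gr <- function(th) {
    o <- .lcmm_obj(th, prep, G, want_grad = TRUE)
    if (is.finite(o$value)) -o$grad else numeric(length(th))
  }
  stats::optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-14))
}

# Initial link coefficients: least-squares projection of the standardised
# identity (y - L)/sd(y) onto the I-spline basis, floored at a small
# positive value so every basis function keeps a positive weight.
.lcmm_init_w <- function(prep, spec) {
  kn <- spec$link$knots
  grid <- seq(kn[1], kn[length(kn)], length.out = 101)
  Bg <- ispline_basis(grid, spec$link)
  s <- stats::sd(prep$y)
  if (s == 0) s <- 1
  target <- (grid - kn[1]) / s
  c0 <- stats::lm.fit(Bg, target)$coefficients
  c0[!is.finite(c0)] <- 0
  sqrt(pmax(c0, 0.05 / s))
}

.lcmm_fit_g1 <- function(prep, spec) {
  w0 <- .lcmm_init_w(prep, spec)
  h0 <- drop(prep$B %*% (w0^2))
  beta0 <- stats::lm.fit(prep$X, h0)$coefficients
  beta0[!is.finite(beta0)] <- 0
  res <- h0 - drop(prep$X %*% beta0)
  s0 <- max(0.2, stats::sd(rowsum(res, prep$idx) / prep$ni))
  theta0 <- c(as.vector(beta0), s0, w0)
  op <- .lcmm_optim(theta0, prep, 1L, 400)
  op$par
}

#' Fit a latent class mixed model by multi-start maximum likelihood
#'
#' Maximises the mixture likelihood over class-membership intercepts,
#' per-class trajectory coefficients, class-specific random-intercept SDs
#' and the monotone link coefficients. The one-class model is fitted first
#' from a deterministic start; for G > 1 a grid of `n_starts` perturbed
#' starting points (trajectory coefficients jittered around the one-class
#' solution, membership intercepts drawn standard normal) is each run for a
#' few iterations and the best candidate refined to full convergence, which
#' guards against local maxima. Convergence reports three criteria:
#' parameter stability, log-likelihood stability and the squared gradient.
#'
#' @param series long data.frame (`subject_id`, `t`, `value`) of annual
#'   intensities, e.g. from [build_series()] or [generate_trajectories()].
#' @param spec an [lcmm_spec()].
#' @param init optional fitted `params` list from a (G-1)-class model of
#'   the same data; each of its classes is split in two to form additional
#'   deterministic starting points (hierarchical grid, as in ladder
#'   fitting).
#' @return object of class `"lcmm_fit"`: maximum-likelihood `params`
#'   (with `pi`, the class proportions), `loglik`, `AIC`, `BIC`,
#'   `posterior`, `modal_class`, convergence diagnostics and the spec.
#' @export
lcmm_fit <- function(series, spec, init = NULL) {
  stopifnot(inherits(spec, "lcmm_spec"))
  prep <- .lcmm_prep(series, spec)
  spec$tbasis <- prep$tbasis
  G <- spec$n_classes
  ctrl <- spec$control
  if (!is.null(spec$seed)) set.seed(spec$seed)

  theta1 <- .lcmm_fit_g1(prep, spec)
  par1 <- .lcmm_unpack(theta1, 1L, prep$p, prep$K)
  if (G == 1L) {
    cand <- list(theta1)
  } else {
    tau <- sqrt(par1$s^2 + 1)
    # subject-level means on the transformed scale seed the class
    # intercepts: half the grid samples them directly (mixture-style
    # initialisation), half jitters the one-class solution
    h1 <- drop(prep$B %*% (par1$w^2))
    subj_mean <- drop(rowsum(h1, prep$idx)) / prep$ni
    cand <- lapply(seq_len(spec$n_starts), function(r) {
      beta <- matrix(par1$beta, prep$p, G)
      if (r %% 2 == 0 && prep$N >= G) {
        qs <- stats::quantile(subj_mean, (seq_len(G) - 0.5) / G, names = FALSE)
        beta[1, ] <- qs + stats::rnorm(G, 0, 0.5 * tau)
      } else {
        beta[1, ] <- beta[1, ] + stats::rnorm(G, 0, 1.5 * tau)
      }
      if (prep$p > 1)
        beta[-1, ] <- beta[-1, ] +
          stats::rnorm((prep$p - 1) * G, 0, 0.5 * abs(beta[-1, ]) + 0.2)
      c(stats::rnorm(G - 1), as.vector(beta),
        abs(par1$s) * exp(stats::rnorm(G, 0, 0.3)), par1$w)
    })
    # hierarchical starts: split each class of a supplied (G-1)-class
    # solution into a +/- 0.5 SD pair of intercepts
    if (!is.null(init) && length(init$pi) == G - 1L) {
      for (g0 in seq_len(G - 1L)) {
        beta <- cbind(init$beta, init$beta[, g0])
        beta[1, g0] <- beta[1, g0] - 0.5 * tau
        beta[1, G] <- beta[1, G] + 0.5 * tau
        pi_new <- c(init$pi, init$pi[g0] / 2)
        pi_new[g0] <- pi_new[g0] / 2
        cand[[length(cand) + 1L]] <-
          c((log(pi_new) - log(pi_new[G]))[seq_len(G - 1L)], as.vector(beta),
            c(init$sigma, init$sigma[g0]), init$w)
      }
    }
    burned <- lapply(cand, function(th) .lcmm_optim(th, prep, G, ctrl$burn_iter))
    cand <- lapply(burned[order(vapply(burned, `[[`, numeric(1), "value"))],
                   `[[`, "par")
  }

  best <- NULL
  for (th in cand) {
    op1 <- .lcmm_optim(th, prep, G, ctrl$max_iter)
    op2 <- .lcmm_optim(op1$par, prep, G, ctrl$max_iter)
    o <- .lcmm_obj(op2$par, prep, G, want_grad = TRUE)
    if (!is.finite(o$value)) next
    if (any(colSums(o$post) < ctrl$min_class_size)) next
    conv <- list(
      param = max(abs(op2$par - op1$par)) < ctrl$tol_param,
      loglik = abs(op2$value - op1$value) < ctrl$tol_loglik,
      gradient = mean(o$grad^2) < ctrl$tol_grad)
    best <- list(theta = op2$par, obj = o, conv = conv)
    break
  }
  if (is.null(best))
    stop("no multi-start candidate converged to an admissible solution")

  par <- .lcmm_unpack(best$theta, G, prep$p, prep$K)
  # stable labelling: classes ordered by decreasing estimated proportion
  pi_g <- unname(exp(best$obj$logpi))
  ord <- order(pi_g, decreasing = TRUE)
  pi_g <- pi_g[ord]
  params <- list(xi = (log(pi_g) - log(pi_g[G]))[seq_len(max(G - 1L, 0L))],
                 pi = pi_g,
                 beta = par$beta[, ord, drop = FALSE],
                 sigma = abs(par$s)[ord],
                 w = par$w, sigma_eps = 1)
  post <- best$obj$post[, ord, drop = FALSE]
  dimnames(post) <- list(prep$ids, paste0("class", seq_len(G)))
  npar <- .lcmm_npar(G, prep$p, prep$K)
  link <- spec$link; link$w <- params$w
  structure(list(
    params = params, link = link, tbasis = prep$tbasis,
    loglik = best$obj$value, n_params = npar,
    AIC = -2 * best$obj$value + 2 * npar,
    BIC = -2 * best$obj$value + npar * log(prep$N),
    converged = all(unlist(best$conv)), criteria = best$conv,
    posterior = post, modal_class = max.col(post, ties.method = "first"),
    n_subjects = prep$N, n_obs = prep$n_obs, spec = spec),
    class = "lcmm_fit")
}

#' @export
print.lcmm_fit <- function(x, ...) {
  G <- length(x$params$pi)
  cat(sprintf("LCMM fit: G = %d classes, %d subjects, %d observations\n",
              G, x$n_subjects, x$n_obs))
  cat(sprintf("  loglik %.3f | AIC %.1f | BIC %.1f | converged: %s\n",
              x$loglik, x$AIC, x$BIC, x$converged))
  cat("  class proportions:", paste(sprintf("%.3f", x$params$pi), collapse = " "),
      "\n  random-intercept SDs:",
      paste(sprintf("%.3f", x$params$sigma), collapse = " "), "\n")
  invisible(x)
}

#' Predicted mean trajectory of a latent class
#'
#' On the latent scale the mean trajectory is the spline curve
#' \eqn{X(t)\beta_g}. On the natural (intensity) scale the marginal mean
#' \eqn{E[H^{-1}(X(t)\beta_g + u + \epsilon)]}, with
#' \eqn{u+\epsilon \sim N(0, \sigma_g^2 + 1)}, is computed by Gauss-Hermite
#' quadrature and is bounded by the link's boundary knots.
#'
#' @param fit an [lcmm_fit()] result.
#' @param class class index in 1..G.
#' @param times years before the index date.
#' @param scale `"latent"` or `"natural"`.
#' @param gh_nodes Gauss-Hermite node count for the natural scale.
#' @return numeric vector of predictions at `times`.
#' @export
predict_trajectory <- function(fit, class, times,
                               scale = c("latent", "natural"),
                               gh_nodes = fit$spec$control$gh_nodes) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "lcmm_fit"), class >= 1,
            class <= length(fit$params$pi))
  X <- ncs_design(times, fit$tbasis)
  mu <- drop(X %*% fit$params$beta[, class])
  if (scale == "latent") return(mu)
  if (sum(fit$link$w^2) <= 0) stop("degenerate flat link")
  gh <- pracma::gaussHermite(gh_nodes)
  sd_tot <- sqrt(fit$params$sigma[class]^2 + fit$params$sigma_eps^2)
  vapply(mu, function(m) {
    z <- m + sqrt(2) * sd_tot * gh$x
    sum(gh$w * link_inverse(z, fit$link)) / sqrt(pi)
  }, numeric(1))
}
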