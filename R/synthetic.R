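#' Generating truth for a synthetic trajectory case-control dataset
#'
#' Holds every parameter of the generating process so that recovery can be
#' scored: class proportions, per-class latent trajectory coefficients on
#' the natural-cubic-spline time basis, class-specific random-intercept and
#' measurement-error SDs, class-specific exposure-window distributions, and
#' the disease model (class log-odds plus confounder effects). Observed
#' intensities are the latent values truncated at zero, so zeros arise
#' structurally — from pre-initiation and post-cessation years and from
#' truncation — as they do in lifetime exposure histories.
#'
#' @param pi class proportions (sum to 1).
#' @param beta p x G matrix of latent trajectory coefficients on `tbasis`
#'   (p = `tbasis$n_basis`); an intercept-only column is a flat plateau.
#' @param sigma length-G random-intercept SDs (>= 0).
#' @param window data.frame with one row per class and columns
#'   `first_min`, `first_max` (years before index of first exposure) and
#'   `cess_min`, `cess_max` (years before index of cessation; 0 = exposed
#'   up to the index date).
#' @param theta length-G class log-odds of disease relative to baseline.
#' @param alpha baseline log-odds of disease.
#' @param gamma_age log-odds per year of age (centred at 60).
#' @param sigma_eps measurement-error SD on the latent scale.
#' @param tbasis a [time_basis()] with explicit boundary knots.
#' @param label free-text description.
#' @return object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(pi, beta, sigma, window, theta,
                            alpha = -1, gamma_age = 0, sigma_eps = 1,
                            tbasis = time_basis(boundary_knots = c(0, 50)),
                            label = "") {
  G <- length(pi)
  beta <- as.matrix(beta)
  stopifnot(abs(sum(pi) - 1) < 1e-8, all(sigma >= 0), ncol(beta) == G,
            nrow(beta) == tbasis$n_basis, nrow(window) == G,
            length(theta) == G, sigma_eps >= 0,
            all(window$first_min <= window$first_max),
            all(window$cess_min <= window$cess_max),
            all(window$cess_max < window$first_min))
  structure(list(pi = pi, beta = beta, sigma = sigma, window = window,
                 theta = theta, alpha = alpha, gamma_age = gamma_age,
                 sigma_eps = sigma_eps, tbasis = tbasis, label = label,
                 G = G),
            class = "synthetic_truth")
}

.expit <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic case-control dataset with latent-class structure
#'
#' For each subject: a class is drawn from the truth's proportions; an
#' exposure window (first exposure and cessation, in whole years before the
#' index date) from the class's window distribution; latent values
#' \eqn{\Lambda(t) = X(t)\beta_g + u_i} with \eqn{u_i \sim N(0,\sigma_g^2)};
#' observed annual intensities \eqn{Y = \max(0, \Lambda + \epsilon)} inside
#' the window and 0 in interruption years after cessation — giving
#' right-skewed series with a point mass at zero. Disease status is
#' Bernoulli with log-odds `alpha + theta[g] + gamma_age (age - 60)`.
#' Identical `(truth, n, seed)` reproduce the dataset exactly.
#'
#' @param truth a [synthetic_truth()].
#' @param n number of subjects (>= 10 per class).
#' @param seed integer seed.
#' @return list: `subjects` (subject_id, outcome, age_index, stratum,
#'   index_year, never_exposed), `series` (long: subject_id, t, value),
#'   `labels` (true class per subject), `truth`.
#' @export
generate_trajectories <- function(truth, n, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), n >= truth$G * 10)
  set.seed(seed)
  G <- truth$G
  cls <- sample.int(G, n, replace = TRUE, prob = truth$pi)
  age <- round(pmin(75, pmax(40, stats::rnorm(n, 60, 8))))
  stratum <- sample(LETTERS[1:4], n, replace = TRUE)
  ids <- sprintf("S%04d", seq_len(n))
  series <- vector("list", n)
  for (i in seq_len(n)) {
    g <- cls[i]
    wn <- truth$window[g, ]
    t_first <- round(stats::runif(1, wn$first_min, wn$first_max))
    t_cess <- round(stats::runif(1, wn$cess_min, wn$cess_max))
    tt <- seq(t_first, 0)
    u <- stats::rnorm(1, 0, truth$sigma[g])
    mu <- drop(ncs_design(tt, truth$tbasis) %*% truth$beta[, g])
    y <- pmax(0, mu + u + stats::rnorm(length(tt), 0, truth$sigma_eps))
    y[tt < t_cess] <- 0
    series[[i]] <- data.frame(subject_id = ids[i], t = tt, value = y)
  }
  lp <- truth$alpha + truth$theta[cls] + truth$gamma_age * (age - 60)
  subjects <- data.frame(
    subject_id = ids, outcome = stats::rbinom(n, 1, .expit(lp)),
    age_index = age, stratum = stratum, index_year = 2005L,
    never_exposed = FALSE)
  list(subjects = subjects, series = do.call(rbind, series),
       labels = cls, truth = truth)
}

# intercept-only coefficient column for a flat plateau at `level`
.flat_beta <- function(level, tbasis) c(level, rep(0, tbasis$n_basis - 1L))

#' Well-separated recovery presets
#'
#' Small generating truths used for parameter-recovery validation: flat
#' plateau classes whose latent means are several total SDs apart
#' (`sqrt(sigma_g^2 + sigma_eps^2)` about 2.2, plateau gaps >= 10), all
#' subjects exposed up to the index date. `preset_two_class()` has plateaus
#' 8 and 22 cig/day; `preset_three_class()` has 5, 15 and 28 cig/day.
#'
#' @return a [synthetic_truth()].
#' @export
preset_two_class <- function() {
  tb <- time_basis(boundary_knots = c(0, 50))
  synthetic_truth(
    pi = c(0.6, 0.4),
    beta = cbind(.flat_beta(8, tb), .flat_beta(22, tb)),
    sigma = c(2, 2),
    window = data.frame(first_min = c(25, 25), first_max = c(45, 45),
                        cess_min = 0, cess_max = 0),
    theta = c(0, 1.2), alpha = -1, tbasis = tb,
    label = "two flat classes, 8 vs 22 cig/day")
}

#' @rdname preset_two_class
#' @export
preset_three_class <- function() {
  tb <- time_basis(boundary_knots = c(0, 50))
  synthetic_truth(
    pi = c(0.4, 0.35, 0.25),
    beta = cbind(.flat_beta(5, tb), .flat_beta(15, tb), .flat_beta(28, tb)),
    sigma = c(2, 2, 2),
    window = data.frame(first_min = rep(25, 3), first_max = rep(45, 3),
                        cess_min = 0, cess_max = 0),
    theta = c(0, 0.8, 1.6), alpha = -1, tbasis = tb,
    label = "three flat classes, 5/15/28 cig/day")
}

#' Study-like generating presets
#'
#' Qualitative presets whose class shapes follow the trajectory profiles
#' typically reported for lifetime smoking and occupational asbestos
#' exposure: a majority class with constant moderate intensity, plus
#' classes whose high-intensity episodes sit recently, long-term, or
#' distantly before the index date — the timing carried by class-specific
#' exposure-window distributions around flat plateaus. The smoking preset
#' has 4 classes with plateaus 8/15/25/22 cig/day; the asbestos preset has
#' 4 modelled classes (0.2/0.4/0.45/0.2 f/mL) plus a very-low-exposure
#' class near 0.005 f/mL intended for the a priori CIE partition. Used for
#' demonstrations and qualitative checks; not calibrated to reproduce any
#' study's estimates.
#'
#' @param exposure `"smoking"` or `"asbestos"`.
#' @return a [synthetic_truth()].
#' @export
icarelike_preset <- function(exposure = c("smoking", "asbestos")) {
  exposure <- match.arg(exposure)
  tb <- time_basis(boundary_knots = c(0, 50))
  if (exposure == "smoking") {
    synthetic_truth(
      pi = c(0.521, 0.229, 0.127, 0.122) / sum(c(0.521, 0.229, 0.127, 0.122)),
      beta = cbind(.flat_beta(8, tb), .flat_beta(15, tb),
                   .flat_beta(25, tb), .flat_beta(22, tb)),
      sigma = c(2, 2, 3, 3),
      window = data.frame(
        first_min = c(25, 18, 38, 45), first_max = c(50, 22, 42, 50),
        cess_min = c(0, 0, 8, 28), cess_max = c(10, 2, 12, 32)),
      theta = c(0, 0.7, 1.8, 1.4), alpha = -1.5,
      sigma_eps = 1.5, tbasis = tb,
      label = "4-class smoking-like preset")
  } else {
    synthetic_truth(
      pi = c(0.45, 0.12, 0.18, 0.11, 0.14),
      beta = cbind(.flat_beta(0.2, tb), .flat_beta(0.4, tb),
                   .flat_beta(0.45, tb), .flat_beta(0.2, tb),
                   .flat_beta(0.005, tb)),
      sigma = c(0.05, 0.08, 0.08, 0.05, 0.002),
      window = data.frame(
        first_min = c(25, 18, 32, 45, 20), first_max = c(50, 22, 38, 50, 40),
        cess_min = c(0, 8, 13, 28, 0), cess_max = c(10, 12, 17, 32, 5)),
      theta = c(0.3, 0.5, 0.8, 0.6, 0.1), alpha = -1.2,
      sigma_eps = 0.08, tbasis = tb,
      label = "5-class asbestos-like preset (class 5 = very low exposure)")
  }
}

#' Generate stage-2 data with known class posteriors and log-odds
#'
#' Exercises the posterior-weighted logistic stage against a known truth
#' without refitting the LCMM: each exposed subject's class is drawn from
#' `pi` and summarised by a Gaussian class score with unit SD and class
#' means `separation` apart; the posterior matrix is the exact Bayes
#' posterior of the class given the score, so it has the calibrated
#' uncertainty a well-discriminating trajectory model produces (the default
#' separation 5 gives relative entropy near 0.97, the discrimination level
#' a well-fitting trajectory model attains). Disease status is drawn from the
#' true class log-odds; never-exposed subjects form the reference.
#'
#' @param n total subjects.
#' @param theta length-G true class log-odds relative to never-exposed.
#' @param alpha baseline log-odds in the never-exposed class.
#' @param pi class proportions among the exposed.
#' @param p_never fraction never exposed.
#' @param separation distance between adjacent class score means, in score
#'   SD units.
#' @param seed integer seed.
#' @return list: `subjects`, `posterior` (exposed only), `reference_ids`,
#'   `labels` (true class, NA for never exposed).
#' @export
generate_association_data <- function(n, theta, alpha = -1,
                                      pi = rep(1 / length(theta), length(theta)),
                                      p_never = 0.3, separation = 5, seed = 1) {
  set.seed(seed)
  G <- length(theta)
  stopifnot(length(pi) == G, abs(sum(pi) - 1) < 1e-8)
  never <- stats::runif(n) < p_never
  cls <- ifelse(never, NA, sample.int(G, n, replace = TRUE, prob = pi))
  ids <- sprintf("A%05d", seq_len(n))
  exposed <- which(!never)
  score <- stats::rnorm(length(exposed), separation * (cls[exposed] - 1), 1)
  logd <- vapply(seq_len(G), function(g)
    log(pi[g]) + stats::dnorm(score, separation * (g - 1), 1, log = TRUE),
    numeric(length(exposed)))
  post <- exp(logd - apply(logd, 1, max))
  post <- post / rowSums(post)
  rownames(post) <- ids[exposed]
  colnames(post) <- paste0("class", seq_len(G))
  age <- round(pmin(75, pmax(40, stats::rnorm(n, 60, 8))))
  lp <- alpha + ifelse(never, 0, theta[cls])
  subjects <- data.frame(
    subject_id = ids, outcome = stats::rbinom(n, 1, .expit(lp)),
    age_index = age, stratum = sample(LETTERS[1:4], n, replace = TRUE),
    never_exposed = never)
  list(subjects = subjects, posterior = post,
       reference_ids = ids[never], labels = cls)
}
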