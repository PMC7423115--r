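subjects_fixture <- function(n = 40, seed = 61) {
  set.seed(seed)
  data.frame(subject_id = sprintf("P%03d", seq_len(n)),
             outcome = rep(0:1, length.out = n),
             age_index = round(runif(n, 45, 74)),
             stratum = rep(c("A", "B"), length.out = n))
}

test_that("weighted expansion replicates subjects with conserved weight", {
  sub <- subjects_fixture(6)
  post <- rbind(c(0.7, 0.3), c(0.5, 0.5), c(1, 0))
  rownames(post) <- sub$subject_id[1:3]
  rec <- expand_weighted(sub, post, reference_ids = sub$subject_id[4:5],
                         a_priori_ids = sub$subject_id[6])
  r1 <- rec[rec$subject_id == sub$subject_id[1], ]
  expect_equal(nrow(r1), 2)
  expect_equal(r1$weight, c(0.7, 0.3))
  expect_equal(as.character(r1$class), c("class1", "class2"))
  rnever <- rec[rec$subject_id == sub$subject_id[4], ]
  expect_equal(nrow(rnever), 1)
  expect_equal(rnever$weight, 1)
  expect_equal(as.character(rnever$class), "never")
  expect_equal(as.character(rec$class[rec$subject_id == sub$subject_id[6]]), "low")
  expect_equal(sum(rec$weight), 6)
  expect_error(expand_weighted(sub, post, reference_ids = sub$subject_id[4]),
               "exactly one")
})

test_that("fractional polynomial transforms follow the power conventions", {
  # x' = 2 with repeated powers (-2,-2)
  m <- fp_transform(c(2, 4), powers = c(-2, -2), shift = 0, scale = 1)
  expect_equal(unname(m[1, ]), c(0.25, 0.25 * log(2)))
  expect_equal(unname(fp_transform(exp(1), 0, shift = 0, scale = 1)[1, 1]), 1)
  # age 61, shift 0, scale 10, powers (-2,-2)
  a <- fp_transform(61, c(-2, -2), shift = 0, scale = 10)
  expect_equal(unname(a[1, ]), c(6.1^-2, 6.1^-2 * log(6.1)))
  # distinct powers give two plain columns; power 0.5/3 as in CSI adjustment
  b <- fp_transform(4, c(0.5, 3), shift = 0, scale = 1)
  expect_equal(unname(b[1, ]), c(2, 64))
  # automatic shift makes nonpositive data positive
  cc <- fp_transform(c(0, 1, 5), 0)
  expect_true(all(is.finite(cc)))
  expect_error(fp_transform(c(-1, -1), 1, shift = 0), "not positive")
})

test_that("weighted logistic reproduces the 2x2 closed form and crisp limit", {
  rec <- data.frame(subject_id = seq_len(30),
                    outcome = c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10)),
                    exposed = c(rep(1, 15), rep(0, 15)), weight = 1)
  m <- weighted_logistic(rec, outcome ~ exposed)
  expect_equal(m$coef_table$OR[m$coef_table$term == "exposed"], 4,
               tolerance = 1e-8)

  # crisp 0/1 posteriors equal an unweighted fit on modal classes
  sub <- subjects_fixture(40)
  set.seed(3)
  modal <- sample(1:2, 40, replace = TRUE)
  post <- cbind(as.numeric(modal == 1), as.numeric(modal == 2))
  rownames(post) <- sub$subject_id
  rec2 <- expand_weighted(sub, post, reference_ids = character(0))
  rec2$class <- droplevels(rec2$class)  # no never-exposed in this fixture
  mw <- weighted_logistic(rec2, outcome ~ class)
  sub$class <- factor(paste0("class", modal))
  mu <- stats::glm(outcome ~ class, binomial, sub)
  expect_equal(mw$coef_table$estimate, unname(coef(mu)), tolerance = 1e-8)

  # halving the weights leaves estimates, widens naive intervals
  rech <- rec; rech$weight <- 0.5
  mh <- weighted_logistic(rech, outcome ~ exposed)
  expect_equal(mh$coef_table$estimate, m$coef_table$estimate, tolerance = 1e-8)
  expect_gt(mh$coef_table$se_naive[2], m$coef_table$se_naive[2])
  expect_error(weighted_logistic(transform(rec, weight = 2), outcome ~ exposed),
               "weights")
})

test_that("uniform weights attenuate class contrasts relative to crisp ones", {
  d <- generate_association_data(1500, theta = c(0.5, 1.5), seed = 71)
  crisp_rec <- expand_weighted(d$subjects, d$posterior, d$reference_ids)
  m_crisp <- weighted_logistic(crisp_rec, outcome ~ class)
  G <- ncol(d$posterior)
  unif <- matrix(1 / G, nrow(d$posterior), G, dimnames = dimnames(d$posterior))
  m_unif <- weighted_logistic(
    expand_weighted(d$subjects, unif, d$reference_ids), outcome ~ class)
  b_crisp <- m_crisp$coef_table$estimate[grep("class", m_crisp$coef_table$term)]
  b_unif <- m_unif$coef_table$estimate[grep("class", m_unif$coef_table$term)]
  expect_lt(max(b_unif) - min(b_unif) + 1e-9, max(b_crisp) - min(b_crisp))
})

test_that("mutual-adjustment strategies behave as designed", {
  set.seed(81)
  d <- generate_association_data(1200, theta = c(0.6, 1.2), seed = 81)
  # an independent second exposure: posteriors and dose unrelated to outcome
  n <- nrow(d$subjects)
  ids <- d$subjects$subject_id
  other_cls <- sample(1:2, n, replace = TRUE)
  other_post <- cbind(as.numeric(other_cls == 1), as.numeric(other_cls == 2))
  rownames(other_post) <- ids
  exposure <- list(posterior = d$posterior, reference_ids = d$reference_ids)
  other <- list(posterior = other_post, reference_ids = character(0),
                dose = stats::setNames(rexp(n, 1) + 0.01, ids),
                dose_powers = 0)
  cmp <- compare_adjustments(d$subjects, exposure, other)
  expect_named(cmp, c("none", "dose", "class", "aic"))
  expect_equal(nrow(cmp$aic), 3)
  est <- function(m) m$coef_table$estimate[
    m$coef_table$term %in% c("classclass1", "classclass2")]
  # with an outcome-independent second exposure all strategies agree
  expect_lt(max(abs(est(cmp$none) - est(cmp$dose))), 0.15)
  expect_lt(max(abs(est(cmp$none) - est(cmp$class))), 0.15)
  # determinism: same inputs give identical AICs
  cmp2 <- compare_adjustments(d$subjects, exposure, other)
  expect_identical(cmp$aic$AIC, cmp2$aic$AIC)
  # constant dose collapses strategy (ii) onto (i)
  other_const <- other
  other_const$dose <- stats::setNames(rep(1, n), ids)
  cmp3 <- compare_adjustments(d$subjects, exposure, other_const)
  expect_equal(cmp3$dose$loglik, cmp3$none$loglik, tolerance = 1e-8)
  # modal-assignment variant also runs
  cmp4 <- compare_adjustments(d$subjects, exposure, other, joint_mode = "modal")
  expect_equal(nrow(cmp4$aic), 3)
})
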