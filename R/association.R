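#' Expand subjects into posterior-probability-weighted records
#'
#' Builds the stage-2 dataset for weighted logistic regression. Each
#' LCMM-classified subject contributes one record per latent class, weighted
#' by the posterior probability of belonging to it; subjects assigned a
#' priori to a class (e.g. the very-low-cumulative-exposure class) and
#' never-exposed subjects each contribute a single record with weight 1.
#' Never-exposed subjects form the reference level of the class factor.
#'
#' @param subjects data.frame with at least `subject_id` and `outcome`
#'   (0/1); any further columns (age, stratum, doses) are carried through.
#' @param posterior N x G matrix with subject ids as row names; rows sum
#'   to 1.
#' @param reference_ids ids of never-exposed subjects.
#' @param a_priori_ids ids assigned a priori to their own class (weight 1).
#' @param a_priori_label factor label for the a priori class.
#' @return data.frame of weighted records: the subject columns plus `class`
#'   (factor, reference level `"never"`) and `weight`. Total weight equals
#'   the number of subjects.
#' @export
expand_weighted <- function(subjects, posterior, reference_ids,
                            a_priori_ids = NULL, a_priori_label = "low") {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "outcome") %in% names(subjects)))
  posterior <- as.matrix(posterior)
  if (is.null(rownames(posterior)))
    stop("posterior needs subject ids as row names")
  if (any(abs(rowSums(posterior) - 1) > 1e-8))
    stop("posterior rows must sum to 1")
  ids <- as.character(subjects$subject_id)
  sets <- list(modelled = rownames(posterior),
               reference = as.character(reference_ids),
               a_priori = as.character(a_priori_ids))
  hits <- sapply(sets, function(s) ids %in% s)
  if (any(rowSums(hits) != 1))
    stop("each subject must be in exactly one of posterior / reference / a priori sets")
  G <- ncol(posterior)
  lev <- c("never", paste0("class", seq_len(G)),
           if (!is.null(a_priori_ids)) a_priori_label)
  blocks <- lapply(seq_len(nrow(subjects)), function(i) {
    row <- subjects[i, , drop = FALSE]
    id <- ids[i]
    if (hits[i, "reference"]) {
      cbind(row, class = "never", weight = 1)
    } else if (hits[i, "a_priori"]) {
      cbind(row, class = a_priori_label, weight = 1)
    } else {
      p <- posterior[id, ]
      keep <- p > 0
      cbind(row[rep(1, sum(keep)), , drop = FALSE],
            class = paste0("class", which(keep)), weight = unname(p[keep]))
    }
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$class <- factor(out$class, levels = lev)
  out
}

#' Fractional-polynomial transformation
#'
#' Transforms a positive covariate by fractional-polynomial powers from the
#' standard set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}: power 0 denotes the
#' natural logarithm, and a repeated power (p, p) expands to
#' \eqn{x^p} and \eqn{x^p \ln x}. Before transformation the variable is
#' shifted to positivity (Royston-Altman rule: the smallest increment
#' between adjacent distinct values minus the minimum, when the minimum is
#' not positive) and scaled by a power of 10 of its range, so the
#' transformed columns are numerically well conditioned.
#'
#' @param x numeric covariate.
#' @param powers one (degree 1) or two (degree 2) powers.
#' @param shift,scale optional constants overriding the automatic rule.
#' @return matrix with one column per term; attributes `shift`, `scale` and
#'   `powers` record the transformation so it can be replayed on new data.
#' @export
fp_transform <- function(x, powers, shift = NULL, scale = NULL) {
  stopifnot(length(powers) %in% 1:2)
  if (is.null(shift)) {
    if (min(x) > 0) shift <- 0
    else {
      ux <- sort(unique(x))
      inc <- if (length(ux) > 1) min(diff(ux)) else 1
      shift <- inc - min(x)
    }
  }
  xs <- x + shift
  if (any(xs <= 0)) stop("covariate not positive after shifting")
  if (is.null(scale)) {
    r <- diff(range(xs))
    scale <- if (r > 0) 10^floor(log10(r)) else 1
  }
  xs <- xs / scale
  one <- function(p) if (p == 0) log(xs) else xs^p
  if (length(powers) == 1) {
    out <- cbind(one(powers[1]))
  } else if (powers[1] == powers[2]) {
    out <- cbind(one(powers[1]), one(powers[1]) * log(xs))
  } else {
    out <- cbind(one(powers[1]), one(powers[2]))
  }
  colnames(out) <- paste0("fp", seq_len(ncol(out)))
  attr(out, "shift") <- shift; attr(out, "scale") <- scale
  attr(out, "powers") <- powers
  out
}

#' Posterior-probability-weighted logistic regression
#'
#' Maximises the weighted Bernoulli log-likelihood
#' \eqn{\sum_r w_r [y_r \ln \mu_r + (1-y_r)\ln(1-\mu_r)]} over the expanded
#' record set. Because weighting replicates subjects across records, the
#' default confidence intervals use a sandwich (robust) variance clustered
#' by subject; naive information-based intervals are also reported for
#' comparison. AIC is computed from the weighted log-likelihood.
#'
#' @param records expanded data, e.g. from [expand_weighted()]; must
#'   contain the response and `weight`, plus a `subject_id` column used as
#'   the default cluster.
#' @param formula model formula, e.g. `outcome ~ class + fp1 + fp2 + stratum`.
#' @param cluster clustering vector for the sandwich variance (default
#'   `records$subject_id`).
#' @param level confidence level.
#' @return object of class `"assoc_fit"`: coefficient table with odds
#'   ratios and both CI flavours, weighted log-likelihood, `AIC`, and the
#'   underlying `glm`.
#' @export
weighted_logistic <- function(records, formula, cluster = records$subject_id,
                              level = 0.95) {
  stopifnot(is.data.frame(records), "weight" %in% names(records))
  if (any(records$weight <= 0 | records$weight > 1))
    stop("weights must be in (0, 1]")
  y <- stats::model.response(stats::model.frame(formula, records))
  if (length(unique(y)) < 2) stop("need both cases and controls")
  fit <- suppressWarnings(
    stats::glm(formula, family = stats::binomial(), data = records,
               weights = weight))  # 'weight' resolved in 'records'
  cf <- stats::coef(fit)
  # separation guard on 0/1 indicator columns (class and stratum dummies);
  # continuous FP columns can carry large coefficients legitimately
  mm <- stats::model.matrix(fit)
  is_ind <- apply(mm, 2, function(v) all(v %in% 0:1)) & colnames(mm) != "(Intercept)"
  if (any(abs(cf[is_ind][!is.na(cf[is_ind])]) > 15))
    stop("separation detected: |coefficient| > 15; check sparse classes")
  mu <- stats::fitted(fit)
  ll <- sum(records$weight * (y * log(mu) + (1 - y) * log(1 - mu)))
  k <- sum(!is.na(cf))
  vc_rob <- sandwich::vcovCL(fit, cluster = cluster)
  # aliased (collinear) terms keep their row with NA standard errors
  se_rob <- se_nai <- stats::setNames(rep(NA_real_, length(cf)), names(cf))
  se_rob[colnames(vc_rob)] <- sqrt(diag(vc_rob))
  vc_nai <- stats::vcov(fit)
  se_nai[colnames(vc_nai)] <- sqrt(diag(vc_nai))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab <- data.frame(
    term = names(cf), estimate = unname(cf),
    se_robust = unname(se_rob), se_naive = unname(se_nai),
    OR = exp(unname(cf)),
    ci_lo = exp(unname(cf - z * se_rob)), ci_hi = exp(unname(cf + z * se_rob)),
    ci_lo_naive = exp(unname(cf - z * se_nai)),
    ci_hi_naive = exp(unname(cf + z * se_nai)))
  structure(list(coef_table = tab, loglik = ll, AIC = -2 * ll + 2 * k,
                 n_records = nrow(records), glm = fit, level = level,
                 vcov_robust = vc_rob),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("Weighted logistic fit: %d records, weighted loglik %.3f, AIC %.1f\n",
              x$n_records, x$loglik, x$AIC))
  tab <- x$coef_table
  tab[, -1] <- round(tab[, -1], 4)
  print(tab[, c("term", "OR", "ci_lo", "ci_hi")], row.names = FALSE)
  invisible(x)
}

# joint expansion over the cross-classification of two exposures; weights
# are products of the two posterior memberships (classifications treated as
# independent given the data), or modal assignment for the second exposure.
.expand_joint <- function(subjects, exp_a, exp_b, mode = c("product", "modal")) {
  mode <- match.arg(mode)
  ra <- expand_weighted(subjects, exp_a$posterior, exp_a$reference_ids,
                        exp_a$a_priori_ids, exp_a$a_priori_label %||% "low")
  names(ra)[names(ra) == "class"] <- "class_a"
  pb <- as.matrix(exp_b$posterior)
  if (mode == "modal") {
    m <- max.col(pb, ties.method = "first")
    pb <- matrix(0, nrow(pb), ncol(pb), dimnames = dimnames(pb))
    pb[cbind(seq_len(nrow(pb)), m)] <- 1
  }
  lev_b <- c("never", paste0("class", seq_len(ncol(pb))),
             if (!is.null(exp_b$a_priori_ids)) exp_b$a_priori_label %||% "low")
  blocks <- lapply(seq_len(nrow(ra)), function(i) {
    row <- ra[i, , drop = FALSE]
    id <- as.character(row$subject_id)
    if (id %in% as.character(exp_b$reference_ids)) {
      cbind(row, class_b = "never")
    } else if (id %in% as.character(exp_b$a_priori_ids)) {
      cbind(row, class_b = exp_b$a_priori_label %||% "low")
    } else {
      p <- pb[id, ]
      keep <- p > 0
      out <- cbind(row[rep(1, sum(keep)), , drop = FALSE],
                   class_b = paste0("class", which(keep)))
      out$weight <- out$weight * unname(p[keep])
      out
    }
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$class_b <- factor(out$class_b, levels = lev_b)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare the three mutual-adjustment strategies
#'
#' Fits, for one exposure's trajectory classes, the three stage-2 models
#' considered for mutual adjustment between two exposures: (i) no mutual
#' adjustment, (ii) adjustment for the cumulative dose of the other
#' exposure at the index date (fractional-polynomial transformed), and
#' (iii) adjustment for the other exposure's trajectory-class membership,
#' where the joint expansion weights each (class, other-class) record by
#' the product of posterior probabilities (or by modal assignment of the
#' other exposure). All models adjust for the supplied confounder terms.
#' Strategies are compared by AIC of the weighted likelihood.
#'
#' @param subjects data.frame with `subject_id`, `outcome`, and every
#'   covariate named in `adjust_terms`.
#' @param exposure list describing the primary exposure:
#'   `posterior` (matrix, rownames = ids), `reference_ids`, optional
#'   `a_priori_ids` and `a_priori_label`.
#' @param other same structure for the other exposure, plus `dose`: named
#'   vector of its cumulative dose (CIE or CSI) per subject, and
#'   `dose_powers`: FP powers for strategy (ii).
#' @param adjust_terms right-hand-side terms shared by all three models
#'   (e.g. `c("age_fp1", "age_fp2", "stratum")`).
#' @param joint_mode `"product"` (default) or `"modal"` weighting for
#'   strategy (iii).
#' @return list with the three `"assoc_fit"`s (`none`, `dose`, `class`) and
#'   an `aic` table.
#' @export
compare_adjustments <- function(subjects, exposure, other,
                                adjust_terms = character(0),
                                joint_mode = c("product", "modal")) {
  joint_mode <- match.arg(joint_mode)
  rhs <- paste(c("class", adjust_terms), collapse = " + ")
  rec1 <- expand_weighted(subjects, exposure$posterior,
                          exposure$reference_ids, exposure$a_priori_ids,
                          exposure$a_priori_label %||% "low")
  f1 <- stats::as.formula(paste("outcome ~", rhs))
  m_none <- weighted_logistic(rec1, f1)

  dose <- other$dose[as.character(rec1$subject_id)]
  fp <- fp_transform(unname(dose), other$dose_powers %||% 0)
  rec2 <- rec1
  for (j in seq_len(ncol(fp))) rec2[[paste0("dose_fp", j)]] <- fp[, j]
  f2 <- stats::as.formula(paste("outcome ~", rhs, "+",
                                paste(paste0("dose_fp", seq_len(ncol(fp))),
                                      collapse = " + ")))
  m_dose <- weighted_logistic(rec2, f2)

  rec3 <- .expand_joint(subjects, exposure, other, mode = joint_mode)
  names(rec3)[names(rec3) == "class_a"] <- "class"
  f3 <- stats::as.formula(paste("outcome ~", rhs, "+ class_b"))
  m_class <- weighted_logistic(rec3, f3)

  list(none = m_none, dose = m_dose, class = m_class,
       aic = data.frame(strategy = c("none", "dose", "class"),
                        AIC = c(m_none$AIC, m_dose$AIC, m_class$AIC)))
}
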